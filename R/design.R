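# Candidate primer/probe enumeration under hard design constraints and
# scoring against the soft selection criteria, replacing manual triage of
# designer output with an auditable ranking.

#' Hard design constraints for candidate enumeration
#'
#' The constraint set a designer feeds a primer-design engine: product size,
#' oligo size, primer and probe melting-temperature windows, and GC range,
#' each with an optimum used for tie-breaking.
#'
#' @param product_size Amplicon length range (bp).
#' @param oligo_size Primer/probe length range (bp) and `oligo_size_opt` its
#'   optimum.
#' @param oligo_size_opt Optimal oligo length.
#' @param primer_tm,primer_tm_opt Primer Tm range and optimum (degC).
#' @param probe_tm,probe_tm_opt Probe Tm range and optimum (degC).
#' @param gc,gc_opt GC content range and optimum (percent).
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(product_size = c(100, 200),
                               oligo_size = c(18, 27), oligo_size_opt = 20,
                               primer_tm = c(58, 63), primer_tm_opt = 60,
                               probe_tm = c(68, 73), probe_tm_opt = 70,
                               gc = c(35, 65), gc_opt = 50) {
  chk <- function(rng, opt, nm) {
    if (length(rng) != 2L || rng[1] > rng[2]) stop(nm, " range must be c(min, max)")
    if (opt < rng[1] || opt > rng[2]) stop(nm, " optimum outside its range")
  }
  chk(oligo_size, oligo_size_opt, "oligo_size")
  chk(primer_tm, primer_tm_opt, "primer_tm")
  chk(probe_tm, probe_tm_opt, "probe_tm")
  chk(gc, gc_opt, "gc")
  if (length(product_size) != 2L || product_size[1] > product_size[2]) {
    stop("product_size range must be c(min, max)")
  }
  structure(list(product_size = product_size,
                 oligo_size = oligo_size, oligo_size_opt = oligo_size_opt,
                 primer_tm = primer_tm, primer_tm_opt = primer_tm_opt,
                 probe_tm = probe_tm, probe_tm_opt = probe_tm_opt,
                 gc = gc, gc_opt = gc_opt),
            class = "design_constraints")
}

#' Soft selection criteria for scoring candidate assays
#'
#' The eight-point checklist used to choose among feasible candidates:
#' primer Tm agreement, probe-over-primer Tm elevation, homopolymer runs,
#' and the 3'/5'-end composition rules. Primer-specific rules must hold for
#' both primers to count as satisfied.
#'
#' @param max_primer_delta_tm Maximum |Tm(F) - Tm(R)| (degC, strictly less).
#' @param probe_delta_tm Window (degC) for probe Tm minus the primer Tm mean.
#' @param max_homopolymer Longest allowed single-base run in any oligo.
#' @param forbid_t_3prime Disallow T at a primer 3' terminus.
#' @param require_cg_3prime Require C or G at a primer 3' terminus.
#' @param min_cg_last5 Minimum C/G count among the 5 terminal primer bases.
#' @param forbid_g_5prime_probe Disallow G at the probe 5' terminus (avoids
#'   fluorophore quenching).
#' @param min_probe_gc Probe GC content must strictly exceed this (percent).
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(max_primer_delta_tm = 5,
                               probe_delta_tm = c(8, 10),
                               max_homopolymer = 3,
                               forbid_t_3prime = TRUE,
                               require_cg_3prime = TRUE,
                               min_cg_last5 = 3,
                               forbid_g_5prime_probe = TRUE,
                               min_probe_gc = 50) {
  stopifnot(is.finite(max_primer_delta_tm), length(probe_delta_tm) == 2L,
            probe_delta_tm[1] <= probe_delta_tm[2], max_homopolymer >= 1)
  structure(list(max_primer_delta_tm = max_primer_delta_tm,
                 probe_delta_tm = probe_delta_tm,
                 max_homopolymer = max_homopolymer,
                 forbid_t_3prime = forbid_t_3prime,
                 require_cg_3prime = require_cg_3prime,
                 min_cg_last5 = min_cg_last5,
                 forbid_g_5prime_probe = forbid_g_5prime_probe,
                 min_probe_gc = min_probe_gc),
            class = "selection_criteria")
}

#' Define a complete hydrolysis-probe assay
#'
#' An F/R/P oligo triple plus protocol metadata: final concentrations,
#' annealing temperature, and the instrument Cq threshold.
#'
#' @param forward,reverse,probe [oligo] objects (roles are checked) or plain
#'   sequences.
#' @param name Assay label.
#' @param concentration_uM Named numeric, final concentrations in micromolar
#'   for `forward`, `reverse`, `probe`.
#' @param ta_C Annealing temperature (degC), between 50 and 72.
#' @param cq_threshold Instrument fluorescence threshold (metadata only).
#' @return An object of class `assay_definition`.
#' @export
assay_definition <- function(forward, reverse, probe, name = "assay",
                             concentration_uM = c(forward = 0.2, reverse = 0.2,
                                                  probe = 0.1),
                             ta_C = 60, cq_threshold = NULL) {
  as_oligo <- function(x, role, default_name) {
    if (inherits(x, "oligo")) {
      if (x$role != role) stop("oligo '", x$name, "' has role '", x$role,
                               "' where ", role, " was expected")
      x
    } else {
      oligo(default_name, x, role)
    }
  }
  forward <- as_oligo(forward, "forward", "F")
  reverse <- as_oligo(reverse, "reverse", "R")
  probe <- as_oligo(probe, "probe", "P")
  if (any(concentration_uM <= 0)) stop("oligo concentrations must be positive")
  if (ta_C < 50 || ta_C > 72) stop("annealing temperature outside 50-72 degC")
  structure(list(name = name, forward = forward, reverse = reverse,
                 probe = probe, concentration_uM = concentration_uM,
                 ta_C = ta_C, cq_threshold = cq_threshold),
            class = "assay_definition")
}

#' @export
print.assay_definition <- function(x, ...) {
  cat(sprintf("<assay %s> Ta %.1f degC\n", x$name, x$ta_C))
  for (role in c("forward", "probe", "reverse")) print(x[[role]])
  invisible(x)
}

.criteria_labels <- c(
  primer_delta_tm = "primer Tm difference within limit",
  probe_delta_tm = "probe Tm 8-10 degC above primer mean",
  homopolymer = "no base run of 4 or more",
  no_t_3prime = "no T at primer 3' end",
  cg_3prime = "C or G at primer 3' end",
  cg_clamp_last5 = ">= 3 C/G in last 5 primer bases",
  no_g_5prime_probe = "no G at probe 5' end",
  probe_gc = "probe GC content > 50%"
)

#' Audit a candidate assay against the selection criteria
#'
#' Evaluates all eight soft selection criteria for an F/R/P triple and
#' reports, per criterion, the measured value and pass/fail. The two primer
#' 3'-end composition rules and the T/homopolymer rules are evaluated for
#' both primers (and, for homopolymers, the probe) and pass only if every
#' oligo concerned passes. Idempotent and independent of any candidate-list
#' context.
#'
#' @param assay An [assay_definition], or a list with `forward`, `reverse`,
#'   `probe` oligos.
#' @param criteria A [selection_criteria].
#' @param thermo A [thermo_params] for the Tm-based criteria.
#' @return A data.frame with columns `criterion`, `description`, `measured`,
#'   `pass`, and attribute `n_satisfied` (0-8).
#' @export
score_candidate <- function(assay, criteria = selection_criteria(),
                            thermo = thermo_params()) {
  stopifnot(inherits(criteria, "selection_criteria"))
  f <- assay$forward$sequence; r <- assay$reverse$sequence
  p <- assay$probe$sequence
  tm <- vapply(c(f, r, p), melting_temperature, numeric(1), params = thermo)
  f3 <- three_prime_report(f); r3 <- three_prime_report(r)
  runs <- vapply(c(f, r, p), max_homopolymer_run, numeric(1))
  gc_p <- gc_content(p)
  d_primer <- abs(tm[1] - tm[2])
  d_probe <- tm[3] - mean(tm[1:2])
  pass <- c(
    primer_delta_tm = d_primer < criteria$max_primer_delta_tm,
    probe_delta_tm = d_probe >= criteria$probe_delta_tm[1] &&
      d_probe <= criteria$probe_delta_tm[2],
    homopolymer = max(runs) <= criteria$max_homopolymer,
    no_t_3prime = !criteria$forbid_t_3prime ||
      (!f3$terminal_is_t && !r3$terminal_is_t),
    cg_3prime = !criteria$require_cg_3prime ||
      (f3$terminal_is_cg && r3$terminal_is_cg),
    cg_clamp_last5 = f3$cg_in_last5 >= criteria$min_cg_last5 &&
      r3$cg_in_last5 >= criteria$min_cg_last5,
    no_g_5prime_probe = !criteria$forbid_g_5prime_probe ||
      substr(p, 1, 1) != "G",
    probe_gc = gc_p > criteria$min_probe_gc
  )
  measured <- c(
    sprintf("%.2f", d_primer), sprintf("%.2f", d_probe),
    sprintf("%d", max(runs)),
    sprintf("F:%s R:%s", f3$terminal_base, r3$terminal_base),
    sprintf("F:%s R:%s", f3$terminal_base, r3$terminal_base),
    sprintf("F:%d R:%d", f3$cg_in_last5, r3$cg_in_last5),
    substr(p, 1, 1), sprintf("%.1f", gc_p)
  )
  out <- data.frame(criterion = names(.criteria_labels),
                    description = unname(.criteria_labels),
                    measured = measured, pass = unname(pass),
                    row.names = NULL)
  attr(out, "n_satisfied") <- sum(pass)
  out
}

# window property table used by enumeration: one row per (start, len)
# window, with everything the hard constraints and soft criteria inspect
.window_table <- function(template, sizes, thermo) {
  L <- nchar(template)
  rows <- list()
  for (len in seq(sizes[1], sizes[2])) {
    if (len > L) next
    starts <- seq_len(L - len + 1L)
    seqs <- substring(template, starts, starts + len - 1L)
    clean <- !vapply(seqs, has_ambiguity, logical(1))
    tm <- gc <- rep(NA_real_, length(seqs))
    tm[clean] <- vapply(seqs[clean], melting_temperature, numeric(1),
                        params = thermo)
    gc[clean] <- vapply(seqs[clean], gc_content, numeric(1))
    run <- vapply(seqs, max_homopolymer_run, numeric(1), USE.NAMES = FALSE)
    first <- substring(seqs, 1L, 1L)
    last <- substring(seqs, len, len)
    tails <- strsplit(substring(seqs, len - 4L, len), "", fixed = TRUE)
    last5_cg <- vapply(tails, function(b) sum(b %in% c("C", "G")), numeric(1))
    # reverse-complement view of the same window (the reverse-primer oligo):
    # its 3' tail is the revcomp of the window's first five bases
    heads <- strsplit(substring(seqs, 1L, 5L), "", fixed = TRUE)
    rc_last5_cg <- vapply(heads, function(b) sum(b %in% c("C", "G")), numeric(1))
    rc_last <- unname(.complement_map[first])
    rows[[length(rows) + 1L]] <- data.frame(
      start = starts, len = len, end = starts + len - 1L,
      seq = seqs, clean = clean, tm = tm, gc = gc, run = run,
      first = first, last = last, last5_cg = last5_cg,
      rc_last = rc_last, rc_last5_cg = rc_last5_cg,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Enumerate candidate primer/probe triples from a template
#'
#' Exhaustively places forward primer, probe, and reverse primer footprints
#' on a template, keeping only triples where every hard constraint holds:
#' product size, oligo sizes, primer/probe Tm windows, GC range, and a probe
#' strictly between the primer footprints on the plus strand. Survivors are
#' scored against the soft [selection_criteria] and ranked.
#'
#' Coordinates are 1-based and inclusive; a reverse primer's coordinate is
#' the plus-strand position paired with its 5' base, so the product length
#' is `r_coord - f_coord + 1` (the naming convention `287F`, `437R`).
#'
#' @param template Template sequence (plain string or single-record
#'   character from [read_fasta()]); windows containing ambiguity codes are
#'   skipped, not errors.
#' @param constraints A [design_constraints].
#' @param thermo A [thermo_params].
#' @param criteria A [selection_criteria] used for scoring.
#' @param top_n Maximum number of ranked candidates to return (`Inf` for
#'   all). The default 10 mirrors typical designer output.
#' @return A data.frame of candidates (one per row) with coordinates,
#'   sequences, Tm, GC, product length, per-criterion pass flags
#'   (`crit_*`), `n_criteria`, and tie-break deviations. When no candidate
#'   is feasible the frame has zero rows and carries a per-constraint
#'   rejection histogram in `attr(, "rejections")`. Deterministic; no
#'   randomness is involved.
#' @export
enumerate_candidates <- function(template, constraints = design_constraints(),
                                 thermo = thermo_params(),
                                 criteria = selection_criteria(),
                                 top_n = 10) {
  stopifnot(inherits(constraints, "design_constraints"))
  if (length(template) != 1L) stop("template must be a single sequence")
  template <- normalize_sequence(template, allow_ambiguity = TRUE,
                                 what = "template")
  L <- nchar(template)
  if (L < constraints$product_size[1]) {
    stop("template (", L, " bp) shorter than minimum product size (",
         constraints$product_size[1], " bp)")
  }
  win <- .window_table(template, constraints$oligo_size, thermo)
  rej <- c(ambiguous_window = sum(!win$clean),
           primer_tm = 0, primer_gc = 0, probe_tm = 0, probe_gc = 0,
           product_size = 0, no_probe_room = 0)
  ok <- win$clean
  gc_ok <- ok & win$gc >= constraints$gc[1] & win$gc <= constraints$gc[2]
  primer_tm_ok <- ok & win$tm >= constraints$primer_tm[1] &
    win$tm <= constraints$primer_tm[2]
  probe_tm_ok <- ok & win$tm >= constraints$probe_tm[1] &
    win$tm <= constraints$probe_tm[2]
  rej["primer_tm"] <- sum(ok & !primer_tm_ok)
  rej["primer_gc"] <- sum(primer_tm_ok & !gc_ok)
  rej["probe_tm"] <- sum(ok & !probe_tm_ok)
  rej["probe_gc"] <- sum(probe_tm_ok & !gc_ok)
  primers <- win[primer_tm_ok & gc_ok, , drop = FALSE]
  probes <- win[probe_tm_ok & gc_ok, , drop = FALSE]
  fi_acc <- ri_acc <- pi_acc <- list()
  if (nrow(primers) && nrow(probes)) {
    p_start <- probes$start; p_end <- probes$end
    f_starts <- primers$start; f_ends <- primers$end
    for (i in seq_len(nrow(primers))) {
      fs <- f_starts[i]; fe <- f_ends[i]
      # reverse-primer windows: product length = window end - f start + 1
      prod_len <- f_ends - fs + 1L
      downstream <- f_starts > fe
      in_prod <- prod_len >= constraints$product_size[1] &
        prod_len <= constraints$product_size[2]
      rej["product_size"] <- rej["product_size"] + sum(downstream & !in_prod)
      p_ok_left <- p_start > fe
      for (j in which(downstream & in_prod)) {
        pk <- which(p_ok_left & p_end < f_starts[j])
        if (!length(pk)) {
          rej["no_probe_room"] <- rej["no_probe_room"] + 1
          next
        }
        k <- length(fi_acc) + 1L
        fi_acc[[k]] <- rep.int(i, length(pk))
        ri_acc[[k]] <- rep.int(j, length(pk))
        pi_acc[[k]] <- pk
      }
    }
  }
  if (!length(fi_acc)) {
    empty <- data.frame(f_start = integer(0), f_len = integer(0),
                        f_seq = character(0), tm_f = numeric(0),
                        gc_f = numeric(0), p_start = integer(0),
                        p_len = integer(0), p_seq = character(0),
                        tm_p = numeric(0), gc_p = numeric(0),
                        r_start = integer(0), r_len = integer(0),
                        r_seq = character(0), tm_r = numeric(0),
                        gc_r = numeric(0), product_length = integer(0))
    attr(empty, "rejections") <- rej
    return(empty)
  }
  fi <- unlist(fi_acc); ri <- unlist(ri_acc); pi <- unlist(pi_acc)
  cand <- .score_triples(primers, probes, fi, ri, pi, criteria, constraints)
  cand <- rank_candidates(cand)
  if (is.finite(top_n)) cand <- utils::head(cand, top_n)
  # materialize sequences only for the returned rows
  cand$f_seq <- primers$seq[cand$.fi]
  cand$p_seq <- probes$seq[cand$.pi]
  r_rc <- vapply(primers$seq, reverse_complement, character(1),
                 USE.NAMES = FALSE)
  cand$r_seq <- r_rc[cand$.ri]
  cand$.fi <- cand$.ri <- cand$.pi <- NULL
  first <- c("rank", "f_start", "f_len", "f_seq", "tm_f", "gc_f",
             "p_start", "p_len", "p_seq", "tm_p", "gc_p",
             "r_start", "r_len", "r_seq", "tm_r", "gc_r", "product_length")
  cand <- cand[, c(first, setdiff(names(cand), first)), drop = FALSE]
  attr(cand, "rejections") <- rej
  cand
}

# vectorized criteria evaluation over index triples into the window table
# (same rules as score_candidate; the reverse primer is the reverse
# complement of its window, hence the rc_* columns)
.score_triples <- function(primers, probes, fi, ri, pi, criteria, constraints) {
  tm_f <- primers$tm[fi]; tm_r <- primers$tm[ri]; tm_p <- probes$tm[pi]
  gc_f <- primers$gc[fi]; gc_r <- primers$gc[ri]; gc_p <- probes$gc[pi]
  d_primer <- abs(tm_f - tm_r)
  d_probe <- tm_p - (tm_f + tm_r) / 2
  tf <- primers$last[fi]; tr <- primers$rc_last[ri]
  cand <- data.frame(
    f_start = primers$start[fi], f_len = primers$len[fi],
    tm_f = tm_f, gc_f = gc_f,
    p_start = probes$start[pi], p_len = probes$len[pi],
    tm_p = tm_p, gc_p = gc_p,
    r_start = primers$end[ri], r_len = primers$len[ri],
    tm_r = tm_r, gc_r = gc_r,
    product_length = primers$end[ri] - primers$start[fi] + 1L,
    crit_primer_delta_tm = d_primer < criteria$max_primer_delta_tm,
    crit_probe_delta_tm = d_probe >= criteria$probe_delta_tm[1] &
      d_probe <= criteria$probe_delta_tm[2],
    # a homopolymer run survives reverse complementation, so the window's
    # run length stands in for the reverse primer's
    crit_homopolymer = pmax(primers$run[fi], primers$run[ri],
                            probes$run[pi]) <= criteria$max_homopolymer,
    crit_no_t_3prime = !criteria$forbid_t_3prime | (tf != "T" & tr != "T"),
    crit_cg_3prime = !criteria$require_cg_3prime |
      (tf %in% c("C", "G") & tr %in% c("C", "G")),
    crit_cg_clamp_last5 = primers$last5_cg[fi] >= criteria$min_cg_last5 &
      primers$rc_last5_cg[ri] >= criteria$min_cg_last5,
    crit_no_g_5prime_probe = !criteria$forbid_g_5prime_probe |
      probes$first[pi] != "G",
    crit_probe_gc = gc_p > criteria$min_probe_gc,
    stringsAsFactors = FALSE, row.names = NULL)
  crit_cols <- grep("^crit_", names(cand), value = TRUE)
  cand$n_criteria <- rowSums(cand[crit_cols])
  cand$tm_dev <- abs(tm_f - constraints$primer_tm_opt) +
    abs(tm_r - constraints$primer_tm_opt) +
    abs(tm_p - constraints$probe_tm_opt)
  cand$gc_dev <- abs(gc_f - constraints$gc_opt) +
    abs(gc_r - constraints$gc_opt) +
    abs(gc_p - constraints$gc_opt)
  cand$.fi <- fi; cand$.ri <- ri; cand$.pi <- pi
  cand
}

#' Rank scored candidates
#'
#' Stable sort by criteria satisfied (descending), then total deviation of
#' oligo Tm from optimum, then GC deviation, then product length -- so for
#' fixed input content the output order is deterministic regardless of
#' input order.
#'
#' @param cand A scored candidate data.frame from [enumerate_candidates()].
#' @return The reordered data.frame.
#' @export
rank_candidates <- function(cand) {
  if (!nrow(cand)) return(cand)
  stopifnot(all(c("n_criteria", "tm_dev", "gc_dev", "product_length") %in%
                  names(cand)))
  key <- order(-cand$n_criteria, cand$tm_dev, cand$gc_dev,
               cand$product_length, cand$f_start, cand$f_len,
               cand$r_start, cand$r_len, cand$p_start, cand$p_len,
               method = "radix")
  out <- cand[key, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  out
}
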