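# In-silico specificity screening: mismatch-tolerant binding-site location,
# per-sequence amplification prediction, and per-group mismatch summaries.
# Matching is ungapped (Hamming) within oligo-length footprints; IUPAC
# ambiguity in the subject counts as a match iff the oligo base lies in the
# code's expansion.

.subject_bits <- function(subject) {
  unname(.iupac_bits[.seq_chars(subject)])
}

# mismatch count per start position of oligo against subject (plus strand)
.hamming_profile <- function(oligo_bits, subject_bits) {
  m <- length(oligo_bits)
  L <- length(subject_bits)
  if (L < m) return(integer(0))
  n_win <- L - m + 1L
  mm <- integer(n_win)
  for (j in seq_len(m)) {
    mm <- mm + as.integer(bitwAnd(subject_bits[j:(j + n_win - 1L)],
                                  oligo_bits[j]) == 0L)
  }
  mm
}

#' Locate binding sites of an oligo in a subject sequence
#'
#' Slides the oligo over both strands of the subject and reports every
#' footprint with at most `max_mismatches` Hamming mismatches. Footprint
#' start positions are 1-based on the subject's plus strand; mismatch
#' positions are in oligo coordinates (5' to 3'). For primers the report
#' notes whether the 3'-terminal base matches, since extension is
#' 3'-sensitive.
#'
#' @param olig An [oligo] (no ambiguity codes) or plain sequence.
#' @param subject Subject DNA (IUPAC ambiguity allowed; codes match
#'   permissively).
#' @param max_mismatches Mismatch budget (>= 0).
#' @return A data.frame with columns `role`, `strand`, `start`,
#'   `mismatches`, `mismatch_positions` (comma-separated, oligo
#'   coordinates), `three_prime_match`; sorted by mismatches then position.
#'   An oligo longer than the subject yields zero rows.
#' @export
find_binding_sites <- function(olig, subject, max_mismatches = 5) {
  stopifnot(max_mismatches >= 0)
  role <- if (inherits(olig, "oligo")) olig$role else "forward"
  oseq <- if (inherits(olig, "oligo")) olig$sequence else
    normalize_sequence(olig, allow_ambiguity = FALSE, what = "oligo")
  if (has_ambiguity(oseq)) stop("ambiguity codes are not allowed in oligos")
  subject <- normalize_sequence(subject, allow_ambiguity = TRUE,
                                what = "subject")
  m <- nchar(oseq)
  sbits <- .subject_bits(subject)
  hits <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") oseq else reverse_complement(oseq)
    obits <- unname(.iupac_bits[.seq_chars(qseq)])
    mm <- .hamming_profile(obits, sbits)
    sel <- which(mm <= max_mismatches)
    if (!length(sel)) next
    pos_list <- vapply(sel, function(st) {
      bad <- which(bitwAnd(sbits[st:(st + m - 1L)], obits) == 0L)
      if (strand == "-") bad <- sort(m - bad + 1L)  # back to oligo coords
      paste(bad, collapse = ",")
    }, character(1))
    # 3'-terminal oligo base: last footprint position on +, first on -
    tpm <- if (strand == "+") {
      bitwAnd(sbits[sel + m - 1L], obits[m]) > 0L
    } else {
      bitwAnd(sbits[sel], obits[1L]) > 0L
    }
    hits[[strand]] <- data.frame(
      role = role, strand = strand, start = sel,
      mismatches = mm[sel], mismatch_positions = pos_list,
      three_prime_match = if (role == "probe") NA else tpm,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(hits)) {
    return(data.frame(role = character(0), strand = character(0),
                      start = integer(0), mismatches = integer(0),
                      mismatch_positions = character(0),
                      three_prime_match = logical(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$mismatches, out$start, out$strand, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screening policy for amplification prediction
#'
#' @param max_mismatches Per-oligo mismatch budgets, named `forward`,
#'   `reverse`, `probe` (a single number is recycled). Default 5, the
#'   conventional cap for compiling candidate cross-reactors.
#' @param product_range Allowed predicted amplicon length (bp); defaults to
#'   the design range 100-200.
#' @param require_three_prime_match If TRUE a primer site only counts when
#'   its 3'-terminal base matches. Off by default.
#' @return An object of class `screening_policy`.
#' @export
screening_policy <- function(max_mismatches = 5,
                             product_range = c(100, 200),
                             require_three_prime_match = FALSE) {
  if (length(max_mismatches) == 1L) {
    max_mismatches <- c(forward = max_mismatches, reverse = max_mismatches,
                        probe = max_mismatches)
  }
  stopifnot(all(c("forward", "reverse", "probe") %in% names(max_mismatches)),
            all(max_mismatches >= 0),
            length(product_range) == 2L, product_range[1] <= product_range[2])
  structure(list(max_mismatches = max_mismatches,
                 product_range = product_range,
                 require_three_prime_match = require_three_prime_match),
            class = "screening_policy")
}

#' Predict whether an assay amplifies a subject sequence
#'
#' A subject is predicted positive when a forward-primer site on the plus
#' strand and a reverse-primer site on the minus strand flank a product of
#' allowed length, and a probe site (either strand) lies strictly inside
#' that product, all within per-oligo mismatch budgets. Among multiple site
#' combinations the one with minimal total mismatches is reported.
#'
#' @param assay An [assay_definition].
#' @param subject Subject DNA sequence.
#' @param policy A [screening_policy].
#' @return A one-row data.frame: `positive`, the chosen site coordinates
#'   and mismatch counts (`f_start`, `f_mm`, `r_start`, `r_mm`, `p_start`,
#'   `p_strand`, `p_mm`), `product_length`, and `reason` (`""` when
#'   positive; otherwise `no F`, `no R`, `wrong orientation`,
#'   `product out of range`, or `no P`).
#' @export
predict_amplification <- function(assay, subject,
                                  policy = screening_policy()) {
  stopifnot(inherits(assay, "assay_definition"),
            inherits(policy, "screening_policy"))
  budgets <- policy$max_mismatches
  negative <- function(reason) data.frame(
    positive = FALSE, f_start = NA_integer_, f_mm = NA_integer_,
    r_start = NA_integer_, r_mm = NA_integer_, p_start = NA_integer_,
    p_strand = NA_character_, p_mm = NA_integer_,
    product_length = NA_integer_, reason = reason)

  fh <- find_binding_sites(assay$forward, subject, budgets[["forward"]])
  fh <- fh[fh$strand == "+", , drop = FALSE]
  if (policy$require_three_prime_match) fh <- fh[fh$three_prime_match, , drop = FALSE]
  if (!nrow(fh)) return(negative("no F"))
  rh <- find_binding_sites(assay$reverse, subject, budgets[["reverse"]])
  rh <- rh[rh$strand == "-", , drop = FALSE]
  if (policy$require_three_prime_match) rh <- rh[rh$three_prime_match, , drop = FALSE]
  if (!nrow(rh)) return(negative("no R"))
  ph <- find_binding_sites(assay$probe, subject, budgets[["probe"]])

  lf <- nchar(assay$forward$sequence)
  lr <- nchar(assay$reverse$sequence)
  lp <- nchar(assay$probe$sequence)
  pairs <- expand.grid(fi = seq_len(nrow(fh)), ri = seq_len(nrow(rh)))
  f_start <- fh$start[pairs$fi]
  r_end <- rh$start[pairs$ri] + lr - 1L   # plus-strand 5' coord of R
  prod <- r_end - f_start + 1L
  oriented <- f_start < r_end
  if (!any(oriented)) return(negative("wrong orientation"))
  in_range <- oriented & prod >= policy$product_range[1] &
    prod <= policy$product_range[2]
  if (!any(in_range)) return(negative("product out of range"))

  best <- NULL
  idx <- which(in_range)
  idx <- idx[order(fh$mismatches[pairs$fi[idx]] + rh$mismatches[pairs$ri[idx]],
                   prod[idx])]
  for (k in idx) {
    fs <- f_start[k]; re <- r_end[k]
    f_end <- fs + lf - 1L
    r_fp_start <- rh$start[pairs$ri[k]]
    cand <- ph[ph$start > f_end & (ph$start + lp - 1L) < r_fp_start, ,
               drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(cand$mismatches, cand$start), , drop = FALSE]
    total <- fh$mismatches[pairs$fi[k]] + rh$mismatches[pairs$ri[k]] +
      cand$mismatches[1]
    if (is.null(best) || total < best$total) {
      best <- list(total = total, fi = pairs$fi[k], ri = pairs$ri[k],
                   p = cand[1, ], prod = prod[k])
    }
  }
  if (is.null(best)) return(negative("no P"))
  data.frame(
    positive = TRUE,
    f_start = fh$start[best$fi], f_mm = fh$mismatches[best$fi],
    r_start = rh$start[best$ri] + lr - 1L, r_mm = rh$mismatches[best$ri],
    p_start = best$p$start, p_strand = best$p$strand, p_mm = best$p$mismatches,
    product_length = best$prod, reason = "")
}

#' Screen a panel of sequences against an assay
#'
#' Applies [predict_amplification()] to every sequence of a panel.
#'
#' @param assay An [assay_definition].
#' @param panel Named character vector of subject sequences (e.g. from
#'   [read_fasta()]).
#' @param policy A [screening_policy].
#' @return A data.frame with one row per sequence, `seq_id` first.
#' @export
screen_panel <- function(assay, panel, policy = screening_policy()) {
  if (is.null(names(panel))) stop("panel sequences must be named")
  res <- lapply(panel, function(s) predict_amplification(assay, s, policy))
  out <- do.call(rbind, res)
  out <- cbind(data.frame(seq_id = names(panel), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}

#' Per-group mismatch summary for an assay
#'
#' For each group of panel sequences and each oligo of the assay, the mean
#' over sequences of the minimum-mismatch binding site. Sequences with no
#' site within the cap are excluded from the mean and counted as no-hits,
#' the convention used when compiling database-wide mismatch tables.
#'
#' @param assay An [assay_definition].
#' @param panel Named character vector of sequences.
#' @param groups Named character vector mapping sequence id to group label;
#'   defaults to a single group `"all"`.
#' @param cap Mismatch cap (default 5).
#' @return A data.frame: `group`, `n`, then for each of
#'   forward/reverse/probe a `mean_mm_*` and `no_hit_*` column.
#' @export
mismatch_summary <- function(assay, panel, groups = NULL, cap = 5) {
  if (is.null(names(panel))) stop("panel sequences must be named")
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(panel)), names(panel))
  }
  missing_ids <- setdiff(names(panel), names(groups))
  if (length(missing_ids)) {
    stop("no group assigned for sequence '", missing_ids[1], "'")
  }
  roles <- c("forward", "reverse", "probe")
  min_mm <- matrix(NA_integer_, nrow = length(panel), ncol = length(roles),
                   dimnames = list(names(panel), roles))
  for (role in roles) {
    min_mm[, role] <- vapply(panel, function(s) {
      h <- find_binding_sites(assay[[role]], s, cap)
      if (nrow(h)) min(h$mismatches) else NA_integer_
    }, integer(1))
  }
  out <- lapply(split(names(panel), groups[names(panel)]), function(ids) {
    row <- list(n = length(ids))
    for (role in roles) {
      v <- min_mm[ids, role]
      row[[paste0("mean_mm_", role)]] <-
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      row[[paste0("no_hit_", role)]] <- sum(is.na(v))
    }
    as.data.frame(row)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(group = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}
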