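# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and their own lookups rather than the
# package's code paths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

rc_naive <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[chars(s)]), collapse = "")
}

# sliding-window Hamming scan on both strands; subject IUPAC codes match
# when the oligo base is in the code's expansion
oracle_find_sites <- function(oligo_seq, subject, max_mm) {
  expand <- Biostrings::IUPAC_CODE_MAP
  m <- nchar(oligo_seq)
  L <- nchar(subject)
  sub_ch <- chars(subject)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") oligo_seq else rc_naive(oligo_seq)
    q_ch <- chars(q)
    if (L >= m) {
      for (st in seq_len(L - m + 1)) {
        mm <- 0
        for (j in seq_len(m)) {
          sc <- sub_ch[st + j - 1]
          hit <- sc %in% names(expand) &&
            grepl(q_ch[j], expand[[sc]], fixed = TRUE)
          if (!hit) mm <- mm + 1
        }
        if (mm <= max_mm) {
          out[[length(out) + 1]] <- data.frame(strand = strand, start = st,
                                               mismatches = mm)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(0), start = integer(0),
                      mismatches = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$mismatches, df$start, df$strand), , drop = FALSE]
}

# exhaustive (F, P, R) placement enumeration with direct per-window checks
oracle_enumerate <- function(template, constraints, thermo) {
  L <- nchar(template)
  sizes <- seq(constraints$oligo_size[1], constraints$oligo_size[2])
  wins <- list()
  for (len in sizes) {
    if (len > L) next
    for (st in seq_len(L - len + 1)) {
      s <- substr(template, st, st + len - 1)
      if (grepl("[^ACGT]", s)) next
      wins[[length(wins) + 1]] <- list(start = st, len = len,
                                       end = st + len - 1, seq = s,
                                       tm = melting_temperature(s, thermo),
                                       gc = gc_content(s))
    }
  }
  in_rng <- function(x, rng) x >= rng[1] & x <= rng[2]
  primer_ok <- Filter(function(w) in_rng(w$tm, constraints$primer_tm) &&
                        in_rng(w$gc, constraints$gc), wins)
  probe_ok <- Filter(function(w) in_rng(w$tm, constraints$probe_tm) &&
                       in_rng(w$gc, constraints$gc), wins)
  keys <- character(0)
  for (f in primer_ok) {
    for (r in primer_ok) {
      prod <- r$end - f$start + 1
      if (r$start <= f$end) next
      if (!in_rng(prod, constraints$product_size)) next
      for (p in probe_ok) {
        if (p$start > f$end && p$end < r$start) {
          keys <- c(keys, paste(f$start, f$len, p$start, p$len,
                                r$end, r$len, sep = ":"))
        }
      }
    }
  }
  sort(keys)
}

# rule-by-rule selection-criteria check with explicit character scans
oracle_rules <- function(f, r, p, thermo) {
  tmf <- melting_temperature(f, thermo)
  tmr <- melting_temperature(r, thermo)
  tmp <- melting_temperature(p, thermo)
  longest_run <- function(s) {
    ch <- chars(s)
    best <- 1; cur <- 1
    for (i in seq_along(ch)[-1]) {
      cur <- if (ch[i] == ch[i - 1]) cur + 1 else 1
      best <- max(best, cur)
    }
    best
  }
  gc_pct <- function(s) 100 * sum(chars(s) %in% c("G", "C")) / nchar(s)
  last_base <- function(s) substr(s, nchar(s), nchar(s))
  cg5 <- function(s) sum(chars(substr(s, nchar(s) - 4, nchar(s))) %in% c("G", "C"))
  dpr <- tmp - (tmf + tmr) / 2
  c(primer_delta_tm = abs(tmf - tmr) < 5,
    probe_delta_tm = dpr >= 8 && dpr <= 10,
    homopolymer = max(longest_run(f), longest_run(r), longest_run(p)) <= 3,
    no_t_3prime = last_base(f) != "T" && last_base(r) != "T",
    cg_3prime = last_base(f) %in% c("C", "G") && last_base(r) %in% c("C", "G"),
    cg_clamp_last5 = cg5(f) >= 3 && cg5(r) >= 3,
    no_g_5prime_probe = substr(p, 1, 1) != "G",
    probe_gc = gc_pct(p) > 50)
}

# literal scan of the LOQ definition: lowest concentration fully detected
# with every higher concentration also fully detected
oracle_loq <- function(std) {
  concs <- sort(unique(std$known_conc_pg_per_ul))
  full <- vapply(concs, function(cc) {
    reps <- std$cq[std$known_conc_pg_per_ul == cc]
    all(!is.na(reps))
  }, logical(1))
  ok <- vapply(seq_along(concs), function(i) all(full[i:length(concs)]),
               logical(1))
  if (!any(ok)) return(NA_real_)
  concs[which(ok)[1]]
}

# minimal standards frame in the plate dialect
make_standards <- function(concs, cq_list) {
  rows <- list()
  for (i in seq_along(concs)) {
    cqs <- cq_list[[i]]
    rows[[i]] <- data.frame(
      sample_id = paste0("std_", concs[i]), role = "standard",
      replicate = seq_along(cqs), cq = cqs,
      known_conc_pg_per_ul = concs[i], template_ul = 2,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# random flanks around a feasible primer/probe cassette, so a candidate
# set is guaranteed non-empty
cassette_template <- function(assay, flank = 30, gap = 25) {
  paste0(random_dna(flank), assay$forward$sequence, random_dna(gap),
         assay$probe$sequence, random_dna(gap),
         rc_naive(assay$reverse$sequence), random_dna(flank))
}

# noiseless dilution-series plate from a known line
noiseless_plate <- function(slope, intercept, concs, reps = 3) {
  make_standards(concs, lapply(concs, function(cc)
    rep(intercept + slope * log10(cc), reps)))
}
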