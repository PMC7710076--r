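# Multi-sequence alignment consumption: identity, consensus, and the
# position-frequency matrices behind binding-region sequence logos.

#' Construct an alignment object
#'
#' @param seqs Named character vector of gapped sequences (gap `-`), all the
#'   same width, unique names.
#' @return An object of class `dna_alignment`.
#' @export
alignment <- function(seqs) {
  if (length(seqs) < 1L) stop("alignment needs at least one row")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("all alignment rows must be named")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate row identifier: ", names(seqs)[duplicated(names(seqs))][1])
  }
  seqs <- vapply(seqs, normalize_sequence, character(1),
                 allow_ambiguity = TRUE, what = "alignment row")
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    stop("alignment rows differ in width (", paste(unique(w), collapse = ", "), ")")
  }
  structure(seqs, class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment: %d rows x %d columns>\n",
              length(x), nchar(x[[1]])))
  invisible(x)
}

.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
}

#' Mean pairwise percent identity of an alignment
#'
#' Mean over all unordered row pairs of the fraction of matching columns,
#' counting only columns where both rows are ungapped.
#'
#' @param aln A [alignment()] with at least two rows.
#' @return Percentage in \[0, 100\].
#' @export
mean_pairwise_identity <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- length(aln)
  if (n < 2L) stop("pairwise identity requires at least two rows")
  m <- .aln_matrix(aln)
  gap <- m == "-"
  ids <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      keep <- !gap[i, ] & !gap[j, ]
      if (!any(keep)) next
      ids <- c(ids, mean(m[i, keep] == m[j, keep]))
    }
  }
  if (!length(ids)) stop("no comparable (mutually ungapped) columns in any pair")
  100 * mean(ids)
}

# minimal IUPAC code covering a base set
.iupac_cover <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  keys <- vapply(strsplit(unname(map), ""), function(b)
    paste(sort(b), collapse = ""), character(1))
  stats::setNames(names(map), keys)
})

#' Consensus sequence of an alignment
#'
#' Per column: the base whose relative frequency (among ungapped rows)
#' reaches `threshold`; otherwise the minimal IUPAC ambiguity code covering
#' every base observed in the column. Columns gapped in at least half the
#' rows are dropped; rarer gaps are ignored.
#'
#' @param aln A [alignment()].
#' @param threshold Call threshold in (0.5, 1].
#' @return Ungapped consensus string.
#' @export
consensus_sequence <- function(aln, threshold = 1.0) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  m <- .aln_matrix(aln)
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (mean(col == "-") >= 0.5) next
    col <- col[col != "-"]
    tab <- table(factor(col, levels = DNA_BASES))
    freq <- tab / sum(tab)
    top <- which.max(freq)
    out[length(out) + 1L] <- if (freq[top] >= threshold) {
      DNA_BASES[top]
    } else {
      .iupac_cover[[paste(sort(DNA_BASES[freq > 0]), collapse = "")]]
    }
  }
  paste(out, collapse = "")
}

.hamming <- function(a, b) sum(a != b)

# Locate an oligo's binding window in one ungapped row.
# Returns ungapped start or NA; tries exact, then <=1 mismatch, then the best
# ungapped match if under max_frac mismatches.
.locate_window <- function(row_ungapped, oligo_seq, max_frac = 0.30) {
  m <- nchar(oligo_seq)
  L <- nchar(row_ungapped)
  if (L < m) return(NA_integer_)
  oc <- .seq_chars(oligo_seq)
  rc <- .seq_chars(row_ungapped)
  n_win <- L - m + 1L
  mism <- integer(n_win)
  for (j in seq_len(m)) {
    mism <- mism + (rc[j:(j + n_win - 1L)] != oc[j])
  }
  best <- which.min(mism)
  if (mism[best] <= 1L) return(best)
  if (mism[best] / m <= max_frac) return(best)
  NA_integer_
}

#' Binding-region position frequency matrix
#'
#' Locates an oligo's binding region in each alignment row and tabulates
#' per-column base frequencies over the oligo-length window -- the data
#' behind a conservation sequence logo. Windows are reported in the oligo's
#' own 5' to 3' orientation: for reverse primers the plus-strand window is
#' reverse-complemented. When the region cannot be located in any row the
#' matrix is empty and flagged `no_contigs` (not an error), mirroring the
#' "no contigs found" outcome of screening a conserved primer against a
#' divergent non-target family.
#'
#' @param aln A [alignment()].
#' @param olig An [oligo]; reverse-role oligos are searched as their reverse
#'   complement on the plus strand.
#' @return An object of class `pfm`: a 4 x width matrix of relative
#'   frequencies (rows A, C, G, T) with attributes `label`, `n_rows`
#'   (rows in which the window was anchored), and `no_contigs`.
#' @export
window_frequencies <- function(aln, olig) {
  stopifnot(inherits(aln, "dna_alignment"), inherits(olig, "oligo"))
  probe_seq <- if (olig$role == "reverse") reverse_complement(olig$sequence) else olig$sequence
  m <- nchar(probe_seq)
  rows <- unclass(aln)
  # anchor the window in each row, mapped back to alignment columns
  col_windows <- list()
  for (id in names(rows)) {
    ch <- .seq_chars(rows[[id]])
    resid_cols <- which(ch != "-")
    ung <- paste(ch[resid_cols], collapse = "")
    s <- .locate_window(ung, probe_seq)
    if (!is.na(s)) col_windows[[id]] <- resid_cols[s:(s + m - 1L)]
  }
  if (!length(col_windows)) {
    mat <- matrix(numeric(0), nrow = 4, ncol = 0,
                  dimnames = list(DNA_BASES, NULL))
    return(structure(mat, label = olig$name, n_rows = 0L,
                     no_contigs = TRUE, class = "pfm"))
  }
  # use the most common column window as the frame
  keys <- vapply(col_windows, paste, character(1), collapse = ",")
  frame <- col_windows[[which(keys == names(which.max(table(keys))))[1]]]
  mat <- .aln_matrix(aln)[, frame, drop = FALSE]
  counts <- apply(mat, 2, function(col)
    table(factor(col[col %in% DNA_BASES], levels = DNA_BASES)))
  freqs <- apply(counts, 2, function(x) if (sum(x) > 0) x / sum(x) else x * 0)
  rownames(freqs) <- DNA_BASES
  if (olig$role == "reverse") {
    freqs <- freqs[, rev(seq_len(ncol(freqs))), drop = FALSE]
    rownames(freqs) <- unname(.complement_map[rownames(freqs)])
    freqs <- freqs[DNA_BASES, , drop = FALSE]
  }
  colnames(freqs) <- seq_len(ncol(freqs))
  structure(freqs, label = olig$name, n_rows = length(col_windows),
            no_contigs = FALSE, class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  if (isTRUE(attr(x, "no_contigs"))) {
    cat(sprintf("<pfm %s: no contigs found>\n", attr(x, "label")))
  } else {
    cat(sprintf("<pfm %s: %d positions, %d rows anchored>\n",
                attr(x, "label"), ncol(x), attr(x, "n_rows")))
    print(round(unclass(x), 3))
  }
  invisible(x)
}

#' Count variable positions in a position frequency matrix
#'
#' Number of columns whose maximum base frequency is below 1, i.e. positions
#' where the aligned sequences disagree.
#'
#' @param pfm A `pfm` from [window_frequencies()].
#' @return Integer count.
#' @export
count_variable_positions <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"))
  if (ncol(pfm) == 0L) stop("empty matrix (no contigs found)")
  sum(apply(unclass(pfm), 2, max) < 1 - 1e-9)
}

#' Write a position frequency matrix as TSV
#'
#' Columns are positions (1-based, 5' to 3' in oligo orientation), rows are
#' the A/C/G/T relative frequencies -- a format logo-plotting tools consume
#' directly.
#'
#' @param pfm A `pfm`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  stopifnot(inherits(pfm, "pfm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ednaqpcr %s; pfm=%s; no_contigs=%s",
                     as.character(utils::packageVersion("ednaqpcr")),
                     attr(pfm, "label"), attr(pfm, "no_contigs")), con)
  df <- data.frame(base = rownames(pfm), unclass(pfm), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a position frequency matrix as a simple sequence logo
#'
#' Stacked per-position letters sized by relative frequency. Requires
#' ggplot2.
#'
#' @param pfm A `pfm`.
#' @return A ggplot object.
#' @export
plot_pfm <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_pfm requires the ggplot2 package")
  }
  if (ncol(pfm) == 0L) stop("empty matrix (no contigs found)")
  df <- do.call(rbind, lapply(seq_len(ncol(pfm)), function(j) {
    f <- unclass(pfm)[, j]
    f <- f[f > 0]
    f <- sort(f)
    data.frame(pos = j, base = names(f), freq = unname(f),
               y = cumsum(unname(f)) - unname(f) / 2)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = pos, y = y,
                                   label = base, colour = base)) +
    ggplot2::geom_text(ggplot2::aes(size = freq), fontface = "bold",
                       show.legend = FALSE) +
    ggplot2::scale_size(range = c(1, 6)) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(pfm))) +
    ggplot2::labs(x = "position (5' to 3')", y = "relative frequency",
                  title = attr(pfm, "label")) +
    ggplot2::theme_minimal()
}
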