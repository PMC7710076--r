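# Sequence primitives and per-oligo physical properties.

DNA_BASES <- c("A", "C", "G", "T")

# bitmask encoding of IUPAC codes: A=1, C=2, G=4, T=8
.iupac_bits <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  bits <- vapply(strsplit(unname(map), ""), function(b) {
    sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[b])
  }, integer(1))
  names(bits) <- names(map)
  c(bits, "-" = 0L, "." = 0L)
})

.complement_map <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", "-" = "-"
)

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Normalize a DNA string: uppercase, U -> T (warning), validate alphabet.
normalize_sequence <- function(s, allow_ambiguity = FALSE, what = "sequence") {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  s <- toupper(s)
  if (grepl("U", s, fixed = TRUE)) {
    warning(what, " contains U; mapped to T", call. = FALSE)
    s <- gsub("U", "T", s, fixed = TRUE)
  }
  permitted <- if (allow_ambiguity) names(.iupac_bits) else DNA_BASES
  ch <- .seq_chars(s)
  bad <- which(!ch %in% permitted)
  if (length(bad)) {
    stop(what, " has invalid character '", ch[bad[1]], "' at position ",
         bad[1], call. = FALSE)
  }
  s
}

has_ambiguity <- function(s) {
  any(!.seq_chars(s) %in% c(DNA_BASES, "-"))
}

#' Construct an oligonucleotide
#'
#' An oligo is a named single-stranded DNA sequence with a role in a
#' hydrolysis-probe assay. Names may encode the 1-based 5' coordinate of the
#' oligo on its design template plus a role suffix, following the common
#' `287F` / `362P` / `437R` convention; when such a suffix is present it must
#' agree with `role`.
#'
#' @param name Oligo label, e.g. `"287F"`.
#' @param sequence DNA string written 5' to 3'. Uppercased on input; `U` is
#'   mapped to `T` with a warning. IUPAC ambiguity codes are rejected unless
#'   `allow_ambiguity = TRUE`.
#' @param role One of `"forward"`, `"reverse"`, `"probe"`.
#' @param reporter,quencher Optional fluorophore / quencher labels for probes
#'   (e.g. `"FAM"`, `"BHQ"`).
#' @param allow_ambiguity Permit IUPAC ambiguity codes in the sequence.
#' @return An object of class `oligo`.
#' @examples
#' oligo("287F", "GCCGCTCCATTAGATCACGA", "forward")
#' @export
oligo <- function(name, sequence, role = c("forward", "reverse", "probe"),
                  reporter = NULL, quencher = NULL, allow_ambiguity = FALSE) {
  role <- match.arg(role)
  sequence <- normalize_sequence(sequence, allow_ambiguity, what = paste0("oligo '", name, "'"))
  if (nchar(sequence) < 1L) stop("oligo sequence must be non-empty")
  suffix <- regmatches(name, regexpr("[FRPfrp]$", name))
  if (length(suffix) == 1L) {
    expected <- c(forward = "F", reverse = "R", probe = "P")[[role]]
    if (toupper(suffix) != expected) {
      stop("oligo name '", name, "' has role suffix '", suffix,
           "' but role is '", role, "'")
    }
  }
  structure(
    list(name = name, sequence = sequence, role = role,
         reporter = reporter, quencher = quencher),
    class = "oligo"
  )
}

#' @export
print.oligo <- function(x, ...) {
  lab <- if (x$role == "probe" && !is.null(x$reporter)) {
    sprintf(" [%s-%s]", x$reporter, if (is.null(x$quencher)) "?" else x$quencher)
  } else ""
  cat(sprintf("<oligo %s (%s)%s> 5'-%s-3' (%d nt)\n",
              x$name, x$role, lab, x$sequence, nchar(x$sequence)))
  invisible(x)
}

#' 1-based 5' template coordinate encoded in an oligo name
#'
#' Oligo names conventionally encode the 5' position of the oligo on its
#' design template plus a role suffix (`287F`, `437R`). For a reverse
#' primer the coordinate is the plus-strand position paired with the
#' primer's 5' base, so an amplicon's length is `R - F + 1` under the
#' inclusive-span convention.
#'
#' @param x An [oligo] or a name string.
#' @return Integer coordinate, or `NA` when the name encodes none.
#' @examples
#' oligo_coordinate("437R") - oligo_coordinate("287F") + 1 # 151
#' @export
oligo_coordinate <- function(x) {
  nm <- if (inherits(x, "oligo")) x$name else x
  m <- regmatches(nm, regexpr("^[0-9]+", nm))
  if (length(m) == 1L) as.integer(m) else NA_integer_
}

.oligo_seq <- function(x, what = "oligo") {
  if (inherits(x, "oligo")) x$sequence
  else normalize_sequence(x, allow_ambiguity = TRUE, what = what)
}

#' Thermodynamic conditions for melting-temperature calculation
#'
#' Defaults reproduce the solution conditions assumed by mainstream primer
#' design software: 50 mM monovalent cation, 1.5 mM divalent cation, 0.6 mM
#' dNTP, and 50 nM total oligo. Divalent cations are folded into a sodium
#' equivalent as 120 * sqrt(divalent - dNTP) (von Ahsen correction); the
#' duplex strand term uses total oligo concentration / 4, the convention for
#' primers in vast excess of template.
#'
#' @param monovalent_mM Monovalent cation concentration (mM).
#' @param divalent_mM Divalent cation concentration (mM).
#' @param dntp_mM dNTP concentration (mM).
#' @param oligo_nM Total oligo concentration (nM).
#' @param nn_set Nearest-neighbor parameter set; only `"santalucia1998"`
#'   (the unified parameters) is implemented.
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(monovalent_mM = 50, divalent_mM = 1.5,
                          dntp_mM = 0.6, oligo_nM = 50,
                          nn_set = "santalucia1998") {
  stopifnot(monovalent_mM >= 0, divalent_mM >= 0, dntp_mM >= 0, oligo_nM > 0)
  nn_set <- match.arg(nn_set, "santalucia1998")
  structure(
    list(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
         dntp_mM = dntp_mM, oligo_nM = oligo_nM, nn_set = nn_set),
    class = "thermo_params"
  )
}

#' GC content of an oligo
#'
#' Percentage of G and C bases, reported to one decimal place (half-up
#' rounding, so 63.64 prints as 63.6 and 52.38 as 52.4).
#'
#' @param x An [oligo] or a plain DNA string.
#' @param mode `"strict"` rejects IUPAC ambiguity codes; `"permissive"`
#'   returns the min-max GC range implied by expanding them.
#' @return A single percentage in strict mode; a length-2 `c(min, max)`
#'   vector in permissive mode when ambiguity codes are present.
#' @examples
#' gc_content("GCCGCTCCATTAGATCACGA") # 55
#' @export
gc_content <- function(x, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  s <- .oligo_seq(x)
  if (nchar(s) == 0L) stop("sequence must be non-empty")
  ch <- .seq_chars(s)
  if (any(!ch %in% DNA_BASES)) {
    if (mode == "strict") {
      stop("ambiguity code '", ch[!ch %in% DNA_BASES][1],
           "' present; GC content requires unambiguous bases ",
           "(use mode = \"permissive\" for a range)")
    }
    bits <- .iupac_bits[ch]
    could_gc <- bitwAnd(bits, 6L) > 0L          # overlaps {C,G}
    must_gc <- bitwAnd(bits, 9L) == 0L          # excludes {A,T}
    return(c(
      min = round_half_up(100 * sum(must_gc) / length(ch), 1),
      max = round_half_up(100 * sum(could_gc) / length(ch), 1)
    ))
  }
  round_half_up(100 * sum(ch %in% c("G", "C")) / length(ch), 1)
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(mol K); each stack keyed by its top-strand dinucleotide.
.nn_unified <- local({
  dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
          CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
          CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
          CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
          CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
          CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  list(dh = dh, ds = ds)
})

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of an oligo against its perfect complement,
#' from the SantaLucia (1998) unified nearest-neighbor parameters with
#' terminal A/T and G/C initiation penalties, an entropic salt correction of
#' 0.368 (N-1) ln\[Na+eq\] cal/(mol K), and Tm = 1000 dH / (dS + R ln CT/4)
#' - 273.15 with R = 1.987 cal/(mol K).
#'
#' @param x An [oligo] or DNA string (length >= 8, no ambiguity codes).
#' @param params A [thermo_params] object.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("GCCGCTCCATTAGATCACGA") # ~60
#' @export
melting_temperature <- function(x, params = thermo_params()) {
  stopifnot(inherits(params, "thermo_params"))
  s <- .oligo_seq(x)
  n <- nchar(s)
  if (n < 8L) {
    stop("nearest-neighbor Tm requires length >= 8 (got ", n, ")")
  }
  ch <- .seq_chars(s)
  if (any(!ch %in% DNA_BASES)) {
    stop("ambiguity codes are not allowed in Tm calculation")
  }
  stacks <- paste0(ch[-n], ch[-1])
  dh <- sum(.nn_unified$dh[stacks])
  ds <- sum(.nn_unified$ds[stacks])
  # terminal base-pair initiation penalties
  for (end in ch[c(1L, n)]) {
    if (end %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else                      { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  # sodium-equivalent ionic strength (von Ahsen et al. 2001)
  mon <- params$monovalent_mM
  if ((params$divalent_mM > 0 || params$dntp_mM > 0) &&
      params$dntp_mM < params$divalent_mM) {
    mon <- mon + 120 * sqrt(params$divalent_mM - params$dntp_mM)
  }
  if (mon <= 0) stop("total cation concentration must be positive")
  ds <- ds + 0.368 * (n - 1) * log(mon * 1e-3)
  ct <- params$oligo_nM / 4 * 1e-9
  1000 * dh / (ds + 1.987 * log(ct)) - 273.15
}

#' Reverse complement of a DNA sequence
#'
#' IUPAC-aware Watson-Crick reverse complement; an involution.
#'
#' @param s DNA string (ambiguity codes and gaps allowed).
#' @return The reverse complement, 5' to 3'.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(s) {
  s <- normalize_sequence(s, allow_ambiguity = TRUE)
  ch <- .seq_chars(s)
  paste(rev(unname(.complement_map[ch])), collapse = "")
}

#' Longest homopolymer run
#'
#' Length of the longest run of a single repeated base; assay design forbids
#' runs of 4 or more.
#'
#' @param s DNA string or [oligo].
#' @return Integer run length (>= 1 for non-empty input).
#' @examples
#' max_homopolymer_run("AAAAG") # 4
#' @export
max_homopolymer_run <- function(s) {
  s <- .oligo_seq(s)
  if (nchar(s) == 0L) stop("sequence must be non-empty")
  max(rle(.seq_chars(s))$lengths)
}

#' 3'-end composition report for a primer
#'
#' Properties of the 3' terminus that the selection criteria inspect: the
#' terminal base, whether it is C/G (the GC clamp), whether it is T, and the
#' number of C/G bases among the last five.
#'
#' @param x An [oligo] or DNA string of length >= 5, written 5' to 3'.
#' @return A list with `terminal_base`, `terminal_is_cg`, `terminal_is_t`,
#'   and `cg_in_last5`.
#' @examples
#' three_prime_report("GCCGCTCCATTAGATCACGA")
#' @export
three_prime_report <- function(x) {
  s <- .oligo_seq(x)
  n <- nchar(s)
  if (n < 5L) stop("3'-end report requires length >= 5 (got ", n, ")")
  last5 <- .seq_chars(substr(s, n - 4L, n))
  term <- last5[5L]
  list(
    terminal_base = term,
    terminal_is_cg = term %in% c("C", "G"),
    terminal_is_t = term == "T",
    cg_in_last5 = sum(last5 %in% c("C", "G"))
  )
}
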