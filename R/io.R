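# Shared format readers/writers: FASTA, oligo TSV, assay YAML, run
# configuration, and the published-assay fixtures shipped with the package.

#' Read sequences from a FASTA file
#'
#' Wraps Biostrings FASTA parsing with the validation the toolkit relies
#' on: ids must be unique and non-empty, case is normalized, the alphabet
#' is checked. A file whose records all share one width and contain gap
#' characters is flagged as an alignment via `attr(, "aligned")`.
#'
#' @param path FASTA file (LF or CRLF).
#' @param what `"template"` permits IUPAC ambiguity codes and gaps;
#'   `"oligo"` restricts to A/C/G/T.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, what = c("template", "oligo")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id '", ids[duplicated(ids)][1], "' in ", path)
  }
  seqs <- vapply(as.character(set), function(s) {
    normalize_sequence(s, allow_ambiguity = (what == "template"),
                       what = "FASTA record")
  }, character(1), USE.NAMES = FALSE)
  names(seqs) <- ids
  widths <- nchar(seqs)
  attr(seqs, "aligned") <- length(seqs) > 1 &&
    length(unique(widths)) == 1L && any(grepl("-", seqs, fixed = TRUE))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.null(names(seqs))) stop("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read an alignment from aligned FASTA
#'
#' @param path FASTA file of equal-width gapped records.
#' @return A [alignment()] object.
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path, what = "template")
  alignment(stats::setNames(as.character(seqs), names(seqs)))
}

#' Read oligos from a three-column TSV
#'
#' Columns: `name`, `role` (forward/reverse/probe), `sequence`; optional
#' `reporter` and `quencher`.
#'
#' @param path TSV file.
#' @return A list of [oligo] objects.
#' @export
read_oligo_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "role", "sequence")
  if (!all(need %in% names(df))) {
    stop("oligo TSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    oligo(df$name[i], df$sequence[i], df$role[i],
          reporter = if ("reporter" %in% names(df) && nzchar(df$reporter[i]))
            df$reporter[i] else NULL,
          quencher = if ("quencher" %in% names(df) && nzchar(df$quencher[i]))
            df$quencher[i] else NULL)
  })
}

#' Read or write an assay definition as YAML
#'
#' @param path YAML file with keys `name`, `ta_C`, optional
#'   `cq_threshold`, and `forward` / `reverse` / `probe` blocks each with
#'   `name`, `sequence`, `concentration_uM` (probes may add `reporter`,
#'   `quencher`).
#' @return An [assay_definition].
#' @export
read_assay_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("name", "forward", "reverse", "probe", "ta_C")
  if (!all(need %in% names(y))) {
    stop("assay YAML must define: ", paste(need, collapse = ", "))
  }
  mk <- function(block, role) {
    oligo(block$name, block$sequence, role,
          reporter = block$reporter, quencher = block$quencher)
  }
  assay_definition(
    forward = mk(y$forward, "forward"),
    reverse = mk(y$reverse, "reverse"),
    probe = mk(y$probe, "probe"),
    name = y$name,
    concentration_uM = c(
      forward = y$forward$concentration_uM %||% 0.2,
      reverse = y$reverse$concentration_uM %||% 0.2,
      probe = y$probe$concentration_uM %||% 0.1),
    ta_C = y$ta_C,
    cq_threshold = y$cq_threshold)
}

#' @rdname read_assay_yaml
#' @param assay An [assay_definition] to serialize.
#' @export
write_assay_yaml <- function(assay, path) {
  stopifnot(inherits(assay, "assay_definition"))
  blk <- function(role) {
    o <- assay[[role]]
    out <- list(name = o$name, sequence = o$sequence,
                concentration_uM = unname(assay$concentration_uM[[role]]))
    if (!is.null(o$reporter)) out$reporter <- o$reporter
    if (!is.null(o$quencher)) out$quencher <- o$quencher
    out
  }
  y <- list(name = assay$name, forward = blk("forward"),
            reverse = blk("reverse"), probe = blk("probe"),
            ta_C = assay$ta_C)
  if (!is.null(assay$cq_threshold)) y$cq_threshold <- assay$cq_threshold
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published marine eDNA assays shipped as test fixtures
#'
#' The three validated hydrolysis-probe assays bundled with the package:
#' humpback whale (mitochondrial d-loop control region), shortbelly
#' rockfish (COI), and common murre (COI), with their printed oligo
#' sequences, reporter/quencher labels, final concentrations, annealing
#' temperatures, Cq thresholds, and target amplicon lengths.
#'
#' @return A named list of [assay_definition] objects, each carrying a
#'   `target_length_nt` attribute.
#' @export
published_assays <- function() {
  path <- system.file("extdata", "published_assays.tsv",
                      package = "ednaqpcr", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  out <- lapply(split(df, df$assay), function(a) {
    get_role <- function(role) a[a$role == role, , drop = FALSE]
    f <- get_role("forward"); r <- get_role("reverse"); p <- get_role("probe")
    asy <- assay_definition(
      forward = oligo(f$oligo_name, f$sequence, "forward"),
      reverse = oligo(r$oligo_name, r$sequence, "reverse"),
      probe = oligo(p$oligo_name, p$sequence, "probe",
                    reporter = p$reporter, quencher = p$quencher),
      name = a$assay[1],
      concentration_uM = c(forward = f$conc_uM, reverse = r$conc_uM,
                           probe = p$conc_uM),
      ta_C = a$ta_C[1], cq_threshold = a$cq_threshold[1])
    attr(asy, "target_length_nt") <- a$target_length_nt[1]
    asy
  })
  out[c("humpback", "rockfish", "murre")]
}

#' Published validation-panel confusion counts
#'
#' Per-assay tissue-panel outcomes shipped as a fixture: numbers of target
#' and non-target individuals and the true/false positive/negative counts
#' from in-vitro testing.
#'
#' @return A data.frame with one row per assay.
#' @export
validation_counts <- function() {
  path <- system.file("extdata", "validation_panel_counts.csv",
                      package = "ednaqpcr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

# ---- run configuration ----

#' Default run configuration
#'
#' Nested list mirroring the tunable surface of every module: `thermo`,
#' `constraints`, `criteria`, `screening`, `analytics`. [load_config()]
#' merges a user YAML over these defaults and rejects unknown keys by name.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    thermo = list(monovalent_mM = 50, divalent_mM = 1.5, dntp_mM = 0.6,
                  oligo_nM = 50),
    constraints = list(product_size = c(100, 200), oligo_size = c(18, 27),
                       oligo_size_opt = 20, primer_tm = c(58, 63),
                       primer_tm_opt = 60, probe_tm = c(68, 73),
                       probe_tm_opt = 70, gc = c(35, 65), gc_opt = 50),
    criteria = list(max_primer_delta_tm = 5, probe_delta_tm = c(8, 10),
                    max_homopolymer = 3, forbid_t_3prime = TRUE,
                    require_cg_3prime = TRUE, min_cg_last5 = 3,
                    forbid_g_5prime_probe = TRUE, min_probe_gc = 50),
    screening = list(max_mismatches = 5, product_range = c(100, 200),
                     require_three_prime_match = FALSE),
    analytics = list(cycles = 40, above_loq = "bloq", dilution_factor = 1,
                     extract_volume_ul = 100, filtered_volume_ml = 1000)
  )
}

.check_config_keys <- function(user, defaults, prefix = "") {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop("unknown configuration key: ", prefix, extra[1], call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) stop("configuration key ", prefix, k,
                                    " must be a mapping", call. = FALSE)
      .check_config_keys(user[[k]], defaults[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(TRUE)
}

#' Load and validate a YAML run configuration
#'
#' @param path YAML file; keys absent from the file keep their defaults,
#'   unknown keys are rejected with the offending key named.
#' @return Merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  .check_config_keys(user, cfg)
  utils::modifyList(cfg, user)
}

.cfg_thermo <- function(cfg) do.call(thermo_params, cfg$thermo)
.cfg_constraints <- function(cfg) do.call(design_constraints, cfg$constraints)
.cfg_criteria <- function(cfg) do.call(selection_criteria, cfg$criteria)
.cfg_policy <- function(cfg) do.call(screening_policy, cfg$screening)

# header comment for report writers: version + config hash
.report_header <- function(cfg = NULL) {
  hash <- if (is.null(cfg)) "default" else {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(cfg, tmp)
    unname(tools::md5sum(tmp))
  }
  sprintf("# ednaqpcr %s; config_hash=%s; coordinates=1-based inclusive",
          as.character(utils::packageVersion("ednaqpcr")), hash)
}

#' Write a data.frame report as TSV with a provenance header
#'
#' @param df Data frame.
#' @param path Output file.
#' @param cfg Optional configuration list hashed into the header.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.report_header(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
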