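# Seeded synthetic-data generators: sequence panels with planted binding
# sites and controlled mismatches, and qPCR plates drawn from a stated
# forward model. All randomness is scoped to the spec's seed via
# withr::with_seed; identical specs give byte-identical output.

.random_dna <- function(n, background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25)) {
  if (n <= 0) return("")
  paste(sample(names(background), n, replace = TRUE, prob = background),
        collapse = "")
}

# plant `k` substitutions into a sequence at distinct random positions,
# each changed to a different base (guaranteed mismatches)
.mutate <- function(s, k, positions = NULL) {
  if (k == 0) return(s)
  ch <- .seq_chars(s)
  if (k > length(ch)) stop("cannot plant ", k, " mismatches in a ",
                           length(ch), " nt oligo region")
  pos <- if (is.null(positions)) sample(length(ch), k) else positions
  for (i in pos) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Specification of a synthetic screening panel
#'
#' Each sequence of the panel is a background of stated base composition
#' with, optionally, a forward-primer footprint, a probe footprint, and a
#' reverse-complemented reverse-primer footprint planted left to right with
#' chosen spacer lengths and per-oligo planted mismatch counts. Leaving
#' `configs` empty draws one random configuration per sequence.
#'
#' @param n Number of sequences.
#' @param seed Integer seed; the generator is deterministic per seed.
#' @param configs Optional list of per-sequence configurations; each a list
#'   with logical `has_f`, `has_p`, `has_r`, integer `mm_f`, `mm_p`,
#'   `mm_r`, and spacer lengths `spacer1` (F to P) and `spacer2` (P to R).
#'   Missing fields take the defaults of `default_config`.
#' @param background Base composition of unplanted sequence.
#' @param pad Length of random sequence flanking the planted cassette.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n, seed, configs = NULL,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       pad = 30) {
  stopifnot(n >= 1, length(background) == 4,
            abs(sum(background) - 1) < 1e-9, all(background >= 0), pad >= 0)
  if (!is.null(configs) && length(configs) != n) {
    stop("configs must have one entry per sequence")
  }
  structure(list(n = n, seed = as.integer(seed), configs = configs,
                 background = background, pad = pad),
            class = "panel_spec")
}

.default_panel_config <- function() {
  list(has_f = TRUE, has_p = TRUE, has_r = TRUE,
       mm_f = 0L, mm_p = 0L, mm_r = 0L,
       spacer1 = 30L, spacer2 = 30L)
}

#' Generate a synthetic screening panel with truth labels
#'
#' Emits `n` sequences built from the spec's planted configurations, plus a
#' truth table giving, per sequence, the expected screening outcome under
#' the supplied policy, derived from the construction itself: positive iff
#' all three oligos are planted within their mismatch budgets and the
#' planted product length falls in the policy's range.
#'
#' @param assay An [assay_definition] whose oligos are planted.
#' @param spec A [panel_spec].
#' @param policy The [screening_policy] the truth labels refer to.
#' @return A list with `sequences` (named character vector) and `truth`
#'   (data.frame: `seq_id`, the planted configuration, `product_length`,
#'   `expected_positive`, `expected_reason`).
#' @export
generate_panel <- function(assay, spec, policy = screening_policy()) {
  stopifnot(inherits(assay, "assay_definition"), inherits(spec, "panel_spec"))
  f <- assay$forward$sequence
  p <- assay$probe$sequence
  r_rc <- reverse_complement(assay$reverse$sequence)
  budgets <- policy$max_mismatches
  withr::with_seed(spec$seed, {
    seqs <- character(spec$n)
    rows <- vector("list", spec$n)
    for (i in seq_len(spec$n)) {
      cfg <- utils::modifyList(
        .default_panel_config(),
        if (is.null(spec$configs)) list(
          has_f = TRUE, has_p = stats::runif(1) < 0.8,
          has_r = stats::runif(1) < 0.8,
          mm_f = sample(0:7, 1), mm_p = sample(0:7, 1), mm_r = sample(0:7, 1),
          spacer1 = sample(20:45, 1), spacer2 = sample(20:45, 1)
        ) else spec$configs[[i]]
      )
      piece <- function(planted, oligo_seq, mm) {
        if (planted) .mutate(oligo_seq, mm)
        else .random_dna(nchar(oligo_seq), spec$background)
      }
      body <- paste0(
        piece(cfg$has_f, f, cfg$mm_f),
        .random_dna(cfg$spacer1, spec$background),
        piece(cfg$has_p, p, cfg$mm_p),
        .random_dna(cfg$spacer2, spec$background),
        piece(cfg$has_r, r_rc, cfg$mm_r)
      )
      seqs[i] <- paste0(.random_dna(spec$pad, spec$background), body,
                        .random_dna(spec$pad, spec$background))
      product_length <- nchar(body)
      ok_f <- cfg$has_f && cfg$mm_f <= budgets[["forward"]]
      ok_p <- cfg$has_p && cfg$mm_p <= budgets[["probe"]]
      ok_r <- cfg$has_r && cfg$mm_r <= budgets[["reverse"]]
      in_range <- product_length >= policy$product_range[1] &&
        product_length <= policy$product_range[2]
      reason <- if (!ok_f) "no F" else if (!ok_r) "no R"
        else if (!in_range) "product out of range"
        else if (!ok_p) "no P" else ""
      rows[[i]] <- data.frame(
        seq_id = sprintf("seq_%03d", i),
        has_f = cfg$has_f, mm_f = cfg$mm_f,
        has_p = cfg$has_p, mm_p = cfg$mm_p,
        has_r = cfg$has_r, mm_r = cfg$mm_r,
        product_length = product_length,
        expected_positive = ok_f && ok_p && ok_r && in_range,
        expected_reason = reason,
        stringsAsFactors = FALSE)
    }
    names(seqs) <- sprintf("seq_%03d", seq_len(spec$n))
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    list(sequences = seqs, truth = truth)
  })
}

#' Specification of a synthetic qPCR plate
#'
#' The forward model is `Cq = intercept + slope * log10(conc) + N(0,
#' sigma)` per replicate; reactions whose Cq exceeds the cycle count, and
#' (with probability `dropout_prob`) reactions below the full-detection
#' threshold, become non-detects. The default dilution series mirrors the
#' bench convention of 200 pg gDNA per 2 uL-template reaction down to 2 fg
#' in ten-fold steps, i.e. 100 down to 0.001 pg/uL of extract.
#'
#' @param slope,intercept True curve parameters (cycles per log10, cycles).
#' @param sigma Gaussian Cq noise standard deviation (cycles).
#' @param start_conc Highest standard concentration (pg/uL).
#' @param fold Dilution factor between consecutive standards (> 1).
#' @param steps Number of dilution points.
#' @param dropout_below Full-detection threshold (pg/uL); below it each
#'   replicate is ND with probability `dropout_prob`.
#' @param dropout_prob Per-replicate dropout probability below threshold.
#' @param replicates Replicates per concentration.
#' @param template_ul Template volume per reaction.
#' @param cycles Instrument cycle count (Cq beyond it is ND).
#' @param seed Integer seed.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(slope = -3.53, intercept = 36, sigma = 0.15,
                       start_conc = 100, fold = 10, steps = 6,
                       dropout_below = 0.1, dropout_prob = 0.5,
                       replicates = 3, template_ul = 2, cycles = 40,
                       seed) {
  stopifnot(fold > 1, sigma >= 0, dropout_prob >= 0, dropout_prob <= 1,
            steps >= 1, replicates >= 1, start_conc > 0)
  structure(list(slope = slope, intercept = intercept, sigma = sigma,
                 start_conc = start_conc, fold = fold, steps = steps,
                 dropout_below = dropout_below, dropout_prob = dropout_prob,
                 replicates = replicates, template_ul = template_ul,
                 cycles = cycles, seed = as.integer(seed)),
            class = "plate_spec")
}

#' Generate a synthetic qPCR plate
#'
#' @param spec A [plate_spec].
#' @param ntc Number of no-template-control wells to append (always ND).
#' @return A plate data.frame in the [read_plate()] dialect (roles
#'   `standard` and `NTC`), deterministic per seed.
#' @export
generate_plate <- function(spec, ntc = 0) {
  stopifnot(inherits(spec, "plate_spec"))
  concs <- spec$start_conc / spec$fold^(seq_len(spec$steps) - 1)
  withr::with_seed(spec$seed, {
    rows <- list()
    for (conc in concs) {
      for (rep_i in seq_len(spec$replicates)) {
        cq <- spec$intercept + spec$slope * log10(conc) +
          stats::rnorm(1, 0, spec$sigma)
        nd <- cq > spec$cycles || cq <= 0 ||
          (conc < spec$dropout_below &&
             stats::runif(1) < spec$dropout_prob)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("std_%g", conc), role = "standard",
          replicate = rep_i, cq = if (nd) NA_real_ else cq,
          known_conc_pg_per_ul = conc, template_ul = spec$template_ul,
          stringsAsFactors = FALSE)
      }
    }
    if (ntc > 0) {
      for (k in seq_len(ntc)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("NTC_%d", k), role = "NTC", replicate = k,
          cq = NA_real_, known_conc_pg_per_ul = NA_real_,
          template_ul = spec$template_ul, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    validate_plate(df, cycles = spec$cycles)
  })
}

#' Simulate environmental replicates from a known concentration
#'
#' Forward model used in round-trip tests: runs a known water concentration
#' through the same dimensional chain [quantify_environmental()] inverts,
#' then adds Gaussian Cq noise.
#'
#' @param true_pg_per_ml True concentration in water (pg/mL).
#' @param curve A `standard_curve` supplying slope and intercept.
#' @param n Replicates.
#' @param dilution_factor,extract_volume_ul,filtered_volume_ml Volume
#'   bookkeeping, as in [quantify_environmental()].
#' @param template_ul Template volume per reaction.
#' @param sigma Cq noise (cycles).
#' @param seed Integer seed.
#' @return Plate rows with role `environmental`.
#' @export
simulate_environmental <- function(true_pg_per_ml, curve, n = 3,
                                   dilution_factor = 1, extract_volume_ul = 100,
                                   filtered_volume_ml = 1000, template_ul = 2,
                                   sigma = 0, seed = 1) {
  conc_template <- true_pg_per_ml * filtered_volume_ml /
    (dilution_factor * extract_volume_ul)
  cq0 <- curve$intercept + curve$slope * log10(conc_template)
  withr::with_seed(seed, {
    data.frame(sample_id = "env_1", role = "environmental",
               replicate = seq_len(n),
               cq = cq0 + stats::rnorm(n, 0, sigma),
               known_conc_pg_per_ul = NA_real_, template_ul = template_ul,
               stringsAsFactors = FALSE)
  })
}
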