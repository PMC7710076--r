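# Plate-level Cq analytics: standard curves, efficiency, limit of
# quantification, positive/negative calls, panel sensitivity/specificity,
# and back-calculation of eDNA concentration in filtered water.

.plate_cols <- c("sample_id", "role", "replicate", "cq",
                 "known_conc_pg_per_ul", "template_ul")
.plate_roles <- c("standard", "target-tissue", "non-target-tissue",
                  "environmental", "NTC")

#' Read a qPCR plate CSV
#'
#' The plate contract is a CSV with columns `sample_id, role, replicate,
#' cq, known_conc_pg_per_ul, template_ul`; `cq` empty or `"ND"` marks a
#' non-detect (a reaction never assigned a quantification cycle). Roles are
#' `standard`, `target-tissue`, `non-target-tissue`, `environmental`, or
#' `NTC`. Standards must carry a positive known concentration (pg genomic
#' DNA per microlitre of extract). An NTC with any Cq raises a
#' contamination warning.
#'
#' @param path CSV file.
#' @param cycles Instrument cycle count; Cq values must lie in (0, cycles].
#' @return A data.frame with `cq` numeric (`NA` = ND).
#' @export
read_plate <- function(path, cycles = 40) {
  if (!file.exists(path)) stop("plate file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "#")
  missing <- setdiff(.plate_cols, names(df))
  if (length(missing)) {
    stop("plate is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, .plate_cols]
  bad_role <- setdiff(unique(df$role), .plate_roles)
  if (length(bad_role)) stop("unknown plate role: ", bad_role[1])
  cq <- trimws(df$cq)
  cq[cq %in% c("", "ND", "nd", "NA")] <- NA
  df$cq <- as.numeric(cq)
  df$replicate <- as.integer(df$replicate)
  df$known_conc_pg_per_ul <- as.numeric(df$known_conc_pg_per_ul)
  df$template_ul <- as.numeric(df$template_ul)
  validate_plate(df, cycles = cycles)
}

#' Validate an in-memory plate data.frame
#'
#' @param df Plate data.frame (see [read_plate()] for the contract).
#' @param cycles Instrument cycle count.
#' @return The validated data.frame, invisibly classed `qpcr_plate`.
#' @export
validate_plate <- function(df, cycles = 40) {
  stopifnot(all(.plate_cols %in% names(df)))
  obs <- df$cq[!is.na(df$cq)]
  if (any(obs <= 0 | obs > cycles)) {
    stop("Cq values must lie in (0, ", cycles, "]")
  }
  std <- df[df$role == "standard", ]
  if (nrow(std) && (anyNA(std$known_conc_pg_per_ul) ||
                    any(std$known_conc_pg_per_ul <= 0))) {
    stop("standards must have a positive known concentration")
  }
  ntc_amp <- df$role == "NTC" & !is.na(df$cq)
  if (any(ntc_amp)) {
    warning("possible contamination: ", sum(ntc_amp),
            " NTC reaction(s) produced a Cq", call. = FALSE)
  }
  class(df) <- unique(c("qpcr_plate", class(df)))
  df
}

#' Limit of quantification of a dilution series
#'
#' The LOQ is the lowest standard concentration at which every replicate is
#' assigned a Cq, with the additional consistency requirement that every
#' higher concentration is also fully detected. Units follow the standards
#' (pg gDNA per microlitre of extract).
#'
#' @param standards Plate rows with role `standard`.
#' @param replicates_required Replicates that must detect at a
#'   concentration for it to count as fully detected; default, all of them.
#' @return A list with `loq` (concentration), `loq_cq` (mean Cq at the
#'   LOQ), and `defined`. When even the highest concentration is not fully
#'   detected, `loq` and `loq_cq` are `NA` and `defined` is `FALSE`.
#' @export
determine_loq <- function(standards, replicates_required = NULL) {
  std <- standards[standards$role == "standard", , drop = FALSE]
  if (!nrow(std)) stop("no standard reactions supplied")
  concs <- sort(unique(std$known_conc_pg_per_ul), decreasing = TRUE)
  loq <- NA_real_
  for (conc in concs) {
    reps <- std[std$known_conc_pg_per_ul == conc, ]
    need <- if (is.null(replicates_required)) nrow(reps) else replicates_required
    if (sum(!is.na(reps$cq)) >= need && nrow(reps) >= need) {
      loq <- conc                      # fully detected; keep walking down
    } else {
      break                            # consistency broken: stop
    }
  }
  if (is.na(loq)) {
    return(list(loq = NA_real_, loq_cq = NA_real_, defined = FALSE))
  }
  list(loq = loq,
       loq_cq = mean(std$cq[std$known_conc_pg_per_ul == loq], na.rm = TRUE),
       defined = TRUE)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(concentration) over detected
#' standard replicates at or above the LOQ (partially detected points below
#' the LOQ would bias the slope and are excluded). Amplification efficiency
#' is `(10^(-1/slope) - 1) * 100`; a slope of -3.3219 (-1/log10 2, perfect
#' per-cycle doubling) gives 100%.
#'
#' @param standards Plate rows with role `standard`.
#' @param loq Optional list from [determine_loq()]; computed if omitted.
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `se_slope`, `df_residual`, `r_squared`, `efficiency_pct`, `loq`,
#'   `loq_cq`, `n_points`, `concentrations`, and `valid` (slope negative).
#' @export
fit_standard_curve <- function(standards, loq = NULL) {
  std <- standards[standards$role == "standard", , drop = FALSE]
  if (!nrow(std)) stop("no standard reactions supplied")
  if (is.null(loq)) loq <- determine_loq(std)
  usable <- std[!is.na(std$cq), , drop = FALSE]
  if (loq$defined) {
    usable <- usable[usable$known_conc_pg_per_ul >= loq$loq, , drop = FALSE]
  }
  concs <- unique(usable$known_conc_pg_per_ul)
  if (length(concs) < 3L) {
    stop("standard curve needs >= 3 usable concentrations (got ",
         length(concs), ")")
  }
  fit <- stats::lm(cq ~ log10(known_conc_pg_per_ul), data = usable)
  slope <- unname(stats::coef(fit)[2])
  # R^2 and slope SE computed directly (summary.lm warns on perfect fits)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((usable$cq - mean(usable$cq))^2)
  x <- log10(usable$known_conc_pg_per_ul)
  sxx <- sum((x - mean(x))^2)
  dfres <- stats::df.residual(fit)
  curve <- structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    se_slope = sqrt(sse / dfres / sxx),
    df_residual = dfres,
    r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
    efficiency_pct = (10^(-1 / slope) - 1) * 100,
    loq = loq$loq, loq_cq = loq$loq_cq,
    n_points = nrow(usable), concentrations = sort(concs),
    valid = slope < 0
  ), class = "standard_curve")
  if (!curve$valid) {
    warning("positive slope: curve flagged invalid", call. = FALSE)
  }
  curve
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    paste0("<standard_curve> Cq = %.3f %+.3f log10(conc)\n",
           "  R^2 %.4f | efficiency %.1f%% | LOQ %s pg/uL (Cq %s) | %d points%s\n"),
    x$intercept, x$slope, x$r_squared, x$efficiency_pct,
    format(x$loq), format(round(x$loq_cq, 2)), x$n_points,
    if (x$valid) "" else " | INVALID (positive slope)"))
  invisible(x)
}

#' Call detection status per sample
#'
#' Replicate rule: a replicate with a Cq below the LOQ Cq is a quantifiable
#' positive; an ND replicate is negative; a replicate with a Cq at or above
#' the LOQ Cq is, by default, a detection below the limit of quantification
#' (`above_loq = "bloq"`), or a negative under `above_loq = "negative"`.
#' Sample rule: all replicates quantifiable positives gives `quantified`;
#' any detection otherwise gives `BLOQ`; no detection gives `ND`.
#'
#' @param reactions Plate rows for the samples to call (non-standard roles).
#' @param curve A [fit_standard_curve()] result with a defined LOQ Cq.
#' @param above_loq How to treat amplifications at Cq >= LOQ Cq.
#' @return A data.frame per sample: `sample_id`, `n_reps`, `n_detected`,
#'   `n_quantifiable`, `status` (`quantified` / `BLOQ` / `ND`), `detected`.
#' @export
call_sample <- function(reactions, curve, above_loq = c("bloq", "negative")) {
  above_loq <- match.arg(above_loq)
  stopifnot(inherits(curve, "standard_curve"))
  if (is.na(curve$loq_cq)) stop("curve has no defined LOQ Cq")
  rx <- reactions[!reactions$role %in% c("standard", "NTC"), , drop = FALSE]
  if (!nrow(rx)) stop("no sample reactions to call")
  out <- lapply(split(rx, rx$sample_id), function(s) {
    quant <- !is.na(s$cq) & s$cq < curve$loq_cq
    det <- if (above_loq == "bloq") !is.na(s$cq) else quant
    status <- if (all(quant)) "quantified"
              else if (any(det)) "BLOQ"
              else "ND"
    data.frame(sample_id = s$sample_id[1], n_reps = nrow(s),
               n_detected = sum(det), n_quantifiable = sum(quant),
               status = status, detected = any(det),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sensitivity and specificity of a validation panel
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP); percentages
#' rounded half-up to the nearest integer for report parity. Supply either
#' raw confusion counts, or `calls` (from [call_sample()], or any frame
#' with `sample_id` and `detected`) plus `labels` mapping each sample id to
#' `TRUE` (target) / `FALSE` (non-target).
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @param calls Optional calls data.frame.
#' @param labels Optional named logical vector (`TRUE` = target sample).
#' @return An object of class `panel_result`: counts, `sensitivity_pct`,
#'   `specificity_pct`.
#' @export
panel_metrics <- function(tp = NULL, fn = NULL, tn = NULL, fp = NULL,
                          calls = NULL, labels = NULL) {
  if (!is.null(calls)) {
    if (is.null(labels)) stop("labels are required with calls")
    unlabeled <- setdiff(calls$sample_id, names(labels))
    if (length(unlabeled)) stop("sample '", unlabeled[1], "' has no label")
    is_target <- labels[calls$sample_id]
    tp <- sum(is_target & calls$detected)
    fn <- sum(is_target & !calls$detected)
    fp <- sum(!is_target & calls$detected)
    tn <- sum(!is_target & !calls$detected)
  }
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("empty panel")
  structure(list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity_pct = round_half_up(100 * tp / (tp + fn)),
    specificity_pct = round_half_up(100 * tn / (tn + fp))
  ), class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf(paste0("<panel_result> TP %d FN %d TN %d FP %d | ",
                     "sensitivity %d%% specificity %d%%\n"),
              x$tp, x$fn, x$tn, x$fp, x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}

#' Back-calculate eDNA concentration in filtered water
#'
#' Inverts the standard curve for each quantifiable replicate and carries
#' the result through the volume bookkeeping of a filtration workflow:
#' `10^((Cq - intercept)/slope)` gives pg per microlitre of (diluted)
#' template; multiplied by the dilution factor it is pg per microlitre of
#' extract; multiplied by the extract volume it is pg recovered on the
#' filter; divided by the filtered water volume it is pg per millilitre of
#' water. The sample mean carries a 95% Student-t confidence interval over
#' replicates. Samples whose status is not `quantified` propagate as BLOQ
#' or ND and never yield a number.
#'
#' @param reactions Plate rows for environmental samples.
#' @param curve A valid [fit_standard_curve()] result.
#' @param dilution_factor Fold-dilution of the extract in the template
#'   (e.g. 5 for a 1:5 dilution).
#' @param extract_volume_ul Total DNA extract volume (microlitres).
#' @param filtered_volume_ml Water volume filtered (millilitres).
#' @param above_loq Passed to [call_sample()].
#' @return A data.frame per sample: `sample_id`, `status`,
#'   `mean_pg_per_ml`, `ci95_half_width`, `n_reps`, and the provenance
#'   factors used.
#' @export
quantify_environmental <- function(reactions, curve, dilution_factor = 1,
                                   extract_volume_ul, filtered_volume_ml,
                                   above_loq = c("bloq", "negative")) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$valid) stop("refusing to quantify from an invalid curve")
  if (extract_volume_ul <= 0 || filtered_volume_ml <= 0 || dilution_factor <= 0) {
    stop("volumes and dilution factor must be positive")
  }
  calls <- call_sample(reactions, curve, above_loq = above_loq)
  rx <- reactions[!reactions$role %in% c("standard", "NTC"), , drop = FALSE]
  out <- lapply(seq_len(nrow(calls)), function(i) {
    id <- calls$sample_id[i]
    base <- data.frame(sample_id = id, status = calls$status[i],
                       mean_pg_per_ml = NA_real_, ci95_half_width = NA_real_,
                       n_reps = calls$n_reps[i],
                       dilution_factor = dilution_factor,
                       extract_volume_ul = extract_volume_ul,
                       filtered_volume_ml = filtered_volume_ml,
                       stringsAsFactors = FALSE)
    if (calls$status[i] != "quantified") return(base)
    s <- rx[rx$sample_id == id, ]
    conc_template <- 10^((s$cq - curve$intercept) / curve$slope)  # pg/uL template
    per_ml <- conc_template * dilution_factor * extract_volume_ul /
      filtered_volume_ml
    n <- length(per_ml)
    base$mean_pg_per_ml <- mean(per_ml)
    base$ci95_half_width <- if (n > 1) {
      stats::qt(0.975, df = n - 1) * stats::sd(per_ml) / sqrt(n)
    } else NA_real_
    base
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a standard curve as JSON
#'
#' @param curve A `standard_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "standard_curve"))
  jsonlite::write_json(
    list(slope = curve$slope, intercept = curve$intercept,
         r2 = curve$r_squared, efficiency_pct = curve$efficiency_pct,
         loq = curve$loq, loq_cq = curve$loq_cq,
         n_points = curve$n_points, valid = curve$valid),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
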