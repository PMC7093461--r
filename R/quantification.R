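# Absolute quantification: single-point per-subclass internal standards,
# external calibration with linear-range and dilution handling, protein
# normalization.

#' Single-point internal-standard quantification
#'
#' The analyte amount in micrograms is the peak-area ratio to the
#' subclass's deuterated internal standard times the spiked amount
#' (response factor 1 unless overridden); the molar amount converts with
#' the analyte's average molecular weight. The internal standard itself
#' quantifies to exactly its spiked amount.
#'
#' @param analyte_area,is_area Peak areas (arbitrary units); `is_area`
#'   must be positive.
#' @param is_amount Spiked internal-standard amount in micrograms.
#' @param analyte_mw Analyte average molecular weight (g/mol).
#' @param response_factor Analyte-to-standard response factor (default 1).
#' @return Amount in pmol (vectorized over `analyte_area`).
#' @export
quantify_by_internal_standard <- function(analyte_area, is_area, is_amount,
                                          analyte_mw, response_factor = 1) {
  if (any(is_area <= 0)) {
    stop("internal-standard peak area must be > 0 for quantification")
  }
  stopifnot(all(is_amount > 0), all(analyte_mw > 0),
            all(analyte_area >= 0), all(response_factor > 0))
  amount_ug <- analyte_area / is_area * is_amount / response_factor
  amount_ug / analyte_mw * 1e6
}

#' Fit an external calibration curve
#'
#' Ordinary least-squares line of response ratio (analyte area / internal
#' standard area) on concentration. On noiseless linear data the fit
#' recovers the generating slope and intercept exactly.
#'
#' @param levels Data frame with columns `concentration` (ug/mL) and
#'   `response_ratio`; at least 2 distinct concentrations.
#' @param linear_min,linear_max Declared linear range in ug/mL (defaults
#'   0.5 and 200, the cholesterol assay range).
#' @return Object of class `calibration_curve` with fields `levels`,
#'   `slope`, `intercept`, `linear_min`, `linear_max`.
#' @export
fit_calibration <- function(levels, linear_min = 0.5, linear_max = 200) {
  stopifnot(is.data.frame(levels),
            all(c("concentration", "response_ratio") %in% names(levels)))
  if (length(unique(levels$concentration)) < 2) {
    stop("calibration needs at least 2 distinct concentrations")
  }
  stopifnot(linear_min < linear_max)
  fit <- stats::lm(response_ratio ~ concentration, data = levels)
  co <- stats::coef(fit)
  if (!is.finite(co[["concentration"]])) stop("calibration slope not finite")
  structure(list(levels = levels, slope = unname(co[["concentration"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 linear_min = linear_min, linear_max = linear_max),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve:", nrow(x$levels), "levels, slope",
      format(x$slope, digits = 6), "intercept",
      format(x$intercept, digits = 6), "\n")
  cat("  linear range:", x$linear_min, "-", x$linear_max, "ug/mL\n")
  invisible(x)
}

#' Quantify by external calibration curve
#'
#' Inverts the calibration line at the observed response ratio and applies
#' the dilution factor. The `out_of_range` flag is set when the undiluted
#' interpolation exceeds the linear range (samples above the upper limit
#' are re-analyzed after dilution; a diluted re-analysis whose response
#' falls inside the range clears the flag and is scaled up).
#'
#' @param analyte_area,is_area Peak areas; `is_area` must be positive.
#' @param curve A [fit_calibration()] curve.
#' @param dilution_factor Dilution applied before re-analysis (>= 1).
#' @return List with `concentration` (ug/mL, dilution-corrected) and
#'   `out_of_range` (logical).
#' @export
quantify_by_calibration <- function(analyte_area, is_area, curve,
                                    dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(is_area <= 0)) stop("internal-standard peak area must be > 0")
  if (curve$slope == 0) stop("calibration slope is zero; cannot invert")
  stopifnot(all(dilution_factor >= 1))
  ratio <- analyte_area / is_area
  raw <- (ratio - curve$intercept) / curve$slope
  list(concentration = raw * dilution_factor,
       out_of_range = raw > curve$linear_max | raw < curve$linear_min)
}

default_is_map <- function() {
  sub <- lipid_subclasses()
  stats::setNames(paste0("IS_", sub), sub)
}

#' Build the absolute quantification table
#'
#' One record per accepted identification of a non-standard species. Each
#' analyte is quantified against its subclass's internal-standard feature
#' in the same sample ([quantify_by_internal_standard()]); subclasses
#' listed in `calibration` use the external-curve path instead, converting
#' the interpolated concentration to an amount with the configured extract
#' volume. Internal-standard features are excluded from the analyte table.
#' Protein normalization divides by the sample's protein amount.
#'
#' @param identifications Audit table from [identify_lipids()].
#' @param features Feature data frame (areas and sample assignment).
#' @param samples Sample metadata from [read_sample_meta()] or
#'   [generate_experiment()].
#' @param library The [spectral_library()] used for identification.
#' @param is_map Named character vector subclass -> internal-standard
#'   species_id; defaults to the built-in panel naming (`IS_<subclass>`).
#' @param calibration Optional named list subclass -> list(curve =
#'   [fit_calibration()] curve, extract_volume_mL, dilution_factor) for
#'   the external-calibration path.
#' @param response_factors Optional named numeric vector species_id ->
#'   response factor override (default 1).
#' @return Data frame with columns `sample_id`, `species_id`, `subclass`,
#'   `amount_pmol`, `amount_pmol_per_ug_protein`, `out_of_range`,
#'   `dilution_applied`.
#' @export
build_quant_table <- function(identifications, features, samples, library,
                              is_map = default_is_map(), calibration = NULL,
                              response_factors = NULL) {
  acc <- identifications[identifications$accepted, , drop = FALSE]
  sp <- library$species
  feat_idx <- match(acc$feature_id, features$feature_id)
  if (anyNA(feat_idx)) {
    stop("accepted identifications reference unknown features: ",
         paste(acc$feature_id[is.na(feat_idx)], collapse = ", "))
  }
  acc$sample_id <- features$sample_id[feat_idx]
  acc$area <- features$area[feat_idx]
  spi <- match(acc$species_id, sp$species_id)
  acc$subclass <- sp$subclass[spi]
  acc$average_mw <- sp$average_mw[spi]
  acc$is_is <- sp$is_internal_standard[spi]

  # internal-standard areas per (sample, subclass), from accepted IS matches
  is_rows <- acc[acc$is_is, , drop = FALSE]
  is_area_of <- function(sample_id, subclass) {
    want <- is_map[[subclass]]
    hit <- is_rows$sample_id == sample_id & is_rows$species_id == want
    if (!any(hit)) return(NA_real_)
    sum(is_rows$area[hit])
  }

  analytes <- acc[!acc$is_is, , drop = FALSE]
  no_route <- setdiff(unique(analytes$subclass),
                      union(names(is_map), names(calibration)))
  if (length(no_route)) {
    stop("no internal standard and no calibration configured for ",
         "subclass(es): ", paste(no_route, collapse = ", "))
  }
  n <- nrow(analytes)
  amount <- numeric(n)
  oor <- logical(n)
  dil <- rep(1, n)
  failed <- character(0)
  for (i in seq_len(n)) {
    sub <- analytes$subclass[i]
    sam <- analytes$sample_id[i]
    rf <- 1
    if (!is.null(response_factors) &&
        analytes$species_id[i] %in% names(response_factors)) {
      rf <- response_factors[[analytes$species_id[i]]]
    }
    if (!is.null(calibration) && sub %in% names(calibration)) {
      cal <- calibration[[sub]]
      isa <- is_area_of(sam, sub)
      if (is.na(isa) || isa <= 0) {
        amount[i] <- NA_real_
        failed <- c(failed, paste0(sam, "/", sub))
        next
      }
      d <- if (is.null(cal$dilution_factor)) 1 else cal$dilution_factor
      q <- quantify_by_calibration(analytes$area[i], isa, cal$curve, d)
      vol <- if (is.null(cal$extract_volume_mL)) 0.1 else cal$extract_volume_mL
      amount[i] <- q$concentration * vol / analytes$average_mw[i] * 1e6
      oor[i] <- q$out_of_range
      dil[i] <- d
    } else {
      meta <- samples[samples$sample_id == sam, , drop = FALSE]
      if (!nrow(meta)) stop("no sample metadata for sample ", sam)
      spikes <- meta$is_spikes[[1]]
      if (!sub %in% names(spikes)) {
        stop("sample ", sam, " has no internal-standard spike for ",
             "subclass ", sub)
      }
      isa <- is_area_of(sam, sub)
      if (is.na(isa) || isa <= 0) {
        amount[i] <- NA_real_
        failed <- c(failed, paste0(sam, "/", sub))
        next
      }
      amount[i] <- quantify_by_internal_standard(
        analytes$area[i], isa, spikes[[sub]], analytes$average_mw[i], rf)
    }
  }
  if (length(failed)) {
    warning("internal-standard area missing or zero; amounts set NA for: ",
            paste(unique(failed), collapse = ", "))
  }
  protein <- samples$protein_amount[match(analytes$sample_id,
                                          samples$sample_id)]
  out <- data.frame(sample_id = analytes$sample_id,
                    species_id = analytes$species_id,
                    subclass = analytes$subclass,
                    amount_pmol = amount,
                    amount_pmol_per_ug_protein = amount / protein,
                    out_of_range = oor, dilution_applied = dil,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a quantification table
#' @param quant Data frame from [build_quant_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  tab <- quant
  tab$amount_pmol <- fmt_num(tab$amount_pmol)
  tab$amount_pmol_per_ug_protein <- fmt_num(tab$amount_pmol_per_ug_protein)
  write_tsv(tab, path)
}

#' Read a quantification table
#' @param path TSV path written by [write_quant_table()].
#' @return Quantification data frame.
#' @export
read_quant_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(sample_id = "character",
                                   species_id = "character"))
}
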