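# Feature <-> library matching: accurate precursor mass search, weighted
# reverse dot-product MS/MS similarity, trapezoidal RT similarity and
# dual-threshold acceptance.

#' Scoring parameters for lipid identification
#'
#' @param mz_weight_m Exponent on fragment m/z in the spectral score
#'   (default 1).
#' @param intensity_weight_n_pos Exponent on fragment intensity in positive
#'   mode (default 0.6).
#' @param intensity_weight_n_neg Exponent on fragment intensity in negative
#'   mode (default 1).
#' @param spectral_threshold Minimum MS/MS spectral similarity for a match
#'   to be kept as a candidate (default 0.8; acceptance requires a score
#'   strictly larger).
#' @param rt_threshold Minimum retention-time similarity for acceptance
#'   (default 0.5, strictly larger).
#' @param precursor_tol_ppm Accurate-mass match window in ppm (default 10).
#' @param fragment_tol_da Fragment m/z match window in Da (default 0.02).
#' @param rt_plateau_a Half-width of the full-score RT plateau in minutes
#'   (default 0.15).
#' @param rt_zero_b Deviation in minutes at and beyond which the RT score
#'   is 0 (default 0.5).
#' @return Object of class `scoring_params`.
#' @export
scoring_params <- function(mz_weight_m = 1, intensity_weight_n_pos = 0.6,
                           intensity_weight_n_neg = 1,
                           spectral_threshold = 0.8, rt_threshold = 0.5,
                           precursor_tol_ppm = 10, fragment_tol_da = 0.02,
                           rt_plateau_a = 0.15, rt_zero_b = 0.5) {
  stopifnot(spectral_threshold > 0, spectral_threshold <= 1,
            rt_threshold > 0, rt_threshold <= 1,
            precursor_tol_ppm > 0, fragment_tol_da > 0,
            rt_plateau_a > 0, rt_zero_b > rt_plateau_a)
  structure(list(mz_weight_m = mz_weight_m,
                 intensity_weight_n_pos = intensity_weight_n_pos,
                 intensity_weight_n_neg = intensity_weight_n_neg,
                 spectral_threshold = spectral_threshold,
                 rt_threshold = rt_threshold,
                 precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_da = fragment_tol_da,
                 rt_plateau_a = rt_plateau_a, rt_zero_b = rt_zero_b),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("Scoring parameters:\n")
  for (k in names(x)) cat(" ", k, "=", x[[k]], "\n")
  invisible(x)
}

#' Accurate-mass candidate search
#'
#' Returns the library entries of the feature's ionization mode whose
#' precursor m/z lies within `precursor_tol_ppm` of the feature m/z,
#' sorted by absolute mass error.
#'
#' @param feature One feature: a list or one-row data frame with fields
#'   `mz` and, when an MS/MS spectrum is attached, `ms2` (its mode selects
#'   the library mode; features without MS/MS match both modes).
#' @param library A [spectral_library()].
#' @param params A [scoring_params()].
#' @return Data frame of matching entries with an extra column
#'   `mass_error_ppm` (signed, feature relative to library).
#' @export
match_mass <- function(feature, library, params = scoring_params()) {
  mz <- feature$mz
  if (is.list(mz)) mz <- mz[[1]]
  stopifnot(mz > 0)
  entries <- library$entries
  ms2 <- feature$ms2
  if (is.data.frame(feature) && !is.null(feature$ms2)) ms2 <- feature$ms2[[1]]
  if (!is.null(ms2)) entries <- entries[entries$mode == ms2$mode, ,
                                        drop = FALSE]
  if (!nrow(entries)) {
    entries$mass_error_ppm <- numeric(0)
    return(entries)
  }
  err <- (mz - entries$precursor_mz) / entries$precursor_mz * 1e6
  keep <- abs(err) <= params$precursor_tol_ppm
  out <- entries[keep, , drop = FALSE]
  out$mass_error_ppm <- err[keep]
  out <- out[order(abs(out$mass_error_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted reverse dot-product MS/MS spectral similarity
#'
#' Cosine-type similarity computed over the reference (library) fragments
#' only. Each fragment's weight is `intensity^n * mz^m`. For every library
#' fragment, the experimental intensity is the sum of experimental peak
#' intensities within `fragment_tol_da` of the library m/z (0 when none)
#' and the experimental m/z is their intensity-weighted mean (the library
#' m/z when none). The score is
#' `sum(wD * wE) / sqrt(sum(wD^2) * sum(wE^2))`, in `[0, 1]`; 0 when no
#' library fragment is matched; 1 for a spectrum scored against itself.
#' The intensity exponent `n` follows the spectra's ionization mode.
#'
#' @param experimental,reference [ms2_spectrum()] objects of equal mode;
#'   `reference` is the library spectrum.
#' @param params A [scoring_params()].
#' @return Similarity score in `[0, 1]`.
#' @export
spectral_similarity <- function(experimental, reference,
                                params = scoring_params()) {
  if (is.null(reference) || !nrow(reference$peaks)) {
    stop("reference spectrum must be non-empty")
  }
  if (!identical(experimental$mode, reference$mode)) {
    stop("experimental and reference spectra must share the ionization mode")
  }
  m <- params$mz_weight_m
  n <- if (reference$mode == "positive") {
    params$intensity_weight_n_pos
  } else params$intensity_weight_n_neg
  tol <- params$fragment_tol_da
  mzD <- reference$peaks$mz
  iD <- reference$peaks$intensity
  mzX <- experimental$peaks$mz
  iX <- experimental$peaks$intensity
  iE <- numeric(length(mzD))
  mzE <- mzD
  for (k in seq_along(mzD)) {
    hit <- which(abs(mzX - mzD[k]) <= tol)
    if (length(hit) == 1L) {
      iE[k] <- iX[hit]
      mzE[k] <- mzX[hit]
    } else if (length(hit) > 1L) {
      iE[k] <- sum(iX[hit])
      if (iE[k] > 0) mzE[k] <- sum(mzX[hit] * iX[hit]) / iE[k]
    }
  }
  wD <- iD^n * mzD^m
  wE <- iE^n * mzE^m
  dd <- sum(wD^2)
  de <- sum(wE^2)
  if (dd == 0 || de == 0) return(0)
  num <- sum(wD * wE)
  # squared-cosine form: a spectrum against itself gives num == dd == de
  # term for term, so the self-match score is exactly 1
  min(1, sqrt(num * num / (dd * de)))
}

#' Trapezoidal retention-time similarity
#'
#' Piecewise-linear score in the absolute RT deviation `d`: 1 on the
#' plateau (`d <= a`), falling linearly to 0 between `a` and `b`, and 0 at
#' and beyond `b`. Continuous everywhere, non-increasing in `d`.
#'
#' @param rt_exp,rt_pred Experimental and library-predicted retention
#'   times in minutes (vectorized).
#' @param params A [scoring_params()] supplying `rt_plateau_a` and
#'   `rt_zero_b`.
#' @return Score(s) in `[0, 1]`.
#' @export
rt_similarity <- function(rt_exp, rt_pred, params = scoring_params()) {
  stopifnot(all(rt_exp >= 0), all(rt_pred >= 0))
  a <- params$rt_plateau_a
  b <- params$rt_zero_b
  d <- abs(rt_exp - rt_pred)
  pmax(0, pmin(1, (b - d) / (b - a)))
}

#' Identify features against a spectral library
#'
#' For every feature with an attached MS/MS spectrum, all accurate-mass
#' candidates are scored for spectral and RT similarity. Candidates with
#' spectral score above `spectral_threshold` are kept; a candidate is
#' accepted when its RT score also exceeds `rt_threshold`. At most one
#' identification per feature is accepted: the highest spectral score,
#' ties broken by smaller absolute mass error, then lexicographic
#' species_id. All scored candidates are returned for audit; features
#' without MS/MS yield no rows.
#'
#' @param features Feature data frame from [read_features()] or
#'   [generate_experiment()].
#' @param library A [spectral_library()].
#' @param params A [scoring_params()].
#' @return Data frame with columns `feature_id`, `species_id`, `mode`,
#'   `adduct`, `mass_error_ppm`, `spectral_score`, `rt_score`, `accepted`.
#' @export
identify_lipids <- function(features, library, params = scoring_params()) {
  stopifnot(inherits(library, "spectral_library"))
  if (!nrow(library$entries)) stop("library must be non-empty")
  rows <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    ms2 <- features$ms2[[i]]
    if (is.null(ms2)) next
    feat <- list(mz = features$mz[i], ms2 = ms2)
    cand <- match_mass(feat, library, params)
    if (!nrow(cand)) next
    spec <- vapply(seq_len(nrow(cand)), function(j) {
      ref <- ms2_spectrum(cand$fragments[[j]]$mz,
                          cand$fragments[[j]]$intensity,
                          mode = cand$mode[j],
                          precursor_mz = cand$precursor_mz[j])
      spectral_similarity(ms2, ref, params)
    }, numeric(1))
    rt <- rt_similarity(features$rt[i], cand$predicted_rt, params)
    accepted <- rep(FALSE, nrow(cand))
    pass <- spec > params$spectral_threshold & rt > params$rt_threshold
    if (any(pass)) {
      ord <- order(-spec, abs(cand$mass_error_ppm), cand$species_id)
      best <- ord[pass[ord]][1]
      accepted[best] <- TRUE
    }
    rows[[i]] <- data.frame(
      feature_id = features$feature_id[i], species_id = cand$species_id,
      mode = cand$mode, adduct = cand$adduct,
      mass_error_ppm = cand$mass_error_ppm, spectral_score = spec,
      rt_score = rt, accepted = accepted, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(), species_id = character(),
                      mode = character(), adduct = character(),
                      mass_error_ppm = numeric(), spectral_score = numeric(),
                      rt_score = numeric(), accepted = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write the identification audit table
#' @param identifications Data frame from [identify_lipids()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_identifications <- function(identifications, path) {
  tab <- identifications
  tab$mass_error_ppm <- fmt_num(tab$mass_error_ppm)
  tab$spectral_score <- fmt_num(tab$spectral_score)
  tab$rt_score <- fmt_num(tab$rt_score)
  write_tsv(tab, path)
}

#' Read an identification audit table
#' @param path TSV path written by [write_identifications()].
#' @return Identification data frame.
#' @export
read_identifications <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(feature_id = "character",
                                   species_id = "character"))
}
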