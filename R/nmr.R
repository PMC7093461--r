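# Residue-resolved NMR intensity-ratio analysis for the VAMP2(1-96)
# construct: normalized in-cell/in-solution ratios (Y) and relative
# signal changes between conditions (Z).

N_RESIDUES <- 96L

#' Construct an NMR peak-intensity table
#'
#' @param intensities Numeric vector of crosspeak intensities indexed by
#'   residue number 1..96; `NA` marks unassignable (MISSING) residues,
#'   which is distinct from an intensity of 0 (disappeared peak).
#' @param condition_id Condition label.
#' @return Object of class `peak_table`.
#' @export
peak_table <- function(intensities, condition_id = "condition") {
  stopifnot(length(intensities) == N_RESIDUES)
  ok <- is.na(intensities) | intensities >= 0
  if (!all(ok)) stop("intensities must be >= 0 or NA")
  structure(list(condition_id = condition_id,
                 intensities = as.numeric(intensities)),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("NMR peak table '", x$condition_id, "': ",
      sum(!is.na(x$intensities)), "/", N_RESIDUES,
      " residues assigned\n", sep = "")
  invisible(x)
}

#' Read an NMR peak-intensity table
#'
#' TSV with columns `residue` and `intensity`; `NA` encodes MISSING.
#' Residues absent from the file are MISSING.
#'
#' @param path Input TSV path.
#' @param condition_id Condition label (default: file name sans extension).
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, condition_id = NULL) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  if (is.null(condition_id)) {
    condition_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("residue", "intensity"), names(tab))
  if (length(missing)) {
    stop("peak table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(tab$residue < 1 | tab$residue > N_RESIDUES)) {
    stop("residue numbers must lie within 1..", N_RESIDUES)
  }
  x <- rep(NA_real_, N_RESIDUES)
  x[tab$residue] <- tab$intensity
  peak_table(x, condition_id)
}

#' Write an NMR peak-intensity table
#' @param table A [peak_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  df <- data.frame(residue = seq_len(N_RESIDUES),
                   intensity = fmt_num(table$intensities))
  df$intensity[is.na(table$intensities)] <- "NA"
  write_tsv(df, path)
}

#' Normalized residue-resolved intensity-ratio profile (Y)
#'
#' For each residue X, `Y(X) = [I(X)/I0(X)] / [I(ref)/I0(ref)]`: the
#' perturbed-to-reference intensity ratio normalized by that of a highly
#' flexible reference residue (residue 5 by default), removing
#' spectrometer-gain differences between the two acquisitions. Residues
#' MISSING in either table are MISSING in Y. Residues whose peak vanished
#' in the perturbed condition (`I = 0`, `I0 > 0`) get `Y = 0` and a
#' `disappeared` flag -- maximal attenuation, distinct from MISSING.
#'
#' @param in_condition [peak_table()] of the perturbed condition (I).
#' @param reference_condition [peak_table()] of the reference condition
#'   (I0), e.g. the protein free in solution.
#' @param reference_residue Normalization residue (default 5); must be
#'   assigned and nonzero in both tables.
#' @return Object of class `ratio_profile`: list with numeric vectors `Y`
#'   and logical `disappeared` (length 96), `reference_residue`, and the
#'   two condition ids.
#' @export
relative_intensity_profile <- function(in_condition, reference_condition,
                                       reference_residue = 5) {
  stopifnot(inherits(in_condition, "peak_table"),
            inherits(reference_condition, "peak_table"),
            reference_residue >= 1, reference_residue <= N_RESIDUES)
  I <- in_condition$intensities
  I0 <- reference_condition$intensities
  rI <- I[reference_residue]
  rI0 <- I0[reference_residue]
  if (is.na(rI) || is.na(rI0) || rI == 0 || rI0 == 0) {
    stop("reference residue ", reference_residue,
         " is MISSING or zero in one of the conditions")
  }
  norm <- rI / rI0
  Y <- rep(NA_real_, N_RESIDUES)
  disappeared <- rep(FALSE, N_RESIDUES)
  defined <- !is.na(I) & !is.na(I0) & I0 > 0
  Y[defined] <- (I[defined] / I0[defined]) / norm
  gone <- defined & I == 0
  disappeared[gone] <- TRUE
  structure(list(Y = Y, disappeared = disappeared,
                 reference_residue = as.integer(reference_residue),
                 condition_id = in_condition$condition_id,
                 reference_condition_id = reference_condition$condition_id),
            class = "ratio_profile")
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat("NMR ratio profile '", x$condition_id, "' vs '",
      x$reference_condition_id, "' (reference residue ",
      x$reference_residue, ")\n", sep = "")
  cat("  defined residues:", sum(!is.na(x$Y)),
      " disappeared:", sum(x$disappeared), "\n")
  invisible(x)
}

#' Relative signal change between two profiles (Z)
#'
#' `Z(X) = (Y(X) - Y0(X)) / Y0(X)` per residue, comparing a treated
#' condition's profile to a control profile sharing the same reference
#' residue. Z is defined only where both profiles are defined and the
#' control Y0 is nonzero; MISSING (`NA`) elsewhere.
#'
#' @param profile [relative_intensity_profile()] of the treated condition.
#' @param control_profile Profile of the control condition.
#' @return Numeric vector Z of length 96.
#' @export
relative_change <- function(profile, control_profile) {
  stopifnot(inherits(profile, "ratio_profile"),
            inherits(control_profile, "ratio_profile"))
  if (profile$reference_residue != control_profile$reference_residue) {
    stop("profiles use different reference residues: ",
         profile$reference_residue, " vs ",
         control_profile$reference_residue)
  }
  Y <- profile$Y
  Y0 <- control_profile$Y
  Z <- rep(NA_real_, N_RESIDUES)
  defined <- !is.na(Y) & !is.na(Y0) & Y0 != 0
  Z[defined] <- (Y[defined] - Y0[defined]) / Y0[defined]
  Z
}

#' Default VAMP2(1-96) domain regions
#'
#' Half-open `[start, end)` residue intervals for the proline-rich
#' N-terminal domain, the SNARE motif and the juxta-membrane segment
#' (residues 78-96, which lose their signals entirely on membranes).
#'
#' @return Named list of `c(start, end)` integer pairs.
#' @export
vamp2_regions <- function() {
  list(p_rich_nt = c(1L, 29L), snare_motif = c(29L, 78L), jmd = c(78L, 97L))
}

#' Regional summary of a profile or Z vector
#'
#' @param values A `ratio_profile` (its Y is summarized) or a numeric
#'   vector of length 96 (e.g. Z from [relative_change()]).
#' @param regions Named list of half-open `[start, end)` residue
#'   intervals (default [vamp2_regions()]).
#' @return Data frame with columns `region`, `mean`, `min`, `n_defined`.
#'   Regions with no defined residue report `NA` summaries with
#'   `n_defined = 0`.
#' @export
region_summary <- function(values, regions = vamp2_regions()) {
  if (inherits(values, "ratio_profile")) values <- values$Y
  stopifnot(length(values) == N_RESIDUES)
  rows <- lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    stopifnot(r[1] >= 1, r[2] <= N_RESIDUES + 1L, r[1] < r[2])
    v <- values[seq.int(r[1], r[2] - 1L)]
    v <- v[!is.na(v)]
    data.frame(region = nm,
               mean = if (length(v)) mean(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               n_defined = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a ratio profile (and optional Z) to TSV
#'
#' Columns `residue`, `Y`, `disappeared`, `Z`; `NA` encodes MISSING.
#' Written and re-read profiles are equal on values and MISSING masks.
#'
#' @param profile A `ratio_profile`.
#' @param path Output TSV path.
#' @param Z Optional Z vector from [relative_change()].
#' @return `path`, invisibly.
#' @export
write_ratio_profile <- function(profile, path, Z = NULL) {
  if (is.null(Z)) Z <- rep(NA_real_, N_RESIDUES)
  df <- data.frame(residue = seq_len(N_RESIDUES),
                   Y = fmt_num(profile$Y),
                   disappeared = as.integer(profile$disappeared),
                   Z = fmt_num(Z), stringsAsFactors = FALSE)
  df$Y[is.na(profile$Y)] <- "NA"
  df$Z[is.na(Z)] <- "NA"
  write_tsv(df, path)
}

#' Read a ratio profile written by [write_ratio_profile()]
#' @param path TSV path.
#' @return List with `Y`, `disappeared`, `Z` vectors of length 96.
#' @export
read_ratio_profile <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  Y <- rep(NA_real_, N_RESIDUES)
  Z <- rep(NA_real_, N_RESIDUES)
  disappeared <- rep(FALSE, N_RESIDUES)
  Y[tab$residue] <- suppressWarnings(as.numeric(tab$Y))
  Z[tab$residue] <- suppressWarnings(as.numeric(tab$Z))
  disappeared[tab$residue] <- tab$disappeared == 1
  list(Y = Y, disappeared = disappeared, Z = Z)
}
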