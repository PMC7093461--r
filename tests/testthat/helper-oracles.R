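# Independent oracles, coded separately from the package implementation.

# Direct evaluation of the weighted reverse dot-product: explicit loops and
# accumulators over the reference (library) fragments.
oracle_spectral_similarity <- function(exp_mz, exp_int, ref_mz, ref_int,
                                       m, n, tol) {
  num <- 0
  den_d <- 0
  den_e <- 0
  for (k in seq_along(ref_mz)) {
    ie <- 0
    mz_sum <- 0
    for (j in seq_along(exp_mz)) {
      if (abs(exp_mz[j] - ref_mz[k]) <= tol) {
        ie <- ie + exp_int[j]
        mz_sum <- mz_sum + exp_mz[j] * exp_int[j]
      }
    }
    mze <- if (ie > 0) mz_sum / ie else ref_mz[k]
    wd <- ref_int[k]^n * ref_mz[k]^m
    we <- ie^n * mze^m
    num <- num + wd * we
    den_d <- den_d + wd^2
    den_e <- den_e + we^2
  }
  if (den_d == 0 || den_e == 0) return(0)
  num / sqrt(den_d * den_e)
}

# Piecewise trapezoid evaluated case by case.
oracle_trapezoid <- function(rt_exp, rt_pred, a, b) {
  d <- abs(rt_exp - rt_pred)
  if (d <= a) return(1)
  if (d >= b) return(0)
  (b - d) / (b - a)
}

# Textbook pooled-variance two-sample t-test (two-sided).
oracle_pooled_t <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Adduct arithmetic recomputed from first principles.
oracle_adduct_mz <- function(mass, adduct) {
  shift <- switch(adduct,
                  "[M+H]+" = 1.007276, "[M+NH4]+" = 18.033823,
                  "[M-H]-" = -1.007276, "[M+HCOO]-" = 44.998201,
                  stop("unknown"))
  mass + shift
}

# Small deterministic fixture library: three species, mixed modes.
make_test_library <- function() {
  species <- rbind(
    lipid_species("PC_34_1", "PC", 34, 1),
    lipid_species("PE_36_2", "PE", 36, 2),
    lipid_species("SM_36_2", "SM", 36, 2))
  entries <- data.frame(
    species_id = c("PC_34_1", "PE_36_2", "SM_36_2"),
    mode = c("positive", "negative", "positive"),
    adduct = c("[M+H]+", "[M-H]-", "[M+H]+"),
    precursor_mz = c(
      precursor_mz(species$monoisotopic_mass[1], "[M+H]+"),
      precursor_mz(species$monoisotopic_mass[2], "[M-H]-"),
      precursor_mz(species$monoisotopic_mass[3], "[M+H]+")),
    predicted_rt = c(5.2, 6.1, 4.3), stringsAsFactors = FALSE)
  entries$fragments <- list(
    data.frame(mz = c(184.0733, 500.5, 255.2), intensity = c(100, 40, 25)),
    data.frame(mz = c(196.0380, 480.3, 281.2), intensity = c(80, 55, 30)),
    data.frame(mz = c(184.0733, 520.4, 264.3), intensity = c(90, 35, 20)))
  spectral_library(species, entries)
}

spectrum_from_entry <- function(library, i) {
  fr <- library$entries$fragments[[i]]
  ms2_spectrum(fr$mz, fr$intensity, library$entries$mode[i],
               library$entries$precursor_mz[i])
}

# Random small spectrum pair generator for oracle-equivalence checks:
# experimental peaks cluster near reference m/z values so the matching
# (including multi-peak sums) is exercised.
random_spectrum_pair <- function(max_peaks = 6, tol = 0.5) {
  nr <- sample.int(max_peaks, 1)
  ref_mz <- sort(runif(nr, 100, 110))
  ref_int <- runif(nr, 0.5, 100)
  ne <- sample.int(max_peaks, 1)
  exp_mz <- sort(runif(ne, 100, 110))
  exp_int <- runif(ne, 0, 100)
  list(ref_mz = ref_mz, ref_int = ref_int, exp_mz = exp_mz,
       exp_int = exp_int, tol = tol)
}
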