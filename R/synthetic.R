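# Seeded synthetic-data generators: in-silico spectral library, two-group
# (lipid raft vs non-raft) lipidomics experiments, calibration levels and
# residue-resolved NMR peak tables, all with joined ground truth.

#' Simulation configuration
#'
#' A single root `seed` derives fixed per-component streams (library,
#' true amounts, measurement noise, unknowns, NMR), so changing a noise
#' level never changes the underlying truth. Group-level truth is shared
#' by the replicates of a group; all noise is per-replicate measurement
#' noise.
#'
#' Subclass effects are raft/non-raft mol-percent ratios applied to the
#' built-in base (non-raft) composition; the PC effect is computed by
#' compositional closure so that the configured ratios of the remaining
#' subclasses hold exactly (PC, the bulk class, absorbs the closure,
#' consistent with it being the least group-discriminating class).
#'
#' @param seed Integer root seed; fixes all generator output bit-for-bit.
#' @param n_species_per_subclass Molecular species generated per subclass
#'   (cholesterol is always a single species).
#' @param replicates_per_group Biological replicates per group (default 3).
#' @param total_lipid_pmol Total lipid moles per sample (default 2000).
#' @param base_composition Named non-raft subclass mole fractions
#'   (defaults are SV-membrane-like, with SM at 0.12 mol%).
#' @param subclass_effects Named raft/non-raft mol% ratios; `NA` for PC
#'   marks the closure class (default SM 6.25, Chol 1.5, Cer 2, acidic
#'   phospholipids depleted in raft).
#' @param chain_effect Per-carbon exponential tilt of raft within-subclass
#'   abundances toward shorter acyl chains (default 0.1).
#' @param saturation_effect Per-double-bond tilt of raft abundances toward
#'   saturated species (default 0.15).
#' @param area_noise_sigma Log-normal sigma of peak-area noise
#'   (default 0.1).
#' @param rt_jitter_sd Gaussian SD of RT jitter in minutes (default 0.05).
#' @param fragment_noise_sigma Log-normal sigma of fragment-intensity
#'   noise (default 0.2); contaminant peaks are added only when > 0.
#' @param n_decoy_library Decoy library species never present in samples
#'   (default 10).
#' @param n_unknown_features Off-library features per experiment
#'   (default 10).
#' @param dropout_rate Probability a non-standard feature is lost
#'   (default 0.05).
#' @param protein_amount_ug Protein amount per sample in ug (default 50).
#' @param rt_carbon_coef,rt_db_coef Coefficients of the predicted-RT model
#'   `subclass offset + c1 * carbons - c2 * double_bonds` in minutes
#'   (defaults 0.15 and 0.35).
#' @param snare_change_up,snare_change_down Relative SNARE-motif Y change
#'   in cholesterol up-/down-regulated conditions (defaults +0.3, -0.3).
#' @param nmr_noise_sd Log-normal sigma of NMR intensity noise (default 0).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_species_per_subclass = 5,
                       replicates_per_group = 3, total_lipid_pmol = 2000,
                       base_composition = NULL, subclass_effects = NULL,
                       chain_effect = 0.1, saturation_effect = 0.15,
                       area_noise_sigma = 0.1, rt_jitter_sd = 0.05,
                       fragment_noise_sigma = 0.2, n_decoy_library = 10,
                       n_unknown_features = 10, dropout_rate = 0.05,
                       protein_amount_ug = 50, rt_carbon_coef = 0.15,
                       rt_db_coef = 0.35, snare_change_up = 0.3,
                       snare_change_down = -0.3, nmr_noise_sd = 0) {
  if (is.null(base_composition)) {
    base_composition <- c(Chol = 0.30, PC = 0.32, PE = 0.20, PS = 0.055,
                          PI = 0.035, PG = 0.02, PA = 0.012, Cer = 0.008,
                          SM = 0.0012, LPC = 0.008, LPE = 0.008,
                          TG = 0.0328)
  }
  if (is.null(subclass_effects)) {
    subclass_effects <- c(Chol = 1.5, PC = NA, PE = 0.85, PS = 0.4,
                          PI = 0.45, PG = 0.5, PA = 0.95, Cer = 2,
                          SM = 6.25, LPC = 1, LPE = 1, TG = 0.8)
  }
  stopifnot(abs(sum(base_composition) - 1) < 1e-9,
            setequal(names(base_composition), lipid_subclasses()),
            setequal(names(subclass_effects), lipid_subclasses()),
            replicates_per_group >= 1, n_species_per_subclass >= 0,
            area_noise_sigma >= 0, rt_jitter_sd >= 0,
            fragment_noise_sigma >= 0, dropout_rate >= 0, dropout_rate < 1,
            n_decoy_library >= 0, n_unknown_features >= 0,
            total_lipid_pmol > 0, protein_amount_ug > 0)
  structure(list(seed = as.integer(seed),
                 n_species_per_subclass = n_species_per_subclass,
                 replicates_per_group = replicates_per_group,
                 total_lipid_pmol = total_lipid_pmol,
                 base_composition = base_composition,
                 subclass_effects = subclass_effects,
                 chain_effect = chain_effect,
                 saturation_effect = saturation_effect,
                 area_noise_sigma = area_noise_sigma,
                 rt_jitter_sd = rt_jitter_sd,
                 fragment_noise_sigma = fragment_noise_sigma,
                 n_decoy_library = n_decoy_library,
                 n_unknown_features = n_unknown_features,
                 dropout_rate = dropout_rate,
                 protein_amount_ug = protein_amount_ug,
                 rt_carbon_coef = rt_carbon_coef, rt_db_coef = rt_db_coef,
                 snare_change_up = snare_change_up,
                 snare_change_down = snare_change_down,
                 nmr_noise_sd = nmr_noise_sd),
            class = "sim_config")
}

#' Resolved subclass effects with compositional closure
#'
#' Returns the raft/non-raft mol% ratio per subclass with the `NA`
#' (closure) entry solved so that the raft fractions sum to 1.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector of effects.
#' @export
resolved_effects <- function(config) {
  f <- config$base_composition
  e <- config$subclass_effects[names(f)]
  open <- names(e)[is.na(e)]
  if (length(open) > 1) stop("at most one closure subclass (NA effect)")
  if (length(open) == 1) {
    rest <- sum(f[names(e) != open] * e[names(e) != open])
    if (rest >= 1) {
      stop("configured effects leave no mass for the closure subclass")
    }
    e[open] <- (1 - rest) / f[open]
  } else if (abs(sum(f * e) - 1) > 1e-9) {
    stop("subclass effects must satisfy sum(f * e) = 1; set one effect NA ",
         "to let that subclass absorb the closure")
  }
  e
}

# --- library generation -----------------------------------------------------

subclass_adduct <- function() {
  c(PC = "[M+H]+", SM = "[M+H]+", LPC = "[M+H]+", Cer = "[M+H]+",
    TG = "[M+NH4]+", Chol = "[M+NH4]+",
    PE = "[M-H]-", PS = "[M-H]-", PI = "[M-H]-", PG = "[M-H]-",
    PA = "[M-H]-", LPE = "[M-H]-")
}

subclass_rt_offset <- function() {
  c(PC = 3.2, PE = 3.0, PS = 2.4, PI = 2.2, PG = 2.6, PA = 2.8, Cer = 4.0,
    SM = 3.4, LPC = 0.8, LPE = 0.6, TG = 6.0, Chol = 5.0)
}

subclass_diagnostic_mz <- function() {
  c(PC = 184.0733, SM = 184.0733, LPC = 184.0733, PE = 196.0380,
    LPE = 196.0380, PS = 152.9958, PI = 241.0119, PG = 227.0326,
    PA = 152.9958, Cer = 264.2686, TG = 173.0801, Chol = 369.3516)
}

subclass_neutral_loss <- function() {
  c(PC = 59.0735, SM = 183.0661, LPC = 18.0106, PE = 43.0422,
    LPE = 43.0422, PS = 87.0320, PI = 162.0528, PG = 74.0368,
    PA = 97.9769, Cer = 18.0106, TG = 17.0265, Chol = 35.0371)
}

subclass_grid <- function(subclass) {
  if (subclass %in% c("LPC", "LPE")) {
    expand.grid(c = seq(14, 22, 2), d = 0:2)
  } else if (subclass == "TG") {
    expand.grid(c = seq(44, 58, 2), d = 0:6)
  } else if (subclass == "Chol") {
    data.frame(c = 27, d = 1)
  } else {
    expand.grid(c = seq(30, 40, 2), d = 0:6)
  }
}

predicted_rt_model <- function(subclass, carbons, dbs, config) {
  off <- subclass_rt_offset()
  pmax(0, unname(off[subclass]) + config$rt_carbon_coef * carbons -
         config$rt_db_coef * dbs)
}

make_fragments <- function(subclass, carbons, dbs, precursor,
                           label_shift = 0) {
  diag_mz <- unname(subclass_diagnostic_mz()[subclass])
  nl_mz <- precursor - unname(subclass_neutral_loss()[subclass])
  if (subclass == "Chol") {
    mz <- c(diag_mz, nl_mz, 161.1325)
  } else if (subclass %in% c("LPC", "LPE")) {
    fa <- 14.01565 * carbons - 2.01565 * dbs + 31.98983 + label_shift
    mz <- c(diag_mz, nl_mz, fa)
  } else {
    c1 <- floor(carbons / 2)
    c2 <- carbons - c1
    d1 <- floor(dbs / 2)
    d2 <- dbs - d1
    fa1 <- 14.01565 * c1 - 2.01565 * d1 + 31.98983
    fa2 <- 14.01565 * c2 - 2.01565 * d2 + 31.98983 + label_shift
    mz <- c(diag_mz, nl_mz, fa1, fa2)
  }
  int <- stats::rgamma(length(mz), shape = 2, rate = 1)
  int <- int / max(int) * 100
  # merge peaks closer than the default fragment tolerance (coincident
  # diagnostic/neutral-loss ions, symmetric acyl splits) so every library
  # spectrum has distinct fragment m/z values
  o <- order(mz)
  mz <- mz[o]
  int <- int[o]
  grp <- cumsum(c(TRUE, diff(mz) > 0.02))
  data.frame(mz = as.numeric(tapply(mz, grp, min)),
             intensity = as.numeric(tapply(int, grp, sum)))
}

internal_standard_specs <- function() {
  d7 <- 7 * DEUTERIUM_SHIFT
  d9 <- 9 * DEUTERIUM_SHIFT
  data.frame(
    species_id = paste0("IS_", c("PC", "PE", "PG", "PS", "PI", "PA", "Cer",
                                 "SM", "LPC", "LPE", "TG", "Chol")),
    subclass = c("PC", "PE", "PG", "PS", "PI", "PA", "Cer", "SM", "LPC",
                 "LPE", "TG", "Chol"),
    c = c(33, 33, 33, 33, 33, 33, 33, 36, 18, 18, 48, 27),
    d = c(1, 1, 1, 1, 1, 1, 1, 2, 1, 1, 1, 1),
    shift = c(d7, d7, d7, d7, d7, d7, d7, d9, d7, d7, d7, d7),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic in-silico spectral library with ground truth
#'
#' Species span the 12 subclasses with varied acyl carbons and double
#' bonds from the built-in mass model; each entry carries a
#' subclass-diagnostic ion, a precursor-derived neutral-loss ion and
#' per-acyl fragments with seeded intensities. Predicted RT follows
#' `subclass offset + c1 * carbons - c2 * double_bonds` (monotone in
#' carbons, antitone in double bonds). The 12 deuterated internal
#' standards are always included; `n_decoy_library` decoy species are
#' added that never occur in generated samples.
#'
#' @param config A [sim_config()].
#' @return List with `library` (a [spectral_library()]) and `truth`
#'   (data frame `species_id`, `subclass`, `is_decoy`,
#'   `is_internal_standard`).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  adducts <- subclass_adduct()
  species_rows <- list()
  entry_rows <- list()
  frags <- list()
  decoy_pool <- list()
  add_species <- function(id, subclass, c, d, shift = 0, is_is = FALSE,
                          decoy = FALSE) {
    sp <- lipid_species(id, subclass, c, d, label_mass_shift = shift,
                        is_internal_standard = is_is, is_decoy = decoy)
    adduct <- unname(adducts[subclass])
    pmz <- precursor_mz(sp$monoisotopic_mass, adduct)
    species_rows[[length(species_rows) + 1L]] <<- sp
    entry_rows[[length(entry_rows) + 1L]] <<- data.frame(
      species_id = id, mode = adduct_mode(adduct), adduct = adduct,
      precursor_mz = pmz,
      predicted_rt = predicted_rt_model(subclass, c, d, config),
      stringsAsFactors = FALSE)
    frags[[length(frags) + 1L]] <<- make_fragments(subclass, c, d, pmz,
                                                   shift)
  }
  for (sub in lipid_subclasses()) {
    grid <- subclass_grid(sub)
    n <- min(config$n_species_per_subclass, nrow(grid))
    if (sub == "Chol") n <- min(1L, config$n_species_per_subclass)
    if (n == 0) {
      decoy_pool[[sub]] <- grid
      next
    }
    pick <- sample.int(nrow(grid), n)
    for (k in pick) {
      add_species(sprintf("%s_%d_%d", sub, grid$c[k], grid$d[k]),
                  sub, grid$c[k], grid$d[k])
    }
    decoy_pool[[sub]] <- grid[-pick, , drop = FALSE]
  }
  is_spec <- internal_standard_specs()
  for (i in seq_len(nrow(is_spec))) {
    add_species(is_spec$species_id[i], is_spec$subclass[i], is_spec$c[i],
                is_spec$d[i], shift = is_spec$shift[i], is_is = TRUE)
  }
  if (config$n_decoy_library > 0) {
    pool_subs <- setdiff(lipid_subclasses(), "Chol")
    made <- 0L
    k <- 0L
    while (made < config$n_decoy_library) {
      sub <- pool_subs[(k %% length(pool_subs)) + 1L]
      k <- k + 1L
      pool <- decoy_pool[[sub]]
      if (is.null(pool) || !nrow(pool)) next
      j <- sample.int(nrow(pool), 1)
      add_species(sprintf("DEC_%s_%d_%d", sub, pool$c[j], pool$d[j]),
                  sub, pool$c[j], pool$d[j], decoy = TRUE)
      decoy_pool[[sub]] <- pool[-j, , drop = FALSE]
      made <- made + 1L
    }
  }
  species <- do.call(rbind, species_rows)
  entries <- do.call(rbind, entry_rows)
  rownames(species) <- rownames(entries) <- NULL
  entries$fragments <- frags
  lib <- spectral_library(species, entries)
  truth <- species[, c("species_id", "subclass", "is_decoy",
                       "is_internal_standard")]
  list(library = lib, truth = truth)
}

# --- experiment generation --------------------------------------------------

#' Generate a two-group lipidomics experiment with ground truth
#'
#' True per-species amounts come from a seeded within-subclass mixture
#' scaled by the group's subclass mole fractions (non-raft base
#' composition times [resolved_effects()] for raft); raft within-subclass
#' weights are tilted toward shorter, more saturated species and
#' renormalized, so subclass mol% ratios equal the configured effects
#' exactly at zero noise. Peak areas are amount (ug) times a per-subclass
#' response times log-normal noise; internal-standard features are spiked
#' per the group's panel and never dropped; feature RT adds Gaussian
#' jitter to the library prediction; MS/MS spectra are library fragments
#' under log-normal intensity noise plus seeded contaminant peaks (only
#' when `fragment_noise_sigma > 0`); non-standard features drop out at
#' `dropout_rate`; `n_unknown_features` features lie off-library by
#' construction (> 50 ppm from every precursor).
#'
#' @param library_truth List from [generate_library()].
#' @param config The same [sim_config()].
#' @return List with `features` (data frame with `ms2` list column),
#'   `samples` (metadata data frame), and `truth` (list with `species`,
#'   `amounts`, `features` data frames).
#' @export
generate_experiment <- function(library_truth, config) {
  stopifnot(inherits(config, "sim_config"))
  lib <- library_truth$library
  sp <- lib$species
  entries <- lib$entries
  R <- config$replicates_per_group
  samples <- data.frame(
    sample_id = c(paste0("raft_", seq_len(R)),
                  paste0("nonraft_", seq_len(R))),
    group = rep(c("raft", "nonraft"), each = R),
    protein_amount = config$protein_amount_ug,
    dilution_factor = 1, stringsAsFactors = FALSE)
  samples$is_spikes <- lapply(samples$group, default_spike_panel)

  real <- sp[!sp$is_decoy & !sp$is_internal_standard, , drop = FALSE]
  effects <- resolved_effects(config)
  f <- config$base_composition

  # group-level truth: within-subclass weights, seeded independent of noise
  set.seed(config$seed + 211L)
  truth_rows <- list()
  for (sub in unique(real$subclass)) {
    rs <- real[real$subclass == sub, , drop = FALSE]
    w <- stats::rgamma(nrow(rs), shape = 2, rate = 1)
    w_non <- w / sum(w)
    tilt <- exp(-config$chain_effect *
                  (rs$total_carbons - mean(rs$total_carbons)) -
                config$saturation_effect *
                  (rs$total_double_bonds - mean(rs$total_double_bonds)))
    w_raft <- w * tilt / sum(w * tilt)
    amt_non <- config$total_lipid_pmol * f[[sub]] * w_non
    amt_raft <- config$total_lipid_pmol * f[[sub]] * effects[[sub]] * w_raft
    truth_rows[[sub]] <- data.frame(
      species_id = rep(rs$species_id, 2),
      group = rep(c("nonraft", "raft"), each = nrow(rs)),
      amount_pmol = c(amt_non, amt_raft), stringsAsFactors = FALSE)
  }
  group_truth <- do.call(rbind, truth_rows)
  rownames(group_truth) <- NULL

  set.seed(config$seed + 223L)
  response <- stats::setNames(
    1e5 * stats::rlnorm(length(lipid_subclasses()), 0, 0.3),
    lipid_subclasses())

  amounts <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    gt <- group_truth[group_truth$group == samples$group[i], , drop = FALSE]
    data.frame(sample_id = samples$sample_id[i],
               species_id = gt$species_id, amount_pmol = gt$amount_pmol,
               stringsAsFactors = FALSE)
  }))

  # per-replicate measurement noise; variate consumption is independent of
  # the noise levels so truth and noise streams stay aligned across configs
  set.seed(config$seed + 307L)
  feat_rows <- list()
  ms2_list <- list()
  truth_feat <- list()
  n_feat <- 0L
  ekey <- entries$species_id
  add_feature <- function(sample_id, species_id, amount_ug, is_is) {
    ei <- match(species_id, ekey)
    e <- entries[ei, ]
    frag <- entries$fragments[[ei]]
    sub <- sp$subclass[match(species_id, sp$species_id)]
    area_noise <- stats::rlnorm(1, 0, config$area_noise_sigma)
    rt_noise <- stats::rnorm(1, 0, max(config$rt_jitter_sd, 0))
    frag_noise <- stats::rlnorm(nrow(frag), 0, config$fragment_noise_sigma)
    cont_mz <- stats::runif(2, 100, max(150, e$precursor_mz - 10))
    cont_int <- stats::runif(2, 0.02, 0.15) * max(frag$intensity)
    drop_u <- stats::runif(1)
    if (!is_is && drop_u < config$dropout_rate) return(invisible(NULL))
    area <- amount_ug * unname(response[sub]) * area_noise
    mzv <- frag$mz
    intv <- frag$intensity * frag_noise
    if (config$fragment_noise_sigma > 0) {
      mzv <- c(mzv, cont_mz)
      intv <- c(intv, cont_int)
    }
    n_feat <<- n_feat + 1L
    id <- sprintf("F%05d", n_feat)
    feat_rows[[n_feat]] <<- data.frame(
      feature_id = id, sample_id = sample_id, mz = e$precursor_mz,
      rt = max(0, e$predicted_rt + rt_noise), area = area,
      stringsAsFactors = FALSE)
    ms2_list[[n_feat]] <<- ms2_spectrum(mzv, intv, e$mode, e$precursor_mz)
    truth_feat[[n_feat]] <<- data.frame(
      feature_id = id, sample_id = sample_id, species_id = species_id,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(samples))) {
    sam <- samples$sample_id[i]
    amt <- amounts[amounts$sample_id == sam, , drop = FALSE]
    for (j in seq_len(nrow(amt))) {
      spi <- match(amt$species_id[j], sp$species_id)
      amount_ug <- amt$amount_pmol[j] * 1e-6 * sp$average_mw[spi]
      add_feature(sam, amt$species_id[j], amount_ug, is_is = FALSE)
    }
    spikes <- samples$is_spikes[[i]]
    for (is_id in sp$species_id[sp$is_internal_standard]) {
      sub <- sp$subclass[match(is_id, sp$species_id)]
      add_feature(sam, is_id, spikes[[sub]], is_is = TRUE)
    }
  }

  # off-library unknowns: > 50 ppm from every library precursor
  set.seed(config$seed + 601L)
  if (config$n_unknown_features > 0) {
    lib_mz <- entries$precursor_mz
    for (u in seq_len(config$n_unknown_features)) {
      repeat {
        mz <- stats::runif(1, 400, 900)
        if (all(abs(mz - lib_mz) / lib_mz * 1e6 > 50)) break
      }
      n_feat <- n_feat + 1L
      id <- sprintf("F%05d", n_feat)
      sam <- samples$sample_id[((u - 1L) %% nrow(samples)) + 1L]
      mode <- if (u %% 2 == 0) "positive" else "negative"
      pk_mz <- sort(stats::runif(3, 100, mz))
      pk_int <- stats::runif(3, 10, 100)
      feat_rows[[n_feat]] <- data.frame(
        feature_id = id, sample_id = sam, mz = mz,
        rt = stats::runif(1, 1, 14),
        area = stats::rlnorm(1, log(1e5), 1), stringsAsFactors = FALSE)
      ms2_list[[n_feat]] <- ms2_spectrum(pk_mz, pk_int, mode, mz)
      truth_feat[[n_feat]] <- data.frame(
        feature_id = id, sample_id = sam, species_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  features <- do.call(rbind, feat_rows)
  rownames(features) <- NULL
  features$ms2 <- ms2_list
  truth <- list(species = library_truth$truth, amounts = amounts,
                features = do.call(rbind, truth_feat))
  rownames(truth$features) <- NULL
  list(features = features, samples = samples, truth = truth)
}

#' Generate external calibration levels
#'
#' Response ratios on a known line with optional Gaussian noise, spanning
#' the assay's declared linear range.
#'
#' @param true_slope,true_intercept Generating line.
#' @param concentrations Level concentrations in ug/mL (defaults span
#'   0.5-200).
#' @param noise_sd Gaussian SD of response noise (default 0).
#' @param seed Seed for the noise draws.
#' @return Data frame with `concentration` and `response_ratio`.
#' @export
generate_calibration <- function(true_slope = 0.05, true_intercept = 0,
                                 concentrations = c(0.5, 1, 5, 20, 50, 100,
                                                    200),
                                 noise_sd = 0, seed = 1) {
  set.seed(seed + 503L)
  data.frame(concentration = concentrations,
             response_ratio = true_slope * concentrations + true_intercept +
               stats::rnorm(length(concentrations), 0, noise_sd))
}

# --- NMR generation ---------------------------------------------------------

nmr_unassignable <- function() {
  sort(c(4L, 8L, 13L, 17L, 22L, 24L, 28L, 32L, 27L, 61L))
}

#' Generate residue-resolved NMR peak tables with ground truth
#'
#' Produces peak tables for four conditions: `solution` (reference),
#' `cell` (control in-cell), `chol_up` and `chol_down`. The in-cell
#' attenuation geography is region-wise: proline-rich N-terminus (1-28)
#' unattenuated, SNARE motif (29-77) attenuated to 0.5, residues 78-96
#' disappeared (intensity 0). Cholesterol up/down scale the SNARE-motif
#' attenuation by `1 + snare_change_up` / `1 + snare_change_down`.
#' Unassignable residues (eight N-terminal prolines, T27, S61, as
#' stand-ins for the real assignment gaps) are MISSING in every table.
#'
#' @param config A [sim_config()].
#' @return List with `tables` (named list of [peak_table()]s) and `truth`
#'   (data frame of per-residue attenuations per condition).
#' @export
generate_nmr_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 401L)
  res <- seq_len(N_RESIDUES)
  base <- ifelse(res <= 28, 130, 100)
  att_cell <- ifelse(res <= 28, 1, ifelse(res <= 77, 0.5, 0))
  att_up <- ifelse(res >= 29 & res <= 77,
                   att_cell * (1 + config$snare_change_up), att_cell)
  att_down <- ifelse(res >= 29 & res <= 77,
                     att_cell * (1 + config$snare_change_down), att_cell)
  noise <- function() {
    if (config$nmr_noise_sd > 0) {
      stats::rlnorm(N_RESIDUES, 0, config$nmr_noise_sd)
    } else rep(1, N_RESIDUES)
  }
  mask <- function(x) {
    x[nmr_unassignable()] <- NA_real_
    x
  }
  tables <- list(
    solution = peak_table(mask(base * noise()), "solution"),
    cell = peak_table(mask(base * att_cell * noise()), "cell"),
    chol_up = peak_table(mask(base * att_up * noise()), "chol_up"),
    chol_down = peak_table(mask(base * att_down * noise()), "chol_down"))
  truth <- data.frame(residue = res, attenuation_cell = att_cell,
                      attenuation_chol_up = att_up,
                      attenuation_chol_down = att_down)
  list(tables = tables, truth = truth)
}

#' Write a full simulated experiment to disk
#'
#' Emits `library.msp`, `features.tsv`, `spectra.mgf`, `samples.yaml`,
#' `truth_amounts.tsv`, `truth_features.tsv` and `nmr_<condition>.tsv`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  libt <- generate_library(config)
  exp <- generate_experiment(libt, config)
  nmr <- generate_nmr_profiles(config)
  paths <- c(library = file.path(outdir, "library.msp"),
             features = file.path(outdir, "features.tsv"),
             spectra = file.path(outdir, "spectra.mgf"),
             samples = file.path(outdir, "samples.yaml"),
             truth_amounts = file.path(outdir, "truth_amounts.tsv"),
             truth_features = file.path(outdir, "truth_features.tsv"))
  write_library(libt$library, paths[["library"]])
  write_features(exp$features, paths[["features"]], paths[["spectra"]])
  write_sample_meta(exp$samples, paths[["samples"]])
  amounts <- exp$truth$amounts
  amounts$amount_pmol <- fmt_num(amounts$amount_pmol)
  write_tsv(amounts, paths[["truth_amounts"]])
  write_tsv(exp$truth$features, paths[["truth_features"]])
  for (nm in names(nmr$tables)) {
    p <- file.path(outdir, paste0("nmr_", nm, ".tsv"))
    write_peak_table(nmr$tables[[nm]], p)
    paths[[paste0("nmr_", nm)]] <- p
  }
  invisible(paths)
}
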