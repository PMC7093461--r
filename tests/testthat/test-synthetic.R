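test_that("equal seeds reproduce every generated artifact bit-for-bit", {
  cfg <- sim_config(seed = 31)
  a <- generate_library(cfg)
  b <- generate_library(cfg)
  expect_identical(a, b)
  ea <- generate_experiment(a, cfg)
  eb <- generate_experiment(b, cfg)
  expect_identical(ea, eb)
  na <- generate_nmr_profiles(cfg)
  expect_identical(na, generate_nmr_profiles(cfg))

  d1 <- file.path(withr::local_tempdir(), "r1")
  d2 <- file.path(withr::local_tempdir(), "r2")
  p1 <- write_simulation(cfg, d1)
  p2 <- write_simulation(cfg, d2)
  for (k in names(p1)) {
    expect_identical(readBin(p1[[k]], "raw", file.size(p1[[k]])),
                     readBin(p2[[k]], "raw", file.size(p2[[k]])),
                     label = paste("bytes of", k))
  }
  # different seed, different draws
  other <- generate_library(sim_config(seed = 32))
  expect_false(identical(a$library$entries$fragments,
                         other$library$entries$fragments))
})

test_that("library composition follows the configuration", {
  cfg0 <- sim_config(seed = 6, n_species_per_subclass = 0,
                     n_decoy_library = 8)
  lt <- generate_library(cfg0)
  sp <- lt$library$species
  expect_true(all(sp$is_decoy | sp$is_internal_standard))
  expect_equal(sum(sp$is_decoy), 8)
  expect_equal(sum(sp$is_internal_standard), 12)

  cfg <- sim_config(seed = 6, n_species_per_subclass = 4,
                    n_decoy_library = 5)
  sp2 <- generate_library(cfg)$library$species
  real <- sp2[!sp2$is_decoy & !sp2$is_internal_standard, ]
  counts <- table(real$subclass)
  expect_equal(unname(counts[["Chol"]]), 1)
  expect_true(all(counts[setdiff(names(counts), "Chol")] == 4))
  # decoys never collide with real species of the same subclass
  key <- paste(sp2$subclass, sp2$total_carbons, sp2$total_double_bonds,
               sp2$is_internal_standard)
  expect_false(anyDuplicated(key) > 0)
})

test_that("the predicted-RT model is linear in carbons and double bonds", {
  cfg <- sim_config(seed = 12)
  lt <- generate_library(cfg)
  lib <- lt$library
  idx <- match(lib$entries$species_id, lib$species$species_id)
  sub <- lib$species$subclass[idx]
  c_ <- lib$species$total_carbons[idx]
  d_ <- lib$species$total_double_bonds[idx]
  for (s in unique(sub)) {
    sel <- which(sub == s)
    if (length(sel) < 2) next
    rt <- lib$entries$predicted_rt[sel]
    pred <- cfg$rt_carbon_coef * c_[sel] - cfg$rt_db_coef * d_[sel]
    expect_equal(rt - pred, rep(rt[1] - pred[1], length(sel)),
                 tolerance = 1e-9)
  }
  # one double bond apart at fixed carbons: exactly the db coefficient
  pc <- which(sub == "PC")
  for (i in pc) for (j in pc) {
    if (c_[i] == c_[j] && d_[i] == d_[j] + 1) {
      expect_equal(lib$entries$predicted_rt[j] - lib$entries$predicted_rt[i],
                   cfg$rt_db_coef, tolerance = 1e-9)
    }
  }
})

test_that("configured group effects are exact in the zero-noise truth", {
  cfg <- sim_config(seed = 13, area_noise_sigma = 0, rt_jitter_sd = 0,
                    fragment_noise_sigma = 0, n_decoy_library = 0,
                    n_unknown_features = 0, dropout_rate = 0)
  lt <- generate_library(cfg)
  sim <- generate_experiment(lt, cfg)
  tr <- sim$truth$amounts
  sub <- lt$library$species$subclass[match(tr$species_id,
                                           lt$library$species$species_id)]
  totals <- tapply(tr$amount_pmol, tr$sample_id, sum)
  expect_equal(as.numeric(totals), rep(cfg$total_lipid_pmol, 6),
               tolerance = 1e-9)
  eff <- resolved_effects(cfg)
  by_sub <- tapply(tr$amount_pmol, list(tr$sample_id, sub), sum)
  for (s in colnames(by_sub)) {
    ratio <- by_sub["raft_1", s] / by_sub["nonraft_1", s]
    expect_equal(unname(ratio), unname(eff[[s]]), tolerance = 1e-9)
  }
  expect_equal(unname(by_sub["raft_1", "SM"] / by_sub["nonraft_1", "SM"]),
               6.25, tolerance = 1e-12)

  # chain and saturation tilts point the configured way
  ids <- identify_lipids(sim$features, lt$library)
  quant <- build_quant_table(ids, sim$features, sim$samples, lt$library)
  pr <- chain_profiles(quant, lt$library)
  mean_c <- setNames(pr$summary$mean_carbons, pr$summary$sample_id)
  mean_d <- setNames(pr$summary$mean_double_bonds, pr$summary$sample_id)
  expect_lt(mean_c[["raft_1"]], mean_c[["nonraft_1"]])
  expect_lt(mean_d[["raft_1"]], mean_d[["nonraft_1"]])
})

test_that("unknown features sit off-library and spikes follow the panel", {
  cfg <- sim_config(seed = 17)
  lt <- generate_library(cfg)
  sim <- generate_experiment(lt, cfg)
  unk <- sim$truth$features$feature_id[is.na(sim$truth$features$species_id)]
  expect_equal(length(unk), cfg$n_unknown_features)
  unk_mz <- sim$features$mz[match(unk, sim$features$feature_id)]
  for (mz in unk_mz) {
    ppm <- abs(mz - lt$library$entries$precursor_mz) /
      lt$library$entries$precursor_mz * 1e6
    expect_gt(min(ppm), 50)
  }
  raft_sp <- sim$samples$is_spikes[[which(sim$samples$group == "raft")[1]]]
  non_sp <- sim$samples$is_spikes[[which(sim$samples$group == "nonraft")[1]]]
  expect_equal(raft_sp[["Cer"]] / non_sp[["Cer"]], 10)
  expect_equal(raft_sp[["SM"]] / non_sp[["SM"]], 5)
})

test_that("generated files parse back cleanly through the readers", {
  cfg <- sim_config(seed = 19, n_species_per_subclass = 3)
  dir <- file.path(withr::local_tempdir(), "sim")
  paths <- write_simulation(cfg, dir)
  expect_no_warning({
    lib <- read_library(paths[["library"]])
    feats <- read_features(paths[["features"]], paths[["spectra"]])
    meta <- read_sample_meta(paths[["samples"]])
  })
  expect_gt(nrow(lib$entries), 0)
  expect_equal(nrow(meta), 6)
  expect_equal(nrow(feats),
               nrow(utils::read.delim(paths[["features"]])))
})

test_that("calibration generator is exact at zero noise and unbiased
           under noise", {
  lv <- generate_calibration(0.07, 0.2, noise_sd = 0)
  expect_equal(lv$response_ratio, 0.07 * lv$concentration + 0.2)
  fits <- vapply(1:100, function(s) {
    fit_calibration(generate_calibration(0.05, 0, noise_sd = 0.01,
                                         seed = s))$slope
  }, numeric(1))
  mc_se <- sd(fits) / sqrt(length(fits))
  expect_lt(abs(mean(fits) - 0.05), 4 * mc_se + 1e-6)
})
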