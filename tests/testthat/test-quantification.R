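test_that("internal-standard quantification follows unit arithmetic", {
  # area ratio 1, equal mw: analyte amount equals the spiked amount
  expect_equal(quantify_by_internal_standard(100, 100, 1.5, 750),
               1.5 / 750 * 1e6)
  expect_equal(quantify_by_internal_standard(0, 100, 1.5, 750), 0)
  # hand oracle: ratio 2 x 0.5 ug = 1 ug; / 750 g/mol -> 1333.33 pmol
  expect_equal(quantify_by_internal_standard(200, 100, 0.5, 750),
               1e6 / 750)
  expect_error(quantify_by_internal_standard(10, 0, 1, 750), "> 0")
})

test_that("quantification is scale-invariant and linear in analyte area", {
  a <- quantify_by_internal_standard(123, 456, 0.7, 810)
  expect_equal(quantify_by_internal_standard(123 * 50, 456 * 50, 0.7, 810),
               a, tolerance = 1e-12)
  expect_equal(quantify_by_internal_standard(123 * 3, 456, 0.7, 810),
               a * 3, tolerance = 1e-12)
})

test_that("calibration fit recovers a noiseless line exactly", {
  lv <- generate_calibration(true_slope = 0.05, true_intercept = 0,
                             noise_sd = 0)
  cur <- fit_calibration(lv)
  expect_equal(cur$slope, 0.05, tolerance = 1e-12)
  expect_equal(cur$intercept, 0, tolerance = 1e-12)

  lv2 <- generate_calibration(true_slope = 0.0123, true_intercept = 0.4,
                              noise_sd = 0)
  cur2 <- fit_calibration(lv2)
  expect_equal(cur2$slope, 0.0123, tolerance = 1e-12)
  expect_equal(cur2$intercept, 0.4, tolerance = 1e-12)

  two <- data.frame(concentration = c(1, 10),
                    response_ratio = c(0.2, 1.1))
  cur3 <- fit_calibration(two)
  expect_equal(cur3$slope * c(1, 10) + cur3$intercept, c(0.2, 1.1),
               tolerance = 1e-12)
  expect_error(fit_calibration(data.frame(concentration = c(1, 1),
                                          response_ratio = c(1, 2))),
               "distinct")
})

test_that("calibration inversion flags and rescales out-of-range samples", {
  lv <- generate_calibration(true_slope = 0.05, true_intercept = 0.1,
                             noise_sd = 0)
  cur <- fit_calibration(lv)
  # response at a measured level returns that concentration
  q <- quantify_by_calibration(lv$response_ratio[4], 1, cur)
  expect_equal(q$concentration, lv$concentration[4], tolerance = 1e-9)
  expect_false(q$out_of_range)

  hi <- 0.05 * 500 + 0.1  # 500 ug/mL, beyond the 200 ug/mL upper limit
  q_hi <- quantify_by_calibration(hi, 1, cur)
  expect_true(q_hi$out_of_range)

  # diluted re-analysis: response now inside range, scaled back up
  q_dil <- quantify_by_calibration(0.05 * 50 + 0.1, 1, cur,
                                   dilution_factor = 10)
  expect_equal(q_dil$concentration, 500, tolerance = 1e-9)
  expect_false(q_dil$out_of_range)

  lo <- 0.05 * 0.1 + 0.1  # below linear_min: flagged, reported as-is
  expect_true(quantify_by_calibration(lo, 1, cur)$out_of_range)
})

noise_free_sim <- function(seed = 42) {
  cfg <- sim_config(seed = seed, area_noise_sigma = 0, rt_jitter_sd = 0,
                    fragment_noise_sigma = 0, n_decoy_library = 0,
                    n_unknown_features = 0, dropout_rate = 0)
  libt <- generate_library(cfg)
  sim <- generate_experiment(libt, cfg)
  list(cfg = cfg, lib = libt$library, sim = sim)
}

test_that("noise-free amounts are recovered exactly, with the group-specific
           spike panels applied", {
  s <- noise_free_sim()
  ids <- identify_lipids(s$sim$features, s$lib)
  quant <- build_quant_table(ids, s$sim$features, s$sim$samples, s$lib)
  # internal standards are excluded from the analyte table
  is_ids <- s$lib$species$species_id[s$lib$species$is_internal_standard]
  expect_false(any(quant$species_id %in% is_ids))
  m <- merge(quant, s$sim$truth$amounts, by = c("sample_id", "species_id"))
  expect_equal(nrow(m), nrow(quant))
  expect_lt(max(abs(m$amount_pmol.x / m$amount_pmol.y - 1)), 1e-9)
  # protein normalization
  prot <- s$sim$samples$protein_amount[
    match(quant$sample_id, s$sim$samples$sample_id)]
  expect_equal(quant$amount_pmol_per_ug_protein, quant$amount_pmol / prot)
  # Cer recovery is exact in both groups although the spike differs 10x
  cer <- m[m$subclass == "Cer", ]
  expect_true(any(grepl("^raft", cer$sample_id)) &&
                any(grepl("^nonraft", cer$sample_id)))
  expect_lt(max(abs(cer$amount_pmol.x / cer$amount_pmol.y - 1)), 1e-9)
})

test_that("a sample containing only internal standards yields an empty
           analyte table", {
  s <- noise_free_sim()
  truth_feat <- s$sim$truth$features
  is_ids <- s$lib$species$species_id[s$lib$species$is_internal_standard]
  keep <- truth_feat$species_id %in% is_ids &
    truth_feat$sample_id == "raft_1"
  feats <- s$sim$features[s$sim$features$feature_id %in%
                            truth_feat$feature_id[keep], ]
  ids <- identify_lipids(feats, s$lib)
  quant <- build_quant_table(ids, feats, s$sim$samples, s$lib)
  expect_equal(nrow(quant), 0)
})

test_that("with log-normal area noise the recovered amounts stay accurate", {
  cfg <- sim_config(seed = 11, rt_jitter_sd = 0, fragment_noise_sigma = 0,
                    n_decoy_library = 0, n_unknown_features = 0,
                    dropout_rate = 0, area_noise_sigma = 0.1)
  libt <- generate_library(cfg)
  sim <- generate_experiment(libt, cfg)
  ids <- identify_lipids(sim$features, libt$library)
  quant <- build_quant_table(ids, sim$features, sim$samples, libt$library)
  m <- merge(quant, sim$truth$amounts, by = c("sample_id", "species_id"))
  relerr <- abs(m$amount_pmol.x / m$amount_pmol.y - 1)
  expect_gt(nrow(m), 200)
  expect_lte(median(relerr), 0.15)
})
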