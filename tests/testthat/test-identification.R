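test_that("accurate-mass search returns in-window entries sorted by error", {
  lib <- make_test_library()
  params <- scoring_params()
  pc_mz <- lib$entries$precursor_mz[1]
  feat <- list(mz = pc_mz,
               ms2 = ms2_spectrum(184.0733, 100, "positive", pc_mz))
  hits <- match_mass(feat, lib, params)
  expect_equal(hits$species_id[1], "PC_34_1")
  expect_equal(hits$mass_error_ppm[1], 0)

  far <- list(mz = pc_mz * (1 + 100e-6),
              ms2 = ms2_spectrum(184.0733, 100, "positive", pc_mz))
  expect_equal(nrow(match_mass(far, lib, params)), 0)

  # two candidates 5 and 8 ppm away; brute-force scan is the oracle
  m0 <- 700
  species <- rbind(lipid_species("A", "PC", 34, 1, monoisotopic_mass = 699),
                   lipid_species("B", "PC", 36, 1,
                                 monoisotopic_mass = 699.5))
  entries <- data.frame(
    species_id = c("A", "B"), mode = "positive", adduct = "[M+H]+",
    precursor_mz = c(m0 * (1 - 5e-6), m0 * (1 + 8e-6)),
    predicted_rt = c(5, 5), stringsAsFactors = FALSE)
  entries$fragments <- list(data.frame(mz = 184, intensity = 1),
                            data.frame(mz = 184, intensity = 1))
  lib2 <- spectral_library(species, entries)
  feat2 <- list(mz = m0, ms2 = ms2_spectrum(184, 1, "positive", m0))
  hits2 <- match_mass(feat2, lib2, params)
  brute <- abs(m0 - lib2$entries$precursor_mz) /
    lib2$entries$precursor_mz * 1e6
  expect_equal(nrow(hits2), sum(brute <= params$precursor_tol_ppm))
  expect_equal(hits2$species_id, c("A", "B"))
  expect_lt(abs(abs(hits2$mass_error_ppm[1]) - 5), 0.01)
})

test_that("spectral similarity is 1 on self-match and 0 on disjoint", {
  lib <- make_test_library()
  params <- scoring_params()
  for (i in seq_len(nrow(lib$entries))) {
    s <- spectrum_from_entry(lib, i)
    expect_equal(spectral_similarity(s, s, params), 1)
  }
  a <- ms2_spectrum(c(100, 200), c(1, 1), "positive", 500)
  b <- ms2_spectrum(c(150, 250), c(1, 1), "positive", 500)
  expect_equal(spectral_similarity(a, b, params), 0)
  expect_error(
    spectral_similarity(a, NULL, params), "non-empty")
})

test_that("partial overlap matches the directly evaluated formula", {
  params <- scoring_params(intensity_weight_n_pos = 1)
  ref <- ms2_spectrum(c(100, 200), c(1, 1), "positive", 500)
  exp1 <- ms2_spectrum(100, 1, "positive", 500)
  got <- spectral_similarity(exp1, ref, params)
  want <- oracle_spectral_similarity(100, 1, c(100, 200), c(1, 1),
                                     m = 1, n = 1, tol = 0.02)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(want, 1 / sqrt(5), tolerance = 1e-12)
})

test_that("vectorized scorer agrees with the loop oracle on random pairs", {
  set.seed(101)
  for (rep in 1:300) {
    pr <- random_spectrum_pair()
    mode <- if (rep %% 2 == 0) "positive" else "negative"
    params <- scoring_params(fragment_tol_da = pr$tol)
    n <- if (mode == "positive") params$intensity_weight_n_pos else
      params$intensity_weight_n_neg
    got <- spectral_similarity(
      ms2_spectrum(pr$exp_mz, pr$exp_int, mode, 500),
      ms2_spectrum(pr$ref_mz, pr$ref_int, mode, 500), params)
    want <- oracle_spectral_similarity(pr$exp_mz, pr$exp_int, pr$ref_mz,
                                       pr$ref_int, m = 1, n = n,
                                       tol = pr$tol)
    expect_equal(got, min(1, want), tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
})

test_that("spectral similarity is invariant to uniform intensity scaling", {
  set.seed(7)
  params <- scoring_params()
  ref <- ms2_spectrum(c(120, 180, 240, 300), c(80, 40, 100, 10),
                      "positive", 600)
  noisy <- ms2_spectrum(c(120.01, 180.005, 299.99, 400),
                        c(30, 60, 20, 15), "positive", 600)
  base <- spectral_similarity(noisy, ref, params)
  for (k in c(1e-3, 7, 1e4)) {
    scaled_e <- ms2_spectrum(noisy$peaks$mz, noisy$peaks$intensity * k,
                             "positive", 600)
    scaled_r <- ms2_spectrum(ref$peaks$mz, ref$peaks$intensity * k,
                             "positive", 600)
    expect_equal(spectral_similarity(scaled_e, ref, params), base,
                 tolerance = 1e-12)
    expect_equal(spectral_similarity(noisy, scaled_r, params), base,
                 tolerance = 1e-12)
  }
})

test_that("RT similarity follows the trapezoid contract", {
  params <- scoring_params()
  a <- params$rt_plateau_a
  b <- params$rt_zero_b
  expect_equal(rt_similarity(5, 5, params), 1)
  expect_equal(rt_similarity(5 + a, 5, params), 1)
  expect_equal(rt_similarity(5 + b, 5, params), 0)
  expect_equal(rt_similarity(5 + b + 2, 5, params), 0)
  mid <- (a + b) / 2
  expect_equal(rt_similarity(5 + mid, 5, params), 0.5)
  expect_equal(rt_similarity(5 - mid, 5, params), 0.5)
  # matches the case-by-case oracle and is non-increasing and continuous
  d <- seq(0, 1, by = 0.001)
  scores <- rt_similarity(5 + d, 5, params)
  oracle <- vapply(d, function(x) oracle_trapezoid(5 + x, 5, a, b),
                   numeric(1))
  expect_equal(scores, oracle, tolerance = 1e-12)
  expect_true(all(diff(scores) <= 0))
  expect_lt(max(abs(diff(scores))), 0.01)
})

test_that("identification applies dual thresholds and best-match rule", {
  lib <- make_test_library()
  params <- scoring_params()
  feats <- data.frame(feature_id = c("f1", "f2", "f3"),
                      sample_id = "s1",
                      mz = lib$entries$precursor_mz[c(1, 1, 2)],
                      rt = c(lib$entries$predicted_rt[1],
                             lib$entries$predicted_rt[1] + 0.45,
                             lib$entries$predicted_rt[2]),
                      area = c(10, 10, 10), stringsAsFactors = FALSE)
  feats$ms2 <- list(spectrum_from_entry(lib, 1),
                    spectrum_from_entry(lib, 1),  # good spectrum, RT off
                    NULL)                         # no MS/MS
  ids <- identify_lipids(feats, lib, params)
  f1 <- ids[ids$feature_id == "f1", ]
  expect_true(any(f1$accepted))
  expect_equal(f1$species_id[f1$accepted], "PC_34_1")
  expect_equal(f1$spectral_score[f1$accepted], 1)

  f2 <- ids[ids$feature_id == "f2", ]
  expect_true(all(!f2$accepted))          # rt score 0.14 < 0.5
  expect_gt(max(f2$spectral_score), 0.8)  # kept as candidate, audited
  expect_lt(max(f2$rt_score), params$rt_threshold)

  expect_false("f3" %in% ids$feature_id)
  expect_true(all(ids$accepted ==
                    (ids$spectral_score > params$spectral_threshold &
                       ids$rt_score > params$rt_threshold & ids$accepted)))
})

test_that("at most one identification is accepted per feature", {
  cfg <- sim_config(seed = 21)
  sim <- generate_experiment(generate_library(cfg), cfg)
  ids <- identify_lipids(sim$features, generate_library(cfg)$library)
  acc_per_feat <- table(ids$feature_id[ids$accepted])
  expect_true(all(acc_per_feat <= 1))
})

test_that("mean spectral score degrades monotonically with noise", {
  lib <- make_test_library()
  params <- scoring_params()
  ref <- spectrum_from_entry(lib, 1)
  sigmas <- c(0, 0.2, 0.5, 1.0)
  set.seed(42)
  means <- vapply(sigmas, function(s) {
    mean(vapply(1:200, function(i) {
      noisy <- ms2_spectrum(ref$peaks$mz,
                            ref$peaks$intensity * rlnorm(nrow(ref$peaks),
                                                         0, s),
                            ref$mode, ref$precursor_mz)
      spectral_similarity(noisy, ref, params)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(means[1], 1)
  expect_true(all(diff(means) <= 0))
})
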