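# Stage orchestration: identify -> quantify -> compose -> compare
# (+ optional NMR profiling), with a written report bundle, and
# evaluation of identifications against simulation ground truth.

#' Evaluate identifications against simulation ground truth
#'
#' Precision is the fraction of accepted identifications whose species
#' matches the feature's true species; recall is the fraction of emitted
#' features with a true species (internal standards included, unknowns
#' excluded) that received a correct accepted identification.
#'
#' @param identifications Audit table from [identify_lipids()].
#' @param truth_features Data frame `feature_id`, `species_id` (NA for
#'   unknowns) from [generate_experiment()]'s `truth$features`.
#' @return List with `precision`, `recall`, `n_accepted`, `n_correct`,
#'   `n_true`.
#' @export
evaluate_identifications <- function(identifications, truth_features) {
  acc <- identifications[identifications$accepted, , drop = FALSE]
  truth_sp <- truth_features$species_id[match(acc$feature_id,
                                              truth_features$feature_id)]
  correct <- !is.na(truth_sp) & acc$species_id == truth_sp
  n_true <- sum(!is.na(truth_features$species_id))
  list(precision = if (nrow(acc)) mean(correct) else NA_real_,
       recall = if (n_true) sum(correct) / n_true else NA_real_,
       n_accepted = nrow(acc), n_correct = sum(correct), n_true = n_true)
}

#' Run the full post-detection analysis pipeline
#'
#' Executes identification, absolute quantification, subclass composition
#' and (when two groups are present) group comparison, writing all stage
#' TSVs, the fully resolved parameters and a run summary into `outdir`.
#' With equal inputs and parameters the outputs are byte-identical across
#' reruns; no stage draws random numbers.
#'
#' @param library A [spectral_library()] or path to an MSP-like file.
#' @param features Feature data frame or path to a feature TSV (then
#'   `spectra` must name the MGF file).
#' @param samples Sample metadata data frame or path to a YAML config.
#' @param outdir Output directory.
#' @param params A [scoring_params()].
#' @param spectra Optional MGF path when `features` is a path.
#' @param compare Length-2 character vector of group labels to compare
#'   (default `c("raft", "nonraft")`); skipped when either group has
#'   fewer than 2 samples.
#' @param truth_features Optional ground-truth feature map; when given,
#'   identification precision/recall are reported in the summary.
#' @param nmr Optional named list with paths or [peak_table()]s:
#'   `in_condition`, `reference`, optional `control` (a second
#'   in-condition table profiled against the same reference as the
#'   control for Z).
#' @return List with `identifications`, `quant`, `composition`,
#'   `comparison`, `summary` (named list) and `paths`, invisibly.
#' @export
run_pipeline <- function(library, features, samples, outdir,
                         params = scoring_params(), spectra = NULL,
                         compare = c("raft", "nonraft"),
                         truth_features = NULL, nmr = NULL) {
  if (is.character(library)) library <- read_library(library)
  if (is.character(features)) features <- read_features(features, spectra)
  if (is.character(samples)) samples <- read_sample_meta(samples)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(identifications = file.path(outdir, "identifications.tsv"),
             quant = file.path(outdir, "quant.tsv"),
             composition = file.path(outdir, "composition.tsv"),
             params = file.path(outdir, "params_resolved.yaml"),
             summary = file.path(outdir, "run_summary.txt"))
  yaml::write_yaml(unclass(params), paths[["params"]])

  ids <- identify_lipids(features, library, params)
  write_identifications(ids, paths[["identifications"]])
  quant <- build_quant_table(ids, features, samples, library)
  write_quant_table(quant, paths[["quant"]])
  composition <- NULL
  if (nrow(quant) && any(!is.na(quant$amount_pmol))) {
    composition <- subclass_composition(quant)
    write_composition(composition, paths[["composition"]])
  } else {
    write_composition(data.frame(sample_id = character(),
                                 subclass = character(),
                                 amount_pmol = numeric(),
                                 mol_percent = numeric(),
                                 pmol_per_ug_protein = numeric()),
                      paths[["composition"]])
  }

  comparison <- NULL
  grp <- if (is.null(composition)) character(0) else
    samples$group[match(composition$sample_id, samples$sample_id)]
  if (!is.null(composition) && !is.null(compare) && length(compare) == 2 &&
      sum(unique(composition$sample_id) %in%
            samples$sample_id[samples$group == compare[1]]) >= 2 &&
      sum(unique(composition$sample_id) %in%
            samples$sample_id[samples$group == compare[2]]) >= 2) {
    comparison <- compare_groups(composition[grp == compare[1], ],
                                 composition[grp == compare[2], ])
    paths[["comparison"]] <- file.path(outdir, "comparison.tsv")
    write_comparison(comparison, paths[["comparison"]])
  }

  nmr_out <- NULL
  if (!is.null(nmr)) {
    get_tab <- function(x, id) {
      if (inherits(x, "peak_table")) x else read_peak_table(x, id)
    }
    prof <- relative_intensity_profile(get_tab(nmr$in_condition, "cond"),
                                       get_tab(nmr$reference, "ref"))
    Z <- NULL
    if (!is.null(nmr$control)) {
      ctrl <- relative_intensity_profile(get_tab(nmr$control, "control"),
                                         get_tab(nmr$reference, "ref"))
      Z <- relative_change(prof, ctrl)
    }
    paths[["nmr_profile"]] <- file.path(outdir, "nmr_profile.tsv")
    write_ratio_profile(prof, paths[["nmr_profile"]], Z)
    nmr_out <- list(profile = prof, Z = Z)
  }

  n_ms2 <- sum(!vapply(features$ms2, is.null, logical(1)))
  summary <- list(
    n_features = nrow(features), n_features_with_ms2 = n_ms2,
    n_candidates_scored = nrow(ids),
    n_spectral_pass = sum(ids$spectral_score > params$spectral_threshold),
    n_accepted = sum(ids$accepted),
    n_quantified = sum(!is.na(quant$amount_pmol)),
    n_samples = length(unique(features$sample_id)),
    spectral_threshold = params$spectral_threshold,
    rt_threshold = params$rt_threshold)
  if (!is.null(truth_features)) {
    ev <- evaluate_identifications(ids, truth_features)
    summary$precision <- ev$precision
    summary$recall <- ev$recall
  }
  lines <- paste0(names(summary), "=",
                  vapply(summary, function(v) fmt_num(v)[1], character(1)))
  con <- file(paths[["summary"]], open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)

  invisible(list(identifications = ids, quant = quant,
                 composition = composition, comparison = comparison,
                 nmr = nmr_out, summary = summary, paths = paths))
}
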