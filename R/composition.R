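# Subclass compositions (mol%), acyl chain-length / saturation profiles,
# and raft vs non-raft group comparison.

#' Per-sample subclass composition
#'
#' Sums the molar amounts of all molecular species within each lipid
#' subclass and normalizes by the total lipid moles of the sample, giving
#' mol%; a per-protein view (pmol per ug protein) is carried alongside.
#' Species absent from a sample contribute 0, so denominators are
#' comparable across replicates.
#'
#' @param quant Quantification table from [build_quant_table()].
#' @param subclasses Subclasses to report; defaults to every subclass
#'   present in `quant`.
#' @return Data frame with columns `sample_id`, `subclass`, `amount_pmol`,
#'   `mol_percent`, `pmol_per_ug_protein`. mol% sums to 100 per sample.
#' @export
subclass_composition <- function(quant, subclasses = NULL) {
  q <- quant[!is.na(quant$amount_pmol), , drop = FALSE]
  if (!nrow(q)) stop("quantification table is empty")
  if (is.null(subclasses)) subclasses <- sort(unique(q$subclass))
  samples <- unique(q$sample_id)
  rows <- lapply(samples, function(s) {
    qs <- q[q$sample_id == s, , drop = FALSE]
    total <- sum(qs$amount_pmol)
    if (total <= 0) stop("total lipid amount is 0 in sample ", s)
    pm <- vapply(subclasses, function(cl) {
      sum(qs$amount_pmol[qs$subclass == cl])
    }, numeric(1))
    pp <- vapply(subclasses, function(cl) {
      sum(qs$amount_pmol_per_ug_protein[qs$subclass == cl])
    }, numeric(1))
    data.frame(sample_id = s, subclass = subclasses, amount_pmol = pm,
               mol_percent = pm / total * 100, pmol_per_ug_protein = pp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Acyl chain-length and saturation profiles
#'
#' Mole-fraction distributions over total acyl carbon count and total
#' double-bond count per sample, restricted by default to the
#' glycerophospholipid subclasses (PC, PE, PS, PI, PG, PA).
#'
#' @param quant Quantification table from [build_quant_table()].
#' @param library The [spectral_library()] (source of acyl compositions).
#' @param subclasses Subclasses to include (default glycerophospholipids).
#' @return List with data frames `carbons` (`sample_id`, `total_carbons`,
#'   `mole_fraction`), `double_bonds` (analogous) and `summary`
#'   (`sample_id`, `mean_carbons`, `mean_double_bonds`).
#' @export
chain_profiles <- function(quant, library,
                           subclasses = c("PC", "PE", "PS", "PI", "PG",
                                          "PA")) {
  sp <- library$species
  q <- quant[!is.na(quant$amount_pmol) & quant$subclass %in% subclasses, ,
             drop = FALSE]
  idx <- match(q$species_id, sp$species_id)
  q$total_carbons <- sp$total_carbons[idx]
  q$total_double_bonds <- sp$total_double_bonds[idx]
  hist_over <- function(var) {
    do.call(rbind, lapply(unique(q$sample_id), function(s) {
      qs <- q[q$sample_id == s, , drop = FALSE]
      tot <- sum(qs$amount_pmol)
      agg <- stats::aggregate(qs$amount_pmol, by = list(v = qs[[var]]), sum)
      data.frame(sample_id = s, value = agg$v,
                 mole_fraction = agg$x / tot, stringsAsFactors = FALSE)
    }))
  }
  carbons <- hist_over("total_carbons")
  names(carbons)[2] <- "total_carbons"
  dbs <- hist_over("total_double_bonds")
  names(dbs)[2] <- "total_double_bonds"
  summary <- do.call(rbind, lapply(unique(q$sample_id), function(s) {
    qs <- q[q$sample_id == s, , drop = FALSE]
    w <- qs$amount_pmol / sum(qs$amount_pmol)
    data.frame(sample_id = s,
               mean_carbons = sum(w * qs$total_carbons),
               mean_double_bonds = sum(w * qs$total_double_bonds),
               stringsAsFactors = FALSE)
  }))
  rownames(carbons) <- rownames(dbs) <- rownames(summary) <- NULL
  list(carbons = carbons, double_bonds = dbs, summary = summary)
}

#' Two-group subclass comparison by Student's t-test
#'
#' Per-subclass two-sample t-test on mol% across biological replicates;
#' equal-variance (pooled) Student's form by default, Welch via
#' `welch = TRUE`. Significance labels follow the declared tiers:
#' `n.s.` (p >= 0.05), `*` (p < 0.05), `***` (p < 0.001).
#'
#' @param profiles_a,profiles_b Composition data frames from
#'   [subclass_composition()] for the two groups (>= 2 replicates each).
#' @param welch Use the Welch unequal-variance form.
#' @return Data frame with columns `subclass`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `t_statistic`, `p_value`, `significance_label`.
#' @export
compare_groups <- function(profiles_a, profiles_b, welch = FALSE) {
  if (length(unique(profiles_a$sample_id)) < 2 ||
      length(unique(profiles_b$sample_id)) < 2) {
    stop("each group needs at least 2 replicates")
  }
  subclasses <- sort(union(profiles_a$subclass, profiles_b$subclass))
  rows <- lapply(subclasses, function(cl) {
    xa <- profiles_a$mol_percent[profiles_a$subclass == cl]
    xb <- profiles_b$mol_percent[profiles_b$subclass == cl]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
      if (!isTRUE(all.equal(mean(xa), mean(xb)))) {
        tt <- list(statistic = c(t = Inf * sign(mean(xa) - mean(xb))),
                   p.value = 0)
      }
    } else {
      tt <- stats::t.test(xa, xb, var.equal = !welch)
    }
    p <- tt$p.value
    label <- if (p < 0.001) "***" else if (p < 0.05) "*" else "n.s."
    data.frame(subclass = cl, mean_a = mean(xa), sd_a = stats::sd(xa),
               mean_b = mean(xb), sd_b = stats::sd(xb),
               t_statistic = unname(tt$statistic), p_value = p,
               significance_label = label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a composition table
#' @param composition Data frame from [subclass_composition()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(composition, path) {
  tab <- composition
  for (col in c("amount_pmol", "mol_percent", "pmol_per_ug_protein")) {
    tab[[col]] <- fmt_num(tab[[col]])
  }
  write_tsv(tab, path)
}

#' Write a group-comparison table
#' @param comparison Data frame from [compare_groups()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  tab <- comparison
  for (col in c("mean_a", "sd_a", "mean_b", "sd_b", "t_statistic",
                "p_value")) {
    tab[[col]] <- fmt_num(tab[[col]])
  }
  write_tsv(tab, path)
}
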