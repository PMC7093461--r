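# Experimental inputs: detected LC-MS feature tables (TSV), attached
# MS/MS spectra (MGF) and sample metadata (YAML). The pipeline starts here,
# downstream of peak detection/alignment.

#' Construct an MS/MS spectrum
#'
#' @param mz,intensity Numeric vectors of equal length; peaks are sorted
#'   ascending by m/z.
#' @param mode `"positive"` or `"negative"`.
#' @param precursor_mz Precursor m/z in Da.
#' @return Object of class `ms2_spectrum`: list with `peaks` (data frame
#'   `mz`, `intensity`), `mode` and `precursor_mz`.
#' @export
ms2_spectrum <- function(mz, intensity, mode, precursor_mz) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1,
            all(mz > 0), all(intensity >= 0),
            mode %in% c("positive", "negative"), precursor_mz > 0)
  o <- order(mz)
  structure(list(peaks = data.frame(mz = mz[o], intensity = intensity[o]),
                 mode = mode, precursor_mz = precursor_mz),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("MS/MS spectrum:", nrow(x$peaks), "peaks,", x$mode,
      "mode, precursor m/z", format(x$precursor_mz, digits = 8), "\n")
  invisible(x)
}

feature_columns <- c("feature_id", "sample_id", "mz", "rt", "area")

#' Read a detected-feature table with optional attached MS/MS spectra
#'
#' The TSV must carry the columns `feature_id`, `sample_id`, `mz`, `rt`,
#' `area`. MS/MS spectra are read from an MGF file whose `TITLE` values
#' match `feature_id`; spectra whose title matches no feature are ignored
#' with a warning. No row is silently dropped: rows in equals features out.
#'
#' @param table_path Path to the feature TSV.
#' @param spectra_path Optional path to an MGF file.
#' @return Data frame of features with a list column `ms2` holding an
#'   [ms2_spectrum()] or `NULL` per row.
#' @export
read_features <- function(table_path, spectra_path = NULL) {
  if (!file.exists(table_path)) stop("feature table not found: ", table_path)
  tab <- utils::read.delim(table_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  missing <- setdiff(feature_columns, names(tab))
  if (length(missing)) {
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab <- tab[, feature_columns, drop = FALSE]
  tab$feature_id <- as.character(tab$feature_id)
  tab$sample_id <- as.character(tab$sample_id)
  if (nrow(tab)) {
    stopifnot(all(tab$mz > 0), all(tab$rt >= 0), all(tab$area >= 0))
    if (anyDuplicated(tab$feature_id)) {
      stop("duplicate feature_id in feature table")
    }
  }
  tab$ms2 <- vector("list", nrow(tab))
  if (!is.null(spectra_path)) {
    spectra <- read_mgf(spectra_path)
    hit <- names(spectra) %in% tab$feature_id
    if (any(!hit)) {
      warning(sum(!hit), " MGF spectra with titles matching no feature ",
              "were ignored")
    }
    idx <- match(tab$feature_id, names(spectra))
    ms2 <- vector("list", nrow(tab))
    ms2[!is.na(idx)] <- spectra[idx[!is.na(idx)]]
    tab$ms2 <- ms2
  }
  tab
}

#' Write a feature table and its MS/MS spectra
#'
#' @param features Feature data frame as returned by [read_features()].
#' @param table_path Output TSV path.
#' @param spectra_path Optional output MGF path for the attached spectra.
#' @return `table_path`, invisibly.
#' @export
write_features <- function(features, table_path, spectra_path = NULL) {
  tab <- features[, feature_columns, drop = FALSE]
  tab$mz <- fmt_num(tab$mz)
  tab$rt <- fmt_num(tab$rt)
  tab$area <- fmt_num(tab$area)
  write_tsv(tab, table_path)
  if (!is.null(spectra_path)) {
    has <- !vapply(features$ms2, is.null, logical(1))
    write_mgf(features$ms2[has], features$feature_id[has], spectra_path)
  }
  invisible(table_path)
}

read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8")
  begin <- which(raw == "BEGIN IONS")
  end <- which(raw == "END IONS")
  if (length(begin) != length(end)) {
    stop("unbalanced BEGIN IONS/END IONS in ", path)
  }
  spectra <- list()
  for (i in seq_along(begin)) {
    block <- raw[(begin[i] + 1L):(end[i] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE))
    pepmass <- as.numeric(sub("^PEPMASS=", "",
                              grep("^PEPMASS=", block, value = TRUE)))
    charge <- sub("^CHARGE=", "", grep("^CHARGE=", block, value = TRUE))
    if (length(title) != 1) {
      stop("MGF record ", i, " must carry exactly one TITLE line")
    }
    mode <- if (length(charge) && grepl("-", charge, fixed = TRUE)) {
      "negative"
    } else "positive"
    peak_lines <- block[!grepl("^[A-Z]+=", block) & nzchar(trimws(block))]
    parts <- strsplit(trimws(peak_lines), "[ \t]+")
    mz <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    int <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    if (anyNA(mz) || anyNA(int)) {
      stop("malformed peak lines in MGF record '", title, "'")
    }
    if (title %in% names(spectra)) {
      stop("TITLE collision in MGF: ", title)
    }
    spectra[[title]] <- ms2_spectrum(mz, int, mode, pepmass)
  }
  spectra
}

write_mgf <- function(spectra, titles, path) {
  stopifnot(length(spectra) == length(titles))
  lines <- unlist(lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    charge <- if (s$mode == "positive") "1+" else "1-"
    c("BEGIN IONS",
      paste0("TITLE=", titles[i]),
      paste0("PEPMASS=", fmt_num(s$precursor_mz)),
      paste0("CHARGE=", charge),
      paste(fmt_num(s$peaks$mz), fmt_num(s$peaks$intensity)),
      "END IONS",
      "")
  }))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Default internal-standard spike panel
#'
#' Spiked amounts (micrograms) of the 12 deuterated standards added per
#' sample before extraction. The raft and non-raft panels differ only in
#' the ceramide (0.2 vs 0.02 ug) and sphingomyelin (0.05 vs 0.01 ug)
#' spikes; cholesterol-d7 (2 ug) serves the cholesterol assay.
#'
#' @param group `"raft"` or `"nonraft"` (any other value gets the
#'   non-raft panel).
#' @return Named numeric vector, subclass -> spiked amount in ug.
#' @export
default_spike_panel <- function(group = "raft") {
  panel <- c(PC = 1.5, PE = 0.5, PG = 0.25, PS = 0.5, PI = 0.5, PA = 0.05,
             Cer = 0.2, SM = 0.05, LPC = 0.02, LPE = 0.02, TG = 10,
             Chol = 2)
  if (!identical(group, "raft")) {
    panel[["Cer"]] <- 0.02
    panel[["SM"]] <- 0.01
  }
  panel
}

#' Read sample metadata from a YAML config
#'
#' Expected schema: top-level key `samples`, a sequence of mappings with
#' keys `sample_id`, `group` (`raft`/`nonraft`/`other`), `protein_amount`
#' (ug), optional `dilution_factor` (default 1) and optional `is_spikes`
#' (subclass -> ug); omitted spikes default to the group's panel from
#' [default_spike_panel()].
#'
#' @param config_path Path to the YAML file.
#' @return Data frame with one row per sample and a list column
#'   `is_spikes` of named numeric vectors.
#' @export
read_sample_meta <- function(config_path) {
  if (!file.exists(config_path)) stop("sample config not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$samples)) stop("sample config must have a 'samples' key")
  rows <- lapply(cfg$samples, function(s) {
    if (is.null(s$sample_id)) stop("sample entry missing sample_id")
    group <- if (is.null(s$group)) "other" else s$group
    protein <- as.numeric(s$protein_amount)
    if (is.na(protein) || protein <= 0) {
      stop("sample ", s$sample_id, ": protein_amount must be > 0")
    }
    dil <- if (is.null(s$dilution_factor)) 1 else as.numeric(s$dilution_factor)
    if (dil < 1) stop("sample ", s$sample_id, ": dilution_factor must be >= 1")
    spikes <- default_spike_panel(group)
    if (!is.null(s$is_spikes)) {
      given <- unlist(s$is_spikes)
      spikes[names(given)] <- as.numeric(given)
    }
    list(sample_id = as.character(s$sample_id), group = group,
         protein_amount = protein, dilution_factor = dil, is_spikes = spikes)
  })
  meta <- data.frame(
    sample_id = vapply(rows, `[[`, character(1), "sample_id"),
    group = vapply(rows, `[[`, character(1), "group"),
    protein_amount = vapply(rows, `[[`, numeric(1), "protein_amount"),
    dilution_factor = vapply(rows, `[[`, numeric(1), "dilution_factor"),
    stringsAsFactors = FALSE)
  meta$is_spikes <- lapply(rows, `[[`, "is_spikes")
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in config")
  meta
}

#' Write sample metadata to a YAML config
#'
#' @param samples Data frame as returned by [read_sample_meta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(samples, path) {
  out <- list(samples = lapply(seq_len(nrow(samples)), function(i) {
    list(sample_id = samples$sample_id[i], group = samples$group[i],
         protein_amount = samples$protein_amount[i],
         dilution_factor = samples$dilution_factor[i],
         is_spikes = as.list(samples$is_spikes[[i]]))
  }))
  yaml::write_yaml(out, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
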