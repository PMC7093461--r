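# In-silico lipid spectral library: species mass model, adduct m/z,
# MSP-like text serialization.

PROTON_MASS <- 1.007276
CH2_MASS <- 14.01565
DB_MASS <- 2.01565            # mass removed per C=C (loss of H2)
DEUTERIUM_SHIFT <- 1.0062767  # 2H - 1H

#' Adduct table for singly charged lipid ions
#'
#' Named numeric vector of mass shifts (Da) added to the neutral
#' monoisotopic mass to obtain the singly charged ion m/z. Positive-mode
#' adducts: `[M+H]+`, `[M+NH4]+`; negative-mode: `[M-H]-`, `[M+HCOO]-`.
#'
#' @return Named numeric vector of adduct mass shifts in Da.
#' @export
adduct_table <- function() {
  c("[M+H]+"    = PROTON_MASS,
    "[M+NH4]+"  = 18.033823,
    "[M-H]-"    = -PROTON_MASS,
    "[M+HCOO]-" = 44.998201)
}

#' Ionization mode of an adduct
#' @param adduct Adduct name present in [adduct_table()].
#' @return `"positive"` or `"negative"`.
#' @export
adduct_mode <- function(adduct) {
  shifts <- adduct_table()
  bad <- setdiff(adduct, names(shifts))
  if (length(bad)) {
    stop("unknown adduct name(s): ", paste(bad, collapse = ", "),
         " (configured adducts: ", paste(names(shifts), collapse = ", "), ")")
  }
  ifelse(endsWith(adduct, "+"), "positive", "negative")
}

#' Precursor m/z of a singly charged adduct ion
#'
#' @param monoisotopic_mass Neutral monoisotopic mass in Da.
#' @param adduct Adduct name present in [adduct_table()].
#' @return m/z in Da (vectorized over both arguments).
#' @examples
#' precursor_mz(100, "[M+H]+")   # 101.007276
#' precursor_mz(100, "[M-H]-")   # 98.992724
#' @export
precursor_mz <- function(monoisotopic_mass, adduct) {
  shifts <- adduct_table()
  bad <- setdiff(adduct, names(shifts))
  if (length(bad)) {
    stop("unknown adduct name(s): ", paste(bad, collapse = ", "),
         " (configured adducts: ", paste(names(shifts), collapse = ", "), ")")
  }
  stopifnot(all(monoisotopic_mass > 0))
  monoisotopic_mass + unname(shifts[adduct])
}

# Per-subclass base masses (Da) at zero acyl carbons / zero double bonds,
# anchored so that base + 14.01565 * C - 2.01565 * DB reproduces reference
# monoisotopic masses (e.g. PC 34:1 -> 759.57797, PI 38:4 -> 886.55724).
subclass_base_mass <- function() {
  c(PC = 285.06152, PE = 243.01452, PS = 287.00435, PI = 362.02514,
    PG = 274.00903, PA = 199.99571, Cer = 62.99564, SM = 228.05039,
    LPC = 271.08209, LPE = 229.03514, TG = 134.00079, Chol = 9.94797)
}

#' Lipid subclasses known to the mass model
#' @return Character vector of the 12 subclass codes.
#' @export
lipid_subclasses <- function() names(subclass_base_mass())

# Glycerophospholipid subclasses (diacyl) used by chain profiling defaults.
glycerophospholipids <- function() c("PC", "PE", "PS", "PI", "PG", "PA")

#' Monoisotopic mass of a lipid species from the built-in mass model
#'
#' Mass = per-subclass base + 14.01565 Da per acyl carbon - 2.01565 Da per
#' C=C double bond, plus an optional isotope-label shift. Cholesterol is a
#' fixed species (27 carbons, 1 double bond, 386.35487 Da unlabeled).
#'
#' @param subclass One of [lipid_subclasses()].
#' @param total_carbons Total acyl-chain carbon count.
#' @param total_double_bonds Total acyl-chain C=C count.
#' @param label_mass_shift Additional mass from isotope labeling (Da).
#' @return Monoisotopic mass in Da.
#' @export
species_mass <- function(subclass, total_carbons, total_double_bonds,
                         label_mass_shift = 0) {
  base <- subclass_base_mass()
  bad <- setdiff(subclass, names(base))
  if (length(bad)) stop("unknown subclass: ", paste(bad, collapse = ", "))
  stopifnot(all(total_carbons >= 0), all(total_double_bonds >= 0))
  unname(base[subclass]) + CH2_MASS * total_carbons -
    DB_MASS * total_double_bonds + label_mass_shift
}

#' Construct a lipid species record
#'
#' @param species_id Opaque unique key.
#' @param subclass One of [lipid_subclasses()].
#' @param total_carbons,total_double_bonds Acyl composition.
#' @param monoisotopic_mass Monoisotopic mass (Da); computed from the
#'   built-in mass model when `NULL`.
#' @param average_mw Average molecular weight (g/mol); defaults to
#'   `monoisotopic_mass * 1.0007`, adequate for the microgram-to-picomole
#'   conversion relative to quantification noise.
#' @param is_internal_standard Whether this is a spiked deuterated standard.
#' @param label_mass_shift Isotope-label mass shift in Da (0 if unlabeled).
#' @param is_decoy Whether the species is a library decoy never present in
#'   samples (synthetic-data bookkeeping).
#' @return One-row data frame.
#' @export
lipid_species <- function(species_id, subclass, total_carbons,
                          total_double_bonds, monoisotopic_mass = NULL,
                          average_mw = NULL, is_internal_standard = FALSE,
                          label_mass_shift = 0, is_decoy = FALSE) {
  if (!subclass %in% lipid_subclasses()) {
    stop("unknown subclass: ", subclass)
  }
  if (subclass == "Chol" && total_carbons != 27) {
    stop("Chol species have total_carbons fixed at 27")
  }
  if (is.null(monoisotopic_mass)) {
    monoisotopic_mass <- species_mass(subclass, total_carbons,
                                      total_double_bonds, label_mass_shift)
  }
  if (is.null(average_mw)) average_mw <- monoisotopic_mass * 1.0007
  stopifnot(total_carbons >= 0, total_double_bonds >= 0,
            monoisotopic_mass > 0, average_mw > 0)
  data.frame(species_id = species_id, subclass = subclass,
             total_carbons = as.integer(total_carbons),
             total_double_bonds = as.integer(total_double_bonds),
             monoisotopic_mass = monoisotopic_mass, average_mw = average_mw,
             is_internal_standard = is_internal_standard,
             label_mass_shift = label_mass_shift, is_decoy = is_decoy,
             stringsAsFactors = FALSE)
}

#' Construct a spectral library
#'
#' @param species Data frame of species rows as built by [lipid_species()].
#' @param entries Data frame with columns `species_id`, `mode`, `adduct`,
#'   `precursor_mz`, `predicted_rt` and a list column `fragments` of
#'   data frames with columns `mz`, `intensity`.
#' @return Object of class `spectral_library`.
#' @export
spectral_library <- function(species, entries) {
  if (nrow(entries)) {
    unresolved <- setdiff(entries$species_id, species$species_id)
    if (length(unresolved)) {
      stop("library entries reference unknown species: ",
           paste(unresolved, collapse = ", "))
    }
    key <- paste(entries$species_id, entries$mode, entries$adduct)
    if (anyDuplicated(key)) {
      stop("duplicate (species_id, mode, adduct) in library: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
    stopifnot(all(entries$precursor_mz > 0), all(entries$predicted_rt >= 0))
    for (fr in entries$fragments) {
      stopifnot(is.data.frame(fr), nrow(fr) >= 1,
                all(fr$mz > 0), all(fr$intensity >= 0))
    }
  }
  if (anyDuplicated(species$species_id)) {
    stop("duplicate species_id in species table")
  }
  structure(list(species = species, entries = entries),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("Spectral library:", nrow(x$entries), "entries,",
      nrow(x$species), "species\n")
  if (nrow(x$species)) {
    cat("  subclasses:",
        paste(sort(unique(x$species$subclass)), collapse = " "), "\n")
    cat("  internal standards:", sum(x$species$is_internal_standard),
        " decoys:", sum(x$species$is_decoy), "\n")
  }
  invisible(x)
}

empty_library <- function() {
  species <- lipid_species("x", "PC", 34, 1)[0, ]
  entries <- data.frame(species_id = character(), mode = character(),
                        adduct = character(), precursor_mz = numeric(),
                        predicted_rt = numeric(), stringsAsFactors = FALSE)
  entries$fragments <- list()
  spectral_library(species, entries)
}

fmt_num <- function(x) trimws(formatC(x, digits = 15, format = "g"))

#' Write a spectral library in the MSP-like text dialect
#'
#' Records are blank-line separated; each record carries the entry header
#' keys (`NAME:`, `SUBCLASS:`, `CARBONS:`, `DOUBLEBONDS:`, `MODE:`,
#' `ADDUCT:`, `PRECURSORMZ:`, `PREDICTED_RT:`, `MW:`, `AVGMW:`,
#' `INTERNAL_STANDARD:`, `LABEL_SHIFT:`, `DECOY:`, `NumPeaks:`) followed by
#' tab-separated `mz<TAB>intensity` fragment lines. UTF-8, `.` decimal.
#'
#' @param library A [spectral_library()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  sp <- library$species
  lines <- character(0)
  if (nrow(library$entries)) {
    recs <- lapply(seq_len(nrow(library$entries)), function(i) {
      e <- library$entries[i, ]
      s <- sp[sp$species_id == e$species_id, ]
      fr <- library$entries$fragments[[i]]
      c(paste0("NAME: ", e$species_id),
        paste0("SUBCLASS: ", s$subclass),
        paste0("CARBONS: ", s$total_carbons),
        paste0("DOUBLEBONDS: ", s$total_double_bonds),
        paste0("MODE: ", e$mode),
        paste0("ADDUCT: ", e$adduct),
        paste0("PRECURSORMZ: ", fmt_num(e$precursor_mz)),
        paste0("PREDICTED_RT: ", fmt_num(e$predicted_rt)),
        paste0("MW: ", fmt_num(s$monoisotopic_mass)),
        paste0("AVGMW: ", fmt_num(s$average_mw)),
        paste0("INTERNAL_STANDARD: ", as.integer(s$is_internal_standard)),
        paste0("LABEL_SHIFT: ", fmt_num(s$label_mass_shift)),
        paste0("DECOY: ", as.integer(s$is_decoy)),
        paste0("NumPeaks: ", nrow(fr)),
        paste(fmt_num(fr$mz), fmt_num(fr$intensity), sep = "\t"),
        "")
    })
    lines <- unlist(recs)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a spectral library from the MSP-like text dialect
#'
#' Inverse of [write_library()]; the round trip is lossless for all fields
#' and preserves entry order.
#'
#' @param path File path.
#' @return A [spectral_library()].
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8")
  nonblank <- which(nzchar(trimws(raw)))
  if (!length(nonblank)) return(empty_library())
  # split into records at blank lines
  grp <- cumsum(c(TRUE, diff(nonblank) > 1))
  recs <- split(nonblank, grp)
  species_rows <- list()
  entry_rows <- list()
  frags <- list()
  for (r in recs) {
    hdr <- list()
    peaks_expected <- NA_integer_
    peak_mz <- numeric(0)
    peak_int <- numeric(0)
    in_peaks <- FALSE
    for (ln in r) {
      txt <- raw[ln]
      if (!in_peaks && grepl("^[A-Za-z_]+[A-Za-z0-9_]*:", txt)) {
        key <- sub(":.*$", "", txt)
        val <- trimws(sub("^[^:]*:", "", txt))
        hdr[[key]] <- val
        if (key == "NumPeaks") {
          peaks_expected <- as.integer(val)
          in_peaks <- TRUE
        }
      } else if (in_peaks) {
        parts <- strsplit(txt, "\t", fixed = TRUE)[[1]]
        if (length(parts) != 2) {
          stop("malformed peak line at line ", ln, ": ", txt)
        }
        v <- suppressWarnings(as.numeric(parts))
        if (anyNA(v)) stop("non-numeric peak values at line ", ln, ": ", txt)
        peak_mz <- c(peak_mz, v[1])
        peak_int <- c(peak_int, v[2])
      } else {
        stop("malformed record line at line ", ln, ": ", txt)
      }
    }
    need <- c("NAME", "SUBCLASS", "CARBONS", "DOUBLEBONDS", "MODE", "ADDUCT",
              "PRECURSORMZ", "PREDICTED_RT", "MW", "AVGMW",
              "INTERNAL_STANDARD", "LABEL_SHIFT", "DECOY", "NumPeaks")
    missing <- setdiff(need, names(hdr))
    if (length(missing)) {
      stop("record starting at line ", r[1], " missing header(s): ",
           paste(missing, collapse = ", "))
    }
    if (!is.na(peaks_expected) && length(peak_mz) != peaks_expected) {
      stop("record starting at line ", r[1], " declares ", peaks_expected,
           " peaks but has ", length(peak_mz))
    }
    species_rows[[length(species_rows) + 1L]] <- lipid_species(
      species_id = hdr$NAME, subclass = hdr$SUBCLASS,
      total_carbons = as.integer(hdr$CARBONS),
      total_double_bonds = as.integer(hdr$DOUBLEBONDS),
      monoisotopic_mass = as.numeric(hdr$MW),
      average_mw = as.numeric(hdr$AVGMW),
      is_internal_standard = as.integer(hdr$INTERNAL_STANDARD) == 1L,
      label_mass_shift = as.numeric(hdr$LABEL_SHIFT),
      is_decoy = as.integer(hdr$DECOY) == 1L)
    entry_rows[[length(entry_rows) + 1L]] <- data.frame(
      species_id = hdr$NAME, mode = hdr$MODE, adduct = hdr$ADDUCT,
      precursor_mz = as.numeric(hdr$PRECURSORMZ),
      predicted_rt = as.numeric(hdr$PREDICTED_RT), stringsAsFactors = FALSE)
    frags[[length(frags) + 1L]] <- data.frame(mz = peak_mz,
                                              intensity = peak_int)
  }
  species <- do.call(rbind, species_rows)
  species <- species[!duplicated(species$species_id), , drop = FALSE]
  rownames(species) <- NULL
  entries <- do.call(rbind, entry_rows)
  rownames(entries) <- NULL
  entries$fragments <- frags
  spectral_library(species, entries)
}
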