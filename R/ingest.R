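#' Declare the experimental design of a quantification table
#'
#' @param strains,conditions,fractions Allowed labels.
#' @param n_replicates Number of biological replicates per strain and
#'   condition.
#' @return A list of class `quant_design`.
#' @export
quant_design <- function(strains,
                         conditions = c("control", "induced"),
                         fractions = c("cytosolic", "membrane", "extracellular"),
                         n_replicates = 3) {
  if (length(strains) < 1 || length(conditions) < 1 || length(fractions) < 1) {
    stop_secretomics("Design declaration must be non-empty.",
                     class = "secretomics_config_error")
  }
  structure(list(strains = strains, conditions = conditions,
                 fractions = fractions,
                 n_replicates = as.integer(n_replicates)),
            class = "quant_design")
}

#' Bundle protein annotation maps
#'
#' Collects the external annotation resources consumed by the pipeline:
#' a PSORTb-style subcellular localization class per protein, a binary
#' Sec-type signal-peptide prediction (GP4-style), hierarchical functional
#' category paths (up to four levels, `/`-separated, SubtiWiki-export
#' style; a protein may carry several paths) and regulon memberships with
#' their regulation mode. Unannotated proteins are permitted in every map.
#'
#' @param localization Tibble with columns `protein`, `localization`
#'   (classes `Cytoplasmic`, `CytoplasmicMembrane`, `Cellwall`,
#'   `Extracellular`, `Unknown`).
#' @param sec_sp Tibble with columns `protein`, `sec_sp` (logical).
#'   Proteins absent from the table are treated as signal-peptide-free.
#' @param categories Tibble with columns `protein`, `path`.
#' @param regulons Tibble with columns `protein`, `regulon`, `mode`
#'   (normalized to `activation`, `repression` or `other`).
#' @return A list of class `annotation_maps`.
#' @export
annotation_maps <- function(localization = NULL, sec_sp = NULL,
                            categories = NULL, regulons = NULL) {
  provided <- c(localization = !is.null(localization),
                sec_sp = !is.null(sec_sp),
                categories = !is.null(categories),
                regulons = !is.null(regulons))
  empty <- function(...) tibble(...)
  if (is.null(localization)) {
    localization <- empty(protein = character(), localization = character())
  }
  if (is.null(sec_sp)) sec_sp <- empty(protein = character(), sec_sp = logical())
  if (is.null(categories)) categories <- empty(protein = character(), path = character())
  if (is.null(regulons)) {
    regulons <- empty(protein = character(), regulon = character(),
                      mode = character())
  }
  localization <- as_tibble(localization)
  sec_sp <- as_tibble(sec_sp)
  categories <- as_tibble(categories)
  regulons <- as_tibble(regulons)

  bad_loc <- setdiff(unique(localization$localization), .loc_classes)
  if (length(bad_loc) > 0) {
    stop_secretomics(paste0("Unknown localization class(es): ",
                            paste(bad_loc, collapse = ", ")))
  }
  if (nrow(categories) > 0) {
    depth <- lengths(strsplit(categories$path, "/", fixed = TRUE))
    if (any(depth > 4)) {
      stop_secretomics("Category paths must have at most 4 levels.")
    }
  }
  if (nrow(regulons) > 0) {
    regulons <- regulons %>%
      mutate(mode = tolower(trimws(.data$mode)),
             mode = dplyr::if_else(.data$mode %in% c("activation", "repression"),
                                   .data$mode, "other"))
  }
  structure(list(localization = localization, sec_sp = sec_sp,
                 categories = categories, regulons = regulons),
            provided = provided,
            class = "annotation_maps")
}

# internal reader dispatch on file extension / explicit format
.read_table_file <- function(path, format = c("auto", "tsv", "csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", xlsx = "xlsx", xls = "xlsx", "tsv")
  }
  if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_secretomics("Reading xlsx files requires the 'readxl' package.")
    }
    return(as_tibble(readxl::read_excel(path)))
  }
  fn <- if (format == "csv") readr::read_csv else readr::read_tsv
  fn(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Read and validate a long-format quantification table
#'
#' Reads a MaxQuant-style LFQ protein quantification export that has
#' already been melted to long format (one row per detected measurement)
#' and validates it against a declared design. Missing measurements must
#' be absent rows; in the MaxQuant dialect (`zero_as_missing = TRUE`)
#' zero intensities are interpreted as "not quantified" and removed,
#' otherwise non-positive intensities are an error. Rows whose strain,
#' condition, fraction or replicate fall outside the declared design are
#' rejected (never silently dropped: they are returned in the
#' `rejected` attribute).
#'
#' @param path File to read.
#' @param design A [quant_design()] declaration.
#' @param format One of `"auto"`, `"tsv"`, `"csv"`, `"xlsx"`.
#' @param col_map Optional named character vector mapping canonical column
#'   names (`protein`, `strain`, `condition`, `fraction`, `replicate`,
#'   `intensity`, `unique_peptides`) to the file's column names.
#' @param intensity_scale `"linear"` (default) or `"log2"` if the file
#'   stores pre-logged intensities; log2 values are converted back to the
#'   linear scale on ingest so that the log transform is applied exactly
#'   once downstream.
#' @param zero_as_missing Treat zero intensities as absent measurements
#'   (MaxQuant dialect) instead of raising an error.
#' @return A validated quantification tibble with attribute `rejected`
#'   (the out-of-design rows).
#' @export
read_quant_table <- function(path, design,
                             format = c("auto", "tsv", "csv", "xlsx"),
                             col_map = NULL,
                             intensity_scale = c("linear", "log2"),
                             zero_as_missing = FALSE) {
  stopifnot(inherits(design, "quant_design"))
  intensity_scale <- match.arg(intensity_scale)
  raw <- .read_table_file(path, match.arg(format))
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src) > 0) {
      stop_secretomics(paste0("Mapped column(s) not in file: ",
                              paste(missing_src, collapse = ", ")))
    }
    raw <- rename(raw, !!!rlang::set_names(col_map, names(col_map)))
  }
  validate_quant_table(raw, design,
                       intensity_scale = intensity_scale,
                       zero_as_missing = zero_as_missing)
}

#' Validate an in-memory quantification table
#'
#' @inheritParams read_quant_table
#' @param quant A data frame with the canonical long-format columns.
#' @return The validated tibble (linear intensities) with attribute
#'   `rejected` holding out-of-design rows.
#' @export
validate_quant_table <- function(quant, design,
                                 intensity_scale = c("linear", "log2"),
                                 zero_as_missing = FALSE) {
  stopifnot(inherits(design, "quant_design"))
  intensity_scale <- match.arg(intensity_scale)
  needed <- c("protein", "strain", "condition", "fraction", "replicate",
              "intensity", "unique_peptides")
  missing_cols <- setdiff(needed, names(quant))
  if (length(missing_cols) > 0) {
    stop_secretomics(paste0("Missing column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  quant <- as_tibble(quant) %>%
    select(all_of(needed)) %>%
    mutate(protein = as.character(.data$protein),
           strain = as.character(.data$strain),
           condition = as.character(.data$condition),
           fraction = as.character(.data$fraction),
           replicate = as.integer(.data$replicate),
           intensity = as.numeric(.data$intensity),
           unique_peptides = as.integer(.data$unique_peptides))

  # absent measurements: NA always; 0 only in the MaxQuant dialect
  quant <- filter(quant, !is.na(.data$intensity))
  if (zero_as_missing) quant <- filter(quant, .data$intensity != 0)
  if (intensity_scale == "log2") {
    quant <- mutate(quant, intensity = 2^.data$intensity)
  }
  bad_frac <- setdiff(unique(quant$fraction), design$fractions)
  if (length(bad_frac) > 0) {
    stop_secretomics(paste0("Unknown fraction label(s): ",
                            paste(bad_frac, collapse = ", ")))
  }
  if (any(quant$intensity <= 0)) {
    stop_secretomics("Non-positive intensities are invalid; missing values must be absent rows.")
  }

  in_design <- quant$strain %in% design$strains &
    quant$condition %in% design$conditions &
    quant$replicate >= 1 & quant$replicate <= design$n_replicates
  rejected <- quant[!in_design, , drop = FALSE]
  kept <- quant[in_design, , drop = FALSE]
  if (nrow(rejected) > 0) {
    warn(sprintf("%d row(s) outside the declared design were rejected.",
                 nrow(rejected)))
  }
  dup <- kept %>%
    count(.data$protein, .data$strain, .data$condition, .data$fraction,
          .data$replicate) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_secretomics(sprintf(
      "Duplicate (protein, strain, condition, fraction, replicate) key(s): %d.",
      nrow(dup)))
  }
  attr(kept, "rejected") <- rejected
  kept
}

#' Read a wide (replicate-columns) quantification table
#'
#' Supplementary-table exports typically store one protein per row with
#' one intensity column per (strain, condition, fraction, replicate)
#' cell. `column_design` maps each such measurement column to its design
#' coordinates; the table is melted to the canonical long format and
#' validated.
#'
#' @inheritParams read_quant_table
#' @param column_design Tibble with columns `column`, `strain`,
#'   `condition`, `fraction`, `replicate` describing each measurement
#'   column of the file.
#' @param protein_col,peptides_col Names of the protein-identifier column
#'   and (optionally) the unique-peptide-count column; without a peptide
#'   column all proteins are given `unique_peptides = NA`.
#' @return A validated long-format quantification tibble.
#' @export
read_quant_wide <- function(path, design, column_design,
                            protein_col = "protein",
                            peptides_col = NULL,
                            format = c("auto", "tsv", "csv", "xlsx"),
                            intensity_scale = c("linear", "log2"),
                            zero_as_missing = TRUE) {
  stopifnot(inherits(design, "quant_design"))
  raw <- .read_table_file(path, match.arg(format))
  missing_src <- setdiff(column_design$column, names(raw))
  if (length(missing_src) > 0) {
    stop_secretomics(paste0("Measurement column(s) not in file: ",
                            paste(missing_src, collapse = ", ")))
  }
  long <- raw %>%
    select(all_of(c(protein_col, peptides_col, column_design$column))) %>%
    tidyr::pivot_longer(all_of(column_design$column),
                        names_to = "column", values_to = "intensity") %>%
    inner_join(column_design, by = "column") %>%
    rename(protein = all_of(protein_col)) %>%
    select(-"column")
  if (is.null(peptides_col)) {
    long$unique_peptides <- NA_integer_
  } else {
    long <- rename(long, unique_peptides = all_of(peptides_col))
  }
  validate_quant_table(long, design,
                       intensity_scale = match.arg(intensity_scale),
                       zero_as_missing = zero_as_missing)
}

#' Read annotation maps from delimited files
#'
#' Each map is optional. The signal-peptide file may either carry a
#' logical `sec_sp` column or be a bare list of SP-positive protein ids;
#' an empty file means no protein carries a predicted Sec signal peptide.
#'
#' @param localization,sec_sp,categories,regulons File paths (TSV/CSV by
#'   extension) or `NULL`.
#' @return An [annotation_maps()] object.
#' @export
read_annotation_maps <- function(localization = NULL, sec_sp = NULL,
                                 categories = NULL, regulons = NULL) {
  rd <- function(p) if (is.null(p)) NULL else .read_table_file(p)
  sec_tbl <- rd(sec_sp)
  if (!is.null(sec_tbl)) {
    if (ncol(sec_tbl) == 0 || nrow(sec_tbl) == 0) {
      sec_tbl <- tibble(protein = character(), sec_sp = logical())
    } else if (!"sec_sp" %in% names(sec_tbl)) {
      sec_tbl <- tibble(protein = as.character(sec_tbl[[1]]), sec_sp = TRUE)
    } else {
      sec_tbl <- mutate(sec_tbl, sec_sp = as.logical(.data$sec_sp))
    }
  }
  annotation_maps(localization = rd(localization), sec_sp = sec_tbl,
                  categories = rd(categories), regulons = rd(regulons))
}

#' Write a pipeline result table as TSV
#'
#' All stage writers emit a plain TSV preceded by a `#` comment line
#' recording the package version and a hash of the run configuration, so
#' that result files are traceable to the parameters that produced them.
#'
#' @param x A data frame.
#' @param path Output file.
#' @param config Optional configuration object to hash into the header.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(x, path, config = NULL) {
  hash <- if (is.null(config)) "none" else rlang::hash(config)
  header <- sprintf("# secretomics %s config_hash=%s",
                    as.character(packageVersion("secretomics")), hash)
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Write annotation maps as TSV files
#'
#' @param maps An [annotation_maps()] object.
#' @param dir Output directory (created if needed).
#' @param config Optional configuration hashed into the file headers.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_annotation_maps <- function(maps, dir, config = NULL) {
  stopifnot(inherits(maps, "annotation_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(localization = file.path(dir, "localization.tsv"),
             sec_sp = file.path(dir, "sec_sp.tsv"),
             categories = file.path(dir, "categories.tsv"),
             regulons = file.path(dir, "regulons.tsv"))
  for (nm in names(paths)) write_stage_tsv(maps[[nm]], paths[[nm]], config)
  invisible(paths)
}
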