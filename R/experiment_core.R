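#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# Column schemas for the long-format assay tables. One row per measurement;
# missing values are empty cells, never sentinel numbers.
assay_schemas <- list(
  design   = c("fragment_id", "holobiont", "colony", "tank", "temperature"),
  pam      = c("fragment_id", "day", "phase", "replicate", "yield"),
  weights  = c("fragment_id", "day", "buoyant_weight_g", "surface_area_cm2"),
  counts   = c("fragment_id", "day", "chamber_count", "dilution_factor",
               "slurry_volume_ml", "surface_area_cm2", "replicate"),
  census   = c("fragment_id", "day", "status"),
  qpcr     = c("fragment_id", "day", "primer", "replicate", "ct"),
  isotopes = c("fragment_id", "fraction", "labeled", "delta13c_permil",
               "organic_carbon_ug"),
  clones   = c("fragment_id", "stage", "its2_type", "clone_count")
)

#' Compose a fragment identifier
#'
#' Fragments are identified by the composite string
#' `"<holobiont>-<colony>-<tank>-<index>"` so that joins across assay tables
#' are unambiguous for fate-tracked ramets.
#'
#' @param holobiont `"PdC"` or `"PdD"`.
#' @param colony Colony number (1-3 per holobiont).
#' @param tank Tank number (1-6 per holobiont; 1-3 control, 4-6 heated).
#' @param index Fragment index within colony.
#' @return Character vector of fragment ids.
#' @export
fragment_id <- function(holobiont, colony, tank, index) {
  paste(holobiont, colony, tank, index, sep = "-")
}

#' Bundle assay tables into a validated assay set
#'
#' An `assay_set` holds the full crossed design (two holobionts, PdC and PdD,
#' each with 3 colonies spread over 6 tanks split between a 26 deg C control
#' arm and a 32 deg C heated arm) together with all per-fragment assay tables.
#' Units are fixed here: mass in g, area in cm^2, isotope values in per mil
#' vs VPDB, qPCR in threshold cycles.
#'
#' @param design Tibble with columns fragment_id, holobiont, colony, tank,
#'   temperature.
#' @param pam,weights,counts,census,qpcr,isotopes,clones Assay tibbles; see
#'   the column schemas in the package vignette. Missing tables default to
#'   empty tibbles of the right shape.
#' @param metadata Free-form provenance list (seed, preset name, units).
#' @return An object of class `assay_set`.
#' @export
assay_set <- function(design, pam = NULL, weights = NULL, counts = NULL,
                      census = NULL, qpcr = NULL, isotopes = NULL,
                      clones = NULL, metadata = list()) {
  tables <- list(design = design, pam = pam, weights = weights,
                 counts = counts, census = census, qpcr = qpcr,
                 isotopes = isotopes, clones = clones)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) {
      tables[[nm]] <- empty_assay_table(nm)
    }
    tables[[nm]] <- tibble::as_tibble(tables[[nm]])
  }
  x <- structure(c(tables, list(metadata = metadata)), class = "assay_set")
  validate_assay_set(x)
  x
}

empty_assay_table <- function(name) {
  cols <- assay_schemas[[name]]
  out <- tibble::as_tibble(stats::setNames(
    rep(list(logical(0)), length(cols)), cols))
  out
}

#' Validate an assay set
#'
#' Checks column schemas, foreign-key closure (every record joins to exactly
#' one design fragment), yield range, the tank-to-temperature-arm mapping,
#' and positivity of masses, areas and volumes.
#'
#' @param x An `assay_set`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_assay_set <- function(x) {
  stopifnot(inherits(x, "assay_set"))
  for (nm in names(assay_schemas)) {
    missing <- setdiff(assay_schemas[[nm]], names(x[[nm]]))
    if (length(missing) > 0) {
      abort(sprintf("table '%s' is missing column(s): %s", nm,
                    paste(missing, collapse = ", ")),
            class = "holotherm_schema_error")
    }
  }
  des <- x$design
  if (anyDuplicated(des$fragment_id)) {
    abort("duplicate fragment_id in design", class = "holotherm_schema_error")
  }
  # each tank maps to exactly one temperature arm within a holobiont
  arm_map <- dplyr::distinct(des, .data$holobiont, .data$tank, .data$temperature)
  if (anyDuplicated(arm_map[c("holobiont", "tank")])) {
    abort("a tank maps to more than one temperature arm",
          class = "holotherm_integrity_error")
  }
  if (!all(des$temperature %in% c(26, 32))) {
    abort("temperature must be 26 or 32 (deg C)",
          class = "holotherm_schema_error")
  }
  for (nm in setdiff(names(assay_schemas), "design")) {
    tab <- x[[nm]]
    if (nrow(tab) == 0) next
    orphan <- !(tab$fragment_id %in% des$fragment_id)
    if (any(orphan)) {
      abort(sprintf(
        "table '%s' references fragment(s) absent from design: %s (rows %s)",
        nm, paste(unique(tab$fragment_id[orphan]), collapse = ", "),
        paste(utils::head(which(orphan), 10), collapse = ", ")),
        class = "holotherm_integrity_error")
    }
  }
  if (nrow(x$pam) > 0) {
    y <- x$pam$yield
    bad <- !is.na(y) & (y < 0 | y > 1)
    if (any(bad)) {
      abort(sprintf("pam yield outside [0, 1] in %d row(s)", sum(bad)),
            class = "holotherm_validation_error")
    }
    if (!all(x$pam$phase %in% c("dark", "light"))) {
      abort("pam phase must be 'dark' or 'light'",
            class = "holotherm_schema_error")
    }
  }
  if (nrow(x$weights) > 0 &&
      any(x$weights$buoyant_weight_g <= 0 | x$weights$surface_area_cm2 <= 0,
          na.rm = TRUE)) {
    abort("buoyant weights and surface areas must be positive",
          class = "holotherm_validation_error")
  }
  if (nrow(x$census) > 0 &&
      !all(x$census$status %in% c("healthy", "bleached", "removed"))) {
    abort("census status must be healthy, bleached or removed",
          class = "holotherm_schema_error")
  }
  if (nrow(x$qpcr) > 0 && !all(x$qpcr$primer %in% c("C", "D"))) {
    abort("qpcr primer must be 'C' or 'D'", class = "holotherm_schema_error")
  }
  invisible(x)
}

#' @export
print.assay_set <- function(x, ...) {
  cat("<assay_set>\n")
  cat(sprintf("  design: %d fragments, %d holobiont(s), %d tank-arm pairs\n",
              nrow(x$design), dplyr::n_distinct(x$design$holobiont),
              nrow(dplyr::distinct(x$design, .data$holobiont, .data$tank))))
  for (nm in setdiff(names(assay_schemas), "design")) {
    cat(sprintf("  %-9s %d rows\n", paste0(nm, ":"), nrow(x[[nm]])))
  }
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load an assay set from a directory of CSV files
#'
#' Reads the long-format tables `design.csv`, `pam.csv`, `weights.csv`,
#' `counts.csv`, `census.csv`, `qpcr.csv`, `isotopes.csv`, `clones.csv`
#' (UTF-8, header row mandatory) and returns a validated [assay_set()].
#' Missing optional tables yield empty collections with a warning; a missing
#' column is a schema error naming the column; a record citing a fragment
#' absent from the design is an integrity error listing the offending rows.
#'
#' @param dir Directory containing the CSV files.
#' @return An `assay_set`.
#' @export
load_assay_set <- function(dir) {
  if (!dir.exists(dir)) {
    abort(sprintf("directory not found: %s", dir), class = "holotherm_io_error")
  }
  read_one <- function(nm, required = FALSE) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      if (required) {
        abort(sprintf("required file missing: %s", path),
              class = "holotherm_io_error")
      }
      warn(sprintf("table '%s' not found in %s; using empty collection",
                   nm, dir))
      return(empty_assay_table(nm))
    }
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(tab) == 0 && ncol(tab) == 0) tab <- empty_assay_table(nm)
    tab
  }
  design <- read_one("design", required = TRUE)
  tabs <- lapply(setdiff(names(assay_schemas), "design"), read_one)
  names(tabs) <- setdiff(names(assay_schemas), "design")
  meta_path <- file.path(dir, "metadata.json")
  metadata <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  do.call(assay_set, c(list(design = design), tabs, list(metadata = metadata)))
}

#' Save an assay set to a directory of CSV files
#'
#' Writes one CSV per assay table plus `metadata.json`. Round-trip guarantee:
#' `load_assay_set(save_assay_set(x, d))` equals `x` field-wise within 1e-9.
#'
#' @param x An `assay_set`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_assay_set <- function(x, dir) {
  validate_assay_set(x)
  ok <- dir.exists(dir) ||
    suppressWarnings(dir.create(dir, recursive = TRUE, showWarnings = FALSE))
  if (!ok) {
    abort(sprintf("cannot create directory: %s", dir),
          class = "holotherm_io_error")
  }
  for (nm in names(assay_schemas)) {
    tryCatch(
      readr::write_csv(x[[nm]], file.path(dir, paste0(nm, ".csv")),
                       progress = FALSE),
      error = function(e) abort(
        sprintf("cannot write %s.csv under %s: %s", nm, dir,
                conditionMessage(e)),
        class = "holotherm_io_error"))
  }
  jsonlite::write_json(x$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Join a table to the design arm labels (holobiont, temperature, colony, tank).
join_design <- function(tab, design) {
  dplyr::left_join(tab, design, by = "fragment_id")
}
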