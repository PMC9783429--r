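#' Read long-format reciprocal common-environment trait observations
#'
#' Reads a delimited file (CSV or TSV, sniffed from the extension unless
#' `delim` is given) with one row per rearing unit x test environment and
#' returns a validated observation tibble. Required columns (after applying
#' `column_map`): `population`, `origin`, `test`, `phase`, `unit`, `eggs`;
#' `adults` is optional and only meaningful for the performance trait.
#' A pre-computed `response` column, if present, is carried through.
#'
#' Environment labels in `origin` and `test` are normalized by trimming
#' whitespace and case-folding. `phase` must resolve to `"field"` (assays of
#' field-derived individuals, e.g. G0/G1) or `"common"` (assays after
#' common-environment rearing, e.g. G2/G3); the generation labels
#' `g0`/`g1`/`g2`/`g3` are accepted as synonyms.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping the canonical
#'   field names to the file's column names, e.g.
#'   `c(population = "pop_id", test = "test_fruit")`. Unmapped canonical
#'   names are looked up directly.
#' @param delim Field delimiter; defaults to `"\t"` for `.tsv` files and
#'   `","` otherwise.
#' @return A tibble of validated observations, row order preserved.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' obs <- generate_dataset(sim_config(pops_per_env = c(2, 2, 2), seed = 1))
#' write_observations(obs, path)
#' head(read_observations(path))
#' @export
read_observations <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) {
    sa_abort_value(paste0("file not found: ", path))
  }
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_observations(raw, column_map = column_map)
}

#' Coerce and validate a data frame of trait observations
#'
#' @param data A data frame with the columns described in
#'   [read_observations()].
#' @inheritParams read_observations
#' @return A validated observation tibble.
#' @export
as_observations <- function(data, column_map = NULL) {
  canonical <- c("population", "origin", "test", "phase", "unit", "eggs",
                 "adults", "response", "capped")
  out <- tibble::tibble(.rows = nrow(data))
  for (nm in canonical) {
    src <- if (!is.null(column_map) && nm %in% names(column_map)) {
      column_map[[nm]]
    } else {
      nm
    }
    if (src %in% names(data)) {
      out[[nm]] <- data[[src]]
    } else if (nm %in% c("population", "origin", "test", "phase", "unit", "eggs")) {
      sa_abort_schema(paste0("required column missing: ", nm,
                             if (src != nm) paste0(" (mapped from '", src, "')") else ""))
    }
  }
  out$population <- as.character(out$population)
  out$unit <- as.character(out$unit)
  out$origin <- normalize_env(out$origin)
  out$test <- normalize_env(out$test)
  out$phase <- normalize_phase(out$phase)
  out$eggs <- check_count(out$eggs, "eggs")
  if ("adults" %in% names(out)) {
    out$adults <- check_count(out$adults, "adults")
  }
  validate_observations(out)
  out
}

normalize_env <- function(x) tolower(trimws(as.character(x)))

normalize_phase <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("g0", "g1")] <- "field"
  x[x %in% c("g2", "g3")] <- "common"
  bad <- setdiff(unique(x), c("field", "common"))
  if (length(bad) > 0) {
    sa_abort_value(paste0("phase must be 'field' or 'common' (or g0-g3), got: ",
                          paste(bad, collapse = ", ")))
  }
  x
}

check_count <- function(x, name) {
  xn <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & (is.na(xn) | xn < 0 | xn != round(xn))
  if (any(bad)) {
    sa_abort_value(paste0("column '", name,
                          "' must contain non-negative integer counts"))
  }
  as.integer(xn)
}

#' Validate the structural invariants of an observation table
#'
#' Checks that each population has a single origin environment, that every
#' origin environment is also used as a test environment (reciprocality),
#' and that each rearing unit belongs to a single population x phase pair.
#' Counts must be non-negative; `eggs` may be `NA` only when a `response`
#' column already carries the trait value (as for Gaussian synthetic data).
#'
#' @param data An observation tibble.
#' @return `data`, invisibly, if all checks pass.
#' @export
validate_observations <- function(data) {
  if (anyNA(data$eggs) && !("response" %in% names(data))) {
    sa_abort_value("eggs contains missing values and no response column is present")
  }
  origin_per_pop <- tapply(data$origin, data$population,
                           function(x) length(unique(x)))
  if (any(origin_per_pop > 1)) {
    bad <- names(origin_per_pop)[origin_per_pop > 1]
    sa_abort_consistency(paste0("population(s) with multiple origin environments: ",
                                paste(bad, collapse = ", ")))
  }
  missing_envs <- setdiff(unique(data$origin), unique(data$test))
  if (length(missing_envs) > 0) {
    sa_abort_consistency(paste0("origin environment(s) never used as test environment: ",
                                paste(missing_envs, collapse = ", ")))
  }
  key <- paste(data$population, data$phase, sep = "\r")
  pairs_per_unit <- tapply(key, data$unit, function(x) length(unique(x)))
  if (any(pairs_per_unit > 1)) {
    bad <- names(pairs_per_unit)[pairs_per_unit > 1]
    sa_abort_consistency(paste0("unit(s) spanning multiple population/phase pairs: ",
                                paste(bad, collapse = ", ")))
  }
  invisible(data)
}

#' Write an observation table to a delimited file
#'
#' The on-disk dialect round-trips through [read_observations()]: reading a
#' written table reproduces the records field for field.
#'
#' @param data An observation tibble.
#' @param path Output path; `.tsv` selects tab delimiting, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_observations <- function(data, path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(data, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Summarize the experimental design of an observation table
#'
#' Tabulates replication per population x test environment x phase cell,
#' counts rearing units, and flags whether the design is balanced (all
#' realized cells carry the same number of records).
#'
#' @param data An observation tibble.
#' @return A list of class `sa_design_summary` with elements `cells`
#'   (tibble of per-cell record counts, zero-filled over the full grid),
#'   `units` (units per population x phase), `pops_per_origin`, and
#'   `balanced`.
#' @export
summarize_design <- function(data) {
  validate_observations(data)
  cells <- data |>
    dplyr::count(.data$population, .data$origin, .data$test, .data$phase,
                 name = "n") |>
    tidyr::complete(
      tidyr::nesting(population, origin),
      test = sort(unique(data$test)),
      phase = sort(unique(data$phase)),
      fill = list(n = 0L)
    ) |>
    dplyr::arrange(.data$population, .data$phase, .data$test)
  units <- data |>
    dplyr::distinct(.data$population, .data$phase, .data$unit) |>
    dplyr::count(.data$population, .data$phase, name = "n_units")
  pops_per_origin <- data |>
    dplyr::distinct(.data$population, .data$origin) |>
    dplyr::count(.data$origin, name = "n_populations")
  structure(
    list(
      cells = cells,
      units = units,
      pops_per_origin = pops_per_origin,
      balanced = length(unique(cells$n)) == 1L
    ),
    class = "sa_design_summary"
  )
}

#' @export
print.sa_design_summary <- function(x, ...) {
  cat("Reciprocal common-environment design\n")
  cat("  populations per origin: ",
      paste(x$pops_per_origin$n_populations, collapse = "/"), "\n", sep = "")
  cat("  balanced: ", x$balanced, "\n", sep = "")
  cat("  cells:\n")
  print(x$cells, n = 6)
  invisible(x)
}
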