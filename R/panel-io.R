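#' Read a long-format region-year panel from CSV
#'
#' The canonical layout is tidy: one row per region-year, with a region id
#' column, an integer year column, and numeric columns for inputs (capital
#' stock in 1e8 yuan, labour in 1e4 persons, energy in 1e4 tce), the
#' desirable output (GDP, 1e8 yuan), the undesirable output (carbon
#' emissions, 1e4 t) and any covariates.  `schema` maps roles to column
#' names; only the roles you name are validated, everything else is carried
#' through untouched.
#'
#' Rows whose required numeric fields fail to parse are dropped with a
#' warning that lists the offending row numbers.  Duplicate (region, year)
#' keys are an error: they would silently corrupt every downstream stage.
#'
#' @param path CSV file with a header row.
#' @param schema named list mapping roles to column names. Recognised roles:
#'   `region`, `year`, `inputs` (character vector), `output_good`,
#'   `output_bad`, `covariates` (character vector). Defaults to
#'   `region`/`year` columns named exactly that.
#' @return A tibble sorted by region then year, with the schema stored in
#'   the `"ecoeff_schema"` attribute.
#' @export
read_panel <- function(path, schema = list()) {
  if (!file.exists(path)) {
    abort(sprintf("panel file not found: %s", path), class = "ecoeff_io_error")
  }
  schema <- utils::modifyList(list(region = "region", year = "year"), schema)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- unlist(schema, use.names = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    roles <- names(unlist(schema))[match(missing, unlist(schema))]
    abort(sprintf("schema column(s) missing from %s: %s",
                  basename(path),
                  paste(sprintf("%s (role %s)", missing, roles), collapse = ", ")),
          class = "ecoeff_schema_error")
  }
  numeric_cols <- setdiff(required, schema$region)
  out <- raw
  for (cl in setdiff(names(out), schema$region)) {
    suppressWarnings(num <- as.numeric(out[[cl]]))
    # only coerce columns that look numeric or are required numeric roles
    if (cl %in% numeric_cols || all(is.na(num) == is.na(out[[cl]]))) {
      out[[cl]] <- num
    }
  }
  bad_rows <- which(Reduce(`|`, lapply(numeric_cols, function(cl) {
    is.na(out[[cl]]) & !is.na(raw[[cl]])
  }), logical(nrow(out))))
  if (length(bad_rows)) {
    warn(sprintf("dropped %d row(s) with non-numeric required fields: rows %s",
                 length(bad_rows), paste(bad_rows, collapse = ", ")))
    out <- out[-bad_rows, ]
  }
  out[[schema$year]] <- as.integer(out[[schema$year]])
  key <- paste(out[[schema$region]], out[[schema$year]], sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort(sprintf("duplicate (region, year) keys: %s",
                  paste(gsub("\r", ", ", dups), collapse = "; ")),
          class = "ecoeff_integrity_error")
  }
  out <- dplyr::arrange(out, .data[[schema$region]], .data[[schema$year]])
  attr(out, "ecoeff_schema") <- schema
  out
}

#' Write a panel back to CSV
#'
#' Numeric columns are written with round-trip ("shortest exact") formatting
#' so `read_panel(write_panel(x))` reproduces finite values bit-exactly.
#'
#' @param data a panel tibble.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Descriptive statistics of panel variables
#'
#' For each requested variable: mean, sample (n-1) standard deviation, min,
#' max over all region-year rows, and the average annual growth rate of the
#' cross-region yearly total, defined as the geometric-mean growth
#' `(total_T / total_1)^(1/(T-1)) - 1`, in percent.
#'
#' @param data panel tibble with a year column.
#' @param variables character vector of numeric column names.
#' @param year name of the year column.
#' @return A tibble with one row per variable: `variable`, `mean`, `sd`,
#'   `min`, `max`, `annual_growth_pct`.
#' @export
summarize_panel <- function(data, variables, year = "year") {
  missing <- setdiff(variables, names(data))
  if (length(missing)) {
    abort(sprintf("variable(s) not in panel: %s", paste(missing, collapse = ", ")),
          class = "ecoeff_lookup_error")
  }
  if (dplyr::n_distinct(data[[year]]) < 2) {
    abort("summarize_panel needs at least 2 years", class = "ecoeff_domain_error")
  }
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    totals <- data |>
      dplyr::group_by(.data[[year]]) |>
      dplyr::summarise(total = sum(.data[[v]], na.rm = TRUE), .groups = "drop") |>
      dplyr::arrange(.data[[year]])
    ny <- nrow(totals)
    growth <- (totals$total[ny] / totals$total[1])^(1 / (ny - 1)) - 1
    tibble(variable = v,
           mean = mean(x, na.rm = TRUE),
           sd = sd(x, na.rm = TRUE),
           min = min(x, na.rm = TRUE),
           max = max(x, na.rm = TRUE),
           annual_growth_pct = 100 * growth)
  })
}
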