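#' Year-by-year organic vs conventional yield comparison
#'
#' Computes the absolute yield gap (organic minus conventional, kg/mu) and
#' the organic yield as an integer percentage of the conventional one,
#' rounded half-up to match how such tables are conventionally displayed.
#'
#' @param records data frame with columns `year`, `organic`, `conventional`
#'   (yields in kg/mu).
#' @return Tibble `year`, `gap`, `ratio_pct`.
#' @export
yield_comparison <- function(records) {
  need <- c("year", "organic", "conventional")
  if (!all(need %in% names(records))) {
    abort("records needs columns year, organic, conventional",
          class = "ecoeff_schema_error")
  }
  if (any(records$conventional <= 0) || any(records$organic <= 0)) {
    abort("yields must be positive", class = "ecoeff_domain_error")
  }
  tibble(year = records$year,
         gap = records$organic - records$conventional,
         ratio_pct = round_half_up(100 * records$organic / records$conventional))
}

round_half_up <- function(x) floor(x + 0.5)

#' Itemized cost totals for organic vs conventional cultivation
#'
#' Sums a per-item cost sheet (RMB/mu) for each cultivation system and
#' reports the difference (organic minus conventional).  Cost sheets often
#' flag owner-imputed items (the farmer's own labour and land rent) that a
#' cash-cost comparison excludes from the conventional column;
#' `exclude_imputed = TRUE` drops flagged items from the conventional total,
#' following that parenthetical convention.
#'
#' @param sheet data frame with columns `item`, `organic`, `conventional`
#'   and logical `imputed`.
#' @param exclude_imputed drop imputed items from the conventional total?
#' @return One-row tibble: `organic_total`, `conventional_total`,
#'   `difference`.
#' @export
cost_totals <- function(sheet, exclude_imputed = FALSE) {
  need <- c("item", "organic", "conventional")
  if (!all(need %in% names(sheet)) || !nrow(sheet)) {
    abort("sheet needs rows and columns item, organic, conventional",
          class = "ecoeff_schema_error")
  }
  if (any(sheet$organic < 0) || any(sheet$conventional < 0)) {
    abort("costs must be nonnegative", class = "ecoeff_domain_error")
  }
  conv <- sheet$conventional
  if (exclude_imputed) {
    imputed <- sheet$imputed %||% rep(FALSE, nrow(sheet))
    conv <- ifelse(imputed, 0, conv)
  }
  org_total <- sum(sheet$organic)
  conv_total <- sum(conv)
  tibble(organic_total = org_total, conventional_total = conv_total,
         difference = org_total - conv_total)
}

#' Check a printed cost sheet against its own arithmetic
#'
#' Published cost tables sometimes disagree with their own columns (a
#' printed total or per-item difference that the items do not reproduce).
#' This checker recomputes every per-item difference and the totals and
#' reports mismatches without altering the data: a reporting tool, not a
#' correction.
#'
#' @param sheet cost sheet as in [cost_totals()], optionally with a printed
#'   `difference` column.
#' @param printed optional named list of printed totals to verify:
#'   any of `organic_total`, `conventional_total`, `difference`.
#' @return Tibble of discrepancies: `where`, `printed`, `recomputed`.
#'   Zero rows when everything is consistent.
#' @export
cost_consistency <- function(sheet, printed = list()) {
  out <- tibble(where = character(), printed = numeric(), recomputed = numeric())
  if (!is.null(sheet$difference)) {
    rec <- sheet$organic - sheet$conventional
    bad <- which(rec != sheet$difference)
    if (length(bad)) {
      out <- dplyr::bind_rows(out, tibble(
        where = paste0("item: ", sheet$item[bad]),
        printed = sheet$difference[bad], recomputed = rec[bad]))
    }
  }
  totals <- cost_totals(sheet)
  for (fld in intersect(names(printed), names(totals))) {
    if (printed[[fld]] != totals[[fld]]) {
      out <- dplyr::bind_rows(out, tibble(
        where = fld, printed = printed[[fld]], recomputed = totals[[fld]]))
    }
  }
  out
}
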