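#' Age-stratified annual rate table
#'
#' Container for the model's event rates: annual waiting-list (dialysis)
#' mortality, death with a functioning graft, and death-censored graft-failure
#' rates by donor source, all stratified over half-open age brackets
#' `[age_lo, age_hi)` that must tile `[0, 90)`; plus three scalar transplant
#' rates per person-waiting-year (pediatric deceased-donor, adult
#' deceased-donor, third transplant).
#'
#' @param brackets Data frame with columns `age_lo`, `age_hi`,
#'   `dialysis_mortality`, `graft_mortality`, `graft_failure_LD`,
#'   `graft_failure_DD`; one row per age bracket, rates per person-year.
#' @param tx_rate_DD_pediatric Annual deceased-donor transplant rate for
#'   waitlisted patients younger than 18 (per person-waiting-year).
#' @param tx_rate_DD_adult Annual deceased-donor transplant rate at ages 18+.
#' @param tx_rate_third Annual transplant rate while awaiting a third graft.
#' @return Object of class `rate_table`.
#' @export
rate_table <- function(brackets, tx_rate_DD_pediatric = 0.40,
                       tx_rate_DD_adult = 0.15, tx_rate_third = 0.12) {
  x <- structure(
    list(
      brackets = as.data.frame(brackets),
      tx_rates = list(
        tx_rate_DD_pediatric = tx_rate_DD_pediatric,
        tx_rate_DD_adult = tx_rate_DD_adult,
        tx_rate_third = tx_rate_third
      )
    ),
    class = "rate_table"
  )
  validate_rate_table(x)
  x
}

.bracket_fields <- c("dialysis_mortality", "graft_mortality",
                     "graft_failure_LD", "graft_failure_DD")
.tx_fields <- c("tx_rate_DD_pediatric", "tx_rate_DD_adult", "tx_rate_third")

#' Validate a rate table
#'
#' Checks bracket coverage (disjoint, contiguous, tiling `[0, 90)`), presence
#' of every rate field, and non-negativity of all rates.
#'
#' @param x A `rate_table`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_rate_table <- function(x) {
  stopifnot(inherits(x, "rate_table"))
  b <- x$brackets
  need <- c("age_lo", "age_hi", .bracket_fields)
  missing_cols <- setdiff(need, names(b))
  if (length(missing_cols)) {
    stop("rate table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  b <- b[order(b$age_lo), ]
  if (b$age_lo[1] != 0 || b$age_hi[nrow(b)] != 90 ||
      any(b$age_hi[-nrow(b)] != b$age_lo[-1])) {
    gaps <- paste0("[", b$age_lo, ",", b$age_hi, ")", collapse = " ")
    stop("age brackets must be disjoint, contiguous and cover [0,90); got ",
         gaps, call. = FALSE)
  }
  if (any(b$age_hi <= b$age_lo)) stop("empty age bracket", call. = FALSE)
  vals <- c(unlist(b[.bracket_fields]), unlist(x$tx_rates))
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("all rates must be non-negative and non-missing", call. = FALSE)
  }
  invisible(x)
}

#' Look up an annual rate by age
#'
#' Returns the rate of the half-open bracket containing `age` for an
#' age-stratified field, or the scalar value for a transplant-rate field.
#'
#' @param table A `rate_table`.
#' @param field One of `dialysis_mortality`, `graft_mortality`,
#'   `graft_failure_LD`, `graft_failure_DD`, `tx_rate_DD_pediatric`,
#'   `tx_rate_DD_adult`, `tx_rate_third`.
#' @param age Age in years; must lie in `[0, 90)` for bracketed fields.
#' @return Annual rate per person-year.
#' @export
lookup_rate <- function(table, field, age) {
  stopifnot(inherits(table, "rate_table"), length(field) == 1)
  if (field %in% .tx_fields) {
    return(table$tx_rates[[field]])
  }
  if (!field %in% .bracket_fields) {
    stop("unknown rate field: ", field, call. = FALSE)
  }
  if (any(age < 0) || any(age >= 90)) {
    stop("age must lie in [0, 90)", call. = FALSE)
  }
  b <- table$brackets[order(table$brackets$age_lo), ]
  i <- findInterval(age, b$age_lo)
  b[[field]][i]
}

#' @export
print.rate_table <- function(x, ...) {
  cat("<rate_table> ", nrow(x$brackets), " age brackets over [0, 90)\n", sep = "")
  print(x$brackets, row.names = FALSE)
  cat(sprintf("transplant rates (per person-waiting-year): pediatric DD %.3g, adult DD %.3g, third %.3g\n",
              x$tx_rates$tx_rate_DD_pediatric, x$tx_rates$tx_rate_DD_adult,
              x$tx_rates$tx_rate_third))
  invisible(x)
}
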