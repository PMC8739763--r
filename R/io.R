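#' Read a rate table from long-format CSV
#'
#' Expects columns `age_lo`, `age_hi`, `field`, `value` and an optional
#' `units` column (`per_person_year`, the default, or
#' `per_100_person_years`, divided by 100 on read). Age-stratified fields
#' must supply exactly one value for every bracket; the scalar transplant
#' rates are given as single rows spanning `[0, 90)`. Validation failures
#' name the offending rows or the missing brackets.
#'
#' @param path CSV file path.
#' @return A [rate_table()].
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("rate table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_lo", "age_hi", "field", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("rate table CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"units" %in% names(df)) df$units <- "per_person_year"
  bad_units <- setdiff(unique(df$units), c("per_person_year", "per_100_person_years"))
  if (length(bad_units)) {
    stop("unknown units: ", paste(bad_units, collapse = ", "), call. = FALSE)
  }
  df$value <- ifelse(df$units == "per_100_person_years", df$value / 100, df$value)
  neg <- which(df$value < 0 | is.na(df$value))
  if (length(neg)) {
    stop("negative or missing rate values at rows: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  bad_fields <- setdiff(unique(df$field), c(.bracket_fields, .tx_fields))
  if (length(bad_fields)) {
    stop("unknown rate fields: ", paste(bad_fields, collapse = ", "), call. = FALSE)
  }

  bdf <- df[df$field %in% .bracket_fields, ]
  brackets <- unique(bdf[order(bdf$age_lo), c("age_lo", "age_hi")])
  out <- brackets
  for (f in .bracket_fields) {
    sub <- bdf[bdf$field == f, ]
    key <- paste(brackets$age_lo, brackets$age_hi)
    m <- match(key, paste(sub$age_lo, sub$age_hi))
    if (any(is.na(m))) {
      gaps <- key[is.na(m)]
      stop("field ", f, " is missing bracket(s): ",
           paste(gsub(" ", "-", gaps), collapse = ", "), call. = FALSE)
    }
    out[[f]] <- sub$value[m]
  }
  tx <- lapply(.tx_fields, function(f) {
    v <- df$value[df$field == f]
    if (length(v) != 1) stop("field ", f, " must appear exactly once", call. = FALSE)
    v
  })
  rate_table(out, tx_rate_DD_pediatric = tx[[1]],
             tx_rate_DD_adult = tx[[2]], tx_rate_third = tx[[3]])
}

#' Write a rate table as long-format CSV
#'
#' Inverse of [read_rate_table()]; values are written per person-year.
#'
#' @param table A `rate_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(table, path) {
  stopifnot(inherits(table, "rate_table"))
  b <- table$brackets[order(table$brackets$age_lo), ]
  long <- do.call(rbind, lapply(.bracket_fields, function(f) {
    data.frame(age_lo = b$age_lo, age_hi = b$age_hi, field = f,
               value = b[[f]], units = "per_person_year")
  }))
  tx <- data.frame(age_lo = 0, age_hi = 90, field = .tx_fields,
                   value = unlist(table$tx_rates), units = "per_person_year")
  utils::write.csv(rbind(long, tx), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a scenario configuration as JSON
#'
#' Field names mirror [scenario_config()]'s arguments.
#'
#' @param path JSON file path.
#' @return A `scenario_config` (reader); `path` invisibly (writer).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scenario_config, x)
}

#' @rdname read_scenario_config
#' @param config A `scenario_config` to serialize.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration echo, MD5 checksums of input files, the seed
#' and the package version so a run can be reproduced and audited.
#'
#' @param dir Output directory (created if needed).
#' @param configs Named list of `scenario_config` objects (or other
#'   serializable settings) to echo.
#' @param inputs Character vector of input file paths to checksum.
#' @param seed Integer seed recorded for the run.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, configs = list(), inputs = character(0), seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "txseq",
    version = as.character(utils::packageVersion("txseq")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    inputs = if (length(inputs)) {
      as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
    } else list(),
    configs = lapply(configs, unclass)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
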