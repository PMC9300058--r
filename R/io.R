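GOSLING_HEADER <- c("gosling_id", "population", "sex", "cohort", "nest_id",
                    "hatch_date", "capture_date", "age_days",
                    "mass_g", "head_mm", "tarsus_mm")

#' Read a gosling biometrics CSV
#'
#' Strict reader for the package's data interchange format: one row per
#' gosling (first capture only), ISO-8601 dates, and the exact header
#' `gosling_id,population,sex,cohort,nest_id,hatch_date,capture_date,`
#' `age_days,mass_g,head_mm,tarsus_mm`. The stored age is cross-checked
#' against `capture_date - hatch_date`.
#'
#' @param path CSV file path.
#' @return a data.frame of typed gosling records.
#' @export
read_gosling_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (!identical(names(d), GOSLING_HEADER))
    stop("header mismatch: expected ", paste(GOSLING_HEADER, collapse = ","))
  parse_date <- function(x, col) {
    out <- as.Date(x, format = "%Y-%m-%d")
    bad <- which(is.na(out) | x != format(out, "%Y-%m-%d"))
    if (length(bad))
      stop("unparseable ", col, " at row ", bad[1], ": '", x[bad[1]], "'")
    out
  }
  d$hatch_date <- parse_date(d$hatch_date, "hatch_date")
  d$capture_date <- parse_date(d$capture_date, "capture_date")
  d$cohort <- as.integer(d$cohort)
  d$age_days <- as.integer(d$age_days)
  for (tr in TRAITS) d[[tr]] <- as.numeric(d[[tr]])
  derived <- as.integer(d$capture_date - d$hatch_date)
  bad <- which(derived != d$age_days)
  if (length(bad))
    stop("age_days inconsistent with dates at row ", bad[1],
         " (stored ", d$age_days[bad[1]], ", dates give ",
         derived[bad[1]], ")")
  bad <- which(d$age_days < 0)
  if (length(bad)) stop("negative age at row ", bad[1])
  d
}

#' Write gosling records to CSV
#'
#' @param records gosling records (see [read_gosling_csv()] for the
#'   schema).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gosling_csv <- function(records, path) {
  d <- records[, GOSLING_HEADER]
  d$hatch_date <- format(as.Date(d$hatch_date), "%Y-%m-%d")
  d$capture_date <- format(as.Date(d$capture_date), "%Y-%m-%d")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
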