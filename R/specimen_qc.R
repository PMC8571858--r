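#' Load a specimen metadata table
#'
#' Reads a CSV transcription of a specimen QC table (one row per herbarium or
#' fresh specimen: species, collection date, DNA concentration, purity ratios,
#' amplification and sequencing outcomes) into a typed data frame.
#'
#' The CSV must carry the columns `specimen_id`, `species`, `collection_date`,
#' `dna_conc_ng_ul`, `od_260_280`, `od_260_230`, `amplified`, `full_sequence`,
#' `genbank_accession`, `source_class`. Dates may be ISO-8601 (`YYYY-MM-DD` or
#' `YYYY-MM`), a bare year `YYYY`, or the literal `ND` (no date). The
#' `amplified`/`full_sequence` columns accept `+`/`-` or `true`/`false`.
#' Extra columns (e.g. a `partial_sequence` flag) are preserved as-is.
#'
#' @param path Path to the CSV file.
#' @param source_class Optional override: `"herbarium"` or `"fresh"`. When
#'   given, every record's `source_class` is set to this value; otherwise the
#'   column in the file is used.
#' @return A data frame of class `specimen_records` with columns
#'   `specimen_id`, `species`, `collection_date` (character, `NA` if absent),
#'   `collection_year` (integer, `NA` if undated), `dna_conc`, `od_260_280`,
#'   `od_260_230`, `amplified` (logical), `full_sequence` (logical),
#'   `genbank_accession` (`NA` if none), `source_class`, plus any extra
#'   columns from the file.
#' @examples
#' tab1 <- system.file("extdata", "table1_herbarium_specimens.csv",
#'                     package = "herbarcode")
#' herb <- load_specimen_table(tab1, source_class = "herbarium")
#' nrow(herb)           # 52 specimens
#' sum(!herb$amplified) # 11 failed amplifications
#' @export
load_specimen_table <- function(path, source_class = NULL) {
  if (!file.exists(path)) stop("specimen table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("specimen_id", "species", "collection_date", "dna_conc_ng_ul",
                "od_260_280", "od_260_230", "amplified", "full_sequence",
                "genbank_accession", "source_class")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop("specimen table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad) > 0L)
      stop(sprintf("unparseable numeric in column '%s' at row %d: '%s'",
                   col, bad[1L], raw[[col]][bad[1L]]))
    v
  }
  parse_flag <- function(col) {
    v <- tolower(trimws(raw[[col]]))
    out <- v %in% c("+", "true", "t", "1", "yes")
    bad <- which(!v %in% c("+", "-", "true", "false", "t", "f", "1", "0",
                           "yes", "no"))
    if (length(bad) > 0L)
      stop(sprintf("unparseable flag in column '%s' at row %d: '%s'",
                   col, bad[1L], raw[[col]][bad[1L]]))
    out
  }
  date_chr <- trimws(raw$collection_date)
  date_chr[date_chr %in% c("", "ND", "nd", "NA")] <- NA_character_
  bad_date <- which(!is.na(date_chr) &
                    !grepl("^\\d{4}(-\\d{2}(-\\d{2})?)?$", date_chr))
  if (length(bad_date) > 0L)
    stop(sprintf("unparseable collection_date at row %d: '%s'",
                 bad_date[1L], raw$collection_date[bad_date[1L]]))
  year <- ifelse(is.na(date_chr), NA_integer_,
                 as.integer(substr(date_chr, 1L, 4L)))
  if (any(!is.na(year) & (year < 1800L | year > 2100L)))
    stop("collection_year outside plausible range [1800, 2100]")

  gb <- trimws(raw$genbank_accession)
  gb[gb %in% c("", "n/a", "NA")] <- NA_character_

  rec <- data.frame(
    specimen_id = raw$specimen_id,
    species = raw$species,
    collection_date = date_chr,
    collection_year = year,
    dna_conc = parse_num("dna_conc_ng_ul"),
    od_260_280 = parse_num("od_260_280"),
    od_260_230 = parse_num("od_260_230"),
    amplified = parse_flag("amplified"),
    full_sequence = parse_flag("full_sequence"),
    genbank_accession = gb,
    source_class = if (is.null(source_class)) raw$source_class else
      rep(match.arg(source_class, c("herbarium", "fresh")), nrow(raw)),
    stringsAsFactors = FALSE
  )
  if (any(rec$dna_conc < 0, na.rm = TRUE))
    stop("negative DNA concentration in specimen table")
  extra <- setdiff(names(raw), required)
  for (col in extra) rec[[col]] <- raw[[col]]
  class(rec) <- c("specimen_records", "data.frame")
  rec
}

#' Summarise a DNA purity or metadata metric
#'
#' Mean, sample standard deviation (denominator n - 1), and range of one
#' numeric specimen metric, with records missing the metric excluded and
#' counted.
#'
#' @param records A `specimen_records` data frame (see
#'   [load_specimen_table()]).
#' @param metric One of `"od_260_280"`, `"od_260_230"`, `"dna_conc"`,
#'   `"collection_year"`.
#' @return A list of class `purity_summary`: `metric`, `n` (values used),
#'   `n_missing`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_purity <- function(records,
                             metric = c("od_260_280", "od_260_230",
                                        "dna_conc", "collection_year")) {
  metric <- match.arg(metric)
  v <- records[[metric]]
  n_missing <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (length(v) < 2L)
    stop("insufficient data: need >= 2 non-missing values for ", metric)
  structure(list(metric = metric, n = length(v), n_missing = n_missing,
                 mean = mean(v), sd = stats::sd(v),
                 min = min(v), max = max(v)),
            class = "purity_summary")
}

#' @export
print.purity_summary <- function(x, ...) {
  cat(sprintf("%s: %.2f +/- %.2f (n = %d, range %.2f-%.2f)\n",
              x$metric, x$mean, x$sd, x$n, x$min, x$max))
  invisible(x)
}

#' Amplification and sequencing success rates
#'
#' Fractions of specimens that (a) amplified, (b) yielded a complete ITS1+ITS2
#' sequence, and (c) yielded a complete sequence among those that amplified.
#'
#' @param records A `specimen_records` data frame.
#' @return A data frame with columns `label`, `numerator`, `denominator`,
#'   `fraction`, and `percent` (the display value, rounded to one decimal).
#' @examples
#' tab1 <- system.file("extdata", "table1_herbarium_specimens.csv",
#'                     package = "herbarcode")
#' success_rates(load_specimen_table(tab1))
#' @export
success_rates <- function(records) {
  if (nrow(records) == 0L) stop("no specimen records")
  n <- nrow(records)
  amp <- sum(records$amplified)
  full <- sum(records$full_sequence)
  rate <- function(label, num, den) {
    data.frame(label = label, numerator = num, denominator = den,
               fraction = num / den, percent = round(100 * num / den, 1L),
               stringsAsFactors = FALSE)
  }
  rbind(rate("amplified", amp, n),
        rate("full_sequence", full, n),
        rate("full_sequence_among_amplified", full, amp))
}

#' Collection-year summaries stratified by amplification outcome
#'
#' Mean and sample SD of collection year, separately for specimens that
#' failed and succeeded PCR amplification. Undated records are excluded and
#' reported. A stratum with fewer than two dated records is marked
#' insufficient rather than summarised.
#'
#' @param records A `specimen_records` data frame.
#' @return A list with elements `failed` and `amplified` (each a
#'   `purity_summary` over `collection_year`, or the string
#'   `"insufficient data"`), and `n_undated`.
#' @export
year_stratified_summary <- function(records) {
  strat <- function(keep) {
    sub <- records[keep & !is.na(records$collection_year), , drop = FALSE]
    if (nrow(sub) < 2L) return("insufficient data")
    summarize_purity(sub, "collection_year")
  }
  list(failed = strat(!records$amplified),
       amplified = strat(records$amplified),
       n_undated = sum(is.na(records$collection_year)))
}

#' Regress DNA concentration on specimen age
#'
#' Ordinary least squares of DNA concentration (ng/ul) on specimen age in
#' years, where age is computed relative to a reference year (by default the
#' study's fresh-tissue harvest year, 2019): `x = reference_year -
#' collection_year`. Undated records are excluded.
#'
#' @param records A `specimen_records` data frame.
#' @param reference_year Year from which specimen age is measured.
#' @return A list of class `age_regression`: `slope` (ng/ul per year of age),
#'   `intercept` (ng/ul), `r_squared`, `p_value` (two-sided test of zero
#'   slope), `n`, `n_undated`, `x_definition`, and the underlying `fit`
#'   (an `lm` object).
#' @examples
#' tab1 <- system.file("extdata", "table1_herbarium_specimens.csv",
#'                     package = "herbarcode")
#' regress_concentration_on_age(load_specimen_table(tab1))
#' @export
regress_concentration_on_age <- function(records, reference_year = 2019) {
  ok <- !is.na(records$collection_year)
  if (sum(ok) < 3L)
    stop("insufficient data: need >= 3 dated records for the age regression")
  x <- reference_year - records$collection_year[ok]
  y <- records$dna_conc[ok]
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  p <- if (nrow(sm$coefficients) < 2L || all(x == x[1L])) NA_real_ else
    sm$coefficients[2L, 4L]
  # a flat response has no explainable variance; lm's mss/(mss + rss) is
  # numerical noise there
  r2 <- if (stats::var(y) == 0) 0 else sm$r.squared
  structure(list(
    slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
    r_squared = r2, p_value = p, n = sum(ok),
    n_undated = sum(!ok),
    x_definition = sprintf("age in years = %d - collection_year",
                           reference_year),
    fit = fit), class = "age_regression")
}

#' @export
print.age_regression <- function(x, ...) {
  cat(sprintf("y = %.3fx + %.1f  (r^2 = %.4f, p = %.2g, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  cat("x:", x$x_definition, "\n")
  invisible(x)
}

#' Assemble the full QC report for a specimen collection
#'
#' Convenience wrapper producing every quality-control summary for a set of
#' herbarium (and optionally fresh) specimen records: purity summaries,
#' success rates, year-stratified amplification outcome, and the
#' concentration-on-age regression.
#'
#' @param herbarium A `specimen_records` data frame of herbarium specimens.
#' @param fresh Optional `specimen_records` data frame of fresh specimens.
#' @param reference_year Passed to [regress_concentration_on_age()].
#' @return A nested list with components `herbarium` (purity, rates, strata,
#'   regression) and, when supplied, `fresh` (purity, rates).
#' @export
qc_report <- function(herbarium, fresh = NULL, reference_year = 2019) {
  strip <- function(s) s[setdiff(names(s), "fit")]
  rep <- list(herbarium = list(
    n = nrow(herbarium),
    od_260_280 = unclass(summarize_purity(herbarium, "od_260_280")),
    od_260_230 = unclass(summarize_purity(herbarium, "od_260_230")),
    dna_conc = unclass(summarize_purity(herbarium, "dna_conc")),
    rates = success_rates(herbarium),
    year_strata = lapply(year_stratified_summary(herbarium), unclass),
    age_regression = strip(unclass(
      regress_concentration_on_age(herbarium, reference_year)))
  ))
  if (!is.null(fresh)) {
    rep$fresh <- list(
      n = nrow(fresh),
      od_260_280 = unclass(summarize_purity(fresh, "od_260_280")),
      od_260_230 = unclass(summarize_purity(fresh, "od_260_230")),
      dna_conc = unclass(summarize_purity(fresh, "dna_conc")),
      rates = success_rates(fresh))
  }
  rep
}
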