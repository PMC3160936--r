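#' Survey-weighted cause-specific fractions
#'
#' The cause-specific mortality fraction f_c is the weighted share of
#' deaths in the denominator group assigned to cause c:
#' f_c = sum(weights of cause-c deaths) / sum(weights of all deaths in the
#' group).  Weighting uses the survey sampling weights, so oversampled
#' subgroups do not bias the fractions.  Denominators: `"under5"` (all
#' deaths; neonatal and postneonatal causes jointly sum to 1), `"neonatal"`
#' (deaths at 0-27 days) or `"1-59m"` (28-1825 days).
#'
#' @param assignments Data.frame from [assign_causes()] (or any data.frame
#'   with `record_id` and `cause`).
#' @param records The matching [va_records] data.frame.
#' @param denominator One of `"under5"`, `"neonatal"`, `"1-59m"`.
#' @return A data.frame of class `va_fractions` with columns `wave`,
#'   `denominator`, `cause`, `fraction`.
#' @export
weighted_fractions <- function(assignments, records,
                               denominator = c("under5", "neonatal", "1-59m")) {
  denominator <- match.arg(denominator)
  stopifnot(nrow(records) == nrow(assignments),
            all(records$record_id == assignments$record_id))
  keep <- switch(denominator,
                 under5 = rep(TRUE, nrow(records)),
                 neonatal = is_neonate(records),
                 `1-59m` = !is_neonate(records))
  if (!any(keep)) stop("no deaths in the ", denominator, " denominator group")
  r <- records[keep, ]; a <- assignments[keep, ]
  out <- list()
  for (w in sort(unique(r$wave))) {
    iw <- r$wave == w
    tot <- sum(r$weight[iw])
    agg <- stats::aggregate(r$weight[iw], by = list(cause = a$cause[iw]), FUN = sum)
    out[[w]] <- data.frame(wave = w, denominator = denominator,
                           cause = agg$cause, fraction = agg$x / tot,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$wave, match(res$cause, VA_ALL_CAUSES)), ]
  rownames(res) <- NULL
  class(res) <- c("va_fractions", "data.frame")
  res
}

# fractions from a finalized mass table (denominator = all under-5 mass per
# wave); by_age keeps the neonate/postneonate split of each cause
mass_to_fractions <- function(mass_table, by_age = FALSE) {
  out <- list()
  for (w in unique(mass_table$wave)) {
    sub <- mass_table[mass_table$wave == w, ]
    tot <- sum(sub$mass)
    if (tot <= 0) stop("zero total mass for wave ", w)
    if (by_age) {
      out[[w]] <- data.frame(wave = w, denominator = "under5",
                             age_group = sub$age_group, cause = sub$cause,
                             fraction = sub$mass / tot, stringsAsFactors = FALSE)
    } else {
      agg <- stats::aggregate(sub$mass, by = list(cause = sub$cause), FUN = sum)
      out[[w]] <- data.frame(wave = w, denominator = "under5",
                             cause = agg$cause, fraction = agg$x / tot,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$wave, match(res$cause, VA_ALL_CAUSES)), ]
  rownames(res) <- NULL
  class(res) <- c("va_fractions", "data.frame")
  res
}

#' Full pipeline: records to final cause fractions
#'
#' Convenience wrapper running assignment, weighted mass aggregation,
#' redistribution and fraction estimation in one call.  Fractions are
#' expressed over all under-5 deaths of each wave.
#'
#' @param records A harmonized [va_records] data.frame.
#' @param hierarchy A [va_hierarchy].
#' @param defs A [va_definition_set].
#' @param by_age Keep the neonate/postneonate split of each cause.
#' @return A `va_fractions` data.frame (with the finalized mass table and
#'   assignments attached as attributes `mass` and `assignments`).
#' @export
cause_fractions <- function(records, hierarchy = default_hierarchy(),
                            defs = default_definitions(), by_age = FALSE) {
  assignments <- assign_causes(records, hierarchy, defs)
  mass <- finalize_causes(cause_mass_table(records, assignments), quiet = TRUE)
  res <- mass_to_fractions(mass, by_age = by_age)
  attr(res, "mass") <- mass
  attr(res, "assignments") <- assignments
  res
}

#' Weighted proportion of neonatal deaths
#'
#' @param records A [va_records] data.frame.
#' @return Named numeric vector, one weighted proportion per wave, of
#'   under-5 deaths aged 0-27 days.
#' @export
neonatal_proportion <- function(records) {
  neo <- is_neonate(records)
  vapply(split(seq_len(nrow(records)), records$wave), function(i) {
    sum(records$weight[i][neo[i]]) / sum(records$weight[i])
  }, numeric(1))
}

#' Interpolate a mortality rate at a survey midpoint
#'
#' Surveys spanning two calendar years are assigned the arithmetic
#' midpoint of the two annual rates (linear interpolation at mid-period).
#'
#' @param rate_year1,rate_year2 Positive rates (per 1,000 live births).
#' @return The midpoint rate.
#' @export
#' @examples
#' interpolate_u5mr(130, 126)  # 128
interpolate_u5mr <- function(rate_year1, rate_year2) {
  stopifnot(rate_year1 > 0, rate_year2 > 0)
  (rate_year1 + rate_year2) / 2
}

#' Read an external mortality-rate series
#'
#' A small delimited table with columns `wave`, `u5mr`, `u5mr_lo`,
#' `u5mr_hi`, `nmr` (rates per 1,000 live births; bounds may be empty).
#' The package ships a demonstration series for the three Bangladesh
#' surveys under `system.file("extdata", "igme_u5mr.csv", package =
#' "hierva")`.
#'
#' @param path Path to the CSV/TSV file.
#' @return A data.frame of class `va_rates`.
#' @export
read_u5mr_series <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("wave", "u5mr")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) stop("rate series missing column(s): ",
                             paste(miss, collapse = ", "))
  for (col in c("u5mr_lo", "u5mr_hi", "nmr")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (any(df$u5mr <= 0)) stop("u5mr must be positive")
  if (any(!is.na(df$nmr) & (df$nmr <= 0 | df$nmr > df$u5mr))) {
    stop("nmr must satisfy 0 < nmr <= u5mr")
  }
  ok_bounds <- is.na(df$u5mr_lo) | is.na(df$u5mr_hi) |
    (df$u5mr_lo <= df$u5mr & df$u5mr <= df$u5mr_hi)
  if (!all(ok_bounds)) stop("u5mr bounds must bracket the point value")
  class(df) <- c("va_rates", "data.frame")
  df
}

#' Cause-specific mortality rates
#'
#' CSMR_c = f_c x U5MR, per 1,000 live births.  The reported value rounds
#' to the nearest integer (half away from zero) when at least 1 per 1,000,
#' and to one decimal below 1 per 1,000.
#'
#' @param fraction_table A `va_fractions` data.frame (column `fraction`,
#'   keyed by `wave` and `cause`).
#' @param rates A `va_rates` data.frame (see [read_u5mr_series()]).
#' @return Data.frame of class `va_csmr` with columns `wave`, `cause`,
#'   `rate` (exact) and `rate_reported` (rounded for presentation).
#' @export
#' @examples
#' f <- data.frame(wave = "2004", denominator = "under5",
#'                 cause = "pneumonia", fraction = 0.33)
#' r <- data.frame(wave = "2004", u5mr = 70, u5mr_lo = NA, u5mr_hi = NA, nmr = 36)
#' csmr(f, r)  # 23.1, reported 23
csmr <- function(fraction_table, rates) {
  stopifnot(all(c("wave", "cause", "fraction") %in% names(fraction_table)),
            all(c("wave", "u5mr") %in% names(rates)))
  miss <- setdiff(unique(fraction_table$wave), rates$wave)
  if (length(miss) > 0) {
    stop("no U5MR available for wave(s): ", paste(miss, collapse = ", "))
  }
  u5mr <- rates$u5mr[match(fraction_table$wave, rates$wave)]
  rate <- fraction_table$fraction * u5mr
  out <- data.frame(wave = fraction_table$wave, cause = fraction_table$cause,
                    rate = rate, rate_reported = report_round(rate),
                    stringsAsFactors = FALSE)
  if ("age_group" %in% names(fraction_table)) {
    out <- cbind(out[1], age_group = fraction_table$age_group, out[-1])
  }
  class(out) <- c("va_csmr", "data.frame")
  out
}

#' Presentation rounding for mortality rates
#'
#' Rates of at least 1 per 1,000 round to the nearest integer, half away
#' from zero; rates below 1 round to one decimal.
#'
#' @param x Numeric vector of rates.
#' @return Numeric vector of reported values.
#' @export
report_round <- function(x) {
  ifelse(abs(x) >= 1, round_half_away(x, 0L), round_half_away(x, 1L))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
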