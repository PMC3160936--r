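#' Plan a stratified clustered bootstrap
#'
#' Resampling respects the survey design: primary sampling units (PSUs)
#' are resampled with replacement within their design strata.  Strata in
#' which only a single PSU contributed deaths cannot be resampled on their
#' own; all such single-PSU strata are merged into one pooled stratum and
#' treated as interchangeable.
#'
#' @param records A [va_records] data.frame from a single survey wave.
#' @return A `va_boot_plan`: list with `strata` (named list of PSU id
#'   vectors, multi-PSU strata only), `pooled` (PSU ids from single-PSU
#'   strata) and `wave`.
#' @export
plan_bootstrap <- function(records) {
  stopifnot(inherits(records, "va_records"))
  if (length(unique(records$wave)) > 1L) {
    stop("bootstrap plans are per survey wave; split the records by wave")
  }
  psu_by_stratum <- lapply(split(records$psu_id, records$stratum_id), unique)
  if (sum(lengths(psu_by_stratum)) == 0L) stop("no PSUs in the records")
  single <- lengths(psu_by_stratum) == 1L
  plan <- list(strata = psu_by_stratum[!single],
               pooled = unname(unlist(psu_by_stratum[single])),
               wave = records$wave[1])
  class(plan) <- "va_boot_plan"
  plan
}

#' @export
print.va_boot_plan <- function(x, ...) {
  cat("<va_boot_plan> wave ", x$wave, ": ", length(x$strata),
      " multi-PSU strata (", sum(lengths(x$strata)), " PSUs), ",
      length(x$pooled), " pooled single-PSU PSUs\n", sep = "")
  invisible(x)
}

# resampling units: multi-PSU strata plus (if any) the pooled stratum
plan_strata <- function(plan) {
  st <- plan$strata
  if (length(plan$pooled) > 0) st <- c(st, list(.pooled = plan$pooled))
  st
}

#' Bootstrap replicate cause fractions
#'
#' For each replicate, PSUs are resampled with replacement within every
#' stratum of the plan (keeping the stratum's PSU count and the original
#' sampling weights), all deaths in the sampled PSUs are kept, and the
#' full pipeline — cause assignment, comorbidity redistribution, weighted
#' fraction estimation — is rerun on the resampled data.  Redistribution
#' is a nonlinear function of the resampled masses, so it must be (and is)
#' recomputed inside every replicate; per-record cause assignment is a
#' pure function of the record and is computed once, which is exactly
#' equivalent to recomputing it per replicate.  Replicate `b` depends only
#' on `seed + b`, so any subset of replicates is reproducible.
#'
#' @param records A harmonized single-wave [va_records] data.frame.
#' @param hierarchy A [va_hierarchy].
#' @param defs A [va_definition_set].
#' @param plan A `va_boot_plan` (default: [plan_bootstrap()] on `records`).
#' @param B Number of replicates.
#' @param seed Integer seed.
#' @return A `va_boot` object: list with `fractions` (final-causes x B
#'   matrix of under-5 fractions), `neonatal_prop` (length-B vector),
#'   `point` (point-estimate fractions), `point_neonatal_prop`, `B`,
#'   `seed`, `plan`, `n_missing` (replicates with an empty denominator,
#'   recorded as NA).
#' @export
bootstrap_fractions <- function(records, hierarchy = default_hierarchy(),
                                defs = default_definitions(),
                                plan = plan_bootstrap(records),
                                B = 1000L, seed = 1L) {
  stopifnot(B >= 1L)
  if (length(unique(records$wave)) > 1L) {
    stop("bootstrap runs per survey wave; split the records by wave")
  }
  assignments <- assign_causes(records, hierarchy, defs)
  K <- length(VA_ALL_CAUSES)
  cause_idx <- match(assignments$cause, VA_ALL_CAUSES)
  age_idx <- ifelse(is_neonate(records), 1L, 2L)
  grp <- (age_idx - 1L) * K + cause_idx
  w <- records$weight
  psu_rows <- split(seq_len(nrow(records)), records$psu_id)
  strata <- plan_strata(plan)
  missing_psu <- setdiff(unlist(strata), names(psu_rows))
  if (length(missing_psu) > 0) {
    stop("plan references PSU(s) absent from the records: ",
         paste(missing_psu, collapse = ", "))
  }

  point_mass <- replicate_mass(seq_len(nrow(records)), grp, w, K)
  point <- mass_matrix_to_fractions(point_mass)
  point_neo <- sum(w[age_idx == 1L]) / sum(w)

  frac <- matrix(NA_real_, nrow = length(VA_FINAL_CAUSES), ncol = B,
                 dimnames = list(VA_FINAL_CAUSES, NULL))
  neo <- rep(NA_real_, B)
  n_missing <- 0L
  for (b in seq_len(B)) {
    set.seed(seed + b)
    idx <- unlist(lapply(strata, function(psus) {
      unlist(psu_rows[sample(psus, length(psus), replace = TRUE)],
             use.names = FALSE)
    }), use.names = FALSE)
    if (length(idx) == 0L) { n_missing <- n_missing + 1L; next }
    M <- replicate_mass(idx, grp, w, K)
    frac[, b] <- mass_matrix_to_fractions(M)
    neo[b] <- sum(w[idx][age_idx[idx] == 1L]) / sum(w[idx])
  }
  if (n_missing > 0) {
    warning(n_missing, " replicate(s) had an empty denominator and were ",
            "recorded as missing")
  }
  structure(list(fractions = frac, neonatal_prop = neo, point = point,
                 point_neonatal_prop = point_neo, B = B, seed = seed,
                 plan = plan, n_missing = n_missing),
            class = "va_boot")
}

# weighted mass by (age group x cause) for the row subset idx
replicate_mass <- function(idx, grp, w, K) {
  rs <- rowsum(w[idx], grp[idx])
  M <- matrix(0, nrow = K, ncol = 2L,
              dimnames = list(VA_ALL_CAUSES, c("neonate", "postneonate")))
  g <- as.integer(rownames(rs))
  M[cbind((g - 1L) %% K + 1L, (g - 1L) %/% K + 1L)] <- rs[, 1L]
  M
}

# finalize both age-group columns and return under-5 fractions by final cause
mass_matrix_to_fractions <- function(M) {
  fin_neo <- finalize_mass_vector(M[, 1L], quiet = TRUE)
  fin_post <- finalize_mass_vector(M[, 2L], quiet = TRUE)
  tot <- sum(M)
  (as.numeric(fin_neo) + as.numeric(fin_post)) / tot
}

#' @export
print.va_boot <- function(x, ...) {
  cat("<va_boot> wave ", x$plan$wave, ", B = ", x$B,
      if (x$n_missing > 0) paste0(" (", x$n_missing, " missing)"), "\n", sep = "")
  invisible(x)
}

#' Percentile uncertainty range
#'
#' The uncertainty range is the empirical 2.5th-97.5th percentile interval
#' of the bootstrap replicates (linear-interpolation percentiles), reported
#' around the stated point estimate.
#'
#' @param replicate_values Numeric vector of replicate values (NAs allowed;
#'   at least one finite value required).
#' @param point The point estimate to carry through.
#' @return A list of class `va_ur`: `point`, `lo`, `hi`, `B` (count of
#'   finite replicates used).
#' @export
percentile_ur <- function(replicate_values, point) {
  v <- replicate_values[is.finite(replicate_values)]
  if (length(v) == 0L) stop("no finite replicate values")
  q <- stats::quantile(v, probs = c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(point = point, lo = q[1], hi = q[2], B = length(v)),
            class = "va_ur")
}

#' @export
print.va_ur <- function(x, ...) {
  cat(sprintf("%.4g (UR %.4g-%.4g; B = %d)\n", x$point, x$lo, x$hi, x$B))
  invisible(x)
}

#' Uncertainty ranges for every cause fraction of a bootstrap run
#'
#' @param boot A `va_boot` object.
#' @return Data.frame with columns `cause`, `point`, `lo`, `hi`, `B`.
#' @export
fraction_ur_table <- function(boot) {
  stopifnot(inherits(boot, "va_boot"))
  rows <- lapply(rownames(boot$fractions), function(cs) {
    ur <- percentile_ur(boot$fractions[cs, ], boot$point[match(cs, VA_FINAL_CAUSES)])
    data.frame(cause = cs, point = ur$point, lo = ur$lo, hi = ur$hi, B = ur$B,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' CSMR uncertainty combining fraction and U5MR uncertainty
#'
#' Each bootstrap fraction replicate is multiplied by an independent draw
#' of the under-5 mortality rate, and the uncertainty range is the 2.5-97.5
#' percentile interval of the products.  The default draw is normal with
#' mean at the point rate and standard deviation `(hi - lo) / 3.92`
#' (matching a symmetric 95% interval), truncated at zero.  With
#' `draw = "fixed"`, or when bounds are unavailable (then with a warning),
#' the rate is held at its point value and only fraction uncertainty
#' propagates.
#'
#' @param boot A `va_boot` object.
#' @param rates A single-wave row of a `va_rates` table (or a table
#'   containing the boot's wave).
#' @param seed Integer seed for the rate draws.
#' @param draw `"normal"` or `"fixed"`.
#' @return Data.frame with columns `cause`, `point`, `lo`, `hi`, `B`
#'   (rates per 1,000 live births).
#' @export
csmr_ur <- function(boot, rates, seed = 1L, draw = c("normal", "fixed")) {
  draw <- match.arg(draw)
  stopifnot(inherits(boot, "va_boot"))
  row <- rates[rates$wave == boot$plan$wave, , drop = FALSE]
  if (nrow(row) != 1L) stop("rates must contain exactly one row for wave ",
                            boot$plan$wave)
  u5mr <- row$u5mr
  if (draw == "normal" && (is.na(row$u5mr_lo) || is.na(row$u5mr_hi))) {
    warning("U5MR bounds unavailable for wave ", boot$plan$wave,
            "; falling back to the fixed point rate")
    draw <- "fixed"
  }
  u5mr_star <- if (draw == "normal") {
    set.seed(seed)
    sd <- (row$u5mr_hi - row$u5mr_lo) / 3.92
    pmax(stats::rnorm(boot$B, mean = u5mr, sd = sd), 0)
  } else rep(u5mr, boot$B)
  rows <- lapply(seq_len(nrow(boot$fractions)), function(i) {
    prod_reps <- boot$fractions[i, ] * u5mr_star
    ur <- percentile_ur(prod_reps, boot$point[i] * u5mr)
    data.frame(cause = rownames(boot$fractions)[i], point = ur$point,
               lo = ur$lo, hi = ur$hi, B = ur$B, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sample bootstrap test for a between-survey change
#'
#' Compares a statistic between two independently resampled surveys using
#' the replicate differences D_b = B_b - A_b.  The two-sided p-value is
#' `2 * min(P(D <= 0), P(D >= 0))` with the add-one correction
#' `(r + 1) / (B + 1)` (so p is never exactly zero), capped at 1.
#'
#' @param replicates_wave_a,replicates_wave_b Equal-length numeric vectors
#'   of bootstrap replicates of the statistic in each survey.
#' @return Two-sided p-value.
#' @export
two_sample_test <- function(replicates_wave_a, replicates_wave_b) {
  if (length(replicates_wave_a) != length(replicates_wave_b)) {
    stop("replicate vectors must have equal length (waves are resampled ",
         "independently with the same B)")
  }
  ok <- is.finite(replicates_wave_a) & is.finite(replicates_wave_b)
  a <- replicates_wave_a[ok]; b <- replicates_wave_b[ok]
  if (length(a) == 0L) stop("no finite replicate pairs")
  d <- b - a
  n <- length(d)
  p_lo <- (sum(d <= 0) + 1) / (n + 1)
  p_hi <- (sum(d >= 0) + 1) / (n + 1)
  min(1, 2 * min(p_lo, p_hi))
}
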