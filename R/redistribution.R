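#' Weighted cause-mass tables
#'
#' A cause-mass table holds, per survey wave and age group, the sum of
#' sampling weights of the deaths assigned to each cause category.  It is
#' the currency of the redistribution step: every operation conserves the
#' total weighted mass.
#'
#' @param records A [va_records] data.frame.
#' @param assignments The matching data.frame from [assign_causes()].
#' @return A data.frame of class `va_mass` with columns `wave`,
#'   `age_group` (`"neonate"`/`"postneonate"`), `cause`, `mass`.
#' @export
cause_mass_table <- function(records, assignments) {
  stopifnot(nrow(records) == nrow(assignments),
            all(records$record_id == assignments$record_id))
  age_group <- ifelse(is_neonate(records), "neonate", "postneonate")
  agg <- stats::aggregate(records$weight,
                          by = list(wave = records$wave, age_group = age_group,
                                    cause = assignments$cause),
                          FUN = sum)
  names(agg)[4] <- "mass"
  agg <- agg[order(agg$wave, agg$age_group, match(agg$cause, VA_ALL_CAUSES)), ]
  rownames(agg) <- NULL
  class(agg) <- c("va_mass", "data.frame")
  agg
}

#' Proportional split of comorbid mass
#'
#' Deaths assigned jointly to two causes (e.g. ARI and diarrhea) are
#' redistributed to the single causes in proportion to their relative
#' importance as assigned single causes: with single-cause masses `a` and
#' `b` and comorbid mass `m`, cause A receives `a + m * a / (a + b)` and
#' cause B the rest.  The sum of the outputs always equals the sum of the
#' inputs.  When both single-cause masses are zero but comorbid mass is
#' positive the proportional rule is undefined; the mass is then split
#' equally (with a message unless `quiet = TRUE`).
#'
#' @param mass_a_only,mass_b_only Non-negative single-cause masses.
#' @param mass_both Non-negative comorbid mass.
#' @param quiet Suppress the equal-split message.
#' @return Numeric vector `c(a_final, b_final)`.
#' @export
#' @examples
#' split_comorbid(20, 10, 6)  # c(24, 12)
split_comorbid <- function(mass_a_only, mass_b_only, mass_both, quiet = FALSE) {
  stopifnot(mass_a_only >= 0, mass_b_only >= 0, mass_both >= 0)
  if (mass_both == 0) return(c(mass_a_only, mass_b_only))
  denom <- mass_a_only + mass_b_only
  if (denom == 0) {
    if (!quiet) {
      message("comorbid mass with no single-cause mass on either side: ",
              "splitting equally")
    }
    return(c(mass_both / 2, mass_both / 2))
  }
  c(mass_a_only + mass_both * mass_a_only / denom,
    mass_b_only + mass_both * mass_b_only / denom)
}

# fast core: named mass vector over VA_ALL_CAUSES for one wave x age group
# -> named vector over VA_FINAL_CAUSES + possible-mass provenance
finalize_mass_vector <- function(m, quiet = TRUE) {
  # (i) measles with ARI/diarrhea merges into measles
  m["measles"] <- m["measles"] + m["measles_with_ari_or_diarrhea"]
  # (ii) comorbid ARI+diarrhea split proportionally to the single causes
  pd <- split_comorbid(m["pneumonia"], m["diarrhea"], m["ari_and_diarrhea"],
                       quiet = quiet)
  m["pneumonia"] <- pd[1]; m["diarrhea"] <- pd[2]
  # (iii) same split for the comorbid possible pair
  ppd <- split_comorbid(m["possible_pneumonia"], m["possible_diarrhea"],
                        m["possible_ari_and_diarrhea"], quiet = quiet)
  # (iv) possible pneumonia/diarrhea grouped into the confirmed causes
  m["pneumonia"] <- m["pneumonia"] + ppd[1]
  m["diarrhea"] <- m["diarrhea"] + ppd[2]
  out <- m[VA_FINAL_CAUSES]
  attr(out, "possible_mass") <- c(pneumonia = unname(ppd[1]),
                                  diarrhea = unname(ppd[2]))
  out
}

#' Finalize a cause-mass table
#'
#' Converts intermediate assignment categories into the final reporting
#' causes, separately within each wave x age-group cell: measles with
#' ARI/diarrhea is merged into measles; comorbid ARI-and-diarrhea mass is
#' split between pneumonia and diarrhea by [split_comorbid()]; the comorbid
#' possible pair is split the same way; and possible pneumonia / possible
#' diarrhea are grouped into pneumonia and diarrhea.  Total weighted mass
#' is conserved, and the operation is the identity on tables that already
#' contain only final causes.
#'
#' The share of each finalized pneumonia/diarrhea mass that originated
#' from the possible categories is kept as provenance and can be queried
#' with [possible_share()].
#'
#' @param table A `va_mass` table from [cause_mass_table()] (may contain
#'   intermediate categories).
#' @param quiet Suppress equal-split messages from degenerate cells.
#' @return A `va_mass` table over final causes only, with a `provenance`
#'   attribute.
#' @export
finalize_causes <- function(table, quiet = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("wave", "age_group", "cause", "mass") %in% names(table)))
  bad <- setdiff(unique(table$cause), VA_ALL_CAUSES)
  if (length(bad) > 0) stop("unknown cause in mass table: ", paste(bad, collapse = ", "))
  cells <- unique(table[, c("wave", "age_group"), drop = FALSE])
  out <- list(); prov <- list()
  for (i in seq_len(nrow(cells))) {
    w <- cells$wave[i]; g <- cells$age_group[i]
    sub <- table[table$wave == w & table$age_group == g, ]
    m <- stats::setNames(numeric(length(VA_ALL_CAUSES)), VA_ALL_CAUSES)
    m[sub$cause] <- m[sub$cause] + sub$mass
    fin <- finalize_mass_vector(m, quiet = quiet)
    pm <- attr(fin, "possible_mass")
    out[[i]] <- data.frame(wave = w, age_group = g, cause = names(fin),
                           mass = as.numeric(fin), stringsAsFactors = FALSE)
    prov[[i]] <- data.frame(wave = w, age_group = g,
                            cause = c("pneumonia", "diarrhea"),
                            possible_mass = as.numeric(pm),
                            final_mass = as.numeric(fin[c("pneumonia", "diarrhea")]),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "provenance") <- do.call(rbind, prov)
  class(res) <- c("va_mass", "data.frame")
  res
}

#' Share of a finalized cause that came from its "possible" category
#'
#' After [finalize_causes()], part of the pneumonia and diarrhea mass
#' originated from the less-specific possible-pneumonia / possible-diarrhea
#' definitions.  `possible_share()` reports that share per wave and age
#' group; it is `NA` where the finalized cause mass is zero.
#'
#' @param table A finalized `va_mass` table (from [finalize_causes()]).
#' @param cause `"pneumonia"` or `"diarrhea"`.
#' @return Data.frame with columns `wave`, `age_group`, `share`.
#' @export
possible_share <- function(table, cause = c("pneumonia", "diarrhea")) {
  cause <- match.arg(cause)
  prov <- attr(table, "provenance")
  if (is.null(prov)) stop("table carries no possible-mass provenance; ",
                          "run finalize_causes() first")
  sub <- prov[prov$cause == cause, ]
  share <- ifelse(sub$final_mass > 0, sub$possible_mass / sub$final_mass, NA_real_)
  data.frame(wave = sub$wave, age_group = sub$age_group, share = share,
             stringsAsFactors = FALSE)
}
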