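#' Assignment hierarchies
#'
#' A hierarchy is an ordered list of tiers.  Each tier holds a set of
#' causes and a mode: in an `exclusive` tier the tier's causes compete and
#' a single category results; in the one `simultaneous` tier (measles /
#' ARI / diarrhea) any two or all three causes may be assigned together,
#' producing the combination categories `measles_with_ari_or_diarrhea` and
#' `ari_and_diarrhea`.  The final tier is always the residual
#' `unspecified`.
#'
#' @param tiers List of tiers; each tier is `list(causes = <character>,
#'   mode = "exclusive"|"simultaneous")`.
#' @param version Version label string.
#' @return A `va_hierarchy` object.
#' @seealso [default_hierarchy()], [assign_causes()]
#' @export
va_hierarchy <- function(tiers, version = "custom") {
  stopifnot(is.list(tiers), length(tiers) >= 1L)
  tiers <- lapply(tiers, function(t) {
    if (is.character(t)) t <- list(causes = t, mode = "exclusive")
    if (is.null(t$mode)) t$mode <- "exclusive"
    stopifnot(t$mode %in% c("exclusive", "simultaneous"))
    t$causes <- as.character(t$causes)
    bad <- setdiff(t$causes, VA_ALL_CAUSES)
    if (length(bad) > 0) stop("unknown cause in hierarchy: ", paste(bad, collapse = ", "))
    t
  })
  all_causes <- unlist(lapply(tiers, `[[`, "causes"))
  if (anyDuplicated(all_causes)) {
    stop("cause appears in more than one tier: ",
         paste(unique(all_causes[duplicated(all_causes)]), collapse = ", "))
  }
  n_sim <- sum(vapply(tiers, function(t) t$mode == "simultaneous", TRUE))
  if (n_sim > 1L) stop("at most one tier may be simultaneous")
  last <- tiers[[length(tiers)]]
  if (!identical(last$causes, "unspecified")) {
    stop("the final tier must be the residual 'unspecified'")
  }
  structure(list(version = version, tiers = tiers), class = "va_hierarchy")
}

#' @export
print.va_hierarchy <- function(x, ...) {
  cat("<va_hierarchy> '", x$version, "'\n", sep = "")
  for (i in seq_along(x$tiers)) {
    t <- x$tiers[[i]]
    cat(sprintf("  %2d. %s%s\n", i, paste(t$causes, collapse = ", "),
                if (t$mode == "simultaneous") "  [simultaneous]" else ""))
  }
  invisible(x)
}

#' Standardized default hierarchy
#'
#' Tier order of the standardized algorithm: neonatal tetanus first, then
#' injury, then the simultaneous measles/ARI/diarrhea tier, congenital
#' abnormality, birth asphyxia/birth injury, possible pneumonia/diarrhea,
#' prematurity/LBW (deliberately placed *before* the remaining other
#' possible serious infections), malnutrition, and the residual
#' unspecified.  The order is shipped as an editable, versioned config so
#' alternative orderings can be dropped in without code changes (see
#' [read_hierarchy()]).
#'
#' @return A [va_hierarchy].
#' @export
default_hierarchy <- function() {
  va_hierarchy(list(
    list(causes = "neonatal_tetanus"),
    list(causes = "injury"),
    list(causes = c("measles", "pneumonia", "diarrhea"), mode = "simultaneous"),
    list(causes = "congenital_abnormality"),
    list(causes = "birth_asphyxia_birth_injury"),
    list(causes = c("possible_pneumonia", "possible_diarrhea")),
    list(causes = "prematurity_lbw"),
    list(causes = "other_possible_serious_infection"),
    list(causes = "malnutrition"),
    list(causes = "unspecified")
  ), version = "standardized-1")
}

#' Read or write a hierarchy config file
#'
#' @param path Path to a YAML file with a `version` string and a `tiers`
#'   list (`causes` plus optional `mode`).
#' @param hierarchy A [va_hierarchy].
#' @return `read_hierarchy()` returns a [va_hierarchy];
#'   `write_hierarchy()` returns `path` invisibly.
#' @export
read_hierarchy <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$tiers)) stop("hierarchy file has no 'tiers' entry: ", path)
  tiers <- lapply(doc$tiers, function(t) {
    list(causes = as.character(unlist(t$causes)), mode = t$mode %||% "exclusive")
  })
  va_hierarchy(tiers, version = doc$version %||% "unversioned")
}

#' @rdname read_hierarchy
#' @export
write_hierarchy <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "va_hierarchy"))
  doc <- list(version = hierarchy$version,
              tiers = lapply(hierarchy$tiers, function(t) {
                list(causes = as.list(t$causes), mode = t$mode)
              }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

# tier index of each cause; named integer vector
hierarchy_tier_index <- function(hierarchy) {
  idx <- integer(0)
  for (i in seq_along(hierarchy$tiers)) {
    cs <- hierarchy$tiers[[i]]$causes
    idx[cs] <- i
  }
  idx
}

# check every non-residual hierarchy cause has at least one definition
check_hierarchy_definitions <- function(hierarchy, defs) {
  need <- setdiff(unlist(lapply(hierarchy$tiers, `[[`, "causes")), "unspecified")
  have <- definition_causes(defs)
  missing <- setdiff(need, have)
  if (length(missing) > 0) {
    stop("hierarchy references cause(s) with no definition: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# records x defined-causes logical matrix: does any age variant of the
# cause's definition fire?
fired_matrix <- function(records, defs) {
  causes <- definition_causes(defs)
  F <- matrix(FALSE, nrow = nrow(records), ncol = length(causes),
              dimnames = list(NULL, causes))
  for (d in defs$definitions) {
    F[, d$cause] <- F[, d$cause] | evaluate_definition(d, records)
  }
  F
}

# collapse the set of causes that fired together into one category
combine_cause_set <- function(fired) {
  if (length(fired) == 1L) return(fired)
  if ("measles" %in% fired && any(c("pneumonia", "diarrhea") %in% fired)) {
    return("measles_with_ari_or_diarrhea")
  }
  if (all(c("pneumonia", "diarrhea") %in% fired)) return("ari_and_diarrhea")
  if (all(c("possible_pneumonia", "possible_diarrhea") %in% fired)) {
    return("possible_ari_and_diarrhea")
  }
  va_canonical_order(fired)[1L]
}

# vectorized combination for the causes of one tier; Fs is records x causes
resolve_tier_fired <- function(Fs, causes) {
  if (length(causes) == 1L) return(rep(causes, nrow(Fs)))
  if (setequal(causes, c("measles", "pneumonia", "diarrhea"))) {
    m <- Fs[, "measles"]; p <- Fs[, "pneumonia"]; d <- Fs[, "diarrhea"]
    return(ifelse(m & (p | d), "measles_with_ari_or_diarrhea",
           ifelse(m, "measles",
           ifelse(p & d, "ari_and_diarrhea",
           ifelse(p, "pneumonia", "diarrhea")))))
  }
  if (setequal(causes, c("possible_pneumonia", "possible_diarrhea"))) {
    p <- Fs[, "possible_pneumonia"]; d <- Fs[, "possible_diarrhea"]
    return(ifelse(p & d, "possible_ari_and_diarrhea",
           ifelse(p, "possible_pneumonia", "possible_diarrhea")))
  }
  apply(Fs, 1L, function(row) combine_cause_set(causes[row]))
}

#' Assign causes of death through the hierarchy
#'
#' Walks the tiers in order; the first tier in which at least one case
#' definition fires determines the record's cause.  In the simultaneous
#' measles/ARI/diarrhea tier, co-firing causes yield the combination
#' categories `measles_with_ari_or_diarrhea` and `ari_and_diarrhea`; a
#' co-firing possible-pneumonia/possible-diarrhea pair yields
#' `possible_ari_and_diarrhea`.  Records firing no definition are
#' `unspecified`.
#'
#' `assign_causes()` processes a whole table and returns one row per
#' record; `assign_cause()` is the single-record form and returns the full
#' assignment result (including the fired-cause set).
#'
#' @param records A harmonized [va_records] data.frame.
#' @param hierarchy A [va_hierarchy].
#' @param defs A [va_definition_set] covering every hierarchy cause.
#' @return `assign_causes()`: data.frame with columns `record_id`, `cause`,
#'   `tier`, `mode`.  `assign_cause()`: list with `record_id`,
#'   `single_cause`, `all_causes`, `tier_index`, `mode`.
#' @export
assign_causes <- function(records, hierarchy = default_hierarchy(),
                          defs = default_definitions()) {
  stopifnot(inherits(records, "va_records"), inherits(hierarchy, "va_hierarchy"))
  check_hierarchy_definitions(hierarchy, defs)
  n <- nrow(records)
  F <- fired_matrix(records, defs)
  cause <- rep(NA_character_, n)
  tier <- rep(NA_integer_, n)
  for (i in seq_along(hierarchy$tiers)) {
    t <- hierarchy$tiers[[i]]
    if (identical(t$causes, "unspecified")) {
      open <- is.na(cause)
      cause[open] <- "unspecified"
      tier[open] <- i
      break
    }
    present <- intersect(t$causes, colnames(F))
    Ft <- F[, present, drop = FALSE]
    hit <- is.na(cause) & rowSums(Ft) > 0
    if (any(hit)) {
      cause[hit] <- resolve_tier_fired(Ft[hit, , drop = FALSE], present)
      tier[hit] <- i
    }
  }
  data.frame(record_id = records$record_id, cause = cause, tier = tier,
             mode = "hierarchical", stringsAsFactors = FALSE)
}

#' @rdname assign_causes
#' @param record A single-row [va_records] data.frame.
#' @export
assign_cause <- function(record, hierarchy = default_hierarchy(),
                         defs = default_definitions()) {
  stopifnot(nrow(record) == 1L)
  res <- assign_causes(record, hierarchy, defs)
  list(record_id = res$record_id, single_cause = res$cause,
       all_causes = res$cause, tier_index = res$tier, mode = "hierarchical")
}

#' Multi-cause assignment without a hierarchy
#'
#' The sensitivity-analysis mode: every cause whose definition fires is
#' returned, with no tier taking precedence.  Records firing nothing are
#' `unspecified`.  [resolve_multicause()] then reapplies a hierarchy to a
#' multi-cause set to recover a single cause; composing the two equals
#' [assign_causes()].
#'
#' @param records A harmonized [va_records] data.frame.
#' @param defs A [va_definition_set].
#' @return For one record, a character vector of causes; for several, a
#'   list of character vectors (one per record).
#' @export
assign_multicause <- function(records, defs = default_definitions()) {
  F <- fired_matrix(records, defs)
  causes <- colnames(F)
  out <- lapply(seq_len(nrow(F)), function(i) {
    s <- causes[F[i, ]]
    if (length(s) == 0L) "unspecified" else s
  })
  if (nrow(F) == 1L) out[[1L]] else out
}

#' @rdname assign_multicause
#' @param causes Non-empty character vector of causes (one record's
#'   multi-cause set).
#' @param hierarchy A [va_hierarchy].
#' @export
resolve_multicause <- function(causes, hierarchy = default_hierarchy()) {
  stopifnot(length(causes) >= 1L)
  idx <- hierarchy_tier_index(hierarchy)
  bad <- setdiff(causes, names(idx))
  if (length(bad) > 0) {
    stop("cause(s) not present in the hierarchy: ", paste(bad, collapse = ", "))
  }
  tiers <- idx[causes]
  top <- causes[tiers == min(tiers)]
  combine_cause_set(top)
}

#' Weighted share of hierarchy-insensitive deaths
#'
#' A death is insensitive to the choice of hierarchy when its multi-cause
#' set has at most one member: either exactly one definition fires or none
#' does (the unspecified residual).  Those deaths keep the same cause under
#' any tier ordering.
#'
#' @param records A harmonized [va_records] data.frame.
#' @param defs A [va_definition_set].
#' @return Weighted proportion in `[0, 1]`.
#' @export
fraction_hierarchy_insensitive <- function(records, defs = default_definitions()) {
  F <- fired_matrix(records, defs)
  insensitive <- rowSums(F) <= 1L
  sum(records$weight[insensitive]) / sum(records$weight)
}
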