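#' Case definitions
#'
#' A case definition ties a cause to a boolean symptom rule plus an age
#' gate.  `age_group` restricts the definition to neonates (0-27 days),
#' postneonates (28-1825 days) or both; an optional `age_window_days`
#' narrows the gate further (inclusive day bounds) and must lie inside the
#' age group's range.
#'
#' @param cause A cause category name (see [va_causes()]).
#' @param age_group `"neonate"`, `"postneonate"` or `"both"`.
#' @param rule A [va_sym()]-style rule object.
#' @param age_window_days Optional `c(min, max)` in days, inclusive.
#' @return A `va_definition` object.
#' @export
va_definition <- function(cause, age_group, rule, age_window_days = NULL) {
  stopifnot(cause %in% VA_ALL_CAUSES, inherits(rule, "va_rule"))
  stopifnot(age_group %in% c("neonate", "postneonate", "both"))
  grp_range <- switch(age_group,
                      neonate = c(0L, 27L),
                      postneonate = c(28L, 1825L),
                      both = c(0L, 1825L))
  if (!is.null(age_window_days)) {
    age_window_days <- as.integer(age_window_days)
    stopifnot(length(age_window_days) == 2L,
              age_window_days[1] <= age_window_days[2])
    if (age_window_days[1] < grp_range[1] || age_window_days[2] > grp_range[2]) {
      stop("age_window_days [", age_window_days[1], ", ", age_window_days[2],
           "] lies outside the ", age_group, " range [", grp_range[1], ", ",
           grp_range[2], "]")
    }
  }
  structure(list(cause = cause, age_group = age_group,
                 age_window_days = age_window_days, rule = rule),
            class = "va_definition")
}

#' @export
print.va_definition <- function(x, ...) {
  win <- if (is.null(x$age_window_days)) "" else
    paste0(", days [", x$age_window_days[1], ", ", x$age_window_days[2], "]")
  cat("<va_definition> ", x$cause, " (", x$age_group, win, "): ",
      deparse_rule(x$rule), "\n", sep = "")
  invisible(x)
}

# inclusive day window implied by the definition's age gate
definition_window <- function(defn) {
  grp <- switch(defn$age_group,
                neonate = c(0L, 27L),
                postneonate = c(28L, 1825L),
                both = c(0L, 1825L))
  if (is.null(defn$age_window_days)) grp else defn$age_window_days
}

#' Evaluate a case definition
#'
#' A definition fires for a record iff the record's age at death lies in
#' the definition's age gate *and* the boolean rule is satisfied.  Missing
#' symptom answers are treated as "no": a rule needs positive evidence.
#'
#' `evaluate_definition()` is the vectorized workhorse (one logical per
#' record); `evaluate()` is the single-record convenience.
#'
#' @param defn A [va_definition].
#' @param records A [va_records] data.frame.
#' @param record A single-row [va_records] data.frame.
#' @return Logical vector (`evaluate_definition`) or scalar (`evaluate`).
#' @export
evaluate_definition <- function(defn, records) {
  stopifnot(inherits(defn, "va_definition"))
  win <- definition_window(defn)
  in_age <- records$age_days >= win[1] & records$age_days <= win[2]
  fired <- eval_rule(defn$rule, symptom_matrix(records))
  in_age & fired
}

#' @rdname evaluate_definition
#' @export
evaluate <- function(defn, record) {
  stopifnot(nrow(record) == 1L)
  as.logical(evaluate_definition(defn, record))
}

#' Neonatal tetanus case definition
#'
#' A death at 4-14 completed days of life, with convulsions, where the baby
#' either cried normally after birth but stopped crying in the final
#' illness, or suckled normally after birth but stopped suckling, or both.
#' This is the definition shared by the first two survey waves; the later
#' wave's refinement (requiring the stopping to begin at least one day
#' before the final illness) is available via
#' `default_definitions(tetanus_2004 = TRUE)` but is off by default so the
#' same rule can be applied to every wave.
#'
#' @param record A single-row [va_records] data.frame (or several rows, in
#'   which case one logical per row is returned).
#' @return Logical.
#' @export
is_neonatal_tetanus <- function(record) {
  age_ok <- record$age_days >= 4L & record$age_days <= 14L
  yes <- function(code) {
    if (!code %in% names(record)) return(rep(FALSE, nrow(record)))
    record[[code]] == "yes"
  }
  cry <- yes("cried_normally_after_birth") & yes("stopped_crying")
  suck <- yes("suckled_normally_after_birth") & yes("stopped_suckling")
  age_ok & yes("convulsions") & (cry | suck)
}

#' Count serious-infection signs
#'
#' Counts how many of the five all-wave serious-infection signs (stopped
#' suckling, difficult breathing, chest indrawing, convulsions, fever) a
#' record reports as "yes".  The other-possible-serious-infection
#' definition fires at two or more.
#'
#' @param records A [va_records] data.frame.
#' @param codebook The codebook; defaults to the records' attribute.
#' @return Integer vector, one count per record.
#' @export
count_serious_infection_signs <- function(records,
                                          codebook = va_record_codebook(records)) {
  codes <- serious_infection_codes(codebook)
  present <- intersect(codes, names(records))
  if (length(present) == 0) return(rep(0L, nrow(records)))
  counts <- Reduce(`+`, lapply(present, function(cl)
    as.integer(records[[cl]] == "yes")))
  as.integer(counts)
}

#' Definition sets
#'
#' A definition set bundles one case definition per assignable cause and
#' age-group variant, under a version label.  [default_definitions()]
#' ships the standardized set: age-specific variants exist for pneumonia,
#' diarrhea, possible pneumonia and possible diarrhea; the residual
#' `unspecified` needs no definition.
#'
#' @param definitions List of [va_definition] objects.
#' @param version Version label string.
#' @return A `va_definition_set`.
#' @export
va_definition_set <- function(definitions, version = "custom") {
  stopifnot(is.list(definitions),
            all(vapply(definitions, inherits, TRUE, "va_definition")))
  ids <- vapply(definitions, function(d) paste(d$cause, d$age_group, sep = ":"), "")
  if (anyDuplicated(ids)) {
    stop("duplicate definition for: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  names(definitions) <- ids
  structure(list(version = version, definitions = definitions),
            class = "va_definition_set")
}

#' @export
print.va_definition_set <- function(x, ...) {
  cat("<va_definition_set> '", x$version, "', ", length(x$definitions),
      " definitions for ", length(definition_causes(x)), " causes\n", sep = "")
  invisible(x)
}

definition_causes <- function(defs) {
  unique(vapply(defs$definitions, function(d) d$cause, ""))
}

definitions_for_cause <- function(defs, cause) {
  Filter(function(d) d$cause == cause, defs$definitions)
}

#' Standardized default case definitions
#'
#' The shipped rules implement the standardized under-5 algorithm on the
#' all-wave symptom set.  The neonatal-tetanus rule and the two-or-more
#' serious-infection-sign rule follow the published standardized algorithm;
#' the remaining rules are editable defaults drawn from common VA practice
#' (e.g. measles as a generalized rash of three or more days with fever at
#' 120+ days of age; birth asphyxia as no cry or no breath at birth with
#' death in the first week) and are *not* claimed to reproduce any
#' particular study's exact wording.  Override any of them by editing a
#' definitions YAML file (see [write_definitions()]).
#'
#' @param tetanus_2004 If `TRUE`, use the later-wave tetanus refinement that
#'   additionally requires the stopping of crying/suckling to have begun at
#'   least one day before the final illness.  Default `FALSE` (the all-wave
#'   comparable rule).
#' @return A [va_definition_set].
#' @export
#' @examples
#' defs <- default_definitions()
#' names(defs$definitions)
default_definitions <- function(tetanus_2004 = FALSE) {
  si5 <- c("stopped_suckling", "difficult_breathing", "chest_indrawing",
           "convulsions", "fever")
  tetanus_core <- va_all(
    va_sym("convulsions"),
    va_any(va_all(va_sym("cried_normally_after_birth"), va_sym("stopped_crying")),
           va_all(va_sym("suckled_normally_after_birth"), va_sym("stopped_suckling")))
  )
  tetanus_rule <- if (tetanus_2004) {
    va_all(tetanus_core, va_sym("signs_preceded_final_illness"))
  } else tetanus_core

  defs <- list(
    va_definition("neonatal_tetanus", "neonate", tetanus_rule,
                  age_window_days = c(4L, 14L)),
    va_definition("injury", "both", va_sym("injury_accident")),
    va_definition("measles", "postneonate",
                  va_all(va_sym("rash_3plus_days"), va_sym("fever")),
                  age_window_days = c(120L, 1825L)),
    # pneumonia/ARI: age-specific variants
    va_definition("pneumonia", "neonate",
                  va_all(va_sym("difficult_breathing"), va_sym("chest_indrawing"))),
    va_definition("pneumonia", "postneonate",
                  va_all(va_sym("cough"),
                         va_any(va_sym("chest_indrawing"), va_sym("difficult_breathing")))),
    # diarrhea: same rule in both age groups but kept as variants so either
    # can be tightened independently
    va_definition("diarrhea", "neonate",
                  va_all(va_sym("loose_stools"), va_sym("very_frequent_stools"))),
    va_definition("diarrhea", "postneonate",
                  va_all(va_sym("loose_stools"), va_sym("very_frequent_stools"))),
    va_definition("congenital_abnormality", "neonate",
                  va_sym("malformation_present")),
    va_definition("birth_asphyxia_birth_injury", "neonate",
                  va_any(va_sym("did_not_cry_at_birth"),
                         va_sym("did_not_breathe_at_birth")),
                  age_window_days = c(0L, 6L)),
    # "possible" variants: compatible but less specific symptom patterns
    va_definition("possible_pneumonia", "neonate",
                  va_all(va_sym("difficult_breathing"), va_sym("fever"))),
    va_definition("possible_pneumonia", "postneonate",
                  va_all(va_sym("cough"), va_sym("fever"))),
    va_definition("possible_diarrhea", "neonate",
                  va_all(va_sym("loose_stools"), va_sym("fever"))),
    va_definition("possible_diarrhea", "postneonate",
                  va_all(va_sym("loose_stools"), va_sym("fever"))),
    va_definition("prematurity_lbw", "neonate",
                  va_any(va_sym("born_early"), va_sym("very_small_at_birth"))),
    va_definition("other_possible_serious_infection", "both",
                  va_at_least(2L, si5)),
    va_definition("malnutrition", "postneonate",
                  va_any(va_sym("visible_wasting"), va_sym("swollen_feet_hands")))
  )
  va_definition_set(defs, version = if (tetanus_2004)
    "standardized-1-tetanus2004" else "standardized-1")
}

#' Read or write a definition-set config file
#'
#' Definition sets are stored as YAML: a `version` string and a
#' `definitions` list whose entries carry `cause`, `age_group`, optional
#' `age_window_days` and a `rule` tree written with `all` / `any` / `not` /
#' `at_least` operators and symptom codes as leaves.
#'
#' @param path Path to a YAML file.
#' @param defs A [va_definition_set].
#' @return `read_definitions()` returns a [va_definition_set];
#'   `write_definitions()` returns `path` invisibly.
#' @export
read_definitions <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$definitions)) {
    stop("definition file has no 'definitions' entry: ", path)
  }
  defs <- lapply(doc$definitions, function(d) {
    win <- if (!is.null(d$age_window_days)) as.integer(unlist(d$age_window_days))
    va_definition(d$cause, d$age_group, rule_from_yaml(d$rule),
                  age_window_days = win)
  })
  va_definition_set(defs, version = doc$version %||% "unversioned")
}

#' @rdname read_definitions
#' @export
write_definitions <- function(defs, path) {
  stopifnot(inherits(defs, "va_definition_set"))
  doc <- list(
    version = defs$version,
    definitions = lapply(unname(defs$definitions), function(d) {
      out <- list(cause = d$cause, age_group = d$age_group)
      if (!is.null(d$age_window_days)) {
        out$age_window_days <- as.list(as.integer(d$age_window_days))
      }
      out$rule <- rule_to_yaml(d$rule)
      out
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
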