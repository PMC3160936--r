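#' Symptom codebook
#'
#' A codebook describes every symptom/sign indicator a VA record may carry:
#' a short machine code, a human label, the age group the question applies
#' to, the survey waves in which the question was asked, and whether the
#' sign counts toward the serious-infection sign tally.
#'
#' Five serious-infection signs must be available in every wave (stopped
#' suckling, difficult breathing, chest indrawing, convulsions, fever);
#' later waves may add further signs, but only the all-wave five survive
#' harmonization and only they feed [count_serious_infection_signs()].
#'
#' @param entries A data.frame with columns `code`, `label`, `age_group`
#'   (one of `"neonate"`, `"postneonate"`, `"both"`), `waves` (list column
#'   of character vectors), `serious_infection_sign` (logical).
#' @return An object of class `va_codebook` (a validated data.frame).
#' @seealso [default_codebook()], [read_codebook()], [write_codebook()]
#' @export
va_codebook <- function(entries) {
  stopifnot(is.data.frame(entries))
  needed <- c("code", "label", "age_group", "waves", "serious_infection_sign")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols) > 0) {
    stop("codebook is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  entries$code <- as.character(entries$code)
  if (anyDuplicated(entries$code)) {
    stop("codebook codes must be unique; duplicated: ",
         paste(unique(entries$code[duplicated(entries$code)]), collapse = ", "))
  }
  if (!all(entries$age_group %in% c("neonate", "postneonate", "both"))) {
    stop("codebook age_group must be one of neonate/postneonate/both")
  }
  if (!is.list(entries$waves)) entries$waves <- as.list(entries$waves)
  entries$serious_infection_sign <- as.logical(entries$serious_infection_sign)

  all_waves <- sort(unique(unlist(entries$waves)))
  in_all <- vapply(entries$waves, function(w) all(all_waves %in% w), logical(1))
  n_si_common <- sum(entries$serious_infection_sign & in_all)
  if (n_si_common != 5L) {
    stop("codebook must flag exactly 5 serious-infection signs available in ",
         "all waves; found ", n_si_common)
  }
  class(entries) <- c("va_codebook", "data.frame")
  entries
}

#' @export
print.va_codebook <- function(x, ...) {
  cat("<va_codebook> ", nrow(x), " symptom codes, waves: ",
      paste(codebook_waves(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

codebook_waves <- function(codebook) sort(unique(unlist(codebook$waves)))

# codes available in every wave of `waves` (default: all codebook waves)
codebook_common_codes <- function(codebook, waves = codebook_waves(codebook)) {
  keep <- vapply(codebook$waves, function(w) all(waves %in% w), logical(1))
  codebook$code[keep]
}

# the serious-infection signs common to all waves (exactly 5 by construction)
serious_infection_codes <- function(codebook) {
  in_all <- vapply(codebook$waves,
                   function(w) all(codebook_waves(codebook) %in% w), logical(1))
  codebook$code[codebook$serious_infection_sign & in_all]
}

#' Default symptom codebook
#'
#' Ships the symptom set used by the standardized under-5 VA algorithm for
#' the three Bangladesh DHS VA waves (1993-1994, 1996-1997, 2004).  The
#' all-wave core carries the five serious-infection signs plus the
#' indicators the shipped case definitions reference; a handful of signs
#' asked only in 2004 (e.g. stiff neck, rapid breathing) are included so
#' multi-wave harmonization has something to drop.
#'
#' @param waves Character vector of wave labels the codebook should cover.
#' @return A [va_codebook] object.
#' @export
#' @examples
#' cb <- default_codebook()
#' nrow(cb)
default_codebook <- function(waves = c("1993-1994", "1996-1997", "2004")) {
  row <- function(code, label, age_group, wv, si) {
    data.frame(code = code, label = label, age_group = age_group,
               waves = I(list(wv)), serious_infection_sign = si,
               stringsAsFactors = FALSE)
  }
  w_all <- waves
  w_2004 <- intersect("2004", waves)
  if (length(w_2004) == 0) w_2004 <- waves[length(waves)]
  entries <- rbind(
    # five serious-infection signs collected in every wave
    row("stopped_suckling", "Stopped suckling during the final illness", "both", w_all, TRUE),
    row("difficult_breathing", "Difficult breathing", "both", w_all, TRUE),
    row("chest_indrawing", "Lower chest indrawing", "both", w_all, TRUE),
    row("convulsions", "Convulsions or spasms", "both", w_all, TRUE),
    row("fever", "Fever during the final illness", "both", w_all, TRUE),
    # neonatal-tetanus items (asked in every wave)
    row("cried_normally_after_birth", "Cried normally after birth", "neonate", w_all, FALSE),
    row("stopped_crying", "Stopped crying during the final illness", "neonate", w_all, FALSE),
    row("suckled_normally_after_birth", "Suckled normally after birth", "neonate", w_all, FALSE),
    # respiratory / gastrointestinal indicators
    row("cough", "Cough during the final illness", "both", w_all, FALSE),
    row("loose_stools", "Loose or liquid stools", "both", w_all, FALSE),
    row("very_frequent_stools", "Six or more loose stools per day", "both", w_all, FALSE),
    # measles
    row("rash_3plus_days", "Generalized rash lasting three days or more", "postneonate", w_all, FALSE),
    # injury
    row("injury_accident", "Death followed an injury, accident or drowning", "both", w_all, FALSE),
    # perinatal indicators
    row("malformation_present", "Visible congenital malformation", "neonate", w_all, FALSE),
    row("did_not_cry_at_birth", "Did not cry at birth", "neonate", w_all, FALSE),
    row("did_not_breathe_at_birth", "Did not breathe at birth", "neonate", w_all, FALSE),
    row("born_early", "Born more than one month early", "neonate", w_all, FALSE),
    row("very_small_at_birth", "Very small at birth", "neonate", w_all, FALSE),
    # malnutrition
    row("visible_wasting", "Visible severe wasting (thin limbs)", "postneonate", w_all, FALSE),
    row("swollen_feet_hands", "Swelling of feet and hands", "postneonate", w_all, FALSE),
    # signs collected only in the last wave
    row("stiff_neck", "Stiff neck", "both", w_2004, FALSE),
    row("rapid_breathing", "Rapid breathing", "both", w_2004, FALSE),
    row("lethargic", "Lethargic or unconscious", "both", w_2004, FALSE),
    row("bulging_fontanel", "Bulging fontanel", "neonate", w_2004, FALSE),
    row("umbilical_redness", "Redness or drainage from the cord stump", "neonate", w_2004, FALSE),
    row("vomits_everything", "Vomited everything", "both", w_2004, FALSE),
    # 2004 refinement item for the tetanus definition
    row("signs_preceded_final_illness", "Stopping of crying/suckling began at least one day before the final illness", "neonate", w_2004, FALSE)
  )
  va_codebook(entries)
}

#' Read or write a codebook config file
#'
#' Codebooks are stored as human-editable YAML: a top-level `symptoms` list
#' whose entries carry `code`, `label`, `age_group`, `waves` and
#' `serious_infection_sign`.
#'
#' @param path Path to a YAML file.
#' @param codebook A [va_codebook] object.
#' @return `read_codebook()` returns a [va_codebook]; `write_codebook()`
#'   returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$symptoms)) stop("codebook file has no 'symptoms' entry: ", path)
  entries <- do.call(rbind, lapply(doc$symptoms, function(e) {
    data.frame(code = e$code, label = e$label, age_group = e$age_group,
               waves = I(list(as.character(unlist(e$waves)))),
               serious_infection_sign = isTRUE(e$serious_infection_sign),
               stringsAsFactors = FALSE)
  }))
  va_codebook(entries)
}

#' @rdname read_codebook
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "va_codebook"))
  doc <- list(symptoms = lapply(seq_len(nrow(codebook)), function(i) {
    list(code = codebook$code[i], label = codebook$label[i],
         age_group = codebook$age_group[i],
         waves = as.list(codebook$waves[[i]]),
         serious_infection_sign = codebook$serious_infection_sign[i])
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}
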