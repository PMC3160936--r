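#' Cause-of-death categories
#'
#' The package distinguishes *final* reporting causes from *intermediate*
#' categories that only exist between assignment and redistribution.
#' Intermediate categories arise when several diagnoses fire together:
#' measles together with ARI or diarrhea, comorbid ARI and diarrhea, and
#' comorbid possible ARI and possible diarrhea.  [finalize_causes()] converts
#' every intermediate category into final causes; intermediate categories
#' never appear in a final cause-fraction table.
#'
#' @return `va_causes()` returns a list with components `final`,
#'   `intermediate` and `all` (character vectors of category names).
#' @export
#' @examples
#' va_causes()$final
va_causes <- function() {
  list(final = VA_FINAL_CAUSES, intermediate = VA_INTERMEDIATE_CAUSES,
       all = VA_ALL_CAUSES)
}

VA_FINAL_CAUSES <- c(
  "pneumonia",
  "diarrhea",
  "measles",
  "injury",
  "neonatal_tetanus",
  "congenital_abnormality",
  "birth_asphyxia_birth_injury",
  "prematurity_lbw",
  "other_possible_serious_infection",
  "malnutrition",
  "unspecified"
)

VA_INTERMEDIATE_CAUSES <- c(
  "possible_pneumonia",
  "possible_diarrhea",
  "ari_and_diarrhea",
  "possible_ari_and_diarrhea",
  "measles_with_ari_or_diarrhea"
)

VA_ALL_CAUSES <- c(VA_FINAL_CAUSES, VA_INTERMEDIATE_CAUSES)

# causes that carry their own case definition (everything assignable except
# the residual and the combination categories)
VA_DEFINED_CAUSES <- c(
  "neonatal_tetanus", "injury", "measles", "pneumonia", "diarrhea",
  "congenital_abnormality", "birth_asphyxia_birth_injury",
  "possible_pneumonia", "possible_diarrhea", "prematurity_lbw",
  "other_possible_serious_infection", "malnutrition"
)

# canonical order used to break ties deterministically when several causes
# fire in one exclusive tier and no combination category applies
va_canonical_order <- function(causes) {
  causes[order(match(causes, VA_ALL_CAUSES))]
}

is_final_cause <- function(x) x %in% VA_FINAL_CAUSES
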