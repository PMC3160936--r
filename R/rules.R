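#' Boolean symptom rules
#'
#' Case definitions are boolean expression trees over symptom codes.  Leaves
#' test whether a symptom was reported `"yes"`; internal nodes combine
#' sub-rules with AND/OR/NOT, plus an at-least-k-of-a-set node used, e.g.,
#' for "two or more signs of serious infection".  Missing answers never
#' satisfy a leaf: a rule can only fire on positive evidence, so
#' `va_not(va_sym("x"))` is true when x is "no" *or* missing.
#'
#' @param code A symptom code (string).
#' @param ... Sub-rules (or, for `va_at_least`, nothing).
#' @param k Minimum number of codes that must be "yes".
#' @param codes Character vector of symptom codes the at-least node counts.
#' @param rule A rule to negate.
#' @return A rule object (class `va_rule`).
#' @export
#' @examples
#' r <- va_all(va_sym("cough"), va_any(va_sym("chest_indrawing"),
#'                                     va_sym("difficult_breathing")))
va_sym <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  structure(list(op = "sym", code = code), class = "va_rule")
}

#' @rdname va_sym
#' @export
va_all <- function(...) structure(list(op = "all", args = list(...)), class = "va_rule")

#' @rdname va_sym
#' @export
va_any <- function(...) structure(list(op = "any", args = list(...)), class = "va_rule")

#' @rdname va_sym
#' @export
va_not <- function(rule) structure(list(op = "not", args = list(rule)), class = "va_rule")

#' @rdname va_sym
#' @export
va_at_least <- function(k, codes) {
  stopifnot(is.numeric(k), length(codes) >= 1L)
  k <- as.integer(k)
  if (k < 1L || k > length(codes)) {
    stop("at-least-k node needs 1 <= k <= number of codes (k = ", k,
         ", set size ", length(codes), ")")
  }
  structure(list(op = "at_least", k = k, codes = as.character(codes)),
            class = "va_rule")
}

# all symptom codes a rule references
rule_codes <- function(rule) {
  switch(rule$op,
    sym = rule$code,
    at_least = rule$codes,
    unique(unlist(lapply(rule$args, rule_codes)))
  )
}

# evaluate a rule against a logical matrix Y (records x codes, TRUE = "yes");
# returns one logical per record
eval_rule <- function(rule, Y) {
  switch(rule$op,
    sym = {
      if (!(rule$code %in% colnames(Y))) {
        stop("rule references symptom code absent from the records: ",
             rule$code)
      }
      Y[, rule$code]
    },
    all = Reduce(`&`, lapply(rule$args, eval_rule, Y = Y)),
    any = Reduce(`|`, lapply(rule$args, eval_rule, Y = Y)),
    not = !eval_rule(rule$args[[1L]], Y),
    at_least = {
      miss <- setdiff(rule$codes, colnames(Y))
      if (length(miss) > 0) {
        stop("rule references symptom code absent from the records: ",
             paste(miss, collapse = ", "))
      }
      rowSums(Y[, rule$codes, drop = FALSE]) >= rule$k
    },
    stop("unknown rule operator: ", rule$op)
  )
}

#' @export
print.va_rule <- function(x, ...) {
  cat(deparse_rule(x), "\n")
  invisible(x)
}

deparse_rule <- function(rule) {
  switch(rule$op,
    sym = rule$code,
    all = paste0("(", paste(vapply(rule$args, deparse_rule, ""), collapse = " & "), ")"),
    any = paste0("(", paste(vapply(rule$args, deparse_rule, ""), collapse = " | "), ")"),
    not = paste0("!", deparse_rule(rule$args[[1L]])),
    at_least = paste0("at_least(", rule$k, "; ", paste(rule$codes, collapse = ", "), ")")
  )
}

# -- YAML (de)serialization ---------------------------------------------------
# a rule is written as: a bare string (leaf), {all: [...]}, {any: [...]},
# {not: rule}, or {at_least: {k: n, of: [codes]}}

rule_to_yaml <- function(rule) {
  switch(rule$op,
    sym = rule$code,
    all = list(all = lapply(rule$args, rule_to_yaml)),
    any = list(any = lapply(rule$args, rule_to_yaml)),
    not = list(not = rule_to_yaml(rule$args[[1L]])),
    at_least = list(at_least = list(k = rule$k, of = as.list(rule$codes)))
  )
}

rule_from_yaml <- function(x) {
  if (is.character(x) && length(x) == 1L) return(va_sym(x))
  if (!is.list(x) || length(x) != 1L) {
    stop("malformed rule node in definition file")
  }
  op <- names(x)
  body <- x[[1L]]
  switch(op,
    all = do.call(va_all, lapply(body, rule_from_yaml)),
    any = do.call(va_any, lapply(body, rule_from_yaml)),
    not = va_not(rule_from_yaml(body)),
    at_least = va_at_least(body$k, as.character(unlist(body$of))),
    stop("unknown rule operator in definition file: ", op)
  )
}
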