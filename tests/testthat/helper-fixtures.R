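# Shared fixtures: hand-built records, random records/rules, and an
# independent rule-evaluation oracle based on R's own expression evaluator.

# a blank record table with all default-codebook symptoms set to "no"
blank_records <- function(n, wave = "2004", age_days = 100L, weight = 1,
                          stratum_id = "S01", psu_id = "S01_P01",
                          codebook = default_codebook()) {
  df <- data.frame(record_id = sprintf("T%03d", seq_len(n)), wave = wave,
                   age_days = age_days, sex = "female", weight = weight,
                   stratum_id = stratum_id, psu_id = psu_id,
                   stringsAsFactors = FALSE)
  for (code in codebook$code) df[[code]] <- "no"
  va_records(df, codebook)
}

# set symptoms to "yes" on selected rows
set_yes <- function(records, codes, rows = seq_len(nrow(records))) {
  for (code in codes) records[[code]][rows] <- "yes"
  records
}

# random records: every symptom independently yes/no/missing
random_records <- function(n, seed, p_yes = 0.3, p_missing = 0.1,
                           codebook = default_codebook()) {
  set.seed(seed)
  rec <- blank_records(n, age_days = sample(0:1825, n, replace = TRUE),
                       codebook = codebook)
  for (code in codebook$code) {
    rec[[code]] <- sample(c("yes", "no", "missing"), n, replace = TRUE,
                          prob = c(p_yes, 1 - p_yes - p_missing, p_missing))
  }
  rec
}

# random boolean rule over the given codes (depth-limited expression tree)
random_rule <- function(codes, depth = 3L) {
  if (depth == 0L || stats::runif(1) < 0.35) return(va_sym(sample(codes, 1L)))
  op <- sample(c("all", "any", "not", "at_least"), 1L)
  if (op == "not") return(va_not(random_rule(codes, depth - 1L)))
  if (op == "at_least") {
    set <- sample(codes, sample(2:min(4, length(codes)), 1L))
    return(va_at_least(sample(seq_along(set), 1L), set))
  }
  n_args <- sample(2:3, 1L)
  args <- lapply(seq_len(n_args), function(i) random_rule(codes, depth - 1L))
  do.call(if (op == "all") va_all else va_any, args)
}

# independent oracle: translate the rule tree to an R logical expression and
# let R's evaluator compute it against one record's yes-indicators
rule_to_r_expression <- function(rule) {
  switch(rule$op,
    sym = paste0("`", rule$code, "`"),
    all = paste0("(", paste(vapply(rule$args, rule_to_r_expression, ""),
                            collapse = " & "), ")"),
    any = paste0("(", paste(vapply(rule$args, rule_to_r_expression, ""),
                            collapse = " | "), ")"),
    not = paste0("(!", rule_to_r_expression(rule$args[[1]]), ")"),
    at_least = paste0("(sum(", paste0("`", rule$codes, "`", collapse = ", "),
                      ") >= ", rule$k, ")")
  )
}

DESIGN_COLS <- c("record_id", "wave", "age_days", "sex", "weight",
                 "stratum_id", "psu_id")

oracle_eval_rule <- function(rule, record) {
  env <- new.env()
  for (code in setdiff(names(record), DESIGN_COLS)) {
    assign(code, record[[code]] == "yes", envir = env)
  }
  expr <- parse(text = rule_to_r_expression(rule))[[1]]
  isTRUE(eval(expr, envir = env))
}

# hierarchy with two tiers swapped (by cause name)
swap_hierarchy_tiers <- function(hierarchy, cause_a, cause_b) {
  tiers <- hierarchy$tiers
  ia <- which(vapply(tiers, function(t) cause_a %in% t$causes, TRUE))
  ib <- which(vapply(tiers, function(t) cause_b %in% t$causes, TRUE))
  tmp <- tiers[[ia]]; tiers[[ia]] <- tiers[[ib]]; tiers[[ib]] <- tmp
  va_hierarchy(tiers, version = paste0(hierarchy$version, "-swapped"))
}

# subset a va_records object preserving attributes
records_subset <- function(records, i) {
  out <- records[i, ]
  attr(out, "codebook") <- attr(records, "codebook")
  class(out) <- class(records)
  out
}
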