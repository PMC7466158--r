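# Shared fixtures and independent oracles.
#
# Oracles here are deliberately written from scratch (per-case loops,
# direct arithmetic) and never call package internals, so they stay
# independent of the code paths they check.

# stable id for triple set comparisons
tid <- function(df) {
  swap <- df$drug1 > df$drug2
  lo <- ifelse(swap, df$drug2, df$drug1)
  hi <- ifelse(swap, df$drug1, df$drug2)
  sort(paste(lo, hi, df$event, sep = "|"))
}

# hand-built 12-case fixture with a known 4x2 tally for (d1, d2, sjs):
#   n111 2, n110 1, n101 1, n100 2, n011 1, n010 1, n001 2, n000 2
fixture_cases <- function() {
  ddi_cases(
    case_id = as.character(1:12),
    suspect_drugs = list(
      c("d1", "d2"), c("d1", "d2"), c("d1", "d2"),     # both
      "d1", "d1", "d1",                                # only d1
      "d2", "d2",                                      # only d2
      "other", character(0), "other", character(0)),   # neither
    events = list(
      "sjs", "sjs", "rash",
      "sjs", "rash", "rash",
      "sjs", "rash",
      "sjs", "sjs", "rash", character(0)))
}

# random case population over a small drug/event vocabulary
random_cases <- function(n, n_drugs = 5, p_drug = 0.3, p_event = 0.3,
                         events = c("ev", "other")) {
  drugs <- paste0("g", seq_len(n_drugs))
  ddi_cases(
    case_id = sprintf("r%04d", seq_len(n)),
    suspect_drugs = replicate(n, drugs[runif(n_drugs) < p_drug],
                              simplify = FALSE),
    events = replicate(n, events[runif(length(events)) < p_event],
                       simplify = FALSE))
}

# ORACLE: classify each case one at a time against a triple
oracle_tabulate <- function(cases, d1, d2, ev) {
  cells <- c(n111 = 0, n110 = 0, n101 = 0, n100 = 0,
             n011 = 0, n010 = 0, n001 = 0, n000 = 0)
  for (i in seq_along(cases$case_id)) {
    a <- d1 %in% cases$suspect_drugs[[i]]
    b <- d2 %in% cases$suspect_drugs[[i]]
    e <- ev %in% cases$events[[i]]
    nm <- paste0("n", as.integer(a), as.integer(b), as.integer(e))
    cells[nm] <- cells[nm] + 1
  }
  cells
}

# ORACLE: brute-force nested-loop enumeration of pairs co-reported with ev
oracle_enumerate <- function(cases, ev) {
  found <- character(0)
  for (i in seq_along(cases$case_id)) {
    if (!(ev %in% cases$events[[i]])) next
    ds <- cases$suspect_drugs[[i]]
    if (length(ds) < 2) next
    for (a in ds) for (b in ds) {
      if (a < b) found <- c(found, paste(a, b, ev, sep = "|"))
    }
  }
  sort(unique(found))
}

# ORACLE: direct evaluation of the ROR point estimate and 95% CI
oracle_ror <- function(n11, n10, n01, n00) {
  est <- (n11 / n10) / (n01 / n00)
  se <- sqrt(1 / n11 + 1 / n10 + 1 / n01 + 1 / n00)
  c(ror = est,
    lo = exp(log(est) - 1.959964 * se),
    hi = exp(log(est) + 1.959964 * se))
}

# random contingency table as a counts row; zeros allowed
random_counts_row <- function(i, lambda = 8) {
  cells <- rpois(8, lambda)
  data.frame(drug1 = "a", drug2 = "b", event = paste0("e", i),
             n111 = cells[1], n110 = cells[2], n101 = cells[3],
             n100 = cells[4], n011 = cells[5], n010 = cells[6],
             n001 = cells[7], n000 = cells[8])
}
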