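# Signal statistics and detection verdicts.
#
# All detectors consume one 4x2 contingency table (class ddi_ct) and are
# pure functions: no options are read from global state, and ties at a
# threshold (ci lower bound = 1, Omega025 = 0, chi-square = critical
# value) are NOT signals (strict inequalities throughout).

# ---------------------------------------------------------------------------
# Subset reporting odds ratio

#' Reporting odds ratio with 95% confidence interval
#'
#' The sample odds ratio of the target event between exposed and
#' unexposed reports of a 2x2 subset table,
#' \deqn{ROR = \frac{N_{11}/N_{10}}{N_{01}/N_{00}},}
#' with the usual log-normal interval
#' \deqn{\exp\{\ln ROR \pm 1.959964\sqrt{1/N_{11}+1/N_{10}+1/N_{01}+1/N_{00}}\}.}
#' If any cell is zero the estimate is marked not computable; no
#' continuity correction is applied unless `haldane = TRUE`, which adds
#' 0.5 to all four cells (exploratory use only).
#'
#' @param view A `ddi_subset` from [subset_view()], or the `N11` count
#'   when the four counts are given directly.
#' @param n10,n01,n00 Remaining counts when `view` is a number.
#' @param haldane Apply the Haldane-Anscombe 0.5 correction.
#' @return A list of class `ddi_ror`: `ror`, `ci_lower`, `ci_upper`,
#'   `computable`.
#' @export
#' @examples
#' ror(20, 80, 100, 800)   # ROR 2.00, CI (1.17, 3.40)
ror <- function(view, n10 = NULL, n01 = NULL, n00 = NULL,
                haldane = FALSE) {
  if (inherits(view, "ddi_subset")) {
    n11 <- view$N11; n10 <- view$N10; n01 <- view$N01; n00 <- view$N00
  } else {
    n11 <- view
  }
  cells <- c(.assert_count(n11, "N11"), .assert_count(n10, "N10"),
             .assert_count(n01, "N01"), .assert_count(n00, "N00"))
  if (haldane) cells <- cells + 0.5
  if (any(cells == 0)) {
    return(structure(list(ror = NA_real_, ci_lower = NA_real_,
                          ci_upper = NA_real_, computable = FALSE),
                     class = "ddi_ror"))
  }
  est <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  se <- sqrt(sum(1 / cells))
  structure(list(ror = est,
                 ci_lower = exp(log(est) - .z975 * se),
                 ci_upper = exp(log(est) + .z975 * se),
                 computable = TRUE),
            class = "ddi_ror")
}

#' @export
print.ddi_ror <- function(x, ...) {
  if (x$computable) {
    cat(sprintf("ROR %.4f (95%% CI %.4f-%.4f)\n", x$ror, x$ci_lower,
                x$ci_upper))
  } else {
    cat("ROR not computable (zero cell)\n")
  }
  invisible(x)
}

# single-subset rule: signal iff computable and CI lower bound exceeds the
# threshold (default 1) and N11 meets the optional report floor
#' @noRd
.ror_signals <- function(r, threshold, min_n11, n11) {
  isTRUE(r$computable) && r$ci_lower > threshold && n11 >= min_n11
}

#' Subset-analysis interaction signal
#'
#' Computes the subset ROR in both directions -- the event signal for
#' drug2 within reports using drug1, and for drug1 within reports using
#' drug2 -- and combines them under one of two criteria. The
#' `"previous"` (either-subset) criterion calls an interaction signal
#' when either directional subset signals; the `"new"` (both-subsets)
#' criterion requires a signal in both directions, which removes
#' signals driven by a single marginally risky drug. A directional
#' subset signals when its ROR is computable and its 95% CI lower bound
#' exceeds `threshold`.
#'
#' @param table A `ddi_ct` contingency table.
#' @param criterion `"new"` (both subsets) or `"previous"` (either).
#' @param threshold Lower-CI cutoff for a single-subset signal
#'   (default 1, the conventional ROR025 > 1 rule).
#' @param min_n11 Optional minimum co-exposed event count N11 for a
#'   subset to signal (default 0 = no floor).
#' @param haldane Passed to [ror()].
#' @return A list of class `ddi_verdict` with fields `algorithm`,
#'   `signal`, and `detail` (the two `ddi_ror` results `d1`, `d2` and
#'   the per-subset booleans).
#' @export
subset_signal <- function(table, criterion = c("new", "previous"),
                          threshold = 1, min_n11 = 0, haldane = FALSE) {
  stopifnot(inherits(table, "ddi_ct"))
  criterion <- match.arg(criterion)
  r1 <- ror(subset_view(table, "within_d1"), haldane = haldane)
  r2 <- ror(subset_view(table, "within_d2"), haldane = haldane)
  s1 <- .ror_signals(r1, threshold, min_n11, table$n111)
  s2 <- .ror_signals(r2, threshold, min_n11, table$n111)
  structure(list(
    algorithm = if (criterion == "new") "subset-new" else "subset-previous",
    signal = if (criterion == "new") s1 && s2 else s1 || s2,
    detail = list(d1 = r1, d2 = r2, signal_d1 = s1, signal_d2 = s2)),
    class = "ddi_verdict")
}

#' @export
print.ddi_verdict <- function(x, ...) {
  cat(sprintf("<ddi_verdict> %s: %s\n", x$algorithm,
              if (isTRUE(x$signal)) "SIGNAL" else "no signal"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Omega shrinkage measure

# odds transform with clamping: the closed form for g11 is undefined at
# f = 1, so f is capped just below 1 (ordering preserved)
#' @noRd
.odds <- function(f) {
  f <- pmin(f, 1 - 1e-12)
  f / (1 - f)
}

#' @noRd
.fcells <- function(table) {
  list(f11 = table$n111 / table$n11p, f10 = table$n101 / table$n10p,
       f01 = table$n011 / table$n01p, f00 = table$n001 / table$n00p)
}

# expected event proportion under no interaction, on the odds scale:
# odds(g11) = max(o00, o10) + max(o00, o01) - o00. Reduces to
# g11 = max(f00, f01) when f10 < f00, and symmetrically.
#' @noRd
.g11 <- function(f00, f10, f01) {
  o <- .odds(c(f00, f10, f01))
  og11 <- max(o[1], o[2]) + max(o[1], o[3]) - o[1]
  1 - 1 / (og11 + 1)
}

#' Omega shrinkage measure signal
#'
#' The shrinkage-regularised log2 ratio of observed to expected
#' co-reporting used for drug-drug interaction surveillance:
#' \deqn{\Omega = \log_2 \frac{n_{111} + 0.5}{E_{111} + 0.5}, \qquad
#'       \Omega_{025} = \Omega - \frac{1.959964}{\ln(2)\sqrt{n_{111}}},}
#' with a signal declared when \eqn{\Omega_{025} > 0}. The expected
#' count is \eqn{E_{111} = g_{11} n_{11+}} where \eqn{g_{11}} combines
#' the background and single-drug event proportions
#' \eqn{f_{ij} = n_{ij1}/n_{ij+}} on the odds scale (highest-risk-drug
#' model); when one drug carries no excess risk this reduces to
#' \eqn{g_{11} = \max(f_{00}, f_{01})} (or \eqn{\max(f_{00}, f_{10})}).
#'
#' Requires all four row marginals positive; otherwise the result is
#' flagged not computable. With \eqn{n_{111} = 0} the lower bound is
#' \eqn{-\infty}, hence never a signal. An event proportion of 1 is
#' clamped to \eqn{1 - 10^{-12}} before the odds transform (flagged in
#' the detail).
#'
#' @param table A `ddi_ct` contingency table.
#' @return A `ddi_verdict` whose `detail` holds `f00`, `f10`, `f01`,
#'   `f11`, `g11`, `e111`, `omega`, `omega025`, `computable`, `clamped`.
#' @export
omega_signal <- function(table) {
  stopifnot(inherits(table, "ddi_ct"))
  if (min(table$n11p, table$n10p, table$n01p, table$n00p) == 0) {
    detail <- list(computable = FALSE)
    return(structure(list(algorithm = "omega", signal = FALSE,
                          detail = detail), class = "ddi_verdict"))
  }
  f <- .fcells(table)
  g11 <- .g11(f$f00, f$f10, f$f01)
  e111 <- g11 * table$n11p
  omega <- log2((table$n111 + 0.5) / (e111 + 0.5))
  omega025 <- if (table$n111 > 0) {
    omega - .z975 / (log(2) * sqrt(table$n111))
  } else {
    -Inf
  }
  detail <- c(f, list(
    g11 = g11, e111 = e111, omega = omega, omega025 = omega025,
    computable = TRUE,
    clamped = any(unlist(f[c("f00", "f10", "f01")]) >= 1)))
  structure(list(algorithm = "omega", signal = omega025 > 0,
                 detail = detail), class = "ddi_verdict")
}

# ---------------------------------------------------------------------------
# Component interaction models (surrogate-truth ingredients)

#' Additive interaction model signal
#'
#' Tests for event risk in the co-exposed cell exceeding the additive
#' expectation from the single-drug cells: excess risk
#' \eqn{\Delta = f_{11} - f_{10} - f_{01} + f_{00}} with variance
#' \eqn{\sum_{ij} f_{ij}(1-f_{ij})/n_{ij+}}; a signal is declared when
#' the lower 95% normal bound of \eqn{\Delta} exceeds 0.
#'
#' @param table A `ddi_ct` contingency table (all four row marginals
#'   must be positive, else flagged not computable).
#' @return A `ddi_verdict` with `detail` fields `delta`, `se`,
#'   `lower`, `computable`.
#' @export
additive_signal <- function(table) {
  stopifnot(inherits(table, "ddi_ct"))
  if (min(table$n11p, table$n10p, table$n01p, table$n00p) == 0) {
    return(structure(list(algorithm = "additive", signal = FALSE,
                          detail = list(computable = FALSE)),
                     class = "ddi_verdict"))
  }
  f <- .fcells(table)
  delta <- f$f11 - f$f10 - f$f01 + f$f00
  v <- f$f11 * (1 - f$f11) / table$n11p +
    f$f10 * (1 - f$f10) / table$n10p +
    f$f01 * (1 - f$f01) / table$n01p +
    f$f00 * (1 - f$f00) / table$n00p
  lower <- delta - .z975 * sqrt(v)
  structure(list(algorithm = "additive", signal = lower > 0,
                 detail = c(f, list(delta = delta, se = sqrt(v),
                                    lower = lower, computable = TRUE))),
            class = "ddi_verdict")
}

#' Multiplicative interaction model signal
#'
#' Tests for the risk ratio of ratios
#' \eqn{R = (f_{11} f_{00}) / (f_{10} f_{01})} exceeding 1, with
#' log-scale variance \eqn{\sum_{ij} (1-f_{ij})/(n_{ij+} f_{ij})}; a
#' signal is declared when the lower 95% bound of \eqn{R} exceeds 1.
#' Requires every cell proportion computable and \eqn{f_{10}, f_{01},
#' f_{00} > 0} (and \eqn{f_{11} > 0} for the log transform); otherwise
#' flagged not computable.
#'
#' @param table A `ddi_ct` contingency table.
#' @return A `ddi_verdict` with `detail` fields `ratio`, `se_log`,
#'   `lower`, `computable`.
#' @export
multiplicative_signal <- function(table) {
  stopifnot(inherits(table, "ddi_ct"))
  if (min(table$n11p, table$n10p, table$n01p, table$n00p) == 0) {
    return(structure(list(algorithm = "multiplicative", signal = FALSE,
                          detail = list(computable = FALSE)),
                     class = "ddi_verdict"))
  }
  f <- .fcells(table)
  if (f$f11 == 0 || f$f10 == 0 || f$f01 == 0 || f$f00 == 0) {
    return(structure(list(algorithm = "multiplicative", signal = FALSE,
                          detail = c(f, list(computable = FALSE))),
                     class = "ddi_verdict"))
  }
  ratio <- (f$f11 * f$f00) / (f$f10 * f$f01)
  v <- (1 - f$f11) / (table$n11p * f$f11) +
    (1 - f$f10) / (table$n10p * f$f10) +
    (1 - f$f01) / (table$n01p * f$f01) +
    (1 - f$f00) / (table$n00p * f$f00)
  lower <- exp(log(ratio) - .z975 * sqrt(v))
  structure(list(algorithm = "multiplicative", signal = lower > 1,
                 detail = c(f, list(ratio = ratio, se_log = sqrt(v),
                                    lower = lower, computable = TRUE))),
            class = "ddi_verdict")
}

#' Chi-square interaction model signal
#'
#' Compares the observed co-exposed event count \eqn{n_{111}} with its
#' expectation under no multiplicative interaction,
#' \eqn{e = n_{11+} f_{10} f_{01} / f_{00}} (clamped to
#' \eqn{[0, n_{11+}]}), using the Yates continuity-corrected statistic
#' \deqn{\chi^2 = (|n_{111} - e| - 0.5)^2 (1/e + 1/(n_{11+} - e)).}
#' A signal requires \eqn{\chi^2 > 3.841} and the one-sided guard
#' \eqn{n_{111} > e} (excesses only; deficits never signal).
#'
#' @param table A `ddi_ct` contingency table. Not computable when a
#'   row marginal is zero, \eqn{f_{00} = 0}, or the clamped expectation
#'   hits 0 or \eqn{n_{11+}}.
#' @return A `ddi_verdict` with `detail` fields `expected`, `chisq`,
#'   `computable`.
#' @export
chi_square_signal <- function(table) {
  stopifnot(inherits(table, "ddi_ct"))
  not_comp <- structure(list(algorithm = "chi-square", signal = FALSE,
                             detail = list(computable = FALSE)),
                        class = "ddi_verdict")
  if (min(table$n11p, table$n10p, table$n01p, table$n00p) == 0) {
    return(not_comp)
  }
  f <- .fcells(table)
  if (f$f00 == 0) return(not_comp)
  e <- table$n11p * (f$f10 * f$f01 / f$f00)
  e <- min(max(e, 0), table$n11p)
  if (e == 0 || e == table$n11p) return(not_comp)
  adj <- max(abs(table$n111 - e) - 0.5, 0)
  chisq <- adj^2 * (1 / e + 1 / (table$n11p - e))
  structure(list(algorithm = "chi-square",
                 signal = chisq > .chisq_crit && table$n111 > e,
                 detail = c(f, list(expected = e, chisq = chisq,
                                    computable = TRUE))),
            class = "ddi_verdict")
}

# ---------------------------------------------------------------------------
# Vectorised driver over a counts table

#' @noRd
.algorithms <- c("subset-new", "subset-previous", "omega", "additive",
                 "multiplicative", "chi-square")

#' Run a detector over a table of tabulated triples
#'
#' Applies one detection algorithm to every row of a counts data.frame
#' (as produced by [tabulate_triples()]) and returns a tidy verdict
#' table: the triple columns, the algorithm's headline statistics, and
#' a `signal` boolean.
#'
#' @param counts Data frame with columns `drug1`, `drug2`, `event`,
#'   `n111` ... `n000`.
#' @param algorithm One of `"subset-new"`, `"subset-previous"`,
#'   `"omega"`, `"additive"`, `"multiplicative"`, `"chi-square"`.
#' @param ... Passed to [subset_signal()] (`threshold`, `min_n11`,
#'   `haldane`) for the subset algorithms; ignored otherwise.
#' @return A data.frame with one row per triple.
#' @export
detect_signals <- function(counts, algorithm = .algorithms, ...) {
  algorithm <- match.arg(algorithm)
  cells <- c("n111", "n110", "n101", "n100", "n011", "n010", "n001", "n000")
  stopifnot(all(c("drug1", "drug2", "event", cells) %in% names(counts)))
  n <- nrow(counts)
  out <- counts[, c("drug1", "drug2", "event"), drop = FALSE]
  out$n111 <- counts$n111
  stat1 <- stat2 <- rep(NA_real_, n)
  signal <- logical(n)
  computable <- logical(n)
  for (i in seq_len(n)) {
    ct <- contingency_table(counts$n111[i], counts$n110[i], counts$n101[i],
                            counts$n100[i], counts$n011[i], counts$n010[i],
                            counts$n001[i], counts$n000[i])
    v <- switch(algorithm,
      "subset-new" = subset_signal(ct, "new", ...),
      "subset-previous" = subset_signal(ct, "previous", ...),
      "omega" = omega_signal(ct),
      "additive" = additive_signal(ct),
      "multiplicative" = multiplicative_signal(ct),
      "chi-square" = chi_square_signal(ct))
    signal[i] <- isTRUE(v$signal)
    d <- v$detail
    if (algorithm %in% c("subset-new", "subset-previous")) {
      stat1[i] <- if (isTRUE(d$d1$computable)) d$d1$ci_lower else NA_real_
      stat2[i] <- if (isTRUE(d$d2$computable)) d$d2$ci_lower else NA_real_
      computable[i] <- isTRUE(d$d1$computable) || isTRUE(d$d2$computable)
    } else if (algorithm == "omega") {
      stat1[i] <- if (isTRUE(d$computable)) d$omega else NA_real_
      stat2[i] <- if (isTRUE(d$computable)) d$omega025 else NA_real_
      computable[i] <- isTRUE(d$computable)
    } else if (algorithm == "additive") {
      stat1[i] <- if (isTRUE(d$computable)) d$delta else NA_real_
      stat2[i] <- if (isTRUE(d$computable)) d$lower else NA_real_
      computable[i] <- isTRUE(d$computable)
    } else if (algorithm == "multiplicative") {
      stat1[i] <- if (isTRUE(d$computable)) d$ratio else NA_real_
      stat2[i] <- if (isTRUE(d$computable)) d$lower else NA_real_
      computable[i] <- isTRUE(d$computable)
    } else {
      stat1[i] <- if (isTRUE(d$computable)) d$expected else NA_real_
      stat2[i] <- if (isTRUE(d$computable)) d$chisq else NA_real_
      computable[i] <- isTRUE(d$computable)
    }
  }
  stat_names <- switch(algorithm,
    "subset-new" = ,
    "subset-previous" = c("ci_lower_d1", "ci_lower_d2"),
    "omega" = c("omega", "omega025"),
    "additive" = c("delta", "delta_lower"),
    "multiplicative" = c("ratio", "ratio_lower"),
    "chi-square" = c("expected", "chisq"))
  out[[stat_names[1]]] <- stat1
  out[[stat_names[2]]] <- stat2
  out$computable <- computable
  out$signal <- signal
  out$algorithm <- rep_len(algorithm, n)  # rep_len: keep 0-row inputs valid
  out
}

#' Surrogate ("hypothetical") truth from three component models
#'
#' With no complete gold standard of adverse-event causality, a
#' surrogate truth set is built as the intersection of the signals of
#' the additive, multiplicative and chi-square interaction models over
#' a common triple universe: a triple is "true" only when all three
#' models signal.
#'
#' @param additive,multiplicative,chi_square Verdict data frames from
#'   [detect_signals()] computed over the same universe (same triples,
#'   same order not required).
#' @return A data.frame of triple keys (`drug1`, `drug2`, `event`)
#'   forming the truth set.
#' @export
hypothetical_truth <- function(additive, multiplicative, chi_square) {
  sets <- list(additive, multiplicative, chi_square)
  ids <- lapply(sets, function(v)
    .triple_id(v$drug1, v$drug2, v$event))
  u <- lapply(ids, sort)
  if (!identical(u[[1]], u[[2]]) || !identical(u[[1]], u[[3]])) {
    stop("verdict sets were not computed over the same triple universe",
         call. = FALSE)
  }
  pos <- lapply(seq_along(sets), function(i) ids[[i]][sets[[i]]$signal])
  keep <- Reduce(intersect, pos)
  sel <- sets[[1]][ids[[1]] %in% keep,
                   c("drug1", "drug2", "event"), drop = FALSE]
  sel[order(sel$drug1, sel$drug2, sel$event), , drop = FALSE]
}
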