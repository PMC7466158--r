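# Report-level synthetic data with known interaction structure.
#
# The generator emulates the shape of a spontaneous-reporting download:
# per case, independent suspect-drug exposures with configured marginal
# probabilities, and a target-event probability driven by the exposure
# cell of the configured pairs (baseline f00; f10/f01 under single
# exposure; f11 under co-exposure). A pooled "other adverse event"
# keeps the other-AE column of the 4x2 tables non-trivial. Ground truth
# is defined analytically: a configured pair is a true interaction when
# its f11 exceeds both the additive and the multiplicative null implied
# by its cells.

#' Scenario configuration for the report-level generator
#'
#' Validates and freezes everything [generate_reports()] needs. For
#' every interaction pair the implied additive null
#' (`f10 + f01 - f00`) and multiplicative null (`f10 * f01 / f00`) are
#' computed, and the pair is annotated with whether it sits on either
#' null and whether it is a true interaction (f11 strictly above both
#' nulls).
#'
#' @param n_cases Number of case reports to draw.
#' @param drugs Named numeric vector: marginal suspect-exposure
#'   probability per drug, each in (0, 1).
#' @param target_event Target adverse-event term.
#' @param baseline_event_prob Event probability for cases exposed to no
#'   configured risk (the f00 analogue), in (0, 1).
#' @param risk_multipliers Optional named numeric vector of per-drug
#'   event-probability multipliers applied to drugs not covered by a
#'   pair cell (default: none).
#' @param interaction_pairs Data frame with columns `drug1`, `drug2`,
#'   `f10`, `f01`, `f11`: cell event probabilities for the pair. Drugs
#'   must be declared in `drugs`. When a case matches several pairs the
#'   first in canonical pair order wins.
#' @param other_event_prob Probability that a case reports the pooled
#'   non-target event, in (0, 1).
#' @param seed Default RNG seed used by [generate_reports()].
#' @return A list of class `ddi_scenario`; `$pairs` carries the null
#'   annotations, `$truth` the true-interaction triples.
#' @export
#' @examples
#' ddi_scenario(1000, drugs = c(a = 0.1, b = 0.1),
#'              interaction_pairs = data.frame(
#'                drug1 = "a", drug2 = "b",
#'                f10 = 0.05, f01 = 0.05, f11 = 0.3))
ddi_scenario <- function(n_cases,
                         drugs,
                         target_event = "stevens-johnson syndrome",
                         baseline_event_prob = 0.01,
                         risk_multipliers = NULL,
                         interaction_pairs = NULL,
                         other_event_prob = 0.9,
                         seed = 1L) {
  stopifnot(is.numeric(n_cases), length(n_cases) == 1L, n_cases >= 1,
            n_cases == trunc(n_cases))
  if (is.null(names(drugs)) || any(!nzchar(names(drugs)))) {
    stop("`drugs` must be a named vector of exposure probabilities",
         call. = FALSE)
  }
  names(drugs) <- .normalize_term(names(drugs))
  if (anyDuplicated(names(drugs))) {
    stop("duplicate drug names in `drugs`", call. = FALSE)
  }
  prob_ok <- function(p) is.numeric(p) & !is.na(p) & p > 0 & p < 1
  if (!all(prob_ok(drugs))) {
    stop("exposure probabilities must lie in (0, 1)", call. = FALSE)
  }
  if (!prob_ok(baseline_event_prob) || !prob_ok(other_event_prob)) {
    stop("event probabilities must lie in (0, 1)", call. = FALSE)
  }
  target_event <- .normalize_term(target_event)
  stopifnot(nzchar(target_event))

  if (!is.null(risk_multipliers)) {
    if (is.null(names(risk_multipliers)) ||
        !all(names(risk_multipliers) %in% names(drugs))) {
      stop("risk_multipliers must be named after declared drugs",
           call. = FALSE)
    }
    names(risk_multipliers) <- .normalize_term(names(risk_multipliers))
    if (any(risk_multipliers < 0) ||
        any(risk_multipliers * baseline_event_prob >= 1)) {
      stop("risk multipliers must keep event probabilities in [0, 1)",
           call. = FALSE)
    }
  }

  pairs <- NULL
  if (!is.null(interaction_pairs)) {
    need <- c("drug1", "drug2", "f10", "f01", "f11")
    stopifnot(is.data.frame(interaction_pairs),
              all(need %in% names(interaction_pairs)))
    pairs <- interaction_pairs[, need, drop = FALSE]
    pairs$drug1 <- .normalize_term(pairs$drug1)
    pairs$drug2 <- .normalize_term(pairs$drug2)
    p <- .canonical_pair(pairs$drug1, pairs$drug2)
    pairs$drug1 <- p$drug1; pairs$drug2 <- p$drug2
    if (!all(c(pairs$drug1, pairs$drug2) %in% names(drugs))) {
      stop("interaction pairs reference undeclared drugs", call. = FALSE)
    }
    if (anyDuplicated(paste(pairs$drug1, pairs$drug2))) {
      stop("duplicate interaction pair", call. = FALSE)
    }
    if (!all(prob_ok(pairs$f10) & prob_ok(pairs$f01)) ||
        !all(is.numeric(pairs$f11) & pairs$f11 >= 0 & pairs$f11 < 1)) {
      stop("pair cell probabilities must lie in (0, 1) (f11 may be 0)",
           call. = FALSE)
    }
    pairs <- pairs[order(pairs$drug1, pairs$drug2), , drop = FALSE]
    rownames(pairs) <- NULL
    # which null does each pair sit on / exceed?
    f00 <- baseline_event_prob
    pairs$additive_null <- pairs$f10 + pairs$f01 - f00
    pairs$multiplicative_null <- pairs$f10 * pairs$f01 / f00
    tol <- 1e-9
    pairs$on_additive_null <- abs(pairs$f11 - pairs$additive_null) < tol
    pairs$on_multiplicative_null <-
      abs(pairs$f11 - pairs$multiplicative_null) < tol
    pairs$is_interaction <- pairs$f11 > pairs$additive_null + tol &
      pairs$f11 > pairs$multiplicative_null + tol
  }

  truth <- if (!is.null(pairs) && any(pairs$is_interaction)) {
    triple_keys(pairs$drug1[pairs$is_interaction],
                pairs$drug2[pairs$is_interaction], target_event)
  } else {
    data.frame(drug1 = character(0), drug2 = character(0),
               event = character(0), stringsAsFactors = FALSE)
  }

  structure(list(n_cases = as.integer(n_cases), drugs = drugs,
                 target_event = target_event,
                 baseline_event_prob = baseline_event_prob,
                 risk_multipliers = risk_multipliers,
                 pairs = pairs, other_event_prob = other_event_prob,
                 seed = as.integer(seed), truth = truth),
            class = "ddi_scenario")
}

#' @export
print.ddi_scenario <- function(x, ...) {
  cat(sprintf("<ddi_scenario> %d cases, %d drugs, %d configured pair(s) (%d true interaction(s)), target event '%s'\n",
              x$n_cases, length(x$drugs),
              if (is.null(x$pairs)) 0L else nrow(x$pairs),
              nrow(x$truth), x$target_event))
  if (!is.null(x$pairs)) {
    print(x$pairs[, c("drug1", "drug2", "f10", "f01", "f11",
                      "on_additive_null", "on_multiplicative_null",
                      "is_interaction")])
  }
  invisible(x)
}

#' Generate JADER-shaped report tables from a scenario
#'
#' Draws `n_cases` case reports: independent drug exposures per the
#' scenario's marginal probabilities, then one target-event Bernoulli
#' draw per case with probability given by the exposure cell (first
#' matching pair in canonical order wins; single-exposure cells use
#' that pair's f10/f01 with drug1 checked before drug2; otherwise the
#' per-drug multiplier of the riskiest exposed drug, or baseline).
#' Emits DEMO/DRUG/REAC data frames in the dialect [read_cases()]
#' expects, plus the analytic ground truth. Fully reproducible from the
#' seed.
#'
#' @param scenario A [ddi_scenario()].
#' @param seed Overrides the scenario's seed if given.
#' @return A list of class `ddi_reports`: `demo`, `drug`, `reac`
#'   data frames, `ground_truth` triples, and the `scenario`.
#' @export
generate_reports <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "ddi_scenario"))
  seed <- if (is.null(seed)) scenario$seed else as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- scenario$n_cases
  drug_names <- names(scenario$drugs)
  k <- length(drug_names)
  exposed <- matrix(stats::runif(n * k) < rep(scenario$drugs, each = n),
                    nrow = n, dimnames = list(NULL, drug_names))

  p_event <- rep(scenario$baseline_event_prob, n)
  decided <- rep(FALSE, n)
  if (!is.null(scenario$pairs)) {
    # pair cells, first matching pair wins (pairs already canonical order)
    for (i in seq_len(nrow(scenario$pairs))) {
      a <- exposed[, scenario$pairs$drug1[i]]
      b <- exposed[, scenario$pairs$drug2[i]]
      both <- !decided & a & b
      p_event[both] <- scenario$pairs$f11[i]
      decided <- decided | both
    }
    for (i in seq_len(nrow(scenario$pairs))) {
      a <- exposed[, scenario$pairs$drug1[i]]
      b <- exposed[, scenario$pairs$drug2[i]]
      only_a <- !decided & a & !b
      p_event[only_a] <- scenario$pairs$f10[i]
      decided <- decided | only_a
      only_b <- !decided & b & !a
      p_event[only_b] <- scenario$pairs$f01[i]
      decided <- decided | only_b
    }
  }
  if (!is.null(scenario$risk_multipliers)) {
    for (d in names(sort(scenario$risk_multipliers))) {
      hit <- !decided & exposed[, d]
      p_event[hit] <- scenario$baseline_event_prob *
        scenario$risk_multipliers[[d]]
    }
  }
  has_event <- stats::runif(n) < p_event
  has_other <- stats::runif(n) < scenario$other_event_prob

  ids <- sprintf("case%06d", seq_len(n))
  demo <- data.frame(case_id = ids, sex = rep_len(c("f", "m"), n),
                     stringsAsFactors = FALSE)
  which_exposed <- which(exposed, arr.ind = TRUE)
  drug <- data.frame(case_id = ids[which_exposed[, 1]],
                     drug_name = drug_names[which_exposed[, 2]],
                     drug_role = "suspect", stringsAsFactors = FALSE)
  drug <- drug[order(match(drug$case_id, ids), drug$drug_name), ]
  rownames(drug) <- NULL
  reac <- rbind(
    data.frame(case_id = ids[has_event],
               event_pt = scenario$target_event, stringsAsFactors = FALSE),
    data.frame(case_id = ids[has_other],
               event_pt = "other adverse reaction", stringsAsFactors = FALSE))
  reac <- reac[order(match(reac$case_id, ids), reac$event_pt), ]
  rownames(reac) <- NULL

  structure(list(demo = demo, drug = drug, reac = reac,
                 ground_truth = scenario$truth, scenario = scenario,
                 seed = seed),
            class = "ddi_reports")
}

#' @export
print.ddi_reports <- function(x, ...) {
  cat(sprintf("<ddi_reports> %d cases, %d drug rows, %d event rows, %d true interaction(s) (seed %d)\n",
              nrow(x$demo), nrow(x$drug), nrow(x$reac),
              nrow(x$ground_truth), x$seed))
  invisible(x)
}

#' Write generated tables to csv
#'
#' Writes DEMO.csv, DRUG.csv, REAC.csv, ground_truth.csv and a
#' provenance.json sidecar into `dir` (atomically).
#'
#' @param reports A `ddi_reports` object from [generate_reports()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_tables <- function(reports, dir) {
  stopifnot(inherits(reports, "ddi_reports"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    .atomic_write(function(p) utils::write.csv(df, p, row.names = FALSE,
                                               fileEncoding = "UTF-8"),
                  file.path(dir, name))
  }
  wr(reports$demo, "DEMO.csv")
  wr(reports$drug, "DRUG.csv")
  wr(reports$reac, "REAC.csv")
  wr(reports$ground_truth, "ground_truth.csv")
  prov <- list(tool = "ddiscreen",
               version = as.character(utils::packageVersion("ddiscreen")),
               seed = reports$seed,
               n_cases = reports$scenario$n_cases,
               config_digest = .config_digest(unclass(reports$scenario)))
  .atomic_write(function(p) jsonlite::write_json(prov, p, auto_unbox = TRUE),
                file.path(dir, "provenance.json"))
  invisible(dir)
}

#' Packaged demonstration scenario
#'
#' 50,000 cases, twelve drugs forming six disjoint pairs: one injected
#' synergistic interaction (cells f00 0.01, f10 = f01 0.05, f11 0.30,
#' well above both nulls) and five null pairs whose cells sit exactly
#' on both interaction nulls (f10 = f01 = f11 = f00, i.e. the drugs
#' carry no excess risk, where the additive and multiplicative nulls
#' coincide). Exposure probability 0.15 per drug.
#'
#' @param seed RNG seed.
#' @param n_cases Number of cases (default 50,000).
#' @return A `ddi_scenario`.
#' @export
demo_scenario <- function(seed = 20200812L, n_cases = 50000) {
  drugs <- stats::setNames(rep(0.15, 12), paste0("drug", letters[1:12]))
  f00 <- 0.01
  pairs <- data.frame(
    drug1 = paste0("drug", letters[c(1, 3, 5, 7, 9, 11)]),
    drug2 = paste0("drug", letters[c(2, 4, 6, 8, 10, 12)]),
    f10 = c(0.05, rep(f00, 5)),
    f01 = c(0.05, rep(f00, 5)),
    f11 = c(0.30, rep(f00, 5)),
    stringsAsFactors = FALSE)
  ddi_scenario(n_cases, drugs = drugs, baseline_event_prob = f00,
               interaction_pairs = pairs, other_event_prob = 0.9,
               seed = seed)
}

#' @describeIn demo_scenario Pure-null variant: the same six pairs all
#'   sit on both nulls (no interaction anywhere), for false-positive
#'   rate studies.
#' @export
null_scenario <- function(seed = 20200812L, n_cases = 2000) {
  drugs <- stats::setNames(rep(0.15, 12), paste0("drug", letters[1:12]))
  f00 <- 0.05
  pairs <- data.frame(
    drug1 = paste0("drug", letters[c(1, 3, 5, 7, 9, 11)]),
    drug2 = paste0("drug", letters[c(2, 4, 6, 8, 10, 12)]),
    f10 = f00, f01 = f00, f11 = f00, stringsAsFactors = FALSE)
  ddi_scenario(n_cases, drugs = drugs, baseline_event_prob = f00,
               interaction_pairs = pairs, other_event_prob = 0.9,
               seed = seed)
}

#' Run the full pipeline on a synthetic scenario
#'
#' generate -> read -> enumerate -> tabulate -> detect -> score:
#' convenience wrapper mirroring the evaluation design at synthetic
#' scale. Ground-truth pairs absent from the realised triple universe
#' (never co-reported with the event) are dropped from the truth with
#' a message, since no detector can see them.
#'
#' @param scenario A [ddi_scenario()].
#' @param algorithms Detector names as in [detect_signals()].
#' @param seed Optional seed override for generation.
#' @return A list: `metrics` (one row per algorithm), `verdicts`
#'   (named list of verdict data frames), `counts`, `truth`,
#'   `reports`.
#' @export
recovery_experiment <- function(scenario,
                                algorithms = c("subset-new",
                                               "subset-previous",
                                               "omega"),
                                seed = NULL) {
  stopifnot(inherits(scenario, "ddi_scenario"))
  algorithms <- match.arg(algorithms, .algorithms, several.ok = TRUE)
  reports <- generate_reports(scenario, seed = seed)
  cases <- read_cases(reports$demo, reports$drug, reports$reac)
  universe <- enumerate_triples(cases, scenario$target_event)
  counts <- tabulate_triples(cases, universe)
  uid <- .triple_id(counts$drug1, counts$drug2, counts$event)
  truth <- reports$ground_truth
  if (nrow(truth)) {
    tid <- .triple_id(truth$drug1, truth$drug2, truth$event)
    missing <- !(tid %in% uid)
    if (any(missing)) {
      message(sprintf("%d ground-truth pair(s) never co-reported with the event; dropped from truth",
                      sum(missing)))
      truth <- truth[!missing, , drop = FALSE]
    }
  }
  verdicts <- lapply(algorithms, function(a) detect_signals(counts, a))
  names(verdicts) <- algorithms
  metrics <- do.call(rbind, lapply(algorithms, function(a) {
    m <- classification_metrics(confusion(verdicts[[a]], truth, counts))
    cbind(data.frame(algorithm = a, stringsAsFactors = FALSE),
          as.data.frame(m))
  }))
  rownames(metrics) <- NULL
  list(metrics = metrics, verdicts = verdicts, counts = counts,
       truth = truth, reports = reports)
}
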