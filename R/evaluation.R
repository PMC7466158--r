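# Scoring signal sets against a truth set, and inter-algorithm agreement.

#' @noRd
.as_id_set <- function(x, what) {
  if (is.character(x)) return(unique(x))
  if (is.data.frame(x)) {
    stopifnot(all(c("drug1", "drug2", "event") %in% names(x)))
    if ("signal" %in% names(x)) x <- x[x$signal, , drop = FALSE]
    return(unique(.triple_id(x$drug1, x$drug2, x$event)))
  }
  stop(sprintf("`%s` must be a data.frame of triples (optionally with a `signal` column) or a character id vector",
               what), call. = FALSE)
}

#' Confusion counts of a signal set against a truth set
#'
#' Counts true/false positives and negatives of a predicted signal set
#' against a truth set over a fixed triple universe. Both sets must be
#' subsets of the universe.
#'
#' @param predicted,truth Data frames of triples (a `signal` column, if
#'   present, selects the positive rows -- [detect_signals()] output
#'   works directly) or character id vectors.
#' @param universe The triple universe: a data.frame of triples or id
#'   vector.
#' @return An object of class `ddi_confusion`: named numeric
#'   `tp, fp, tn, fn` summing to the universe size.
#' @export
#' @examples
#' confusion(predicted = c("a", "b"), truth = c("b", "c"),
#'           universe = letters[1:5])
confusion <- function(predicted, truth, universe) {
  p <- .as_id_set(predicted, "predicted")
  t <- .as_id_set(truth, "truth")
  u <- .as_id_set(universe, "universe")
  outside <- c(setdiff(p, u), setdiff(t, u))
  if (length(outside)) {
    stop(sprintf("%d element(s) outside the universe (first: %s)",
                 length(outside), outside[1]), call. = FALSE)
  }
  tp <- length(intersect(p, t))
  fp <- length(setdiff(p, t))
  fn <- length(setdiff(t, p))
  structure(c(tp = tp, fp = fp, tn = length(u) - tp - fp - fn, fn = fn),
            class = "ddi_confusion")
}

#' @export
print.ddi_confusion <- function(x, ...) {
  cat(sprintf("<ddi_confusion> TP %d  FP %d  TN %d  FN %d (N = %d)\n",
              x[["tp"]], x[["fp"]], x[["tn"]], x[["fn"]], sum(x)))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' The seven standard indicators: accuracy (TP+TN)/N, precision (PPV)
#' TP/(TP+FP), recall (sensitivity) TP/(TP+FN), specificity TN/(FP+TN),
#' Youden's index (sensitivity + specificity - 1), F-measure (harmonic
#' mean of precision and recall) and NPV TN/(TN+FN). A metric whose
#' denominator is zero is returned as `NA` (undefined), never coerced
#' to 0 or 1. Values are unrounded; `print` shows 3 decimals.
#'
#' @param x A `ddi_confusion`, or the `tp` count.
#' @param fp,tn,fn Remaining counts when given directly.
#' @return A list of class `ddi_metrics` with fields `accuracy`,
#'   `precision`, `recall`, `specificity`, `youden`, `f_measure`,
#'   `npv` (plus the input counts).
#' @export
#' @examples
#' classification_metrics(542, 367, 2634, 381)   # both-subsets row
classification_metrics <- function(x, fp = NULL, tn = NULL, fn = NULL) {
  if (inherits(x, "ddi_confusion")) {
    tp <- x[["tp"]]; fp <- x[["fp"]]; tn <- x[["tn"]]; fn <- x[["fn"]]
  } else {
    tp <- .assert_count(x, "tp"); fp <- .assert_count(fp, "fp")
    tn <- .assert_count(tn, "tn"); fn <- .assert_count(fn, "fn")
  }
  n <- tp + fp + tn + fn
  if (n == 0) stop("all confusion counts are zero", call. = FALSE)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- frac(tp, tp + fp)
  recall <- frac(tp, tp + fn)
  specificity <- frac(tn, fp + tn)
  youden <- if (!is.na(recall) && !is.na(specificity)) {
    recall + specificity - 1
  } else {
    NA_real_
  }
  f_measure <- if (!is.na(precision) && !is.na(recall) &&
                   precision + recall > 0) {
    2 * recall * precision / (recall + precision)
  } else {
    NA_real_
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / n,
                 precision = precision,
                 recall = recall,
                 specificity = specificity,
                 youden = youden,
                 f_measure = f_measure,
                 npv = frac(tn, tn + fn)),
            class = "ddi_metrics")
}

#' @export
print.ddi_metrics <- function(x, digits = 3, ...) {
  v <- unlist(x[c("accuracy", "precision", "recall", "specificity",
                  "youden", "f_measure", "npv")])
  cat("<ddi_metrics>\n")
  print(round(v, digits))
  invisible(x)
}

#' @export
as.data.frame.ddi_metrics <- function(x, ...) {
  data.frame(x[c("tp", "fp", "tn", "fn", "accuracy", "precision",
                 "recall", "specificity", "youden", "f_measure", "npv")],
             stringsAsFactors = FALSE)
}

#' Agreement between two signal sets
#'
#' Cross-tabulates two binary signal sets over a common triple universe
#' (a = both signal, b = only A, c = only B, d = neither) and reports
#' Cohen's kappa with an asymptotic 95% CI plus the chance-uncorrected
#' proportionate agreements for positive and negative ratings,
#' \eqn{P_{pos} = 2a/(2a+b+c)} and \eqn{P_{neg} = 2d/(2d+b+c)}.
#'
#' Kappa is \eqn{(p_o - p_e)/(1 - p_e)} with observed agreement
#' \eqn{p_o = (a+d)/N} and chance agreement from the marginals. The CI
#' uses the large-sample standard error of Fleiss, Cohen and Everitt
#' (1969), \eqn{\kappa \pm 1.959964\,SE}. Degenerate marginals
#' (\eqn{p_e = 1}) leave kappa undefined (`NA`).
#'
#' @param set_a,set_b Signal sets: verdict data frames (a `signal`
#'   column selects positives) or triple id vectors.
#' @param universe Common triple universe.
#' @return A list of class `ddi_agreement`: `kappa`, `kappa_ci_lower`,
#'   `kappa_ci_upper`, `p_positive`, `p_negative`, `table` (a, b, c, d).
#' @export
#' @examples
#' agreement(letters[1:4], letters[3:6], letters[1:10])
agreement <- function(set_a, set_b, universe) {
  A <- .as_id_set(set_a, "set_a")
  B <- .as_id_set(set_b, "set_b")
  u <- .as_id_set(universe, "universe")
  outside <- c(setdiff(A, u), setdiff(B, u))
  if (length(outside)) {
    stop(sprintf("%d element(s) outside the universe (first: %s)",
                 length(outside), outside[1]), call. = FALSE)
  }
  a <- length(intersect(A, B))
  b <- length(setdiff(A, B))
  cc <- length(setdiff(B, A))
  d <- length(u) - a - b - cc
  n <- length(u)
  po <- (a + d) / n
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
  if (pe >= 1) {
    kappa <- ci_l <- ci_u <- NA_real_
  } else {
    kappa <- (po - pe) / (1 - pe)
    # Fleiss-Cohen-Everitt (1969) asymptotic variance of kappa-hat,
    # evaluated on the 2x2 proportions
    p <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE) / n
    prow <- rowSums(p); pcol <- colSums(p)
    t1 <- sum(diag(p) * (1 - (prow + pcol) * (1 - kappa))^2)
    t2 <- (1 - kappa)^2 *
      (p[1, 2] * (pcol[1] + prow[2])^2 + p[2, 1] * (pcol[2] + prow[1])^2)
    t3 <- (kappa - pe * (1 - kappa))^2
    se <- sqrt(max(t1 + t2 - t3, 0) / (n * (1 - pe)^2))
    ci_l <- kappa - .z975 * se
    ci_u <- kappa + .z975 * se
  }
  p_pos <- if (2 * a + b + cc > 0) 2 * a / (2 * a + b + cc) else NA_real_
  p_neg <- if (2 * d + b + cc > 0) 2 * d / (2 * d + b + cc) else NA_real_
  structure(list(kappa = kappa, kappa_ci_lower = ci_l,
                 kappa_ci_upper = ci_u, p_positive = p_pos,
                 p_negative = p_neg,
                 table = c(a = a, b = b, c = cc, d = d)),
            class = "ddi_agreement")
}

#' @export
print.ddi_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("<ddi_agreement> kappa %.3f (95%% CI %.3f-%.3f)  P+ %.3f  P- %.3f\n",
              x$kappa, x$kappa_ci_lower, x$kappa_ci_upper,
              x$p_positive, x$p_negative))
  invisible(x)
}

#' Restrict verdicts to triples with enough co-exposed event reports
#'
#' Filters one or more verdict data frames (and the implied universe)
#' to triples whose `n111` in the counts table is at least `min_n111`,
#' e.g. the "three or more reports" stratification. Confusion and
#' agreement computed on the filtered output equal those computed from
#' scratch on the restricted universe.
#'
#' @param verdicts A verdict data.frame or a (possibly named) list of
#'   them, all over the counts' universe.
#' @param counts The counts data.frame the verdicts were computed from.
#' @param min_n111 Report floor; `0` is the identity.
#' @return A list: `universe` (filtered counts) and `verdicts`
#'   (filtered data frames, same shape as the input).
#' @export
stratify_by_reports <- function(verdicts, counts, min_n111 = 0) {
  stopifnot(is.numeric(min_n111), length(min_n111) == 1L, min_n111 >= 0)
  single <- is.data.frame(verdicts)
  if (single) verdicts <- list(verdicts)
  uid <- .triple_id(counts$drug1, counts$drug2, counts$event)
  keep_ids <- uid[counts$n111 >= min_n111]
  out <- lapply(verdicts, function(v) {
    vid <- .triple_id(v$drug1, v$drug2, v$event)
    if (!setequal(vid, uid)) {
      stop("verdicts do not match the counts' triple universe",
           call. = FALSE)
    }
    v[vid %in% keep_ids, , drop = FALSE]
  })
  list(universe = counts[uid %in% keep_ids, , drop = FALSE],
       verdicts = if (single) out[[1]] else out)
}
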