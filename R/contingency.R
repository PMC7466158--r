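# Report-level case assembly and 4x2 contingency tables.
#
# A spontaneous-reporting database (JADER-style) ships report-level csv
# tables keyed by a case id. For one (drug1, drug2, event) triple every
# case falls in exactly one of eight cells: (uses drug1?) x (uses drug2?)
# crossed with (reports the target event?). The 4x2 table
#
#                      target AE   other AEs
#   both drugs            n111        n110
#   only drug1            n101        n100
#   only drug2            n011        n010
#   neither drug          n001        n000
#
# is the common input of every interaction detection statistic here.

#' Column mapping for report-level tables
#'
#' Describes which columns of the DEMO/DRUG/REAC tables hold the case id,
#' drug name, drug role (and which role value marks a suspect drug) and
#' adverse-event preferred term. The defaults match the csv dialect written
#' by [generate_reports()]; use [jader_columns()] for the Japanese headers
#' of an actual JADER download.
#'
#' @param case_id Name of the case-id column, shared by all tables.
#' @param drug_name Drug (generic) name column in the DRUG table.
#' @param drug_role Role column in the DRUG table distinguishing suspect
#'   from concomitant drugs.
#' @param suspect_value Value of `drug_role` that marks a suspect drug.
#' @param event_pt Adverse-event preferred-term column in the REAC table.
#' @return A named list of class `ddi_columns`.
#' @export
#' @examples
#' report_columns(case_id = "ID")
report_columns <- function(case_id = "case_id",
                           drug_name = "drug_name",
                           drug_role = "drug_role",
                           suspect_value = "suspect",
                           event_pt = "event_pt") {
  out <- list(case_id = case_id, drug_name = drug_name,
              drug_role = drug_role, suspect_value = suspect_value,
              event_pt = event_pt)
  stopifnot(vapply(out, function(x) is.character(x) && length(x) == 1L &&
                     nzchar(x), logical(1)))
  structure(out, class = "ddi_columns")
}

#' @describeIn report_columns Column mapping matching the headers of the
#'   JADER csv distribution (identification number, generic drug name,
#'   drug involvement with "suspect drug" role, adverse-event name).
#' @export
jader_columns <- function() {
  # Japanese headers written as unicode escapes to keep the source ASCII:
  # identification number; drug (generic name); drug involvement;
  # suspect drug; adverse event.
  report_columns(
    case_id = "\u8b58\u5225\u756a\u53f7",
    drug_name = "\u533b\u85ac\u54c1\uff08\u4e00\u822c\u540d\uff09",
    drug_role = "\u533b\u85ac\u54c1\u306e\u95a2\u4e0e",
    suspect_value = "\u88ab\u7591\u85ac",
    event_pt = "\u6709\u5bb3\u4e8b\u8c61")
}

#' Case reports: one record per spontaneous report
#'
#' Constructs the case-level container used throughout the package: per
#' case, the set of suspect drugs and the set of reported adverse-event
#' preferred terms. Drug and event strings are normalised (trimmed,
#' case-folded) and deduplicated; empty strings are dropped.
#'
#' @param case_id Character vector of non-empty, unique case identifiers.
#' @param suspect_drugs List (parallel to `case_id`) of character vectors
#'   of suspect drug names; may contain empty vectors.
#' @param events List of character vectors of adverse-event terms.
#' @return An object of class `ddi_cases`.
#' @seealso [read_cases()] to build one from csv tables.
#' @export
#' @examples
#' ddi_cases(c("1", "2"),
#'           suspect_drugs = list(c("a", "b"), "a"),
#'           events = list("rash", character(0)))
ddi_cases <- function(case_id, suspect_drugs, events) {
  case_id <- as.character(case_id)
  if (length(case_id) == 0 && length(suspect_drugs) == 0 &&
      length(events) == 0) {
    return(structure(list(case_id = character(0),
                          suspect_drugs = list(), events = list()),
                     class = "ddi_cases"))
  }
  if (any(!nzchar(case_id)) || anyNA(case_id)) {
    stop("case ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(case_id)) {
    stop("case ids must be unique", call. = FALSE)
  }
  if (length(suspect_drugs) != length(case_id) ||
      length(events) != length(case_id)) {
    stop("suspect_drugs and events must have one entry per case",
         call. = FALSE)
  }
  clean <- function(x) {
    x <- .normalize_term(unlist(x, use.names = FALSE))
    sort(unique(x[nzchar(x) & !is.na(x)]))
  }
  structure(list(case_id = case_id,
                 suspect_drugs = lapply(suspect_drugs, clean),
                 events = lapply(events, clean)),
            class = "ddi_cases")
}

#' @export
length.ddi_cases <- function(x) length(x$case_id)

#' @export
print.ddi_cases <- function(x, ...) {
  cat(sprintf("<ddi_cases> %d case reports, %d distinct suspect drugs, %d distinct events\n",
              length(x),
              length(unique(unlist(x$suspect_drugs))),
              length(unique(unlist(x$events)))))
  invisible(x)
}

#' @export
as.data.frame.ddi_cases <- function(x, ...) {
  data.frame(
    case_id = x$case_id,
    suspect_drugs = vapply(x$suspect_drugs, paste, "", collapse = ";"),
    events = vapply(x$events, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
}

#' @noRd
.read_table <- function(x, what, columns, need) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(sprintf("%s table not found: %s", what, x),
                              call. = FALSE)
    x <- utils::read.csv(x, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  }
  if (!is.data.frame(x)) {
    stop(sprintf("%s must be a data.frame or a csv path", what),
         call. = FALSE)
  }
  missing_cols <- setdiff(unlist(columns[need]), names(x))
  if (length(missing_cols)) {
    stop(sprintf("%s table lacks required column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Read report-level tables into case reports
#'
#' Assembles one [ddi_cases()] record per case from the three report-level
#' tables of a JADER-style distribution: DEMO (case identifiers), DRUG
#' (case id, drug name, suspect/concomitant role) and REAC (case id,
#' adverse-event term). Only drugs whose role equals the configured
#' suspect value are kept. Cases listed in DEMO with no suspect drug or no
#' event are retained with empty sets -- they still populate the
#' "neither drug" rows of the contingency tables. A HIST table, if passed,
#' is accepted and ignored.
#'
#' Duplicate case ids in DEMO (JADER ships quarterly files with report
#' revisions) are resolved by keeping the last-seen record, with a
#' warning. DRUG/REAC rows whose case id has no DEMO record are dropped
#' with a warning.
#'
#' @param demo,drug,reac Data frames or csv file paths.
#' @param hist Optional past-history table; read-tolerated, unused.
#' @param columns A [report_columns()] mapping.
#' @return A `ddi_cases` object with one entry per DEMO case id, in DEMO
#'   order (last occurrence for duplicates).
#' @export
#' @examples
#' demo <- data.frame(case_id = c("1", "2"))
#' drug <- data.frame(case_id = c("1", "1", "2"),
#'                    drug_name = c("alpha", "beta", "alpha"),
#'                    drug_role = c("suspect", "concomitant", "suspect"))
#' reac <- data.frame(case_id = "1", event_pt = "rash")
#' read_cases(demo, drug, reac)
read_cases <- function(demo, drug, reac, hist = NULL,
                       columns = report_columns()) {
  stopifnot(inherits(columns, "ddi_columns"))
  demo <- .read_table(demo, "DEMO", columns, "case_id")
  drug <- .read_table(drug, "DRUG", columns,
                      c("case_id", "drug_name", "drug_role"))
  reac <- .read_table(reac, "REAC", columns, c("case_id", "event_pt"))
  if (!is.null(hist)) .read_table(hist, "HIST", columns, "case_id")

  ids <- as.character(demo[[columns$case_id]])
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("DEMO contains empty case ids", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    warning(sprintf("%d duplicate case id(s) in DEMO; keeping last-seen record",
                    sum(duplicated(ids))), call. = FALSE)
    keep <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[keep]
  }

  pick_rows <- function(tab, value_col, filter = NULL) {
    cid <- as.character(tab[[columns$case_id]])
    val <- tab[[value_col]]
    keep <- !is.na(cid) & nzchar(cid)
    if (!is.null(filter)) keep <- keep & filter
    cid <- cid[keep]; val <- as.character(val[keep])
    unknown <- !(cid %in% ids)
    if (any(unknown)) {
      warning(sprintf("dropping %d row(s) with case ids absent from DEMO",
                      sum(unknown)), call. = FALSE)
      cid <- cid[!unknown]; val <- val[!unknown]
    }
    split(val, factor(cid, levels = ids))
  }

  role <- .normalize_term(drug[[columns$drug_role]])
  drugs_by_case <- pick_rows(drug, columns$drug_name,
                             role == .normalize_term(columns$suspect_value))
  events_by_case <- pick_rows(reac, columns$event_pt)

  ddi_cases(ids, drugs_by_case[ids], events_by_case[ids])
}

#' Canonical (drug1, drug2, event) triple keys
#'
#' Stores the drug pair in lexicographic order so that (A, B) and (B, A)
#' name the same triple. Vectorised.
#'
#' @param drug1,drug2 Character vectors of distinct drug names.
#' @param event Character vector of event terms (recycled if length 1).
#' @return A data.frame with columns `drug1`, `drug2`, `event`.
#' @export
triple_keys <- function(drug1, drug2, event) {
  drug1 <- .normalize_term(drug1)
  drug2 <- .normalize_term(drug2)
  event <- .normalize_term(event)
  if (any(!nzchar(c(drug1, drug2, event)))) {
    stop("triple components must be non-empty", call. = FALSE)
  }
  p <- .canonical_pair(drug1, drug2)
  n <- max(length(p$drug1), length(event))
  data.frame(drug1 = rep_len(p$drug1, n), drug2 = rep_len(p$drug2, n),
             event = rep_len(event, n), stringsAsFactors = FALSE)
}

#' Enumerate candidate triples for one target event
#'
#' Returns every canonical suspect-drug pair that co-occurs with the
#' target event in at least one case (n111 >= 1), sorted
#' lexicographically. Pairs never co-reported with the event carry no
#' information for screening and are excluded from the triple universe.
#'
#' @param cases A `ddi_cases` object.
#' @param target_event Non-empty event term.
#' @return A data.frame of [triple_keys()] rows (possibly zero rows).
#' @export
enumerate_triples <- function(cases, target_event) {
  stopifnot(inherits(cases, "ddi_cases"))
  target_event <- .normalize_term(target_event)
  if (length(target_event) != 1L || !nzchar(target_event)) {
    stop("target_event must be a single non-empty term", call. = FALSE)
  }
  with_event <- vapply(cases$events, function(e) target_event %in% e,
                       logical(1))
  pairs <- character(0)
  for (drugs in cases$suspect_drugs[with_event]) {
    if (length(drugs) >= 2L) {
      cmb <- utils::combn(drugs, 2L)  # drugs sorted, so pairs canonical
      pairs <- c(pairs, paste(cmb[1L, ], cmb[2L, ], sep = "\x1f"))
    }
  }
  pairs <- sort(unique(pairs))
  if (!length(pairs)) {
    return(data.frame(drug1 = character(0), drug2 = character(0),
                      event = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(pairs, "\x1f", fixed = TRUE)
  data.frame(drug1 = vapply(parts, `[`, "", 1L),
             drug2 = vapply(parts, `[`, "", 2L),
             event = target_event, stringsAsFactors = FALSE)
}

#' 4x2 contingency table for one triple
#'
#' Holds the eight cell counts; row marginals (`n11p`, `n10p`, `n01p`,
#' `n00p`), column totals (`np1`, `np0`) and the grand total `nppp` are
#' always derived from the cells at construction, never stored
#' independently.
#'
#' @param n111,n110,n101,n100,n011,n010,n001,n000 Non-negative report
#'   counts: first index = uses drug1, second = uses drug2, third = 1 for
#'   the target event and 0 for any other event.
#' @return An object of class `ddi_ct`.
#' @export
#' @examples
#' contingency_table(5, 20, 3, 72, 4, 90, 40, 2000)
contingency_table <- function(n111, n110, n101, n100,
                              n011, n010, n001, n000) {
  cells <- c(n111 = .assert_count(n111, "n111"),
             n110 = .assert_count(n110, "n110"),
             n101 = .assert_count(n101, "n101"),
             n100 = .assert_count(n100, "n100"),
             n011 = .assert_count(n011, "n011"),
             n010 = .assert_count(n010, "n010"),
             n001 = .assert_count(n001, "n001"),
             n000 = .assert_count(n000, "n000"))
  out <- as.list(cells)
  out$n11p <- cells[["n111"]] + cells[["n110"]]
  out$n10p <- cells[["n101"]] + cells[["n100"]]
  out$n01p <- cells[["n011"]] + cells[["n010"]]
  out$n00p <- cells[["n001"]] + cells[["n000"]]
  out$np1 <- cells[["n111"]] + cells[["n101"]] + cells[["n011"]] +
    cells[["n001"]]
  out$np0 <- sum(cells) - out$np1
  out$nppp <- sum(cells)
  structure(out, class = "ddi_ct")
}

#' @export
print.ddi_ct <- function(x, ...) {
  m <- matrix(c(x$n111, x$n110, x$n101, x$n100, x$n011, x$n010,
                x$n001, x$n000), ncol = 2, byrow = TRUE,
              dimnames = list(c("both drugs", "only drug1", "only drug2",
                                "neither"),
                              c("target AE", "other AEs")))
  cat(sprintf("<ddi_ct> 4x2 contingency table (N = %d)\n", x$nppp))
  print(cbind(m, total = rowSums(m)))
  invisible(x)
}

#' Tabulate contingency tables for a set of triples
#'
#' Classifies every case into one of the eight cells of the 4x2 table for
#' each requested triple. Each case contributes to exactly one cell, so
#' cell counts always sum to the number of cases.
#'
#' @param cases A `ddi_cases` object.
#' @param triples A data.frame with columns `drug1`, `drug2`, `event`
#'   (canonical order as from [triple_keys()] or [enumerate_triples()]).
#' @return A data.frame: the triple columns followed by the eight cell
#'   counts `n111` ... `n000`.
#' @export
tabulate_triples <- function(cases, triples) {
  stopifnot(inherits(cases, "ddi_cases"),
            all(c("drug1", "drug2", "event") %in% names(triples)))
  n <- length(cases)
  # membership cache: one logical vector per distinct drug / event
  need_drugs <- unique(c(triples$drug1, triples$drug2))
  need_events <- unique(triples$event)
  drug_member <- lapply(need_drugs, function(d)
    vapply(cases$suspect_drugs, function(s) d %in% s, logical(1)))
  names(drug_member) <- need_drugs
  event_member <- lapply(need_events, function(e)
    vapply(cases$events, function(s) e %in% s, logical(1)))
  names(event_member) <- need_events

  k <- nrow(triples)
  counts <- matrix(0, nrow = k, ncol = 8,
                   dimnames = list(NULL, c("n111", "n110", "n101", "n100",
                                           "n011", "n010", "n001", "n000")))
  for (i in seq_len(k)) {
    a <- drug_member[[triples$drug1[i]]]
    b <- drug_member[[triples$drug2[i]]]
    e <- event_member[[triples$event[i]]]
    # cell index 0..7: 4*(has d1) + 2*(has d2) + (has event)
    idx <- 4L * a + 2L * b + e
    tab <- tabulate(idx + 1L, nbins = 8L)
    # tab order: 000,001,010,011,100,101,110,111 over (d1,d2,ev)
    counts[i, ] <- tab[c(8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L)]
  }
  cbind(triples[, c("drug1", "drug2", "event")],
        as.data.frame(counts))
}

#' @describeIn tabulate_triples Tabulate a single triple, returning a
#'   [contingency_table()] object.
#' @param drug1,drug2,event Components of one triple.
#' @export
tabulate_triple <- function(cases, drug1, drug2, event) {
  row <- tabulate_triples(cases, triple_keys(drug1, drug2, event))
  contingency_table(row$n111, row$n110, row$n101, row$n100,
                    row$n011, row$n010, row$n001, row$n000)
}

#' Convert one tabulated row to a contingency table object
#'
#' @param row A one-row data.frame with columns `n111` ... `n000`, as
#'   produced by [tabulate_triples()].
#' @return A `ddi_ct` object.
#' @export
as_contingency <- function(row) {
  stopifnot(nrow(row) == 1L)
  contingency_table(row$n111, row$n110, row$n101, row$n100,
                    row$n011, row$n010, row$n001, row$n000)
}

#' Directional 2x2 subset views of a 4x2 table
#'
#' The subset analysis restricts the database to users of one drug and
#' asks whether the other drug disproportionally co-reports with the
#' event there. Within drug-D1 users the 2x2 table is
#' (N11, N10, N01, N00) = (n111, n110, n101, n100); within drug-D2 users
#' it is (n111, n110, n011, n010). Both views share N11 and N10.
#'
#' @param table A `ddi_ct` object.
#' @param perspective `"within_d1"` (reports using drug1) or
#'   `"within_d2"`.
#' @return A list of class `ddi_subset` with fields `N11`, `N10`, `N01`,
#'   `N00` and `perspective`.
#' @export
subset_view <- function(table, perspective = c("within_d1", "within_d2")) {
  stopifnot(inherits(table, "ddi_ct"))
  perspective <- match.arg(perspective)
  v <- if (perspective == "within_d1") {
    list(N11 = table$n111, N10 = table$n110,
         N01 = table$n101, N00 = table$n100)
  } else {
    list(N11 = table$n111, N10 = table$n110,
         N01 = table$n011, N00 = table$n010)
  }
  structure(c(v, list(perspective = perspective)), class = "ddi_subset")
}
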