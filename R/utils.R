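# Internal constants and helpers shared across modules.

# 97.5% standard-normal quantile, fixed to double precision so results are
# reproducible independently of qnorm() implementation details.
.z975 <- 1.959964

# 95% chi-square critical value on 1 df.
.chisq_crit <- 3.841

#' @noRd
.assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != trunc(x)) {
    stop(sprintf("`%s` must be a single non-negative count, got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  }
  as.numeric(x)
}

# Canonical lexicographic ordering of a drug pair, vectorised.
#' @noRd
.canonical_pair <- function(drug1, drug2) {
  if (any(drug1 == drug2)) {
    stop("drug1 and drug2 must differ within a triple", call. = FALSE)
  }
  swap <- drug1 > drug2
  lo <- ifelse(swap, drug2, drug1)
  hi <- ifelse(swap, drug1, drug2)
  list(drug1 = lo, drug2 = hi)
}

# Stable string id for a triple, used for set operations on triples.
#' @noRd
.triple_id <- function(drug1, drug2, event) {
  p <- .canonical_pair(drug1, drug2)
  paste(p$drug1, p$drug2, event, sep = "\x1f")
}

# Normalisation applied to drug names and event terms before matching:
# trim surrounding whitespace, case-fold. No dictionary mapping.
#' @noRd
.normalize_term <- function(x) {
  tolower(trimws(as.character(x)))
}

# Tiny FNV-1a hash of a deparsed object; used for provenance config digests
# without pulling in a hashing dependency.
#' @noRd
.config_digest <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Write a data.frame (or character vector) atomically: temp file in the
# destination directory, then rename.
#' @noRd
.atomic_write <- function(writer, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
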