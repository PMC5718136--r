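# Inter-rater agreement harness: weighted Cohen's kappa over paired ordinal
# ratings, with Landis-Koch interpretation bands.

#' Build a contingency table from paired ordinal ratings
#'
#' @param rater_a,rater_b equal-length vectors of labels.
#' @param categories ordered character vector of the ordinal categories;
#'   every label must come from it.
#' @return an object of class `contingency_table` with the ordered
#'   `categories`, a k x k `counts` matrix (rows = rater A), and `n`.
#' @export
contingency_from_ratings <- function(rater_a, rater_b, categories) {
  if (length(rater_a) != length(rater_b)) {
    stop("rating vectors differ in length (", length(rater_a), " vs ",
         length(rater_b), ")")
  }
  if (length(rater_a) == 0) stop("at least one rating pair is required")
  if (anyDuplicated(categories)) stop("categories must be distinct")
  unknown <- setdiff(unique(c(rater_a, rater_b)), categories)
  if (length(unknown) > 0) {
    stop("unknown category label(s): ", paste(unknown, collapse = ", "))
  }
  fa <- factor(rater_a, levels = categories)
  fb <- factor(rater_b, levels = categories)
  counts <- unclass(table(fa, fb))
  dimnames(counts) <- list(rater_a = categories, rater_b = categories)
  structure(list(categories = categories, counts = counts,
                 n = length(rater_a)),
            class = "contingency_table")
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordinal categories, penalizing
#' disagreements by ordinal distance.  With observed counts `o[i,j]`,
#' expected counts `e[i,j] = row_i * col_j / n` and disagreement weights
#' `w[i,j] = |i-j| / (k-1)` (linear) or `(i-j)^2 / (k-1)^2` (quadratic),
#' `kappa_w = 1 - sum(w * o) / sum(w * e)`.  For k = 2 the linear scheme
#' reduces to unweighted Cohen's kappa.
#'
#' When both raters put all mass in a single category the denominator is 0:
#' the result is flagged degenerate, with kappa 1 if agreement is perfect
#' and `NA` otherwise.
#'
#' @param table a `contingency_table`.
#' @param scheme weighting scheme, `"linear"` (default) or `"quadratic"`.
#' @return an object of class `kappa_result` with `kappa`, `scheme`,
#'   `weights`, `expected`, `band` ([interpret_kappa()] label, `NA` when
#'   kappa is undefined), and a `degenerate` flag.
#' @export
weighted_kappa <- function(table, scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(table, "contingency_table"))
  o <- table$counts
  k <- length(table$categories)
  n <- table$n
  idx <- seq_len(k) - 1L
  d <- abs(outer(idx, idx, "-"))
  w <- if (k == 1) matrix(0, 1, 1) else
    if (scheme == "linear") d / (k - 1) else d^2 / (k - 1)^2
  e <- outer(rowSums(o), colSums(o)) / n
  denom <- sum(w * e)
  degenerate <- denom == 0
  kappa <- if (degenerate) {
    if (sum(o) == sum(diag(o))) 1 else NA_real_
  } else {
    1 - sum(w * o) / denom
  }
  structure(
    list(kappa = kappa, scheme = scheme, weights = w, expected = e,
         observed = o, n = n,
         band = if (is.na(kappa)) NA_character_ else interpret_kappa(kappa),
         degenerate = degenerate),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("weighted kappa (%s): %.4f  [%s]%s\n", x$scheme, x$kappa,
              x$band, if (x$degenerate) " (degenerate table)" else ""))
  invisible(x)
}

#' Landis-Koch interpretation of a kappa value
#'
#' Bands: Poor (< 0.00), Slight (0.00-0.20), Fair (0.21-0.40), Moderate
#' (0.41-0.60), Substantial (0.61-0.80), Almost Perfect (0.81-1.00).  Band
#' boundaries are closed on the upper end, matching the printed two-decimal
#' ranges: 0.80 is Substantial, 0.81 is Almost Perfect.
#'
#' @param kappa a number in `[-1, 1]`.
#' @return the band label.
#' @export
interpret_kappa <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) ||
      kappa < -1 || kappa > 1) {
    stop("kappa must be a single number in [-1, 1]")
  }
  if (kappa < 0) "Poor"
  else if (kappa <= 0.20) "Slight"
  else if (kappa <= 0.40) "Fair"
  else if (kappa <= 0.60) "Moderate"
  else if (kappa <= 0.80) "Substantial"
  else "Almost Perfect"
}

#' Read paired ratings from CSV
#'
#' Expected columns: `id, rater_a, rater_b`.
#'
#' @param path CSV file path.
#' @return data frame with the three columns.
#' @export
read_ratings_csv <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), c("id", "rater_a", "rater_b"))) {
    stop("ratings CSV header mismatch; expected: id,rater_a,rater_b")
  }
  df
}
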