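#' Convert counts to percent-of-total per sample
#'
#' `percent[s, i] = 100 * count[s, i] / total_i`, making binding profiles
#' comparable across samples despite differences in sequencing depth.
#'
#' @param m Count matrix with positive column totals.
#' @return Numeric matrix; each column sums to 100.
#' @export
to_percent <- function(m) {
  validate_count_matrix(m)
  totals <- colSums(m)
  bad <- colnames(m)[totals == 0]
  if (length(bad))
    stop("zero-total sample(s): ", paste(bad, collapse = ", "))
  sweep(m, 2L, totals, "/") * 100
}

#' Scale percent abundances by the per-sequence mean
#'
#' Each percent value is divided by the average percent for that sequence
#' across the samples in `scope` (default: all samples of the matrix, i.e.
#' the cohort being analyzed).  A value of 1 indicates no deviation from the
#' sequence's mean relative binding; values below/above 1 indicate
#' reduced/increased relative binding.  Scaled values are invariant to
#' per-sample depth rescaling of the counts.
#'
#' @param percent Percent matrix from [to_percent()].
#' @param scope Optional character vector of sample IDs over which the
#'   per-sequence mean is taken (must be a subset of the columns).
#' @return Numeric matrix of scaled relative-binding values; when
#'   `scope` spans all columns, each row has mean exactly 1.
#' @export
to_scaled <- function(percent, scope = NULL) {
  if (is.null(scope)) scope <- colnames(percent)
  missing <- setdiff(scope, colnames(percent))
  if (length(missing)) stop("scope samples not in matrix: ", paste(missing, collapse = ", "))
  mu <- rowMeans(percent[, scope, drop = FALSE])
  bad <- rownames(percent)[mu == 0]
  if (length(bad))
    stop("zero-mean sequence(s) in scope: ", paste(head(bad, 5), collapse = ", "))
  sweep(percent, 1L, mu, "/")
}

#' Full normalization of a count matrix
#'
#' Convenience wrapper: percent-of-total then per-sequence mean scaling.
#'
#' @param m Count matrix.
#' @inheritParams to_scaled
#' @return List of class `scaled_matrix` with `percent` and `scaled`
#'   matrices (same dimnames as `m`).
#' @export
normalize_counts <- function(m, scope = NULL) {
  percent <- to_percent(m)
  scaled <- to_scaled(percent, scope = scope)
  structure(list(percent = percent, scaled = scaled), class = "scaled_matrix")
}
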