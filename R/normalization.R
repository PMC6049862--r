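# Normalization: quantile (microarray-style) and median-of-ratios size
# factors (RNA-Seq depth correction), plus the detection-flag filter.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' target distribution is the vector of row means of the column-sorted matrix,
#' and each value is replaced by the target value at its within-column rank.
#' Ties within a column receive the mean of the target values at their tied
#' ranks, so a constant column maps to a constant.
#'
#' @param m An [expression_matrix()] with at least one sample.
#' @return An [expression_matrix()] of the same shape; flags and groups carry
#'   over unchanged.
#' @examples
#' x <- matrix(c(1, 4, 3, 2), 2, 2, dimnames = list(c("f1","f2"), c("s1","s2")))
#' em <- expression_matrix(x, c(s1 = "tumor", s2 = "control"))
#' quantile_normalize(em)$values
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  v <- m$values
  if (nrow(v) == 0L || ncol(v) == 0L) stop("empty expression matrix")
  target <- rowMeans(apply(v, 2L, sort))
  out <- apply(v, 2L, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- target
    if (anyDuplicated(col)) {           # tie block -> mean of its target values
      for (val in unique(col[duplicated(col)])) {
        idx <- col == val
        res[idx] <- mean(res[idx])
      }
    }
    res
  })
  dimnames(out) <- dimnames(v)
  expression_matrix(out, m$groups, m$scale, m$flags)
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth correction in the DESeq2 style: the reference
#' for each feature is its geometric mean across samples, computed over
#' features positive in every sample; a sample's factor is the median over
#' those features of count / reference. Dividing each column by its factor
#' yields the depth-normalized matrix.
#'
#' @param counts An [expression_matrix()] with `scale = "linear_count"` and
#'   non-negative values.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$scale != "linear_count")
    stop("size factors require a linear_count matrix")
  v <- counts$values
  if (any(v < 0)) stop("negative counts")
  all_pos <- rowSums(v > 0) == ncol(v)
  if (!any(all_pos))
    stop("no feature has positive counts in every sample; cannot form reference")
  lv <- log(v[all_pos, , drop = FALSE])
  ref_log <- rowMeans(lv)                  # log geometric mean
  apply(lv, 2L, function(col) exp(stats::median(col - ref_log)))
}

#' Divide each sample by its size factor
#'
#' @param counts A `linear_count` [expression_matrix()].
#' @param factors Optional precomputed factors; defaults to
#'   [size_factors()] of `counts`.
#' @return A depth-normalized `linear_count` [expression_matrix()].
#' @export
apply_size_factors <- function(counts, factors = size_factors(counts)) {
  stopifnot(identical(sort(names(factors)), sort(colnames(counts$values))))
  v <- sweep(counts$values, 2L, factors[colnames(counts$values)], "/")
  expression_matrix(v, counts$groups, counts$scale, counts$flags)
}

#' Detection-flag filter
#'
#' Keeps features flagged Present or Marginal in at least `min_present`
#' samples (inclusive), the microarray reliability filter applied before
#' differential expression (the study used 7 of 28 samples). When the matrix
#' carries no flags the filter is a no-op with a warning.
#'
#' @param m An [expression_matrix()].
#' @param min_present Minimum number of Present/Marginal samples.
#' @return A filtered [expression_matrix()].
#' @export
flag_filter <- function(m, min_present = 7L) {
  stopifnot(inherits(m, "expression_matrix"))
  if (is.null(m$flags)) {
    warning("no detection flags attached; flag_filter is a no-op")
    return(m)
  }
  ok <- m$flags %in% c("P", "M", "Present", "Marginal")
  dim(ok) <- dim(m$flags)
  keep <- rowSums(ok) >= min_present
  if (!any(keep)) stop("flag filter removed every feature")
  subset_expression(m, features = rownames(m$values)[keep])
}
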