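# Tumor-vs-control differential expression on log2 matrices: per-feature
# two-sample t-test, log2 fold change as difference of group means, BH FDR.

#' Differential expression between tumor and control samples
#'
#' Per feature: a two-sample t-test (Welch by default; pooled variance with
#' `cfg$de_var_equal`) between tumor and control columns of a log2-scale
#' matrix, log2 fold change as tumor mean minus control mean, and
#' Benjamini-Hochberg FDR across all tested features. A feature is called
#' `up`/`down` when its linear fold change `2^|log2_fc|` reaches
#' `cfg$de_fc_threshold` and its p-value (or FDR when `cfg$de_use_fdr`) falls
#' below the stage threshold; otherwise `unchanged`. Features with zero
#' variance in both groups get p = 1 with a warning rather than an error.
#'
#' @param m An [expression_matrix()] with `scale = "log2"` and at least two
#'   samples per group.
#' @param cfg A [pipeline_config()].
#' @return Data frame with columns `feature_id`, `mean_log2_tumor`,
#'   `mean_log2_control`, `log2_fc`, `p_value`, `fdr`, `direction`.
#' @examples
#' set.seed(1)
#' v <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
#' g <- setNames(rep(c("tumor", "control"), each = 5), colnames(v))
#' differential_expression(expression_matrix(v, g), pipeline_config())
#' @export
differential_expression <- function(m, cfg = pipeline_config()) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log2") stop("differential expression expects a log2 matrix")
  tum <- m$values[, m$groups == "tumor", drop = FALSE]
  ctl <- m$values[, m$groups == "control", drop = FALSE]
  if (ncol(tum) < 2L || ncol(ctl) < 2L)
    stop("need >= 2 samples per group")
  n <- nrow(m$values)
  mt <- rowMeans(tum); mc <- rowMeans(ctl)
  pv <- numeric(n)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    x <- tum[i, ]; y <- ctl[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      pv[i] <- 1
      degenerate <- TRUE
    } else {
      pv[i] <- stats::t.test(x, y, var.equal = cfg$de_var_equal)$p.value
    }
  }
  if (degenerate)
    warning("feature(s) with zero variance in both groups: p set to 1")
  fdr <- stats::p.adjust(pv, method = "BH")
  lfc <- mt - mc
  sig <- if (cfg$de_use_fdr) fdr < cfg$de_fdr_threshold else pv < cfg$de_p_threshold
  called <- sig & (2^abs(lfc) >= cfg$de_fc_threshold)
  direction <- ifelse(called & lfc > 0, "up",
                      ifelse(called & lfc < 0, "down", "unchanged"))
  data.frame(feature_id = rownames(m$values),
             mean_log2_tumor = mt, mean_log2_control = mc,
             log2_fc = lfc, p_value = pv, fdr = fdr,
             direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ids of features called differentially expressed
#'
#' @param de A data frame from [differential_expression()].
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Character vector of feature ids.
#' @export
de_features <- function(de, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") de$direction != "unchanged"
          else de$direction == direction
  de$feature_id[keep]
}
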