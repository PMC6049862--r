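# Expression-based survival signature: per-lncRNA univariate Cox screening
# with eligibility filters, a coefficient-weighted risk score, median-split
# stratification with Kaplan-Meier / log-rank testing, and multivariate
# adjustment for the standard glioma prognostic covariates.

#' Survival-screen eligibility filter
#'
#' Keeps lncRNAs of the allowed positional subtypes that are detected
#' (value > 0) in at least `cfg$expression_presence_fraction` of samples —
#' the reliability filter applied before univariate Cox screening
#' ("at least 1 read in >= 30% of samples" on counts; value > 0 on log2
#' matrices).
#'
#' @param lnc_expr An [expression_matrix()].
#' @param subtypes Output of [classify_lncrnas()], or `NULL` to skip the
#'   subtype filter.
#' @param cfg A [pipeline_config()].
#' @param allowed_subtypes Subtypes admitted to the screen.
#' @return Character vector of eligible feature ids.
#' @export
eligibility_filter <- function(lnc_expr, subtypes = NULL,
                               cfg = pipeline_config(),
                               allowed_subtypes = c("intergenic",
                                                    "intron_sense_overlapping")) {
  stopifnot(inherits(lnc_expr, "expression_matrix"))
  ids <- rownames(lnc_expr$values)
  detected <- rowMeans(lnc_expr$values > 0) >= cfg$expression_presence_fraction
  keep <- detected
  if (!is.null(subtypes)) {
    st <- subtypes$subtype[match(ids, subtypes$lncrna_id)]
    keep <- keep & !is.na(st) & st %in% allowed_subtypes
  }
  ids[keep]
}

#' Univariate Cox regression on one feature
#'
#' Proportional-hazards partial-likelihood fit of survival on a single
#' continuous covariate (log2 expression), with Wald p-value and 95% CI on
#' the hazard ratio.
#'
#' @param expr_row Named numeric vector of log2 expression per sample.
#' @param surv A [survival_table()] whose sample ids match `names(expr_row)`.
#' @return One-row data frame: `coefficient`, `hazard_ratio`, `p_value`,
#'   `ci_low`, `ci_high`, `converged`.
#' @export
univariate_cox <- function(expr_row, surv) {
  stopifnot(inherits(surv, "survival_table"))
  idx <- match(surv$sample_id, names(expr_row))
  if (anyNA(idx)) stop("expression missing for sample(s): ",
                       paste(surv$sample_id[is.na(idx)], collapse = ", "))
  x <- as.numeric(expr_row[idx])
  fit <- tryCatch(
    survival::coxph(survival::Surv(surv$time, surv$event) ~ x),
    error = function(e) NULL, warning = function(w) {
      # ran-out-of-iterations / infinite-coefficient warnings flag the fit
      f <- suppressWarnings(
        survival::coxph(survival::Surv(surv$time, surv$event) ~ x))
      attr(f, "lncscape_flagged") <- TRUE
      f
    })
  if (is.null(fit))
    return(data.frame(coefficient = NA_real_, hazard_ratio = NA_real_,
                      p_value = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, converged = FALSE))
  s <- summary(fit)
  data.frame(coefficient = unname(stats::coef(fit)),
             hazard_ratio = unname(exp(stats::coef(fit))),
             p_value = unname(s$coefficients[1L, "Pr(>|z|)"]),
             ci_low = unname(s$conf.int[1L, "lower .95"]),
             ci_high = unname(s$conf.int[1L, "upper .95"]),
             converged = !isTRUE(attr(fit, "lncscape_flagged")),
             stringsAsFactors = FALSE)
}

#' Univariate Cox screen over an expression matrix
#'
#' Runs [univariate_cox()] on every (eligible) feature; non-converged fits
#' are flagged and excluded from ranking.
#'
#' @param lnc_expr An [expression_matrix()] (log2).
#' @param surv A [survival_table()].
#' @param features Feature ids to screen (default all rows).
#' @return Data frame with `feature_id` plus the [univariate_cox()] columns,
#'   ordered by p-value among converged fits.
#' @export
cox_screen <- function(lnc_expr, surv, features = rownames(lnc_expr$values)) {
  res <- do.call(rbind, lapply(features, function(f)
    univariate_cox(lnc_expr$values[f, ], surv)))
  res <- cbind(feature_id = features, res, stringsAsFactors = FALSE)
  res[order(!res$converged, res$p_value), , drop = FALSE]
}

#' Select the top signature features
#'
#' Ranks converged univariate Cox results by p-value (ties broken by larger
#' |coefficient|) and returns the top `k`.
#'
#' @param screen Output of [cox_screen()].
#' @param k Number of signature features (default 5).
#' @return The selected rows of `screen`.
#' @export
select_signature <- function(screen, k = 5L) {
  ok <- screen[screen$converged & !is.na(screen$p_value), , drop = FALSE]
  ok <- ok[order(ok$p_value, -abs(ok$coefficient)), , drop = FALSE]
  utils::head(ok, k)
}

#' Per-sample lncRNA risk score
#'
#' Risk score of a sample = sum over signature lncRNAs of (Cox regression
#' coefficient x log2 expression of the lncRNA in that sample). Samples with
#' score strictly above the cohort median are the high-risk group; ties at
#' the median go to low risk.
#'
#' @param selected Data frame with `feature_id` and `coefficient` (e.g. from
#'   [select_signature()]).
#' @param lnc_expr An [expression_matrix()] (log2) containing every selected
#'   feature.
#' @param samples Sample ids to score (default all columns).
#' @return Data frame `sample_id`, `score`, `group` (`"low"`/`"high"`).
#' @export
risk_score <- function(selected, lnc_expr, samples = colnames(lnc_expr$values)) {
  missing <- setdiff(selected$feature_id, rownames(lnc_expr$values))
  if (length(missing))
    stop("signature feature(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  v <- lnc_expr$values[selected$feature_id, samples, drop = FALSE]
  score <- as.numeric(crossprod(v, selected$coefficient))
  data.frame(sample_id = samples, score = score,
             group = ifelse(score > stats::median(score), "high", "low"),
             stringsAsFactors = FALSE)
}

#' Stratify by risk group and test survival separation
#'
#' Kaplan-Meier estimates per risk group, the two-group log-rank test, and
#' median survival per group (smallest time at which the survival estimate
#' drops to 0.5 or below; `NA` = not reached).
#'
#' @param scores Output of [risk_score()].
#' @param surv A [survival_table()].
#' @return List with `median_survival` (named vector, months), `logrank_p`,
#'   `logrank_chisq`, `km` (data frame of per-group step curves: `group`,
#'   `time`, `surv`, `n_risk`, `n_event`).
#' @export
stratify_and_test <- function(scores, surv) {
  stopifnot(inherits(surv, "survival_table"))
  m <- merge(scores, as.data.frame(surv), by = "sample_id")
  if (length(unique(m$group)) < 2L)
    stop("both risk groups must be non-empty")
  sv <- survival::Surv(m$time, m$event)
  fit <- survival::survfit(sv ~ group, data = m)
  if (sum(m$event) > 0L) {
    sd <- survival::survdiff(sv ~ group, data = m)
    chisq <- unname(sd$chisq)
    p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  } else {   # no events at all: the log-rank statistic is undefined
    chisq <- NA_real_; p <- NA_real_
  }
  strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  km <- data.frame(group = strata, time = fit$time, surv = fit$surv,
                   n_risk = fit$n.risk, n_event = fit$n.event,
                   stringsAsFactors = FALSE)
  med <- vapply(split(km, km$group), function(g) {
    hit <- g$time[g$surv <= 0.5]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  list(median_survival = med, logrank_p = p,
       logrank_chisq = chisq, km = km)
}

#' Multivariate Cox adjustment of the risk score
#'
#' Joint proportional-hazards fit of the risk score (continuous by default,
#' or the dichotomized group) with clinical covariates such as age, G-CIMP
#' status, IDH1 mutation and MGMT promoter methylation. Rows with missing
#' covariates are dropped (count reported); a covariate collinear with the
#' rest is flagged and the model refitted without it.
#'
#' @param scores Output of [risk_score()].
#' @param surv A [survival_table()] carrying covariate columns.
#' @param use `"score"` (continuous) or `"group"`.
#' @return List with `results` (data frame: `term`, `coefficient`,
#'   `hazard_ratio`, `p_value`, `ci_low`, `ci_high`), `n_used`, `n_dropped`,
#'   `dropped_collinear` (character).
#' @export
multivariate_cox <- function(scores, surv, use = c("score", "group")) {
  use <- match.arg(use)
  covs <- surv_covariate_names(surv)
  m <- merge(scores, as.data.frame(surv), by = "sample_id")
  complete <- stats::complete.cases(m[, c("time", "event", use, covs)])
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  if (use == "group") m$group <- as.integer(m$group == "high")
  terms <- c(use, covs)
  dropped <- character(0)
  repeat {
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(terms, collapse = " + ")))
    fit <- survival::coxph(fml, data = m)
    alias <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    if (!length(alias)) break
    dropped <- c(dropped, alias)
    terms <- setdiff(terms, alias)
    if (!length(terms)) stop("all covariates collinear")
  }
  s <- summary(fit)
  res <- data.frame(term = rownames(s$coefficients),
                    coefficient = s$coefficients[, "coef"],
                    hazard_ratio = s$coefficients[, "exp(coef)"],
                    p_value = s$coefficients[, "Pr(>|z|)"],
                    ci_low = s$conf.int[, "lower .95"],
                    ci_high = s$conf.int[, "upper .95"],
                    row.names = NULL, stringsAsFactors = FALSE)
  list(results = res, n_used = nrow(m), n_dropped = n_dropped,
       dropped_collinear = dropped)
}
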