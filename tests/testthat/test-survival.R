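# eligibility filter, Cox screen, risk score, stratification, adjustment

make_surv <- function(x, coef, n, censor = 0.3, seed = 1) {
  em <- expression_matrix(
    matrix(x, 1, n, dimnames = list("F1", sprintf("T%03d", 1:n))),
    stats::setNames(rep("tumor", n), sprintf("T%03d", 1:n)))
  simulate_survival(em, c(F1 = coef), censor_frac = censor, seed = seed)$surv
}

test_that("eligibility combines detection fraction and subtype, matching a recount", {
  set.seed(59)
  n_feat <- 50; n_samp <- 20
  v <- matrix(rnorm(n_feat * n_samp, 1, 2), n_feat, n_samp)
  em <- toy_matrix(v, n_tumor = n_samp)
  cfg <- pipeline_config()
  subs <- data.frame(
    lncrna_id = rownames(em$values),
    subtype = sample(c("intergenic", "intron_sense_overlapping",
                       "natural_antisense"), n_feat, replace = TRUE),
    stringsAsFactors = FALSE)
  got <- eligibility_filter(em, subs, cfg)
  oracle <- rownames(em$values)[
    rowSums(v > 0) / n_samp >= cfg$expression_presence_fraction &
      subs$subtype %in% c("intergenic", "intron_sense_overlapping")]
  expect_setequal(got, oracle)

  # boundary: detected in 29% of samples at a 30% threshold -> excluded
  v2 <- rbind(low = c(rep(1, 29), rep(0, 71)),
              hi = rep(1, 100))
  em2 <- toy_matrix(v2, n_tumor = 100)
  expect_equal(eligibility_filter(em2, NULL, cfg), "hi")
  # an everywhere-detected natural-antisense feature is still excluded
  subs2 <- data.frame(lncrna_id = c("low", "hi"),
                      subtype = c("intergenic", "natural_antisense"))
  expect_length(eligibility_filter(em2, subs2, cfg), 0L)
})

test_that("univariate Cox recovers a planted coefficient of 0.5 within 0.15", {
  errs <- vapply(c(101, 202), function(seed) {
    set.seed(seed)
    x <- rnorm(200)
    surv <- make_surv(x, 0.5, 200, censor = 0.3, seed = seed)
    fit <- univariate_cox(stats::setNames(x, sprintf("T%03d", 1:200)), surv)
    fit$coefficient - 0.5
  }, numeric(1))
  expect_true(all(abs(errs) <= 0.15))
})

test_that("expression unrelated to survival gives near-zero coefficients", {
  set.seed(61)
  x <- rnorm(150)
  surv <- make_surv(rnorm(150), 0.7, 150, seed = 7)  # hazard driven elsewhere
  fit <- univariate_cox(stats::setNames(x, sprintf("T%03d", 1:150)), surv)
  expect_lt(abs(fit$coefficient), 0.3)
  expect_gt(fit$p_value, 0.001)
  expect_equal(fit$hazard_ratio, exp(fit$coefficient))
  expect_lte(fit$ci_low, fit$hazard_ratio)
  expect_gte(fit$ci_high, fit$hazard_ratio)
})

test_that("Cox estimates are invariant to doubling all times (rank invariance)", {
  set.seed(67)
  x <- rnorm(80)
  surv <- make_surv(x, 0.5, 80, seed = 3)
  doubled <- survival_table(surv$sample_id, surv$time * 2, surv$event,
                            covariates = surv[, surv_covariate_names(surv)])
  f1 <- univariate_cox(stats::setNames(x, surv$sample_id), surv)
  f2 <- univariate_cox(stats::setNames(x, surv$sample_id), doubled)
  expect_equal(f1$coefficient, f2$coefficient, tolerance = 1e-10)
})

test_that("risk score arithmetic and median-split grouping", {
  sel <- data.frame(feature_id = c("A", "B"), coefficient = c(0.5, -0.2))
  vv <- cbind(s1 = c(2, 3), s2 = c(3, 3), s3 = c(4, 3))
  rownames(vv) <- c("A", "B")
  em <- expression_matrix(vv, stats::setNames(rep("tumor", 3), colnames(vv)))
  rs <- risk_score(sel, em)
  expect_equal(rs$score[rs$sample_id == "s1"], 0.5 * 2 - 0.2 * 3)  # 0.4
  # adding c to one feature's expression shifts every score by coef * c
  expect_equal(rs$score, c(0.4, 0.9, 1.4))
  # strict median split: the median sample itself goes to low risk
  expect_equal(rs$group, c("low", "low", "high"))

  # zero coefficients -> all scores zero
  z <- risk_score(data.frame(feature_id = c("A", "B"), coefficient = c(0, 0)), em)
  expect_true(all(z$score == 0))

  # group sizes differ by at most one under unique scores
  set.seed(71)
  em2 <- toy_matrix(matrix(rnorm(40), 2, 20), n_tumor = 20)
  rs2 <- risk_score(data.frame(feature_id = c("f01", "f02"),
                               coefficient = c(0.3, -0.4)), em2)
  expect_lte(abs(sum(rs2$group == "high") - sum(rs2$group == "low")), 1L)

  expect_error(risk_score(data.frame(feature_id = "missing", coefficient = 1),
                          em), "missing")
})

test_that("median split separates survival when hazard follows the score", {
  set.seed(73)
  n <- 150
  x <- rnorm(n)
  surv <- make_surv(x, log(2), n, censor = 0.2, seed = 11)  # hazard ratio 2
  scores <- data.frame(sample_id = surv$sample_id, score = x,
                       group = ifelse(x > stats::median(x), "high", "low"),
                       stringsAsFactors = FALSE)
  st <- stratify_and_test(scores, surv)
  expect_lt(st$logrank_p, 0.01)
  expect_true(st$median_survival["high"] < st$median_survival["low"])
  # median survival = first time the KM estimate reaches 0.5
  km_low <- st$km[st$km$group == "low", ]
  expect_equal(unname(st$median_survival["low"]),
               min(km_low$time[km_low$surv <= 0.5]))
})

test_that("degenerate stratifications behave: identical groups and all-censored cohorts", {
  set.seed(79)
  n <- 50
  base <- make_surv(rnorm(n), 0, n, censor = 0.2, seed = 13)
  # two groups with literally identical survival experience -> log-rank p = 1
  surv <- survival_table(c(base$sample_id, paste0("dup_", base$sample_id)),
                         rep(base$time, 2), rep(base$event, 2))
  scores <- data.frame(sample_id = surv$sample_id,
                       score = rep(c(0, 1), each = n),
                       group = rep(c("low", "high"), each = n),
                       stringsAsFactors = FALSE)
  st <- stratify_and_test(scores, surv)
  expect_equal(st$logrank_p, 1, tolerance = 1e-6)

  # all-censored cohort: KM constant at 1, median never reached, p undefined
  surv2 <- survival_table(surv$sample_id, surv$time, rep(0L, 2 * n))
  st2 <- stratify_and_test(scores, surv2)
  expect_true(all(st2$km$surv == 1))
  expect_true(all(is.na(st2$median_survival)))
  expect_true(is.na(st2$logrank_p))
})

test_that("multivariate adjustment flags collinear covariates and recovers the score", {
  set.seed(83)
  n <- 150
  x <- rnorm(n)
  surv <- make_surv(x, 0.6, n, censor = 0.2, seed = 17)
  scores <- data.frame(sample_id = surv$sample_id, score = x,
                       group = ifelse(x > stats::median(x), "high", "low"),
                       stringsAsFactors = FALSE)
  fit <- multivariate_cox(scores, surv)
  res <- fit$results
  expect_gt(res$coefficient[res$term == "score"], 0)
  expect_lt(res$p_value[res$term == "score"], 0.01)
  # covariates were generated independent of the hazard
  expect_true(all(res$p_value[res$term %in% c("g_cimp", "idh1", "mgmt")] > 0.001))

  # a covariate duplicating the score is collinear and gets dropped
  surv_dup <- survival_table(surv$sample_id, surv$time, surv$event,
                             covariates = cbind(surv[, surv_covariate_names(surv)],
                                                dup = x))
  fit2 <- multivariate_cox(scores, surv_dup)
  expect_true("dup" %in% fit2$dropped_collinear ||
                !"dup" %in% fit2$results$term)

  # joint row permutation leaves estimates unchanged
  perm <- sample(n)
  surv_p <- survival_table(surv$sample_id[perm], surv$time[perm],
                           surv$event[perm],
                           covariates = surv[perm, surv_covariate_names(surv)])
  fit3 <- multivariate_cox(scores, surv_p)
  expect_equal(fit3$results$coefficient, fit$results$coefficient,
               tolerance = 1e-8)
})
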