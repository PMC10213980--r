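test_that("median normalization equalizes sample medians and undoes scaling", {
  set.seed(19)
  v <- matrix(rlnorm(40 * 5), nrow = 40,
              dimnames = list(sprintf("f%02d", 1:40), sprintf("s%d", 1:5)))
  # pin the sample medians to 1, then to known levels far enough apart that
  # doubling the smallest cannot move the median of medians
  v <- sweep(v, 2, apply(v, 2, median), `/`)
  v <- sweep(v, 2, c(1, 10, 12, 14, 16), `*`)
  norm0 <- median_normalize(expression_matrix(v, "c"))$values
  v2 <- v
  v2[, 1] <- 2 * v2[, 1]
  restored <- median_normalize(expression_matrix(v2, "c"))$values
  expect_equal(restored, norm0, tolerance = 1e-12)
  meds <- apply(norm0, 2, median)
  expect_equal(unname(meds), rep(12, 5), tolerance = 1e-12)

  # already-equal medians: identity
  eq <- matrix(c(1, 2, 3, 3, 2, 1), nrow = 3,
               dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  expect_equal(median_normalize(expression_matrix(eq, "c"))$values, eq)
  neg <- eq; neg[1, 1] <- -5
  expect_error(median_normalize(expression_matrix(neg, "c")), "positive")
  expect_equal(median_normalize(expression_matrix(eq, "c"), log2 = TRUE)$values,
               log2(eq))
})

test_that("differential regression recovers a planted standardized shift", {
  set.seed(20)
  n <- 100
  tt <- data.frame(sample_id = sprintf("s%03d", 1:(2 * n)),
                   group = rep(c("case", "control"), each = n),
                   age = rnorm(2 * n, 40, 8), stringsAsFactors = FALSE)
  v <- matrix(rnorm(50 * 2 * n), nrow = 50,
              dimnames = list(sprintf("f%02d", 1:50), tt$sample_id))
  v[1, tt$group == "case"] <- v[1, tt$group == "case"] + 1
  de <- differential_expression(expression_matrix(v, "c"), tt,
                                covariates = "age")
  # d on the standardized scale: shift 1 SD attenuated by standardization
  expect_lt(de$p[1], 1e-8)
  expect_gt(de$d[1], 0.8)
  expect_equal(sign(de$coef), sign(de$d))
  expect_equal(de$n_case[1], n)

  # covariate equal to the group indicator is flagged as collinear
  tt$dup <- as.numeric(tt$group == "case")
  expect_error(differential_expression(expression_matrix(v, "c"), tt,
                                       covariates = "dup"), "collinear.*dup")
})

test_that("null features give uniform p and nominal type-I error", {
  set.seed(21)
  n <- 30
  tt <- data.frame(sample_id = sprintf("s%03d", 1:(2 * n)),
                   group = rep(c("case", "control"), each = n),
                   stringsAsFactors = FALSE)
  v <- matrix(rnorm(2000 * 2 * n), nrow = 2000,
              dimnames = list(sprintf("f%04d", 1:2000), tt$sample_id))
  de <- differential_expression(expression_matrix(v, "c"), tt)
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
  expect_gt(mean(de$p < 0.05), 0.04)
  expect_lt(mean(de$p < 0.05), 0.06)
})

test_that("Stouffer combination matches closed-form arithmetic", {
  # single cohort: identity
  one <- stouffer_combine(0.037, 1, 50)
  expect_equal(one$p, 0.037, tolerance = 1e-12)

  # two cohorts, p = 0.05, same sign, equal n
  two <- stouffer_combine(c(0.05, 0.05), c(1, 1), c(80, 80))
  expect_equal(two$z, 2 * qnorm(0.975) / sqrt(2), tolerance = 1e-6)
  expect_lt(abs(two$z - 2.7718), 1e-4)
  expect_lt(abs(two$p - 0.0056), 1e-4)
  expect_equal(two$p, 2 * pnorm(-2 * qnorm(0.975) / sqrt(2)), tolerance = 1e-12)

  # opposite signs cancel exactly
  opp <- stouffer_combine(c(0.01, 0.01), c(1, -1), c(60, 60))
  expect_equal(opp$z, 0, tolerance = 1e-12)
  expect_equal(opp$p, 1, tolerance = 1e-12)

  # unequal n weights by sqrt(n)
  un <- stouffer_combine(c(0.05, 0.5), c(1, 1), c(400, 100))
  zk <- c(qnorm(0.975), qnorm(0.75))
  expect_equal(un$z, sum(sqrt(c(400, 100)) * zk) / sqrt(500), tolerance = 1e-10)

  expect_warning(stouffer_combine(c(0, 0.5), c(1, 1), c(10, 10)), "clamped")
})

test_that("FDR corrections reproduce the step-up hand computation", {
  q_by <- adjust_pvalues(c(0.01, 0.02, 0.03), "BY")
  expect_equal(q_by, rep(0.055, 3), tolerance = 1e-12)
  expect_equal(adjust_pvalues(0.2, "BY"), 0.2)
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
  set.seed(22)
  p <- runif(50)
  expect_true(all(adjust_pvalues(p, "BY") >= adjust_pvalues(p, "BH") - 1e-15))
  # order invariance
  o <- sample(50)
  expect_equal(adjust_pvalues(p, "BY")[o], adjust_pvalues(p[o], "BY"))
})

test_that("DerSimonian-Laird pooling matches hand computation and metafor", {
  res <- random_effects_meta(c(0.5, 0.5), c(0.1, 0.1))
  expect_equal(res$Q, 0)
  expect_equal(res$tau2, 0)
  expect_equal(res$pooled_d, 0.5)
  expect_equal(res$se, 0.2236, tolerance = 1e-4)
  expect_equal(res$z, 2.236, tolerance = 1e-3)

  # tau2 = 0 reduces to the fixed-effect estimate
  d <- c(0.2, 0.25, 0.22); v <- c(0.5, 0.5, 0.5)
  r2 <- random_effects_meta(d, v)
  if (r2$tau2 == 0)
    expect_equal(r2$pooled_d, sum(d / v) / sum(1 / v), tolerance = 1e-12)

  skip_if_not_installed("metafor")
  set.seed(23)
  for (i in 1:10) {
    K <- sample(2:5, 1)
    d <- rnorm(K, 0.3, 0.4)
    v <- runif(K, 0.02, 0.3)
    mine <- random_effects_meta(d, v)
    ref <- metafor::rma(yi = d, vi = v, method = "DL")
    expect_equal(mine$pooled_d, unname(ref$beta[1]), tolerance = 1e-8)
    expect_equal(mine$se, ref$se, tolerance = 1e-8)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(mine$Q, ref$QE, tolerance = 1e-8)
    expect_equal(mine$Q_p, ref$QEp, tolerance = 1e-8)
  }
})

test_that("homogeneous effects give uniform Q_p and near-zero tau2", {
  set.seed(24)
  K <- 3
  reps <- 2000
  v <- 0.04
  d <- matrix(rnorm(reps * K, mean = 0.5, sd = sqrt(v)), ncol = K)
  res <- random_effects_meta(d, matrix(v, reps, K))
  expect_gt(ks.test(res$Q_p, "punif")$p.value, 0.01)
  expect_lt(median(res$tau2), 0.01)
})

test_that("direction-consistency applies the sign and p < 0.1 rule", {
  mk <- function(coef, p)
    data.frame(feature_id = paste0("f", seq_along(coef)), coef = coef, p = p,
               stringsAsFactors = FALSE)
  de <- list(mk(c(1, 1, 1), c(0.05, 0.2, 0.05)),
             mk(c(2, -1, 1), c(0.09, 0.01, 0.11)),
             mk(c(0.5, 1, 1), c(0.01, 0.01, 0.01)))
  flag <- direction_consistency(de)
  expect_identical(unname(flag), c(TRUE, FALSE, FALSE))
  expect_error(direction_consistency(de[1]), ">= 2")
})

test_that("the persistent set is the exact intersection of the four routes", {
  ids <- paste0("f", 1:6)
  training <- data.frame(feature_id = ids,
                         p = c(0.001, 0.001, 0.5, 0.001, 0.001, 0.001),
                         stringsAsFactors = FALSE)
  meta <- data.frame(feature_id = ids,
                     stouffer_q = c(0.01, 0.01, 0.01, 0.2, 0.01, 0.01),
                     rem_p = c(0.01, 0.2, 0.01, 0.2, 0.01, 0.01),
                     direction_consistent = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  members <- c("f1", "f2", "f3", "f4", "f5")   # f6 outside the module route
  ps <- persistent_feature_set(members, training, meta)
  expect_identical(ps$feature_id, c("f1", "f2"))
  expect_true(all(ps$route_module & ps$route_training &
                  ps$route_meta & ps$route_direction))

  # AND rule additionally drops f2 (rem_p fails)
  ps_and <- persistent_feature_set(members, training, meta, meta_rule = "and")
  expect_identical(ps_and$feature_id, "f1")

  # empty meta-significant set gives an empty result
  meta0 <- meta
  meta0$stouffer_q <- 1; meta0$rem_p <- 1
  expect_equal(nrow(persistent_feature_set(members, training, meta0)), 0)

  expect_error(persistent_feature_set("fX", training, meta), "universe")
})
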