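test_that("dendrogram has linkage structure expected from block similarity", {
  # two identical features merge first, at (near-)zero TOM dissimilarity
  set.seed(6)
  prof <- rnorm(100)
  X <- toy_expr(list(a = prof, b = prof, c = rnorm(100), d = rnorm(100)))
  tom <- topological_overlap(adjacency_from_expression(X, beta = 4))
  dend <- build_dendrogram(tom)
  expect_true(all(diff(dend$height) >= -1e-12))
  first <- sort(dend$labels[-dend$merge[1, ]])
  expect_lt(dend$height[1], 0.01)
  expect_identical(first, c("a", "b"))

  # block-diagonal similarity: final merge joins the two blocks at max height
  s <- diag(6)
  s[1:3, 1:3] <- 0.9; s[4:6, 4:6] <- 0.9; diag(s) <- 1
  dimnames(s) <- list(paste0("f", 1:6), paste0("f", 1:6))
  d2 <- build_dendrogram(structure(list(values = s, kind = "single"),
                                   class = "overlap"))
  expect_equal(max(d2$height), 1)
  expect_equal(sort(unlist(cutree(d2, k = 2))), sort(rep(1:2, 3)),
               ignore_attr = TRUE)
  expect_error(build_dendrogram(matrix(1, 1, 1)), "2 features")
})

test_that("static cut recovers planted modules and respects min size", {
  fx <- default_fixture()
  asg <- default_assignment()
  truth <- fx$truth$module_labels[names(asg$labels)]
  keep <- asg$labels > 0
  expect_gte(adjusted_rand(truth[keep], asg$labels[keep]), 0.8)
  sizes <- table(asg$labels[asg$labels > 0])
  expect_true(all(sizes >= 30))
  # labels are ordered by decreasing size
  expect_true(all(diff(as.numeric(sizes)) <= 0))

  # a 10-feature cluster with min_size 30 goes to label 0
  set.seed(8)
  f <- rnorm(40)
  rows <- c(lapply(1:10, function(i) 0.95 * f + rnorm(40, sd = 0.2)),
            lapply(1:10, function(i) rnorm(40)))
  names(rows) <- paste0("f", 1:20)
  Xs <- toy_expr(rows)
  ds <- build_dendrogram(topological_overlap(adjacency_from_expression(Xs, 4)))
  a30 <- cut_modules(ds, min_size = 30, cut_height = 0.5)
  expect_true(all(a30$labels == 0))
  # cut at the top collects everything into one module
  a1 <- cut_modules(ds, min_size = 2, cut_height = 1.0)
  expect_true(all(a1$labels == 1))
  expect_error(cut_modules(ds, min_size = 1), "min_size")
})

test_that("eigengenes summarize modules with oriented unit-variance scores", {
  prof <- rnorm(30)
  rows <- setNames(lapply(1:5, function(i) 2 * prof + i), paste0("f", 1:5))
  X <- toy_expr(rows)
  asg <- structure(list(labels = setNames(rep(1L, 5), names(rows))),
                   class = "module_assignment")
  me <- module_eigengenes(X, asg)
  expect_equal(me$var_explained[["ME1"]], 1)
  expect_equal(cor(me$values["ME1", ], prof), 1, tolerance = 1e-10)
  expect_equal(sd(me$values["ME1", ]), 1, tolerance = 1e-10)

  # the orientation rule is deterministic: flipping every member profile
  # flips the mean profile, hence the oriented eigengene flips with it and
  # |correlation| is preserved exactly
  Xf <- expression_matrix(-X$values, "toy")
  mef <- module_eigengenes(Xf, asg)
  expect_equal(mef$values, -me$values, tolerance = 1e-10)
})

test_that("the eigen-solver reproduces the 2x2 worked eigenpair", {
  A <- rbind(c(2, 1), c(4, 2))
  e <- leading_eigen(A)
  expect_equal(e$value, 4, tolerance = 1e-12)
  expect_equal(e$vector, c(1, 2), tolerance = 1e-12)
  expect_equal(as.numeric(A %*% e$vector), 4 * e$vector, tolerance = 1e-12)
})

test_that("modules driven by near-identical factors merge; threshold 0 is a no-op", {
  set.seed(9)
  n <- 60
  f1 <- rnorm(n)
  f2 <- 0.95 * f1 + sqrt(1 - 0.95^2) * rnorm(n)  # factor correlation 0.95
  f3 <- rnorm(n)
  mk <- function(f, k, tag)
    setNames(lapply(1:k, function(i) 0.8 * f + 0.6 * rnorm(n)),
             paste0(tag, 1:k))
  X <- toy_expr(c(mk(f1, 10, "a"), mk(f2, 10, "b"), mk(f3, 10, "c")))
  labels <- setNames(rep(1:3, each = 10), rownames(X$values))
  asg <- structure(list(labels = labels, params = list()),
                   class = "module_assignment")
  merged <- merge_modules(X, asg, merge_threshold = 0.25)
  expect_equal(length(unique(merged$labels)), 2)
  expect_equal(length(unique(merged$labels[1:20])), 1)

  same <- merge_modules(X, asg, merge_threshold = 0)
  expect_equal(table(same$labels), table(labels), ignore_attr = TRUE)

  # greedy smallest-dissimilarity-first is invariant to input label order
  relab <- setNames(c(3L, 1L, 2L)[labels], names(labels))
  asg2 <- structure(list(labels = relab, params = list()),
                    class = "module_assignment")
  merged2 <- merge_modules(X, asg2, merge_threshold = 0.25)
  expect_equal(adjusted_rand(merged$labels, merged2$labels), 1)
})

test_that("module-trait correlation matches the exact t-transform", {
  fx <- default_fixture()
  norm <- normalized_cohorts()
  me <- module_eigengenes(norm[[1]], default_assignment())
  tt <- fx$traits[[1]]
  res <- module_trait_table(me, tt, trait_cols = c("CAPS_total", "age"))
  for (i in sample(nrow(res), 4)) {
    m <- res$module[i]
    ct <- cor.test(me$values[m, tt$sample_id], tt[[res$trait[i]]])
    expect_equal(res$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(res$p[i], ct$p.value, tolerance = 1e-10)
  }
  # an eigengene used as its own trait correlates perfectly
  tt2 <- tt
  tt2$self <- me$values[1, tt$sample_id]
  res2 <- module_trait_table(me, tt2, trait_cols = "self")
  expect_equal(res2$r[res2$module == rownames(me$values)[1]], 1,
               tolerance = 1e-12)
  expect_error(module_trait_table(me, transform(tt, flat = 1),
                                  trait_cols = "flat"), "constant")
})

test_that("module-trait flags hold the nominal type-I rate under the null", {
  me <- module_eigengenes(normalized_cohorts()[[1]], default_assignment())
  n <- ncol(me$values)
  set.seed(10)
  reps <- 400
  null_traits <- matrix(rnorm(n * reps), nrow = n)
  r <- cor(t(me$values), null_traits)
  p <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  frac <- mean(p < 0.01)
  ci <- qbinom(c(0.0005, 0.9995), length(p), 0.01) / length(p)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("membership, significance, and hub statistics are consistent", {
  fx <- default_fixture()
  norm <- normalized_cohorts()
  asg <- default_assignment()
  me <- module_eigengenes(norm[[1]], asg)
  trait <- setNames(fx$traits[[1]]$CAPS_total, fx$traits[[1]]$sample_id)
  ms <- membership_and_significance(norm[[1]], me, trait, asg)

  # GS of the trait itself is 1
  Xplus <- expression_matrix(rbind(norm[[1]]$values,
                                   traitrow = trait[colnames(norm[[1]]$values)]),
                             "c1")
  ms2 <- membership_and_significance(Xplus, me, trait, asg)
  expect_equal(unname(ms2$GS["traitrow"]), 1, tolerance = 1e-12)

  # hub ranking by soft connectivity equals the row-sum oracle
  m1 <- names(asg$labels)[asg$labels == 1][1:10]
  sub <- norm[[1]]$values[m1, ]
  r <- cor(t(sub))
  oracle <- rowSums(r) - 1
  asg_small <- structure(list(labels = setNames(rep(1L, 10), m1)),
                         class = "module_assignment")
  Xs <- expression_matrix(sub, "c1")
  mes <- module_eigengenes(Xs, asg_small)
  ms3 <- membership_and_significance(Xs, mes, trait, asg_small)
  expect_equal(order(ms3$k_soft[m1]), order(oracle))
  expect_equal(unname(ms3$k_soft[m1]), unname(oracle), tolerance = 1e-10)

  # the strongest-loading feature attains the max |kME| in its module
  lambda <- fx$truth$loadings
  top <- names(which.max(lambda[asg$labels == 1 & fx$truth$module_labels == 1]))
  kme1 <- abs(ms$kME[names(asg$labels)[asg$labels == 1], "ME1"])
  expect_gte(kme1[top], quantile(kme1, 0.9))
})

test_that("pathway scores track the planted module factor", {
  fx <- default_fixture()
  norm <- normalized_cohorts()
  m1 <- names(fx$truth$module_labels)[fx$truth$module_labels == 1]
  sc <- pathway_sample_scores(norm[[1]], m1)
  f1 <- fx$truth$factors[[1]]["module1", ]
  expect_gte(abs(cor(sc, f1[names(sc)])), 0.9)

  # invariant to member order; identical members reproduce the profile
  sc2 <- pathway_sample_scores(norm[[1]], rev(m1))
  expect_equal(sc, sc2, tolerance = 1e-12)
  expect_error(pathway_sample_scores(norm[[1]], c("P0001", "nope", "nah")),
               "nope")
})
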