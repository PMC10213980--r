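# Shared fixtures are generated once per test run and cached in this
# environment; everything is deterministic given the configs below.
.cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.cache$fx)) .cache$fx <- generate_fixture(synth_config())
  .cache$fx
}

# default fixture after median normalization + log2, as the pipeline sees it
normalized_cohorts <- function() {
  if (is.null(.cache$norm))
    .cache$norm <- lapply(default_fixture()$expression, median_normalize,
                          log2 = TRUE)
  .cache$norm
}

consensus_tom <- function() {
  if (is.null(.cache$cons)) {
    toms <- lapply(normalized_cohorts(), function(x)
      topological_overlap(adjacency_from_expression(x, beta = 4)))
    .cache$toms <- toms
    .cache$cons <- consensus_overlap(toms)
  }
  .cache$cons
}

default_assignment <- function() {
  if (is.null(.cache$asg)) {
    norm <- normalized_cohorts()
    asg <- cut_modules(build_dendrogram(consensus_tom()), min_size = 30,
                       cut_height = 0.99, X = norm[[1]])
    .cache$asg <- merge_modules(norm[[1]], asg, merge_threshold = 0.25)
  }
  .cache$asg
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# tiny expression matrix with exactly controllable profiles
toy_expr <- function(rows, cohort = "toy") {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  expression_matrix(m, cohort)
}

# brute-force triple-loop TOM oracle
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    out[i, j] <- (L + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# random valid adjacency (symmetric, [0,1], unit diagonal)
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("f", 1:n), paste0("f", 1:n))
  a
}
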