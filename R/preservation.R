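#' Density and connectivity preservation statistics for one module
#'
#' Density is the mean off-diagonal adjacency among module members in the
#' test network; the connectivity statistic is the Pearson correlation
#' between the reference and test intramodular connectivity (kIM) vectors
#' over the members.
#'
#' @param members Character vector of module feature ids (>= 3).
#' @param ref_adj,test_adj `adjacency` objects (or matrices) covering the
#'   members.
#' @return List with `density` and `connectivity`.
#' @export
preservation_statistics <- function(members, ref_adj, test_adj) {
  if (length(members) < 3) stop("module size must be >= 3")
  ra <- if (inherits(ref_adj, "adjacency")) ref_adj$values else ref_adj
  ta <- if (inherits(test_adj, "adjacency")) test_adj$values else test_adj
  rs <- ra[members, members, drop = FALSE]
  ts <- ta[members, members, drop = FALSE]
  dens <- (sum(ts) - length(members)) / (length(members) * (length(members) - 1))
  kim_ref <- rowSums(rs) - 1
  kim_test <- rowSums(ts) - 1
  conn <- if (stats::sd(kim_ref) == 0 || stats::sd(kim_test) == 0) NA_real_
          else stats::cor(kim_ref, kim_test)
  list(density = dens, connectivity = conn)
}

#' Permutation Z-summary module preservation
#'
#' For each reference module, the observed density and connectivity
#' statistics in the test cohort are compared with a permutation null built
#' by drawing, per permutation, a uniform random feature set of the module's
#' size. Z = (observed - null mean)/null SD per statistic; Z_summary is the
#' median of the two. Classification: "high" when Z_summary > 10, "moderate"
#' when 5 <= Z_summary <= 10, "weak" otherwise.
#'
#' The null pool defaults to all features of the shared universe (the
#' canonical label-permutation null); restricting it to assigned
#' (nonzero-module) features is available via `null_pool = "assigned"` but
#' deflates preservation whenever most assigned features are genuinely
#' co-expressed, because the null then consists of mixtures of real modules.
#'
#' @param ref_assignment A `module_assignment` from the reference cohort.
#' @param ref_X,test_X `expr_mat` for reference and test cohorts (shared
#'   feature universe).
#' @param beta Soft-thresholding power for the preservation adjacencies
#'   (same as network construction; default 4).
#' @param n_permutations Number of null draws (default 300; < 50 warns).
#' @param seed Integer seed (required: the null is stochastic).
#' @param null_pool "all" (default) or "assigned".
#' @return A `preservation_result` data frame: one row per module with
#'   observed statistics, null means/SDs, Z_density, Z_connectivity,
#'   Z_summary, and `class`; attributes `n_permutations`, `seed`.
#' @export
preservation_zsummary <- function(ref_assignment, ref_X, test_X, beta = 4,
                                  n_permutations = 300, seed,
                                  null_pool = c("all", "assigned")) {
  if (missing(seed)) stop("seed is required")
  null_pool <- match.arg(null_pool)
  if (n_permutations < 50)
    warning("n_permutations < 50: Z estimates will be unstable")
  ref_adj <- adjacency_from_expression(ref_X, beta = beta)$values
  test_adj <- adjacency_from_expression(test_X, beta = beta)$values
  labels <- ref_assignment$labels
  labels <- labels[names(labels) %in% rownames(test_adj)]
  assigned <- if (null_pool == "assigned") names(labels)[labels > 0]
              else names(labels)
  mods <- sort(unique(labels[labels > 0]))
  set.seed(seed)
  rows <- lapply(mods, function(m) {
    members <- names(labels)[labels == m]
    obs <- preservation_statistics(members, ref_adj, test_adj)
    null_d <- numeric(n_permutations)
    null_c <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      pick <- sample(assigned, length(members))
      st <- preservation_statistics(pick, ref_adj, test_adj)
      null_d[b] <- st$density
      null_c[b] <- st$connectivity
    }
    zval <- function(o, nl) {
      s <- stats::sd(nl)
      if (s == 0) return(structure(Inf, degenerate = TRUE))
      (o - mean(nl)) / s
    }
    zd <- zval(obs$density, null_d)
    zc <- zval(obs$connectivity, null_c)
    zs <- stats::median(c(zd, zc))
    data.frame(module = m, size = length(members),
               density_obs = obs$density, density_null_mean = mean(null_d),
               density_null_sd = stats::sd(null_d),
               connectivity_obs = obs$connectivity,
               connectivity_null_mean = mean(null_c),
               connectivity_null_sd = stats::sd(null_c),
               Z_density = as.numeric(zd), Z_connectivity = as.numeric(zc),
               Z_summary = as.numeric(zs),
               class = if (zs > 10) "high" else if (zs >= 5) "moderate" else "weak",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  class(out) <- c("preservation_result", "data.frame")
  out
}
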