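#' Soft-thresholded adjacency from expression
#'
#' Pairwise Pearson correlation of feature profiles raised elementwise to the
#' soft-thresholding power beta. The default is the unsigned network
#' a_ij = |cor(x_i, x_j)|^beta; a signed variant ((1 + r)/2)^beta is exposed
#' behind `mode = "signed"` but is not the default. The diagonal is set to 1
#' by convention.
#'
#' Missing values are an error: silent pairwise-complete correlations break
#' the topological-overlap guarantees. Use `impute = "mean"` to mean-impute
#' per feature beforehand.
#'
#' @param X An `expr_mat` or named features x samples matrix (at least 3
#'   samples).
#' @param beta Soft-thresholding power, >= 1 (default 4).
#' @param mode "unsigned" (default) or "signed".
#' @param impute "none" (default; missing values error) or "mean".
#' @return An `adjacency` object: list with `values` (symmetric matrix in
#'   [0,1]), `beta`, `mode`.
#' @export
adjacency_from_expression <- function(X, beta = 4, mode = c("unsigned", "signed"),
                                      impute = c("none", "mean")) {
  mode <- match.arg(mode)
  impute <- match.arg(impute)
  v <- expr_values(X)
  if (ncol(v) < 3) stop("need at least 3 samples")
  if (beta < 1) stop("beta must be >= 1")
  if (anyNA(v)) {
    if (impute == "none")
      stop("missing values in expression; re-run with impute = \"mean\" ",
           "or impute upstream")
    rm_ <- rowMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- rm_[idx[, 1]]
  }
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(rownames(v)[sds == 0], collapse = ", "))
  r <- stats::cor(t(v))
  a <- if (mode == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 1
  structure(list(values = a, beta = beta, mode = mode), class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %d features, beta = %g, mode = %s\n",
              nrow(x$values), x$beta, x$mode))
  invisible(x)
}

# scale-free fit index: connectivity binned into `nbins` equal-count bins;
# density per bin estimated as count/(n * width) so that variable-width
# bins carry information; R^2 of log10(density) on log10(mean k), signed
# negative when the slope is positive.
scale_free_fit <- function(k, nbins = 10) {
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = nbins + 1)))
  if (length(br) < 3) return(NA_real_)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  cnt <- tabulate(bin, nbins = nlevels(bin))
  width <- diff(br)
  dens <- cnt / (length(k) * width)
  keep <- dens > 0 & dk > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(dens[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] > 0) -r2 else r2
}

#' Scan soft-thresholding powers for approximate scale-free topology
#'
#' For each candidate power, computes the connectivity k_i = sum_{j != i}
#' a_ij, the scale-free model fit R^2 (signed negative when the log-log
#' slope is positive, as a scale-free degree distribution must have a
#' negative slope), and the mean connectivity.
#'
#' @param X An `expr_mat` or named matrix (>= 20 features).
#' @param powers Numeric vector of candidate powers.
#' @param mode Passed to [adjacency_from_expression()].
#' @return Data frame with columns `power`, `sft_r2`, `mean_k`.
#' @export
soft_threshold_scan <- function(X, powers = c(1:10, 12, 14, 16, 18, 20),
                                mode = "unsigned") {
  if (length(powers) == 0) stop("powers must be nonempty")
  v <- expr_values(X)
  if (nrow(v) < 20) stop("need at least 20 features for degree binning")
  base <- adjacency_from_expression(X, beta = 1, mode = mode)$values
  out <- lapply(powers, function(p) {
    a <- base^p
    k <- rowSums(a) - 1
    data.frame(power = p, sft_r2 = scale_free_fit(k), mean_k = mean(k))
  })
  do.call(rbind, out)
}

#' Topological overlap matrix
#'
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) where
#' L_ij = sum_{u != i,j} a_iu a_uj and k_i = sum_{u != i} a_iu; the diagonal
#' is fixed at 1 (so dissimilarity 1 - TOM has a zero diagonal).
#'
#' @param adj An `adjacency` object (or symmetric matrix in [0,1] with unit
#'   diagonal).
#' @return An `overlap` object: list with `values`, `kind = "single"`.
#' @export
topological_overlap <- function(adj) {
  a <- if (inherits(adj, "adjacency")) adj$values else adj
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  n <- nrow(a)
  k <- rowSums(a) - 1
  # (A %*% A)_ij includes u = i and u = j terms; with unit diagonal each
  # contributes a_ij, hence the -2a correction off-diagonal.
  L <- a %*% a - 2 * a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  structure(list(values = tom, kind = "single"), class = "overlap")
}

#' @export
print.overlap <- function(x, ...) {
  cat(sprintf("<overlap> %d features (%s)\n", nrow(x$values), x$kind))
  invisible(x)
}

#' Consensus topological overlap across cohorts
#'
#' Component-wise ("parallel") minimum of the single-cohort TOMs, so the
#' consensus records only overlap supported in every cohort.
#'
#' @param toms List of >= 2 `overlap` objects over identical feature ids in
#'   identical order.
#' @return An `overlap` object with `kind = "consensus"`.
#' @export
consensus_overlap <- function(toms) {
  if (length(toms) < 2) stop("need at least 2 overlap matrices")
  ids <- lapply(toms, function(t) rownames(t$values))
  for (i in seq_along(ids)[-1]) {
    if (!identical(ids[[1]], ids[[i]])) {
      d <- union(setdiff(ids[[1]], ids[[i]]), setdiff(ids[[i]], ids[[1]]))
      stop("feature sets differ",
           if (length(d)) paste0(" (symmetric difference: ",
                                 paste(utils::head(d, 10), collapse = ", "), ")")
           else " (same features, different order)")
    }
  }
  v <- Reduce(pmin, lapply(toms, `[[`, "values"))
  structure(list(values = v, kind = "consensus"), class = "overlap")
}
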