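# standardize rows of a features x samples matrix
.std_rows <- function(m) {
  s <- apply(m, 1, stats::sd)
  if (any(s == 0))
    stop("zero-variance feature(s): ", paste(rownames(m)[s == 0], collapse = ", "))
  (m - rowMeans(m)) / s
}

# first principal component across samples of a standardized member matrix,
# sign-oriented so its correlation with the mean member profile is >= 0;
# returns list(score, var_explained), score scaled to unit variance
first_pc <- function(z) {
  sv <- svd(z, nu = 0, nv = 1)
  score <- sv$v[, 1]
  mean_profile <- colMeans(z)
  if (stats::sd(mean_profile) > 0 && stats::cor(score, mean_profile) < 0)
    score <- -score
  score <- score / stats::sd(score)
  list(score = score, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Leading eigenvalue and eigenvector of a square matrix
#'
#' Thin wrapper over the base eigen-solver returning the eigenpair with the
#' largest-magnitude eigenvalue; the eigenvector is scaled so its smallest
#' nonzero entry is 1, which makes small worked examples read naturally
#' (e.g. the 2x2 matrix rbind(c(2,1), c(4,2)) has leading eigenvalue 4 with
#' eigenvector (1, 2)).
#'
#' @param A Square numeric matrix.
#' @return List with `value` and `vector`.
#' @export
leading_eigen <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  e <- eigen(A)
  i <- which.max(abs(e$values))
  val <- e$values[i]
  vec <- e$vectors[, i]
  if (is.complex(val) && all(abs(Im(c(val, vec))) < 1e-12)) {
    val <- Re(val); vec <- Re(vec)
  }
  nz <- vec[abs(vec) > 1e-12]
  if (length(nz)) vec <- vec / nz[which.min(abs(nz))]
  list(value = val, vector = vec)
}

#' Average-linkage dendrogram on topological-overlap dissimilarity
#'
#' @param tom An `overlap` object (or symmetric similarity matrix).
#' @return An `hclust` tree on dissimilarity 1 - TOM.
#' @export
build_dendrogram <- function(tom) {
  v <- if (inherits(tom, "overlap")) tom$values else tom
  if (nrow(v) < 2) stop("need at least 2 features")
  stats::hclust(stats::as.dist(1 - v), method = "average")
}

# renumber labels 1..M by decreasing module size (0 stays 0)
.renumber_by_size <- function(labels) {
  nz <- labels[labels > 0]
  if (length(nz) == 0) return(labels)
  sizes <- sort(table(nz), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  out <- labels
  out[labels > 0] <- remap[as.character(nz)]
  stats::setNames(as.integer(out), names(labels))
}

#' Cut a dendrogram into modules
#'
#' Static cut at `cut_height` times the maximum merge height; clusters
#' smaller than `min_size` are relabeled 0 (the "grey"/unassigned role).
#' When expression is supplied, an optional reassignment pass attaches each
#' unassigned feature to the module maximizing |kME| provided
#' |kME| >= `kme_reattach`. Labels are renumbered by decreasing size.
#'
#' @param dend `hclust` tree from [build_dendrogram()].
#' @param min_size Minimum module size (default 30, must be >= 2).
#' @param cut_height Fraction of the maximum merge height in (0, 1]
#'   (default 0.99).
#' @param X Optional `expr_mat` enabling the kME reattachment pass.
#' @param kme_reattach |kME| threshold for reattachment (default 0.3).
#' @return A `module_assignment`: list with `labels` (named integer vector,
#'   0 = unassigned), `dendrogram`, `params`.
#' @export
cut_modules <- function(dend, min_size = 30, cut_height = 0.99,
                        X = NULL, kme_reattach = 0.3) {
  if (min_size < 2) stop("min_size must be >= 2")
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must be in (0, 1]")
  h <- cut_height * max(dend$height)
  raw <- stats::cutree(dend, h = h)
  sizes <- table(raw)
  labels <- ifelse(sizes[as.character(raw)] >= min_size, raw, 0L)
  names(labels) <- dend$labels
  labels <- .renumber_by_size(labels)

  if (!is.null(X) && any(labels == 0) && any(labels > 0)) {
    me <- module_eigengenes(X, structure(list(labels = labels),
                                         class = "module_assignment"))
    v <- .std_rows(expr_values(X)[names(labels), , drop = FALSE])
    grey <- names(labels)[labels == 0]
    kme <- stats::cor(t(v[grey, , drop = FALSE]), t(me$values))
    best <- max.col(abs(kme), ties.method = "first")
    best_val <- abs(kme)[cbind(seq_along(grey), best)]
    attach_ok <- best_val >= kme_reattach
    labels[grey[attach_ok]] <- as.integer(best[attach_ok])
    labels <- .renumber_by_size(labels)
  }
  structure(list(labels = labels, dendrogram = dend,
                 params = list(min_size = min_size, cut_height = cut_height,
                               kme_reattach = kme_reattach)),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("<module_assignment> %d features, %d modules (+%d unassigned)\n",
              length(x$labels), sum(names(tb) != "0"),
              if ("0" %in% names(tb)) tb[["0"]] else 0L))
  invisible(x)
}

#' Module eigengenes (first principal component per module)
#'
#' Each module's member rows are standardized and the first principal
#' component across samples taken as the module's per-sample summary
#' profile, scaled to unit variance and sign-oriented so it correlates
#' non-negatively with the module's mean standardized expression. Variance
#' explained is the leading eigenvalue of the member covariance over its
#' trace.
#'
#' @param X An `expr_mat` containing all assigned features.
#' @param assignment A `module_assignment`.
#' @return An `eigengene_matrix`: list with `values` (modules x samples),
#'   `var_explained`.
#' @export
module_eigengenes <- function(X, assignment) {
  v <- expr_values(X)
  labels <- assignment$labels
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("no assigned modules")
  scores <- matrix(NA_real_, nrow = length(mods), ncol = ncol(v),
                   dimnames = list(paste0("ME", mods), colnames(v)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    members <- names(labels)[labels == mods[i]]
    if (length(members) < 2) stop("module ", mods[i], " has < 2 members")
    missing <- setdiff(members, rownames(v))
    if (length(missing))
      stop("features missing from expression: ", paste(missing, collapse = ", "))
    pc <- first_pc(.std_rows(v[members, , drop = FALSE]))
    scores[i, ] <- pc$score
    ve[i] <- pc$var_explained
  }
  structure(list(values = scores, var_explained = ve),
            class = "eigengene_matrix")
}

#' @export
print.eigengene_matrix <- function(x, ...) {
  cat(sprintf("<eigengene_matrix> %d modules x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Merge modules with similar eigengenes
#'
#' Greedy smallest-dissimilarity-first merging of module pairs whose
#' eigengene dissimilarity 1 - cor(ME_a, ME_b) is below `merge_threshold`;
#' eigengenes are recomputed after each merge until no pair qualifies.
#'
#' @param X An `expr_mat`.
#' @param assignment A `module_assignment`.
#' @param merge_threshold Dissimilarity cutoff (default 0.25).
#' @return A `module_assignment` with merged, size-renumbered labels.
#' @export
merge_modules <- function(X, assignment, merge_threshold = 0.25) {
  labels <- assignment$labels
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    me <- module_eigengenes(X, structure(list(labels = labels),
                                         class = "module_assignment"))
    d <- 1 - stats::cor(t(me$values))
    diag(d) <- Inf
    if (min(d) >= merge_threshold) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    a <- mods[ij[1]]; b <- mods[ij[2]]
    labels[labels == b] <- a
  }
  labels <- .renumber_by_size(labels)
  structure(list(labels = labels, dendrogram = assignment$dendrogram,
                 params = c(assignment$params,
                            list(merge_threshold = merge_threshold))),
            class = "module_assignment")
}

# Pearson r -> two-sided Student-t p at n-2 df
.cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Correlate module eigengenes with clinical traits
#'
#' Pearson r with the two-sided Student-t p at n - 2 df per (module, trait);
#' modules with p < `flag_p` against any trait are flagged as
#' trait-correlated.
#'
#' @param eigengenes An `eigengene_matrix`.
#' @param traits Trait data frame with a `sample_id` column; `group`
#'   (case/control) is coded 1/0.
#' @param trait_cols Columns to correlate (default: `group` plus all numeric
#'   columns except sample bookkeeping).
#' @param flag_p Significance flag threshold (default 0.01).
#' @return Data frame (module, trait, r, p, n, flagged).
#' @export
module_trait_table <- function(eigengenes, traits,
                               trait_cols = NULL, flag_p = 0.01) {
  me <- eigengenes$values
  common <- intersect(colnames(me), traits$sample_id)
  if (length(common) < 10) stop("need sample overlap >= 10")
  traits <- traits[match(common, traits$sample_id), , drop = FALSE]
  me <- me[, common, drop = FALSE]
  if (is.null(trait_cols)) {
    num <- names(traits)[vapply(traits, is.numeric, logical(1))]
    trait_cols <- c(if ("group" %in% names(traits)) "group",
                    setdiff(num, c("sample_id")))
  }
  tv <- lapply(trait_cols, function(tc) {
    x <- traits[[tc]]
    if (tc == "group" && !is.numeric(x)) x <- as.numeric(x == "case")
    x
  })
  names(tv) <- trait_cols
  keep <- !vapply(tv, function(x) all(is.na(x)), logical(1))
  tv <- tv[keep]
  out <- list()
  for (tc in names(tv)) {
    x <- tv[[tc]]
    ok <- !is.na(x)
    if (stats::sd(x[ok]) == 0) stop("constant trait: ", tc)
    r <- as.numeric(stats::cor(t(me[, ok, drop = FALSE]), x[ok]))
    n <- sum(ok)
    out[[tc]] <- data.frame(module = rownames(me), trait = tc, r = r,
                            p = .cor_pvalue(r, n), n = n,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$flagged <- res$p < flag_p
  rownames(res) <- NULL
  res
}

#' Module membership, trait significance, and soft connectivity
#'
#' kME_im = cor(x_i, ME_m) (module membership); GS_i = |cor(x_i, trait)|
#' (feature significance); soft connectivity of a feature is the sum of its
#' correlations with the other members of its own module (hub measure).
#'
#' @param X An `expr_mat`.
#' @param eigengenes An `eigengene_matrix`.
#' @param trait Numeric vector named by sample id (or aligned with columns).
#' @param assignment A `module_assignment` (for soft connectivity).
#' @return List with `kME` (features x modules), `GS` (named vector), and
#'   `k_soft` (named vector, NA for unassigned features).
#' @export
membership_and_significance <- function(X, eigengenes, trait, assignment) {
  v <- .std_rows(expr_values(X))
  me <- eigengenes$values[, colnames(v), drop = FALSE]
  kME <- stats::cor(t(v), t(me))
  if (!is.null(names(trait))) trait <- trait[colnames(v)]
  GS <- abs(as.numeric(stats::cor(t(v), trait)))
  names(GS) <- rownames(v)
  labels <- assignment$labels[intersect(rownames(v), names(assignment$labels))]
  k_soft <- stats::setNames(rep(NA_real_, nrow(v)), rownames(v))
  for (m in sort(unique(labels[labels > 0]))) {
    members <- names(labels)[labels == m]
    r <- stats::cor(t(v[members, , drop = FALSE]))
    k_soft[members] <- rowSums(r) - 1
  }
  list(kME = kME, GS = GS, k_soft = k_soft)
}

#' Per-sample pathway scores by dimension reduction
#'
#' First principal component of the standardized member submatrix — the
#' same summary used for module eigengenes — giving one value per sample
#' for the pathway.
#'
#' @param X An `expr_mat`.
#' @param members Character vector of member feature ids (>= 2 present).
#' @return Named numeric vector of per-sample scores (unit variance).
#' @export
pathway_sample_scores <- function(X, members) {
  v <- expr_values(X)
  present <- intersect(members, rownames(v))
  if (length(present) < 2) {
    missing <- setdiff(members, rownames(v))
    stop("fewer than 2 member features found; missing: ",
         paste(missing, collapse = ", "))
  }
  pc <- first_pc(.std_rows(v[present, , drop = FALSE]))
  stats::setNames(pc$score, colnames(v))
}
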