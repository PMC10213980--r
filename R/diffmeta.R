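#' Median signal normalization
#'
#' Scales each sample so its median equals the global median of sample
#' medians, removing inter-sample level differences. Optionally log2-
#' transforms afterwards (requires positive values).
#'
#' @param X An `expr_mat` with positive abundances.
#' @param log2 Apply log2 after scaling (default FALSE).
#' @return A normalized `expr_mat`.
#' @export
median_normalize <- function(X, log2 = FALSE) {
  v <- expr_values(X)
  if (any(v <= 0)) stop("median normalization requires positive abundances")
  med <- apply(v, 2, stats::median)
  target <- stats::median(med)
  v <- sweep(v, 2, target / med, `*`)
  if (log2) {
    if (any(v <= 0)) stop("log2 requires positive values")
    v <- base::log2(v)
  }
  expression_matrix(v, if (inherits(X, "expr_mat")) X$cohort_id else "cohort")
}

# design-matrix builder with collinearity check; returns model matrix
.build_design <- function(traits, covariates) {
  g <- as.numeric(traits$group == "case")
  cols <- list("(Intercept)" = rep(1, nrow(traits)), group = g)
  for (cv in covariates) {
    x <- traits[[cv]]
    if (is.null(x)) stop("covariate not found in trait table: ", cv)
    if (is.character(x) || is.factor(x)) {
      f <- factor(x)
      if (nlevels(f) > 1) {
        dmat <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(dmat) <- paste0(cv, levels(f)[-1])
        for (j in colnames(dmat)) cols[[j]] <- dmat[, j]
      }
    } else {
      cols[[cv]] <- as.numeric(x)
    }
  }
  mm <- do.call(cbind, cols)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("collinear design columns: ", paste(bad, collapse = ", "))
  }
  mm
}

#' Per-cohort covariate-adjusted differential abundance
#'
#' Ordinary least-squares fit of each standardized feature on the
#' case/control indicator plus covariates; t and two-sided p from the
#' residual degrees of freedom. Cohen's d is the group coefficient (the
#' covariate-adjusted case-minus-control difference) divided by the pooled
#' residual SD, optionally with the Hedges small-sample correction.
#'
#' @param X An `expr_mat` (already normalized/log-transformed as desired).
#' @param traits Trait data frame with `sample_id`, `group`, and covariates.
#' @param covariates Character vector of covariate column names.
#' @param hedges Apply the Hedges g correction to d (default FALSE).
#' @return Data frame (feature_id, coef, se, t, p, d, n_case, n_control)
#'   with attribute `covariates`.
#' @export
differential_expression <- function(X, traits, covariates = character(),
                                    hedges = FALSE) {
  v <- expr_values(X)
  common <- intersect(colnames(v), traits$sample_id)
  traits <- traits[match(common, traits$sample_id), , drop = FALSE]
  v <- v[, common, drop = FALSE]
  n_case <- sum(traits$group == "case")
  n_ctrl <- sum(traits$group == "control")
  if (n_case < 3 || n_ctrl < 3) stop("need >= 3 samples per group")
  z <- .std_rows(v)
  mm <- .build_design(traits, covariates)
  qr_ <- qr(mm)
  coefs <- qr.coef(qr_, t(z))               # p_design x features
  resid <- t(z) - mm %*% coefs
  df <- nrow(mm) - ncol(mm)
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- solve(crossprod(mm))
  se_g <- sqrt(sigma2 * xtx_inv["group", "group"])
  beta <- coefs["group", ]
  tstat <- beta / se_g
  p <- 2 * stats::pt(-abs(tstat), df = df)
  # pooled residual SD across groups for d
  g <- traits$group == "case"
  rss_case <- colSums(resid[g, , drop = FALSE]^2)
  rss_ctrl <- colSums(resid[!g, , drop = FALSE]^2)
  s_pool <- sqrt((rss_case + rss_ctrl) / (n_case + n_ctrl - 2))
  d <- beta / s_pool
  if (hedges) d <- d * (1 - 3 / (4 * (n_case + n_ctrl) - 9))
  out <- data.frame(feature_id = rownames(z), coef = beta, se = se_g,
                    t = tstat, p = p, d = d,
                    n_case = n_case, n_control = n_ctrl,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "covariates") <- covariates
  out
}

#' Stouffer's weighted combined probability test
#'
#' Per feature, Z_k = sign_k * qnorm(1 - p_k/2); weights w_k = sqrt(n_k);
#' Z_comb = sum(w_k Z_k) / sqrt(sum(w_k^2)); combined two-sided
#' p = 2 * (1 - pnorm(|Z_comb|)). Zero p-values are clamped to the smallest
#' representable double with a warning.
#'
#' @param p Matrix features x cohorts of two-sided p-values (a vector is one
#'   feature).
#' @param sign Matrix of effect signs in {-1, +1}, same shape.
#' @param n Vector of cohort sample sizes.
#' @return List with `z` and `p` (vectors over features).
#' @export
stouffer_combine <- function(p, sign, n) {
  if (is.vector(p)) p <- matrix(p, nrow = 1)
  if (is.vector(sign)) sign <- matrix(sign, nrow = 1)
  stopifnot(identical(dim(p), dim(sign)), length(n) == ncol(p),
            all(sign %in% c(-1, 1)))
  if (any(p <= 0)) {
    warning("p-values of 0 clamped to the smallest representable value")
    p[p <= 0] <- .Machine$double.xmin
  }
  if (any(p > 1)) stop("p-values must be in (0, 1]")
  zk <- sign * stats::qnorm(1 - p / 2)
  w <- sqrt(n)
  zc <- as.numeric(zk %*% w) / sqrt(sum(w^2))
  list(z = zc, p = 2 * stats::pnorm(-abs(zc)))
}

#' Multiple-testing adjustment
#'
#' Step-up false-discovery-rate corrections (Benjamini-Yekutieli by
#' default, valid under arbitrary dependence; Benjamini-Hochberg) or
#' Bonferroni, via [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param method "BY", "BH", or "bonferroni".
#' @return Adjusted q-values, input order preserved.
#' @export
adjust_pvalues <- function(p, method = c("BY", "BH", "bonferroni")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Fixed weights w_k = 1/v_k give the fixed-effect pool and Cochran's
#' Q = sum(w_k (d_k - d_FE)^2); tau^2 = max(0, (Q - (K-1)) /
#' (sum(w) - sum(w^2)/sum(w))); random-effects weights 1/(v_k + tau^2) give
#' the pooled effect, SE = 1/sqrt(sum(weights)), z and two-sided p; Q_p from
#' the chi-square with K-1 df.
#'
#' @param d Matrix features x cohorts of effect sizes (vector = one feature).
#' @param v Matrix of within-cohort effect variances (> 0), same shape.
#' @return Data frame (pooled_d, se, z, p, Q, Q_df, Q_p, tau2) per feature.
#' @export
random_effects_meta <- function(d, v) {
  if (is.vector(d)) d <- matrix(d, nrow = 1)
  if (is.vector(v)) v <- matrix(v, nrow = 1)
  stopifnot(identical(dim(d), dim(v)))
  K <- ncol(d)
  if (K < 2) stop("need K >= 2 cohorts")
  if (any(v <= 0)) stop("variances must be > 0")
  w <- 1 / v
  sw <- rowSums(w)
  d_fe <- rowSums(w * d) / sw
  Q <- rowSums(w * (d - d_fe)^2)
  cc <- sw - rowSums(w^2) / sw
  tau2 <- pmax(0, (Q - (K - 1)) / cc)
  wr <- 1 / (v + tau2)
  swr <- rowSums(wr)
  pooled <- rowSums(wr * d) / swr
  se <- 1 / sqrt(swr)
  z <- pooled / se
  data.frame(pooled_d = pooled, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)),
             Q = Q, Q_df = K - 1,
             Q_p = stats::pchisq(Q, df = K - 1, lower.tail = FALSE),
             tau2 = tau2)
}

#' Direction-consistency filter across cohorts
#'
#' A feature passes when its effect sign is identical in every cohort and
#' its per-cohort p-value is below `p_threshold` ("at least somewhat
#' significant") in every cohort.
#'
#' @param de_list List (>= 2) of per-cohort differential results
#'   ([differential_expression()] output) over the same features.
#' @param p_threshold Per-cohort significance filter (default 0.1).
#' @return Named logical vector per feature.
#' @export
direction_consistency <- function(de_list, p_threshold = 0.1) {
  if (length(de_list) < 2) stop("need >= 2 cohorts")
  ids <- de_list[[1]]$feature_id
  for (de in de_list[-1]) stopifnot(identical(de$feature_id, ids))
  signs <- sapply(de_list, function(de) sign(de$coef))
  ps <- sapply(de_list, function(de) de$p)
  flag <- apply(signs, 1, function(s) length(unique(s)) == 1 && all(s != 0)) &
    apply(ps, 1, function(x) all(x < p_threshold))
  stats::setNames(flag, ids)
}

#' Cross-cohort meta-analysis of differential results
#'
#' Combines per-cohort regression outputs: Stouffer weighted Z with BY q;
#' DerSimonian-Laird random-effects pooling of Cohen's d (variance
#' v_k = (n1+n2)/(n1 n2) + d^2/(2(n1+n2))) with Cochran's Q; and the
#' direction-consistency flag.
#'
#' @param de_list List of per-cohort [differential_expression()] outputs
#'   over identical features.
#' @param direction_p Direction-filter per-cohort threshold (default 0.1).
#' @param adjust Correction for the Stouffer combined p (default "BY").
#' @return Data frame (feature_id, stouffer_z, stouffer_p, stouffer_q,
#'   pooled_d, rem_se, rem_z, rem_p, Q, Q_p, tau2, direction_consistent).
#' @export
meta_analyze <- function(de_list, direction_p = 0.1, adjust = "BY") {
  stopifnot(length(de_list) >= 2)
  ids <- de_list[[1]]$feature_id
  p <- sapply(de_list, function(de) de$p)
  s <- sapply(de_list, function(de) ifelse(de$coef >= 0, 1, -1))
  n <- vapply(de_list, function(de) de$n_case[1] + de$n_control[1], numeric(1))
  st <- stouffer_combine(p, s, n)
  d <- sapply(de_list, function(de) de$d)
  nc <- vapply(de_list, function(de) de$n_case[1], numeric(1))
  nn <- vapply(de_list, function(de) de$n_control[1], numeric(1))
  v <- sweep(d^2, 2, 2 * (nc + nn), `/`) +
    matrix(rep((nc + nn) / (nc * nn), each = nrow(d)), nrow = nrow(d))
  rem <- random_effects_meta(d, v)
  data.frame(feature_id = ids,
             stouffer_z = st$z, stouffer_p = st$p,
             stouffer_q = adjust_pvalues(st$p, adjust),
             pooled_d = rem$pooled_d, rem_se = rem$se, rem_z = rem$z,
             rem_p = rem$p, Q = rem$Q, Q_p = rem$Q_p, tau2 = rem$tau2,
             direction_consistent =
               unname(direction_consistency(de_list, direction_p)),
             stringsAsFactors = FALSE)
}

#' Persistent-feature intersection across evidence routes
#'
#' Default rule: members of preserved AND trait-correlated modules,
#' intersected with training-cohort FDR q < `training_q`, with
#' meta-analytic significance (Stouffer q < `meta_q` OR random-effects
#' p < `rem_p`; "and" combinable via `meta_rule`), and with the
#' direction-consistency flag. Every member carries per-route provenance.
#'
#' @param module_members Character vector: member features of preserved,
#'   trait-correlated modules (the module route). `NULL` drops the route
#'   (with a notice), e.g. when preservation was not run.
#' @param training_de Training-cohort [differential_expression()] output.
#' @param meta [meta_analyze()] output on the same feature universe.
#' @param training_q Training FDR threshold (default 0.1).
#' @param training_method FDR flavor for training (default "BH").
#' @param meta_q Stouffer BY q threshold (default 0.05).
#' @param rem_p Random-effects p threshold (default 0.05).
#' @param meta_rule "or" (default) or "and" combination of the two
#'   meta-analytic routes.
#' @return A `persistent_set` data frame of passing features with logical
#'   provenance columns (route_module, route_training, route_meta,
#'   route_direction); attribute `rule` records the rule string.
#' @export
persistent_feature_set <- function(module_members, training_de, meta,
                                   training_q = 0.1, training_method = "BH",
                                   meta_q = 0.05, rem_p = 0.05,
                                   meta_rule = c("or", "and")) {
  meta_rule <- match.arg(meta_rule)
  if (!identical(sort(training_de$feature_id), sort(meta$feature_id)))
    stop("feature universe mismatch between training DE and meta results")
  ids <- meta$feature_id
  tq <- adjust_pvalues(training_de$p, training_method)
  route_training <- stats::setNames(tq < training_q, training_de$feature_id)[ids]
  m_st <- meta$stouffer_q < meta_q
  m_rem <- meta$rem_p < rem_p
  route_meta <- if (meta_rule == "or") m_st | m_rem else m_st & m_rem
  route_direction <- meta$direction_consistent
  if (is.null(module_members)) {
    message("module route disabled (no preserved/trait-correlated module set)")
    route_module <- rep(TRUE, length(ids))
    rule <- "training & meta & direction"
  } else {
    if (length(setdiff(module_members, ids)))
      stop("module members outside the feature universe: ",
           paste(utils::head(setdiff(module_members, ids), 5), collapse = ", "))
    route_module <- ids %in% module_members
    rule <- "module & training & meta & direction"
  }
  pass <- route_module & route_training & route_meta & route_direction
  out <- data.frame(feature_id = ids,
                    route_module = route_module,
                    route_training = unname(route_training),
                    route_meta = route_meta,
                    route_direction = route_direction,
                    stringsAsFactors = FALSE)[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rule") <- sprintf("%s (training %s q<%g; meta: stouffer BY q<%g %s REM p<%g; direction p-filter upstream)",
                               rule, training_method, training_q, meta_q,
                               toupper(meta_rule), rem_p)
  class(out) <- c("persistent_set", "data.frame")
  out
}
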