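#' Minor allele frequency from additively coded dosages
#'
#' Coded-allele frequency f = sum(dosage) / (2 * n_nonmissing); the MAF is
#' min(f, 1 - f).
#'
#' @param dosages Numeric vector of 0/1/2 dosages, NA = missing.
#' @return MAF in [0, 0.5].
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0) stop("all dosages missing")
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' Candidate cis variant-gene pairs within a window
#'
#' A pair is emitted when variant and gene share a chromosome and the
#' distance from the variant to the nearest gene-body edge is at most
#' `window` (inclusive boundary; 0 when the variant lies inside the gene).
#' Distance is signed: negative upstream of the gene start, positive
#' downstream of the end. Coordinates are 1-based inclusive throughout; no
#' strand logic.
#'
#' @param genes Data frame feature_id/chrom/start/end.
#' @param variant_map Data frame variant_id/chrom/pos.
#' @param window Maximum distance in bp (default 1e6).
#' @return Data frame (variant_id, feature_id, distance).
#' @export
cis_candidate_pairs <- function(genes, variant_map, window = 1e6) {
  if (any(is.na(genes$chrom)) || any(!nzchar(genes$chrom)))
    stop("unknown (missing) chromosome in gene table")
  if (any(is.na(variant_map$chrom)) || any(!nzchar(variant_map$chrom)))
    stop("unknown (missing) chromosome in variant table")
  out <- list()
  for (ch in unique(variant_map$chrom)) {
    vm <- variant_map[variant_map$chrom == ch, , drop = FALSE]
    gn <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(gn) == 0) next
    for (i in seq_len(nrow(vm))) {
      pos <- vm$pos[i]
      dist <- ifelse(pos < gn$start, pos - gn$start,
                     ifelse(pos > gn$end, pos - gn$end, 0))
      keep <- abs(dist) <= window
      if (any(keep)) {
        out[[length(out) + 1]] <- data.frame(
          variant_id = vm$variant_id[i],
          feature_id = gn$feature_id[keep],
          distance = dist[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(variant_id = character(0), feature_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Additive-genotype cis-pQTL scan
#'
#' For each candidate pair with MAF above `maf_min` (strict), ordinary
#' least squares of the standardized protein level on the dosage (plus
#' optional covariates) over non-missing samples; BH correction across all
#' emitted rows. Pairs with fewer than 10 usable samples are skipped;
#' MAF-filtered and skipped counts are recorded in attributes.
#'
#' @param X An `expr_mat` of (normalized) protein levels.
#' @param genotypes A `geno_mat` sharing sample ids with `X`.
#' @param pairs Data frame from [cis_candidate_pairs()].
#' @param traits Optional trait data frame supplying covariates.
#' @param covariates Covariate column names in `traits`.
#' @param maf_min MAF threshold, exclusive lower bound (default 0.05).
#' @param adjust FDR method across emitted rows (default "BH").
#' @param sig_q "Significant" tier q threshold (default 0.05).
#' @param suggestive_p "Suggestive" tier p threshold (default 1e-3).
#' @return Data frame (variant_id, feature_id, distance, maf, n, beta, se,
#'   t, p, q, tier) with attributes `n_maf_filtered`, `n_skipped`.
#' @export
pqtl_scan <- function(X, genotypes, pairs, traits = NULL,
                      covariates = character(), maf_min = 0.05,
                      adjust = "BH", sig_q = 0.05, suggestive_p = 1e-3) {
  v <- expr_values(X)
  z <- .std_rows(v)
  sid <- intersect(colnames(z), colnames(genotypes$dosages))
  if (length(sid) < 10) stop("fewer than 10 shared samples")
  z <- z[, sid, drop = FALSE]
  dos <- genotypes$dosages[, sid, drop = FALSE]
  cov_mat <- NULL
  if (length(covariates)) {
    stopifnot(!is.null(traits))
    tr <- traits[match(sid, traits$sample_id), , drop = FALSE]
    cov_mat <- do.call(cbind, lapply(covariates, function(cv) {
      x <- tr[[cv]]
      if (is.character(x) || is.factor(x)) as.numeric(factor(x)) else as.numeric(x)
    }))
    colnames(cov_mat) <- covariates
  }
  n_maf_filtered <- 0L
  n_skipped <- 0L
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    vi <- pairs$variant_id[i]; fe <- pairs$feature_id[i]
    if (!vi %in% rownames(dos) || !fe %in% rownames(z)) next
    g <- dos[vi, ]
    ok <- !is.na(g)
    if (sum(ok) < 10) { n_skipped <- n_skipped + 1L; next }
    maf <- minor_allele_frequency(g[ok])
    if (maf <= maf_min) { n_maf_filtered <- n_maf_filtered + 1L; next }
    y <- z[fe, ok]
    mm <- cbind(1, g[ok])
    if (!is.null(cov_mat)) mm <- cbind(mm, cov_mat[ok, , drop = FALSE])
    fit <- stats::lm.fit(mm, y)
    df <- sum(ok) - ncol(mm)
    if (df < 1 || fit$qr$rank < ncol(mm)) { n_skipped <- n_skipped + 1L; next }
    sigma2 <- sum(fit$residuals^2) / df
    xtx_inv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    beta <- fit$coefficients[2]
    tval <- beta / se
    rows[[i]] <- data.frame(variant_id = vi, feature_id = fe,
                            distance = pairs$distance[i], maf = maf,
                            n = sum(ok), beta = beta, se = se, t = tval,
                            p = 2 * stats::pt(-abs(tval), df = df),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant_id = character(0), feature_id = character(0),
                      distance = numeric(0), maf = numeric(0), n = integer(0),
                      beta = numeric(0), se = numeric(0), t = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  out$q <- if (nrow(out)) adjust_pvalues(out$p, adjust) else numeric(0)
  out$tier <- ifelse(out$q < sig_q, "significant",
                     ifelse(out$p < suggestive_p, "suggestive", "none"))
  rownames(out) <- NULL
  attr(out, "n_maf_filtered") <- n_maf_filtered
  attr(out, "n_skipped") <- n_skipped
  out
}
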