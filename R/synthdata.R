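#' Configuration for the synthetic multi-cohort generator
#'
#' Defines the statistical structure of the planted ground truth: module
#' sizes and loadings for the latent single-factor co-expression model,
#' case/control mean shifts (in SD units) with an optional inconsistent
#' fraction, trait loadings per module, and cis genetic effects.
#'
#' Defaults describe the study conditions exercised throughout the package:
#' three cohorts of 100 cases / 100 controls (two veteran-like cohorts scored
#' on the CAPS, one active-duty-like cohort scored on the PCL), 500 features
#' of which three planted modules of 100 each (minimum module size 30 applies
#' downstream), factor loadings uniform on (0.5, 0.9), case shifts of 0.8 SD
#' on 60 features with 20% of them sign-flipped in one cohort, and five
#' planted cis effects of 1 SD per allele.
#'
#' @param n_cohorts Number of cohorts.
#' @param samples_per_cohort List of length `n_cohorts`; each element
#'   `c(n_case, n_control)`.
#' @param cohort_types Character vector, one of "CAPS" (veteran-like,
#'   case total >= 40, control < 20) or "PCL" (active-duty-like, case
#'   total >= 38, control < 22) per cohort.
#' @param n_features Total number of features.
#' @param module_sizes Integer vector of planted module sizes; each >= 30 by
#'   default convention, summing to at most `n_features`.
#' @param loading_range Interval in (0,1) for per-feature factor loadings.
#' @param case_effect_sd Case-minus-control shift applied to affected
#'   features, in SD units of the latent scale.
#' @param n_affected Number of module-member features receiving case shifts.
#' @param frac_inconsistent Proportion of affected features whose shift sign
#'   is flipped in one (randomly chosen) cohort.
#' @param trait_loadings Numeric vector (recycled/padded over modules) of
#'   module-factor coefficients on the latent severity trait.
#' @param trait_noise_sd SD of the trait noise.
#' @param n_variants Number of genotyped variants.
#' @param maf_range Interval in (0, 0.5] for simulated allele frequencies.
#' @param n_cis_effects Number of planted (variant, feature) cis pairs.
#' @param cis_beta Planted effect per coded allele, SD units.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_cohorts = 3,
                         samples_per_cohort = rep(list(c(100, 100)), n_cohorts),
                         cohort_types = c("CAPS", "CAPS", "PCL"),
                         n_features = 500,
                         module_sizes = c(100, 100, 100),
                         loading_range = c(0.5, 0.9),
                         case_effect_sd = 0.8,
                         n_affected = 60,
                         frac_inconsistent = 0.2,
                         trait_loadings = c(2, -2, 2),
                         trait_noise_sd = 0.5,
                         n_variants = 200,
                         maf_range = c(0.05, 0.5),
                         n_cis_effects = 5,
                         cis_beta = 1.0,
                         seed = 7) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = lapply(samples_per_cohort, as.integer),
              cohort_types = rep_len(as.character(cohort_types), n_cohorts),
              n_features = as.integer(n_features),
              module_sizes = as.integer(module_sizes),
              loading_range = as.numeric(loading_range),
              case_effect_sd = as.numeric(case_effect_sd),
              n_affected = as.integer(n_affected),
              frac_inconsistent = as.numeric(frac_inconsistent),
              trait_loadings = as.numeric(trait_loadings),
              trait_noise_sd = as.numeric(trait_noise_sd),
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              n_cis_effects = as.integer(n_cis_effects),
              cis_beta = as.numeric(cis_beta),
              seed = as.integer(seed))
  if (cfg$n_cohorts < 1) stop("configuration error: n_cohorts must be >= 1")
  if (length(cfg$samples_per_cohort) != cfg$n_cohorts)
    stop("configuration error: samples_per_cohort must have n_cohorts entries")
  for (s in cfg$samples_per_cohort)
    if (length(s) != 2 || any(s <= 0))
      stop("configuration error: each cohort needs positive (n_case, n_control)")
  if (!all(cfg$cohort_types %in% c("CAPS", "PCL")))
    stop("configuration error: cohort_types must be 'CAPS' or 'PCL'")
  if (sum(cfg$module_sizes) > cfg$n_features)
    stop("configuration error: sum(module_sizes) exceeds n_features")
  if (any(cfg$module_sizes < 2))
    stop("configuration error: module sizes must be >= 2")
  if (length(cfg$loading_range) != 2 ||
      any(cfg$loading_range <= 0) || any(cfg$loading_range >= 1) ||
      diff(cfg$loading_range) < 0)
    stop("configuration error: loading_range must be an interval within (0,1)")
  if (cfg$frac_inconsistent < 0 || cfg$frac_inconsistent > 1)
    stop("configuration error: frac_inconsistent must be in [0,1]")
  if (cfg$n_affected > sum(cfg$module_sizes))
    stop("configuration error: n_affected exceeds the number of module members")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || diff(cfg$maf_range) < 0)
    stop("configuration error: maf_range must lie within (0, 0.5]")
  if (cfg$n_cis_effects > cfg$n_variants)
    stop("configuration error: n_cis_effects exceeds n_variants")
  cfg$trait_loadings <- rep_len(cfg$trait_loadings, length(cfg$module_sizes))
  class(cfg) <- "synth_config"
  cfg
}

# Trait score ranges used to dichotomize the latent severity at the printed
# instrument cutoffs (case >= 40 / control < 20 for CAPS; case >= 38 /
# control < 22 for PCL, subthreshold 22-37 unused since groups are binary).
.trait_ranges <- list(
  CAPS = list(col = "CAPS_total", case = c(40, 100), control = c(0, 19)),
  PCL  = list(col = "PCL_total",  case = c(38, 85),  control = c(5, 21))
)

# Rank-preserving affine map of x into [lo, hi], rounded to integer scores.
.map_to_range <- function(x, lo, hi) {
  if (length(x) == 0) return(numeric(0))
  r <- range(x)
  if (diff(r) == 0) return(rep(round((lo + hi) / 2), length(x)))
  round(lo + (x - r[1]) / diff(r) * (hi - lo))
}

#' Generate multi-cohort expression and trait fixtures with planted truth
#'
#' Features in module m follow the latent single-factor model
#' x_i = lambda_i * f_m + sqrt(1 - lambda_i^2) * eps on a standardized
#' latent scale; background features are pure noise. Affected features get an
#' additive case shift of `case_effect_sd` whose sign is constant across
#' cohorts except for the planted inconsistent fraction (flipped in one
#' cohort). The severity trait is a linear combination of module factors plus
#' noise, then rank-preservingly mapped so cases and controls land in the
#' printed CAPS/PCL score ranges. Emitted abundances are 2^(8 + z): positive,
#' log-normal on the latent scale, so median normalization followed by log2
#' recovers z up to an additive constant.
#'
#' @param config A `synth_config`.
#' @return List with `expression` (list of `expr_mat`), `traits` (list of
#'   data frames), and `truth` (a `synth_truth` list: `module_labels`,
#'   `affected` data frame with per-cohort signs, `trait_loadings`,
#'   `cis_pairs`, `enriched_sets`).
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  p <- config$n_features
  fid <- sprintf("P%04d", seq_len(p))
  M <- length(config$module_sizes)
  labels <- integer(p)
  names(labels) <- fid
  labels[seq_len(sum(config$module_sizes))] <-
    rep(seq_len(M), times = config$module_sizes)

  lambda <- numeric(p)
  in_mod <- labels > 0
  lambda[in_mod] <- stats::runif(sum(in_mod),
                                 config$loading_range[1], config$loading_range[2])

  # planted case effects: choose members, base signs, one flipped cohort for
  # the inconsistent subset
  aff_idx <- sort(sample(which(in_mod), config$n_affected))
  base_sign <- sample(c(-1, 1), length(aff_idx), replace = TRUE)
  n_inc <- round(config$frac_inconsistent * length(aff_idx))
  inc_pos <- if (n_inc > 0) sample(seq_along(aff_idx), n_inc) else integer(0)
  sign_mat <- matrix(rep(base_sign, config$n_cohorts),
                     nrow = length(aff_idx), ncol = config$n_cohorts,
                     dimnames = list(fid[aff_idx],
                                     paste0("cohort", seq_len(config$n_cohorts))))
  if (config$n_cohorts >= 2) {
    for (j in inc_pos) {
      flip_c <- sample(config$n_cohorts, 1)
      sign_mat[j, flip_c] <- -sign_mat[j, flip_c]
    }
  }
  consistent <- as.logical(apply(sign_mat, 1,
                                 function(s) length(unique(s)) == 1))

  exprs <- vector("list", config$n_cohorts)
  traits <- vector("list", config$n_cohorts)
  factors <- vector("list", config$n_cohorts)
  for (cix in seq_len(config$n_cohorts)) {
    nc <- config$samples_per_cohort[[cix]][1]
    nn <- config$samples_per_cohort[[cix]][2]
    n <- nc + nn
    sid <- sprintf("C%d_S%03d", cix, seq_len(n))
    group <- c(rep("case", nc), rep("control", nn))
    f <- matrix(stats::rnorm(M * n), nrow = M,
                dimnames = list(paste0("module", seq_len(M)), sid))
    factors[[cix]] <- f
    z <- matrix(stats::rnorm(p * n), nrow = p, dimnames = list(fid, sid))
    z[in_mod, ] <- lambda[in_mod] * f[labels[in_mod], , drop = FALSE] +
      sqrt(1 - lambda[in_mod]^2) * z[in_mod, ]
    case_ind <- as.numeric(group == "case")
    z[aff_idx, ] <- z[aff_idx, ] +
      config$case_effect_sd * sign_mat[, cix] %o% case_ind

    trait_latent <- as.numeric(config$trait_loadings %*% f) +
      stats::rnorm(n, sd = config$trait_noise_sd)
    rng <- .trait_ranges[[config$cohort_types[cix]]]
    score <- numeric(n)
    score[group == "case"] <- .map_to_range(trait_latent[group == "case"],
                                            rng$case[1], rng$case[2])
    score[group == "control"] <- .map_to_range(trait_latent[group == "control"],
                                               rng$control[1], rng$control[2])
    tt <- data.frame(sample_id = sid,
                     cohort_id = paste0("cohort", cix),
                     group = group,
                     CAPS_total = NA_real_,
                     PCL_total = NA_real_,
                     age = round(stats::runif(n, 25, 55)),
                     BMI = round(stats::rnorm(n, 27, 4), 1),
                     batch = sample(c("b1", "b2"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
    tt[[rng$col]] <- score
    exprs[[cix]] <- expression_matrix(2^(8 + z), paste0("cohort", cix))
    traits[[cix]] <- tt
  }
  names(exprs) <- names(traits) <- names(factors) <-
    paste0("cohort", seq_len(config$n_cohorts))

  truth <- structure(list(
    module_labels = labels,
    loadings = stats::setNames(lambda, fid),
    affected = data.frame(feature_id = fid[aff_idx],
                          magnitude = rep(config$case_effect_sd,
                                          length(aff_idx)),
                          consistent = unname(consistent),
                          sign_mat,
                          stringsAsFactors = FALSE),
    trait_loadings = stats::setNames(config$trait_loadings,
                                     paste0("module", seq_len(M))),
    cis_pairs = data.frame(variant_id = character(0),
                           feature_id = character(0),
                           beta = numeric(0), stringsAsFactors = FALSE),
    enriched_sets = character(0),
    # per-cohort realized module factors (modules x samples); kept in memory
    # for validation, not serialized by write_fixture
    factors = factors
  ), class = "synth_truth")

  list(expression = exprs, traits = traits, truth = truth)
}

#' Generate Hardy-Weinberg genotypes, a toy gene map, and planted cis pairs
#'
#' Genes are placed on a linear toy genome ("chr1", one gene per feature,
#' 10 kb bodies every 250 kb); one in five variants is placed on a gene-less
#' decoy chromosome ("chr2") so that candidates both inside and outside the
#' 1 Mb cis window exist. Dosages are Binomial(2, f) draws at allele
#' frequencies uniform on `maf_range`. Planted cis pairs put the variant
#' within 1 Mb of its feature's gene; the expression perturbation itself is
#' applied by [apply_cis_effects()].
#'
#' @param config A `synth_config`.
#' @param features Character vector of feature ids (order defines gene order).
#' @param sample_ids Character vector of sample ids to genotype.
#' @return List with `genotypes` (`geno_mat`), `gene_coords` (data frame
#'   feature_id/chrom/start/end, 1-based inclusive), `cis_pairs` (data frame
#'   variant_id/feature_id/beta).
#' @export
generate_genotypes <- function(config, features, sample_ids) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_cis_effects > config$n_variants)
    stop("configuration error: n_cis_effects exceeds n_variants")
  set.seed(config$seed + 1L)
  p <- length(features)
  gene_coords <- data.frame(feature_id = features,
                            chrom = "chr1",
                            start = 250000L * seq_len(p) + 1L,
                            end = 250000L * seq_len(p) + 10000L,
                            stringsAsFactors = FALSE)

  nv <- config$n_variants
  vid <- sprintf("rs%05d", seq_len(nv))
  n_cis <- config$n_cis_effects
  cis_feat <- if (n_cis > 0) sample(features, n_cis) else character(0)
  chrom <- character(nv)
  pos <- integer(nv)
  if (n_cis > 0) {
    g <- gene_coords[match(cis_feat, gene_coords$feature_id), ]
    chrom[seq_len(n_cis)] <- g$chrom
    # inside the window: uniform within +/- 500 kb of the gene body
    pos[seq_len(n_cis)] <- pmax(1L, as.integer(
      round(stats::runif(n_cis, g$start - 5e5, g$end + 5e5))))
  }
  rest <- setdiff(seq_len(nv), seq_len(n_cis))
  on_decoy <- rest[seq_along(rest) %% 5 == 0]
  on_chr1 <- setdiff(rest, on_decoy)
  chrom[on_chr1] <- "chr1"
  pos[on_chr1] <- as.integer(round(stats::runif(length(on_chr1), 1,
                                                250000 * p + 1.2e6)))
  chrom[on_decoy] <- "chr2"
  pos[on_decoy] <- as.integer(round(stats::runif(length(on_decoy), 1, 1e7)))

  f <- stats::runif(nv, config$maf_range[1], config$maf_range[2])
  dos <- matrix(stats::rbinom(nv * length(sample_ids), 2L, rep(f, length(sample_ids))),
                nrow = nv, dimnames = list(vid, sample_ids))
  map <- data.frame(variant_id = vid, chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  cis_pairs <- data.frame(variant_id = vid[seq_len(n_cis)],
                          feature_id = cis_feat,
                          beta = rep(config$cis_beta, n_cis),
                          stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dos, map),
       gene_coords = gene_coords,
       cis_pairs = cis_pairs)
}

#' Apply planted cis effects to expression matrices
#'
#' Adds beta * dosage per coded allele to each planted feature on the latent
#' log2 scale (abundances are multiplied by 2^(beta * dosage)).
#'
#' @param exprs List of `expr_mat` (samples disjoint across cohorts).
#' @param genotypes A `geno_mat` covering all samples.
#' @param cis_pairs Data frame variant_id/feature_id/beta.
#' @return The modified list of `expr_mat`.
#' @export
apply_cis_effects <- function(exprs, genotypes, cis_pairs) {
  if (nrow(cis_pairs) == 0) return(exprs)
  for (k in seq_len(nrow(cis_pairs))) {
    v <- cis_pairs$variant_id[k]; fe <- cis_pairs$feature_id[k]
    for (cix in seq_along(exprs)) {
      sid <- sample_ids(exprs[[cix]])
      d <- genotypes$dosages[v, sid]
      d[is.na(d)] <- 0
      exprs[[cix]]$values[fe, ] <- exprs[[cix]]$values[fe, ] *
        2^(cis_pairs$beta[k] * d)
    }
  }
  exprs
}

#' Generate pathway sets over the synthetic universe
#'
#' Builds one enriched set per effect direction (affected, direction-
#' consistent members padded with background features; direction annotations
#' match the planted signs) and several null sets drawn uniformly from the
#' background. With no affected features only null sets are produced.
#'
#' @param truth A `synth_truth` from [generate_cohorts()].
#' @param config The `synth_config` used.
#' @param n_null Number of null sets (default 5).
#' @param null_size Size of each null set (default 20).
#' @param enriched_background Background members padded into each enriched
#'   set (default 5).
#' @return A `pathway_db`; enriched set names start with "planted_".
#' @export
generate_pathways <- function(truth, config, n_null = 5, null_size = 20,
                              enriched_background = 5) {
  stopifnot(inherits(truth, "synth_truth"))
  set.seed(config$seed + 2L)
  universe <- names(truth$module_labels)
  if (null_size > length(universe))
    stop("configuration error: requested set size exceeds the universe")
  background <- universe[truth$module_labels == 0]
  sets <- list(); dirs <- list()
  aff <- truth$affected
  if (nrow(aff) > 0) {
    cons <- aff[aff$consistent, , drop = FALSE]
    if (nrow(cons) > 0) {
      members <- cons$feature_id
      sgn <- stats::setNames(as.numeric(cons[, grep("^cohort", names(cons))[1]]),
                             members)
      take <- utils::head(order(members), 15)
      m <- members[take]
      pad <- sample(setdiff(background, m),
                    min(enriched_background, length(background)))
      sets[["planted_affected"]] <- c(m, pad)
      d <- c(sgn[m], stats::setNames(sample(c(-1, 1), length(pad), TRUE), pad))
      dirs[["planted_affected"]] <- d
    }
  }
  for (i in seq_len(n_null)) {
    pool <- if (length(background) >= null_size) background else universe
    sets[[sprintf("null_set_%02d", i)]] <- sample(pool, null_size)
  }
  db <- pathway_db(sets, directions = if (length(dirs)) dirs else NULL,
                   source = "synthetic")
  db
}

#' Generate a complete synthetic fixture
#'
#' Convenience wrapper: cohorts, genotypes (cis effects applied), pathways;
#' the truth object is updated with the cis pairs and enriched set names.
#'
#' @param config A `synth_config` (default `synth_config()`).
#' @return List with `expression`, `traits`, `truth`, `genotypes`,
#'   `gene_coords`, `pathways`, and `config`.
#' @export
generate_fixture <- function(config = synth_config()) {
  cohorts <- generate_cohorts(config)
  all_sids <- unlist(lapply(cohorts$expression, sample_ids), use.names = FALSE)
  geno <- generate_genotypes(config, feature_ids(cohorts$expression[[1]]),
                             all_sids)
  cohorts$expression <- apply_cis_effects(cohorts$expression, geno$genotypes,
                                          geno$cis_pairs)
  cohorts$truth$cis_pairs <- geno$cis_pairs
  pdb <- generate_pathways(cohorts$truth, config)
  cohorts$truth$enriched_sets <- grep("^planted_", names(pdb$sets), value = TRUE)
  c(cohorts, list(genotypes = geno$genotypes, gene_coords = geno$gene_coords,
                  pathways = pdb, config = config))
}
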