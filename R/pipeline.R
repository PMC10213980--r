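# stage seeds derived deterministically from the global seed; kept < 2^31
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 11L, network = 23L, modules = 37L, preservation = 53L,
            diffmeta = 71L, enrich = 89L, pqtl = 101L)
  as.integer((as.numeric(seed) * 1009 + offs[[stage]]) %% 2147483647)
}

#' Pipeline configuration with the study defaults
#'
#' Every printed analysis threshold appears here: soft power beta = 4,
#' minimum module size 30, 300 preservation permutations with Z_summary > 10
#' "high" and 5-10 "moderate", module-trait p < 0.01, training FDR q < 0.1,
#' meta BY q < 0.05, direction filter p < 0.1, MAF > 0.05, 1 Mb cis window.
#'
#' @param seed Global seed; each stochastic stage receives a seed derived
#'   deterministically from it and the stage name.
#' @param ... Overrides for any default listed below.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 7, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = TRUE,
    synth = synth_config(seed = .stage_seed(seed, "simulate")),
    beta = 4,
    min_size = 30,
    cut_height = 0.99,
    merge_threshold = 0.25,
    kme_reattach = 0.3,
    n_permutations = 300,
    preservation_class = "high",
    module_trait_p = 0.01,
    covariates = c("age", "BMI"),
    direction_p = 0.1,
    training_q = 0.1,
    training_method = "BH",
    meta_q = 0.05,
    rem_p = 0.05,
    meta_rule = "or",
    enrich_method = "bonferroni",
    min_overlap = 3,
    maf_min = 0.05,
    cis_window = 1e6,
    run_preservation = TRUE,
    run_pqtl = TRUE,
    outdir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load and cross-validate pipeline inputs from a fixture directory
#'
#' Reads expression, traits, pathways, genotypes, and gene coordinates and
#' checks cross-file consistency: unique ids, identical feature universes
#' across cohorts, every expression sample present in the trait table.
#'
#' @param dir Directory written by [write_fixture()] (or following the same
#'   layout).
#' @return Validated fixture list (see [read_fixture()]).
#' @export
load_inputs <- function(dir) {
  fx <- read_fixture(dir)
  ids <- lapply(fx$expression, feature_ids)
  for (i in seq_along(ids)[-1])
    if (!identical(ids[[1]], ids[[i]]))
      stop("feature universe differs between cohorts ",
           names(ids)[1], " and ", names(ids)[i])
  for (nm in names(fx$expression)) {
    missing <- setdiff(sample_ids(fx$expression[[nm]]),
                       fx$traits[[nm]]$sample_id)
    if (length(missing))
      stop("trait table for ", nm, " missing sample(s): ",
           paste(missing, collapse = ", "))
  }
  fx
}

#' Run the full multi-cohort persistence pipeline
#'
#' Stages, in order: simulate (optional) -> median normalization + log2 ->
#' per-cohort networks and TOMs -> consensus TOM -> module detection on the
#' reference (first) cohort assignment -> permutation preservation in every
#' other cohort -> per-cohort differential abundance -> Stouffer +
#' random-effects meta-analysis with the direction filter -> persistent-set
#' intersection -> pathway over-representation, activation scores, and
#' pathway-trait correlations -> cis-pQTL scan (optional). All stage tables
#' are returned, and written as TSV plus a JSON summary when
#' `config$outdir` is set.
#'
#' @param config A `pipeline_config`.
#' @param fixture Optional pre-built fixture (used when
#'   `config$simulate = FALSE` or to reuse data across runs).
#' @return List of stage outputs plus `summary` (named scalars).
#' @export
run_pipeline <- function(config = pipeline_config(), fixture = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }

  if (is.null(fixture)) {
    if (!config$simulate) stop("no fixture supplied and simulate disabled")
    say("stage simulate: generating synthetic fixture (seed %d)",
        config$synth$seed)
    fixture <- generate_fixture(config$synth)
  }
  exprs <- fixture$expression
  traits <- fixture$traits
  cohorts <- names(exprs)
  ref <- cohorts[1]
  say("cohorts: %s (reference: %s)", paste(cohorts, collapse = ", "), ref)

  say("stage normalize: median normalization + log2")
  norm <- lapply(exprs, median_normalize, log2 = TRUE)

  say("stage network: beta = %g unsigned adjacency + TOM per cohort", config$beta)
  toms <- lapply(norm, function(x)
    topological_overlap(adjacency_from_expression(x, beta = config$beta)))
  cons <- if (length(toms) >= 2) consensus_overlap(toms) else toms[[1]]

  say("stage modules: average-linkage tree, cut at %g, min size %d, merge %g",
      config$cut_height, config$min_size, config$merge_threshold)
  dend <- build_dendrogram(cons)
  assignment <- cut_modules(dend, min_size = config$min_size,
                            cut_height = config$cut_height,
                            X = norm[[ref]], kme_reattach = config$kme_reattach)
  assignment <- merge_modules(norm[[ref]], assignment,
                              merge_threshold = config$merge_threshold)
  me <- module_eigengenes(norm[[ref]], assignment)
  mt <- module_trait_table(me, traits[[ref]],
                           trait_cols = intersect(c("group", "CAPS_total", "PCL_total"),
                                                  names(traits[[ref]])),
                           flag_p = config$module_trait_p)

  preservation <- NULL
  preserved_modules <- sort(unique(assignment$labels[assignment$labels > 0]))
  if (config$run_preservation && length(cohorts) > 1) {
    say("stage preservation: %d permutations per test cohort",
        config$n_permutations)
    preservation <- lapply(cohorts[-1], function(cn)
      preservation_zsummary(assignment, norm[[ref]], norm[[cn]],
                            beta = config$beta,
                            n_permutations = config$n_permutations,
                            seed = .stage_seed(config$seed, "preservation") +
                              match(cn, cohorts)))
    names(preservation) <- cohorts[-1]
    keep_class <- if (config$preservation_class == "high") "high"
                  else c("high", "moderate")
    preserved_modules <- Reduce(intersect, lapply(preservation, function(pr)
      pr$module[pr$class %in% keep_class]))
  }
  flagged <- unique(sub("^ME", "", mt$module[mt$flagged]))
  sel_modules <- intersect(preserved_modules, as.integer(flagged))
  module_members <- names(assignment$labels)[assignment$labels %in% sel_modules]
  say("modules preserved & trait-correlated: %s (%d member features)",
      paste(sel_modules, collapse = ","), length(module_members))

  say("stage diffmeta: OLS per cohort (covariates: %s), Stouffer + REM",
      paste(config$covariates, collapse = ", "))
  de <- lapply(cohorts, function(cn)
    differential_expression(norm[[cn]], traits[[cn]],
                            covariates = config$covariates))
  names(de) <- cohorts
  meta <- meta_analyze(de, direction_p = config$direction_p)
  persistent <- persistent_feature_set(
    if (config$run_preservation) module_members else NULL,
    de[[ref]], meta,
    training_q = config$training_q, training_method = config$training_method,
    meta_q = config$meta_q, rem_p = config$rem_p, meta_rule = config$meta_rule)
  say("persistent set: %d features", nrow(persistent))

  enrichment <- NULL; activation <- NULL; ptc <- NULL
  if (!is.null(fixture$pathways) && nrow(persistent) > 0) {
    say("stage enrich: hypergeometric (%s), activation, pathway-trait r",
        config$enrich_method)
    universe <- feature_ids(exprs[[ref]])
    enrichment <- hypergeometric_enrichment(persistent$feature_id,
                                            fixture$pathways, universe,
                                            method = config$enrich_method,
                                            min_overlap = config$min_overlap)
    obs_signs <- stats::setNames(ifelse(meta$pooled_d >= 0, 1, -1),
                                 meta$feature_id)
    activation <- activation_scores(fixture$pathways, obs_signs)
    scores <- do.call(rbind, lapply(names(fixture$pathways$sets), function(nm) {
      sc <- tryCatch(pathway_sample_scores(norm[[ref]],
                                           fixture$pathways$sets[[nm]]),
                     error = function(e) NULL)
      if (is.null(sc)) return(NULL)
      matrix(sc, nrow = 1, dimnames = list(nm, names(sc)))
    }))
    if (!is.null(scores))
      ptc <- pathway_trait_correlation(scores, traits[[ref]])
  }

  pqtl <- NULL
  if (config$run_pqtl && !is.null(fixture$genotypes)) {
    say("stage pqtl: cis window %g bp, MAF > %g", config$cis_window,
        config$maf_min)
    pairs <- cis_candidate_pairs(fixture$gene_coords, fixture$genotypes$map,
                                 window = config$cis_window)
    all_norm <- do.call(cbind, lapply(norm, expr_values))
    pooled <- expression_matrix(all_norm, "pooled")
    pqtl <- pqtl_scan(pooled, fixture$genotypes, pairs,
                      maf_min = config$maf_min)
  }

  summary <- list(
    n_cohorts = length(cohorts),
    n_features = nrow(expr_values(exprs[[ref]])),
    n_modules = length(unique(assignment$labels[assignment$labels > 0])),
    n_preserved_trait_modules = length(sel_modules),
    n_persistent = nrow(persistent),
    n_enriched_sets = if (is.null(enrichment)) 0L else sum(enrichment$q < 0.05),
    n_pqtl_significant = if (is.null(pqtl)) 0L else sum(pqtl$tier == "significant"),
    seed = config$seed
  )

  out <- list(fixture = fixture, normalized = norm, toms = toms,
              consensus = cons, assignment = assignment, eigengenes = me,
              module_trait = mt, preservation = preservation,
              selected_modules = sel_modules, de = de, meta = meta,
              persistent = persistent, enrichment = enrichment,
              activation = activation, pathway_trait = ptc, pqtl = pqtl,
              summary = summary, log = log_lines)

  if (!is.null(config$outdir)) .write_run_dir(out, config)
  out
}

# stage TSVs + machine-readable summary + log; plain text only
.write_run_dir <- function(out, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(config$outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(data.frame(feature_id = names(out$assignment$labels),
                module = out$assignment$labels), "module_assignment.tsv")
  wt(data.frame(module = rownames(out$eigengenes$values),
                out$eigengenes$values, check.names = FALSE), "eigengenes.tsv")
  wt(out$module_trait, "module_trait.tsv")
  if (!is.null(out$preservation))
    for (nm in names(out$preservation))
      wt(out$preservation[[nm]], paste0("preservation_", nm, ".tsv"))
  for (nm in names(out$de)) wt(out$de[[nm]], paste0("de_", nm, ".tsv"))
  wt(out$meta, "meta.tsv")
  wt(as.data.frame(out$persistent), "persistent_set.tsv")
  wt(out$enrichment, "enrichment.tsv")
  wt(out$activation, "activation.tsv")
  wt(out$pathway_trait, "pathway_trait.tsv")
  wt(out$pqtl, "pqtl.tsv")
  cfg <- unclass(config)
  cfg$synth <- unclass(cfg$synth)
  jsonlite::write_json(list(summary = out$summary, config = cfg),
                       file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(paste("R", getRversion()), out$log),
             file.path(config$outdir, "run.log"))
  invisible(NULL)
}
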