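#' Write a synthetic fixture to plain-text files
#'
#' Emits one expression TSV and one trait CSV per cohort, a GMT pathway
#' file, a genotype TSV (variant id, chrom, pos, then dosages), a BED-like
#' gene coordinate table (1-based inclusive, convention stated in a header
#' comment), a truth JSON, and a manifest echoing the config with an MD5
#' hash of its canonical JSON serialization.
#'
#' @param dir Output directory (created, with a notice, if missing).
#' @param fixture A fixture list from [generate_fixture()].
#' @return The manifest, invisibly.
#' @export
write_fixture <- function(dir, fixture) {
  if (!dir.exists(dir)) {
    message("creating fixture directory: ", dir)
    ok <- dir.create(dir, recursive = TRUE)
    if (!ok) stop("I/O error: cannot create directory ", dir)
  }
  for (nm in names(fixture$expression)) {
    v <- fixture$expression[[nm]]$values
    df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, paste0("expression_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(fixture$traits[[nm]],
                     file.path(dir, paste0("traits_", nm, ".csv")),
                     row.names = FALSE)
  }
  write_gmt(fixture$pathways, file.path(dir, "pathways.gmt"))
  g <- fixture$genotypes
  gdf <- data.frame(g$map, g$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(gdf, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "gene_coords.tsv"), "w")
  writeLines("# coordinates are 1-based inclusive", con)
  utils::write.table(fixture$gene_coords, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  truth <- fixture$truth
  jsonlite::write_json(list(
    module_labels = as.list(truth$module_labels),
    loadings = as.list(truth$loadings),
    affected = truth$affected,
    trait_loadings = as.list(truth$trait_loadings),
    cis_pairs = truth$cis_pairs,
    enriched_sets = truth$enriched_sets
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  cfg <- unclass(fixture$config)
  manifest <- list(seed = cfg$seed, config = cfg,
                   config_hash = config_hash(fixture$config),
                   cohorts = names(fixture$expression))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' MD5 hash of a config's canonical JSON serialization
#' @param config A `synth_config` (or any list).
#' @return Hash string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Read a fixture directory back into memory
#'
#' Inverse of [write_fixture()]; performs the same cross-file consistency
#' checks as [load_inputs()].
#'
#' @param dir Fixture directory.
#' @return A fixture list (without the original `config` object; the
#'   manifest echo is attached as `manifest`).
#' @export
read_fixture <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cohorts <- manifest$cohorts
  exprs <- list(); traits <- list()
  for (nm in cohorts) {
    exprs[[nm]] <- read_expression_tsv(
      file.path(dir, paste0("expression_", nm, ".tsv")), cohort_id = nm)
    tt <- utils::read.csv(file.path(dir, paste0("traits_", nm, ".csv")),
                          stringsAsFactors = FALSE)
    for (sc in intersect(c("CAPS_total", "PCL_total"), names(tt)))
      tt[[sc]] <- as.numeric(tt[[sc]])  # all-NA score columns parse as logical
    traits[[nm]] <- tt
  }
  g <- read_genotypes_tsv(file.path(dir, "genotypes.tsv"))
  gc <- read_gene_coords(file.path(dir, "gene_coords.tsv"))
  pdb <- read_gmt(file.path(dir, "pathways.gmt"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth <- structure(list(
    module_labels = unlist(tr$module_labels),
    loadings = unlist(tr$loadings),
    affected = as.data.frame(tr$affected, stringsAsFactors = FALSE),
    trait_loadings = unlist(tr$trait_loadings),
    cis_pairs = as.data.frame(tr$cis_pairs, stringsAsFactors = FALSE),
    enriched_sets = unlist(tr$enriched_sets) %||% character(0)
  ), class = "synth_truth")
  list(expression = exprs, traits = traits, truth = truth,
       genotypes = g, gene_coords = gc, pathways = pdb, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an expression TSV (feature id first column, samples after)
#' @param path File path.
#' @param cohort_id Cohort label for the returned `expr_mat`.
#' @return An `expr_mat`.
#' @export
read_expression_tsv <- function(path, cohort_id = basename(path)) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression cells in ", path)
  rownames(m) <- df[[1]]
  expression_matrix(m, cohort_id)
}

#' Read a genotype TSV (variant_id, chrom, pos, then per-sample dosages)
#' @param path File path.
#' @return A `geno_mat`.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- df[, c("variant_id", "chrom", "pos")]
  dos <- as.matrix(df[, setdiff(names(df), c("variant_id", "chrom", "pos")),
                      drop = FALSE])
  rownames(dos) <- df$variant_id
  genotype_matrix(dos, map)
}

#' Read a gene coordinate table (1-based inclusive; header comment allowed)
#' @param path File path.
#' @return Data frame feature_id/chrom/start/end.
#' @export
read_gene_coords <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("feature_id", "chrom", "start", "end") %in% names(df)))
  if (any(df$start > df$end)) stop("gene coordinates with start > end")
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature id(s) in gene coordinates")
  df
}

#' Write a pathway collection as GMT
#' @param db A `pathway_db`.
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$sets), function(nm) {
    paste(c(nm, db$source, db$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT file into a pathway collection
#' @param path GMT path (tab-separated: name, description, members...).
#' @return A `pathway_db` (no direction annotations; GMT does not carry them).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  pathway_db(sets, source = parts[[1]][2] %||% "gmt")
}
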