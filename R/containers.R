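#' Expression matrix container
#'
#' Wraps a features x samples abundance matrix together with a cohort label.
#' Row names are feature ids, column names are sample ids; both must be
#' unique and non-empty.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique dimnames.
#' @param cohort_id Single string labelling the cohort.
#' @return An object of class `expr_mat`.
#' @export
expression_matrix <- function(values, cohort_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  structure(list(values = values, cohort_id = as.character(cohort_id)[1]),
            class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> cohort '%s': %d features x %d samples\n",
              x$cohort_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Feature ids of an expression matrix
#' @param x An `expr_mat`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Sample ids of an expression matrix
#' @param x An `expr_mat`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

# Coerce an expr_mat or bare matrix to the underlying numeric matrix.
expr_values <- function(x) {
  if (inherits(x, "expr_mat")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("matrix input must carry feature/sample dimnames")
    return(x)
  }
  stop("expected an `expr_mat` or a named numeric matrix")
}

#' Genotype matrix container
#'
#' Additively coded dosages (0/1/2 of the coded allele, NA = missing) with a
#' variant map giving 1-based positions.
#'
#' @param dosages Integer/numeric matrix, variants x samples, values in
#'   {0,1,2,NA}; dimnames required.
#' @param map Data frame with columns `variant_id`, `chrom`, `pos` (1-based),
#'   one row per dosage row, in order.
#' @return An object of class `geno_mat`.
#' @export
genotype_matrix <- function(dosages, map) {
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("`dosages` must have variant ids as rownames and sample ids as colnames")
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(map)),
            nrow(map) == nrow(dosages))
  if (!identical(as.character(map$variant_id), rownames(dosages)))
    stop("`map$variant_id` must match rownames(dosages) in order")
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  structure(list(dosages = dosages, map = map), class = "geno_mat")
}

#' @export
print.geno_mat <- function(x, ...) {
  cat(sprintf("<geno_mat> %d variants x %d samples\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Pathway collection container
#'
#' Named gene sets with optional per-member direction annotations (+1/-1,
#' the expected sign of each member under pathway activation).
#'
#' @param sets Named list of character vectors (unique members each).
#' @param directions Optional named list; for a set name, a named numeric
#'   vector of -1/+1 over (a subset of) its members.
#' @param source Label for provenance.
#' @return An object of class `pathway_db`.
#' @export
pathway_db <- function(sets, directions = NULL, source = "custom") {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]]))
      stop("duplicate members in set '", nm, "'")
  }
  if (!is.null(directions)) {
    stopifnot(is.list(directions))
    for (nm in names(directions)) {
      d <- directions[[nm]]
      if (!all(d %in% c(-1, 1)))
        stop("direction annotations must be -1 or +1 (set '", nm, "')")
      if (!all(names(d) %in% sets[[nm]]))
        stop("direction annotations name non-members in set '", nm, "'")
    }
  }
  structure(list(sets = sets, directions = directions, source = source),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d sets (source: %s)\n", length(x$sets), x$source))
  invisible(x)
}
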