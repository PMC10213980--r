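#' Hypergeometric over-representation of a hit set in pathway sets
#'
#' One-sided over-representation p = P(X >= overlap) under the
#' hypergeometric distribution given the universe, each set intersected
#' with the universe, and the hit list. Sets whose overlap with the hits is
#' below `min_overlap` are excluded before correction (so the number of
#' tests m reflects the exclusion); Bonferroni family-wise correction by
#' default, with BH/BY available. Rows are sorted by p.
#'
#' @param hits Character vector of significant features (subset of
#'   `universe`).
#' @param db A `pathway_db`.
#' @param universe Character vector: the assayed feature panel.
#' @param method "bonferroni" (default), "BH", or "BY".
#' @param min_overlap Minimum overlap tested (default 3).
#' @return Data frame (set, overlap, set_size, n_hits, universe_size, p, q).
#' @export
hypergeometric_enrichment <- function(hits, db, universe,
                                      method = c("bonferroni", "BH", "BY"),
                                      min_overlap = 3) {
  method <- match.arg(method)
  if (length(universe) == 0) stop("empty universe")
  if (length(hits) == 0) stop("empty hit list")
  if (length(setdiff(hits, universe)))
    stop("hits outside the universe: ",
         paste(utils::head(setdiff(hits, universe), 5), collapse = ", "))
  rows <- lapply(names(db$sets), function(nm) {
    s <- intersect(db$sets[[nm]], universe)
    k <- length(intersect(s, hits))
    data.frame(set = nm, overlap = k, set_size = length(s),
               n_hits = length(hits), universe_size = length(universe),
               p = stats::phyper(k - 1, length(s),
                                 length(universe) - length(s),
                                 length(hits), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$overlap >= min_overlap, , drop = FALSE]
  if (nrow(out) == 0) return(cbind(out, q = numeric(0)))
  out$q <- if (method == "bonferroni") pmin(1, nrow(out) * out$p)
           else adjust_pvalues(out$p, method)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sign-consistency pathway activation score
#'
#' Transparent stand-in for proprietary activation scoring: each annotated
#' member contributes s_i = observed_i * expected_i in {-1, +1} and
#' z = sum(s_i)/sqrt(N). Positive z indicates activation (observed effect
#' directions agree with the directions expected under pathway activation),
#' negative z inhibition.
#'
#' @param observed Named vector of observed effect signs (-1/+1) per member.
#' @param expected Named vector of expected-under-activation signs.
#' @return z (length-1 numeric); NA with attribute `reason` when no member
#'   carries both annotations.
#' @export
activation_zscore <- function(observed, expected) {
  common <- intersect(names(observed), names(expected))
  if (length(common) == 0)
    return(structure(NA_real_, reason = "no members with both observed and expected signs"))
  s <- observed[common] * expected[common]
  stopifnot(all(s %in% c(-1, 1)))
  sum(s) / sqrt(length(s))
}

#' Activation scores for every annotated set in a collection
#'
#' @param db A `pathway_db` with direction annotations.
#' @param observed_signs Named vector of observed effect signs over features
#'   (e.g. sign of the pooled meta-analytic effect).
#' @return Data frame (set, n_annotated, activation_z).
#' @export
activation_scores <- function(db, observed_signs) {
  if (is.null(db$directions)) {
    return(data.frame(set = character(0), n_annotated = integer(0),
                      activation_z = numeric(0)))
  }
  rows <- lapply(names(db$directions), function(nm) {
    z <- activation_zscore(observed_signs, db$directions[[nm]])
    data.frame(set = nm,
               n_annotated = length(intersect(names(db$directions[[nm]]),
                                              names(observed_signs))),
               activation_z = as.numeric(z), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate per-sample pathway scores with clinical traits
#'
#' Pearson r with two-sided Student-t p per (pathway score, trait); the
#' cross-cohort sign pattern of these correlations is the pathway-severity
#' map (negative r: pathway score falls with symptom severity).
#'
#' @param scores Matrix sets x samples of per-sample pathway scores (e.g.
#'   stacked [pathway_sample_scores()] outputs), or a single named vector.
#' @param traits Trait data frame with `sample_id`.
#' @param trait_cols As in [module_trait_table()].
#' @return Data frame (set, trait, r, p, n).
#' @export
pathway_trait_correlation <- function(scores, traits, trait_cols = NULL) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1,
                                          dimnames = list("score", names(scores)))
  fake_me <- structure(list(values = scores), class = "eigengene_matrix")
  res <- module_trait_table(fake_me, traits, trait_cols = trait_cols)
  names(res)[names(res) == "module"] <- "set"
  res$flagged <- NULL
  res
}

#' Express a count ratio as a printed percentage
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @param digits Decimal digits (default 1).
#' @return `100 * k / n` rounded to `digits`.
#' @export
overlap_percent <- function(k, n, digits = 1) {
  if (n <= 0) stop("denominator must be positive")
  round(100 * k / n, digits)
}
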