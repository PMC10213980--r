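test_that("minor allele frequency folds the coded-allele frequency", {
  expect_equal(minor_allele_frequency(c(0, 0, 1, 2)), 0.375)
  expect_equal(minor_allele_frequency(c(2, 2, 2)), 0)
  expect_equal(minor_allele_frequency(c(1, 1, 1, 1)), 0.5)
  expect_equal(minor_allele_frequency(c(0, NA, 1)), 0.25)
  expect_error(minor_allele_frequency(c(NA, NA)), "missing")
})

test_that("cis window is inclusive at exactly 1 Mb from the gene edge", {
  genes <- data.frame(feature_id = "G1", chrom = "chr1",
                      start = 1000000, end = 1050000,
                      stringsAsFactors = FALSE)
  vm <- data.frame(variant_id = c("in_b", "out_b", "inside", "up"),
                   chrom = "chr1",
                   pos = c(2050000, 2050001, 1020000, 1),
                   stringsAsFactors = FALSE)
  pairs <- cis_candidate_pairs(genes, vm, window = 1e6)
  expect_true("in_b" %in% pairs$variant_id)
  expect_false("out_b" %in% pairs$variant_id)
  expect_equal(pairs$distance[pairs$variant_id == "in_b"], 1e6)
  expect_equal(pairs$distance[pairs$variant_id == "inside"], 0)
  expect_equal(pairs$distance[pairs$variant_id == "up"], 1 - 1000000)

  vm$chrom[1] <- NA
  expect_error(cis_candidate_pairs(genes, vm), "chromosome")
})

test_that("cis distances agree with a brute-force interval check", {
  set.seed(50)
  genes <- data.frame(feature_id = paste0("G", 1:20), chrom = "chr1",
                      start = sort(sample.int(4.9e7, 20) + 1e6),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(1e3:5e4, 20)
  vm <- data.frame(variant_id = paste0("v", 1:50), chrom = "chr1",
                   pos = sample.int(5.2e7, 50), stringsAsFactors = FALSE)
  w <- 1e6
  pairs <- cis_candidate_pairs(genes, vm, window = w)
  key <- paste(pairs$variant_id, pairs$feature_id)
  for (i in 1:50) for (j in 1:20) {
    p <- vm$pos[i]
    d <- if (p < genes$start[j]) p - genes$start[j]
         else if (p > genes$end[j]) p - genes$end[j] else 0
    inwin <- abs(d) <= w
    expect_equal(paste(vm$variant_id[i], genes$feature_id[j]) %in% key, inwin)
    if (inwin)
      expect_equal(pairs$distance[pairs$variant_id == vm$variant_id[i] &
                                  pairs$feature_id == genes$feature_id[j]], d)
  }
})

test_that("the scan recovers the planted cis effect and applies the MAF filter", {
  fx <- default_fixture()
  norm <- normalized_cohorts()
  pooled <- expression_matrix(do.call(cbind, lapply(norm, function(x) x$values)),
                              "pooled")
  pairs <- cis_candidate_pairs(fx$gene_coords, fx$genotypes$map)
  res <- pqtl_scan(pooled, fx$genotypes, pairs, maf_min = 0.05)
  planted <- merge(res, fx$truth$cis_pairs, by = c("variant_id", "feature_id"))
  found <- planted[planted$p < 1e-6, ]
  expect_gte(nrow(found), 1)
  expect_true(all(found$beta.x > 0))           # planted beta positive
  expect_true(all(abs(found$beta.x - found$beta.y) < 0.3))
  expect_true(all(res$maf > 0.05))
  expect_true(all(abs(res$distance) <= 1e6))

  # a variant below the MAF threshold is dropped and counted
  g <- fx$genotypes
  rare <- g
  rare$dosages[1, ] <- 0L
  rare$dosages[1, 1:15] <- 1L   # MAF = 15 / (2 * 600) = 0.0125
  res2 <- pqtl_scan(pooled, rare, pairs[pairs$variant_id == g$map$variant_id[1], ,
                                        drop = FALSE])
  expect_equal(nrow(res2), 0)
  expect_gte(attr(res2, "n_maf_filtered"), 1)
})

test_that("swapping the coded allele flips beta but not the test", {
  fx <- default_fixture()
  norm <- normalized_cohorts()
  pooled <- expression_matrix(do.call(cbind, lapply(norm, function(x) x$values)),
                              "pooled")
  cp <- fx$truth$cis_pairs[1, ]
  pairs <- data.frame(variant_id = cp$variant_id, feature_id = cp$feature_id,
                      distance = 0, stringsAsFactors = FALSE)
  res <- pqtl_scan(pooled, fx$genotypes, pairs)
  flipped <- fx$genotypes
  flipped$dosages[cp$variant_id, ] <- 2L - flipped$dosages[cp$variant_id, ]
  res_f <- pqtl_scan(pooled, flipped, pairs)
  expect_equal(res$beta, -res_f$beta, tolerance = 1e-10)
  expect_equal(res$p, res_f$p, tolerance = 1e-10)
  expect_equal(res$maf, res_f$maf, tolerance = 1e-12)
})

test_that("null genotype-feature pairs hold the nominal type-I rate", {
  set.seed(51)
  n <- 150
  sid <- sprintf("s%03d", 1:n)
  nrep <- 2000
  v <- matrix(rnorm(nrep * n), nrow = nrep,
              dimnames = list(sprintf("f%04d", 1:nrep), sid))
  dos <- matrix(rbinom(nrep * n, 2, 0.3), nrow = nrep,
                dimnames = list(sprintf("v%04d", 1:nrep), sid))
  g <- genotype_matrix(dos, data.frame(variant_id = rownames(dos),
                                       chrom = "chr1", pos = seq_len(nrep),
                                       stringsAsFactors = FALSE))
  pairs <- data.frame(variant_id = rownames(dos),
                      feature_id = rownames(v), distance = 0,
                      stringsAsFactors = FALSE)
  res <- pqtl_scan(expression_matrix(v, "null"), g, pairs)
  expect_equal(nrow(res), nrep)
  expect_gt(mean(res$p < 0.05), 0.04)
  expect_lt(mean(res$p < 0.05), 0.06)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})
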