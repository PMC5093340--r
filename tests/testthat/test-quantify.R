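make_counts <- function(seed = 2, n_genes = 50, n_samples = 6) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda = 50) + 1L,
              n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  m
}

test_that("size factors: identity, scale equivariance, formula oracle", {
  counts <- make_counts()
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- c("a", "b", "c")
  expect_equal(unname(size_factors(same)), c(1, 1, 1))

  doubled <- cbind(counts, x2 = counts[, 1] * 2L)
  sf <- size_factors(doubled)
  expect_equal(unname(sf[["x2"]] / sf[["s1"]]), 2)

  # literal median-of-ratios re-implementation
  eligible <- rowSums(counts > 0) == ncol(counts)
  geo <- apply(counts[eligible, ], 1, function(v) exp(mean(log(v))))
  oracle <- apply(counts[eligible, ], 2, function(col) median(col / geo))
  expect_equal(size_factors(counts), oracle)

  zero <- counts
  zero[cbind(seq_len(nrow(zero)), rep_len(seq_len(ncol(zero)), nrow(zero)))] <- 0L
  expect_error(size_factors(zero), "pre-filter")
})

test_that("size factors agree with the DESeq median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  counts <- make_counts(seed = 7)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  # the reference takes the median on the log scale; with an even number
  # of eligible genes the two medians differ at the 4th decimal
  expect_equal(size_factors(counts), ref, tolerance = 1e-3)
})

test_that("FPKM arithmetic and scale equivariance", {
  # count 100, length 1000 bp, effective library 1e7 -> FPKM 10
  counts <- matrix(c(100L, 9999900L), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  sf <- c(s1 = 1)
  fp <- fpkm_matrix(counts, c(g1 = 1000, g2 = 1e6), sf)
  expect_equal(fp["g1", "s1"], 100 * 1e9 / (1000 * 1e7))
  expect_equal(fp["g1", "s1"], 10)

  counts2 <- make_counts()
  counts2[3, 2] <- 0L
  fp2 <- fpkm_matrix(counts2, setNames(rep(500, nrow(counts2)),
                                       rownames(counts2)))
  expect_equal(fp2[3, 2], 0)

  # scaling one whole library cancels through the size factor up to a
  # single constant: the scaled sample's FPKM vector stays proportional,
  # with factor c^(1/n) * mean(lib_old) / mean(lib_new) (the geometric
  # means absorb c^(1/n), the denominator anchor follows the raw mean)
  scaled <- counts2
  scaled[, 4] <- scaled[, 4] * 3L
  fp3 <- fpkm_matrix(scaled, setNames(rep(500, nrow(scaled)),
                                      rownames(scaled)))
  const <- 3^(1 / ncol(counts2)) *
    mean(colSums(counts2)) / mean(colSums(scaled))
  expect_equal(fp3[, 4], fp2[, 4] * const, tolerance = 1e-12)

  # spreadsheet-style recomputation
  sf2 <- size_factors(counts2)
  lib <- colSums(counts2)
  oracle <- counts2
  for (j in seq_len(ncol(counts2)))
    oracle[, j] <- counts2[, j] * 1e9 / (500 * sf2[j] * mean(lib))
  expect_equal(fp2, oracle)

  bad <- counts2
  bad[, 1] <- 0L
  expect_error(fpkm_matrix(bad, setNames(rep(500, nrow(bad)), rownames(bad))),
               "zero total counts")
})

test_that("intergenic read fractions, contributors and conservation", {
  genes <- c("cod1", "cod2", "int1", "int2", "int3", "gen1")
  catalogue <- data.frame(
    gene_id = c("int1", "int2", "int3", "gen1"),
    class = c("intergenic", "intergenic", "intergenic", "genic"),
    nearest_coding_id = NA, distance_bp = c(Inf, Inf, Inf, 0),
    stringsAsFactors = FALSE)
  smap <- data.frame(sample = c("s1", "s2", "s3", "s4"),
                     cancer = c("A", "A", "B", "B"),
                     stringsAsFactors = FALSE)

  all_coding <- matrix(10L, 6, 4, dimnames = list(genes, smap$sample))
  all_coding[3:6, ] <- 0L
  res0 <- intergenic_read_fraction(all_coding, catalogue, smap)
  expect_equal(unname(res0$fraction), rep(0, 4))

  counts <- matrix(100L, 6, 4, dimnames = list(genes, smap$sample))
  counts["int1", c("s1", "s2")] <- 600L   # dominant contributor in A
  res <- intergenic_read_fraction(counts, catalogue, smap)
  inter_total <- colSums(counts[c("int1", "int2", "int3"), ])
  expect_equal(res$fraction, inter_total / colSums(counts))
  # conservation: intergenic + non-intergenic = 1
  other <- colSums(counts[c("cod1", "cod2", "gen1"), ]) / colSums(counts)
  expect_equal(unname(res$fraction + other), rep(1, 4))

  ca <- res$contributors[res$contributors$cancer == "A", ]
  expect_equal(ca$gene_id[1], "int1")
  expect_equal(ca$share[1], 1200 / sum(counts[, c("s1", "s2")]))
  pc <- res$per_cancer
  expect_true(all(pc$topk_contribution <= pc$intergenic_fraction + 1e-12))
})

test_that("one-way ANOVA on fractions behaves as the classical null F-test", {
  catalogue <- data.frame(gene_id = "i1", class = "intergenic",
                          nearest_coding_id = NA, distance_bp = Inf)
  smap <- data.frame(sample = sprintf("s%02d", 1:30),
                     cancer = rep(c("A", "B", "C"), each = 10))
  set.seed(4)
  fs <- replicate(40, {
    counts <- rbind(i1 = rpois(30, 50) + 1L, c1 = rpois(30, 450) + 1L)
    colnames(counts) <- smap$sample
    res <- intergenic_read_fraction(counts, catalogue, smap)
    # cross-check against aov on the same data
    f_aov <- summary(stats::aov(res$fraction ~ factor(smap$cancer)))[[1]]$`F value`[1]
    expect_equal(res$anova$f, f_aov, tolerance = 1e-10)
    res$anova$f
  })
  expect_equal(mean(fs), 1, tolerance = 0.35)  # E[F] = (n-k)/(n-k-2) ~ 1.08
})

test_that("DNA-RNA correlation: exact, null and planted-slope cases", {
  smap <- data.frame(sample = sprintf("s%03d", 1:200), cancer = "A")
  set.seed(6)
  amp <- matrix(rnorm(200), 1, 200, dimnames = list("g1", smap$sample))
  # expression exactly linear in amplitude -> r = 1
  fp <- matrix(10 + 2 * amp, 1, 200, dimnames = dimnames(amp))
  res <- dna_rna_correlation(fp, amp, smap)
  expect_equal(res$A$correlations$r, 1)

  # independent amplitude -> r near 0
  fp_null <- matrix(rnorm(200, 10), 1, 200, dimnames = dimnames(amp))
  res0 <- dna_rna_correlation(fp_null, amp, smap)
  expect_lt(abs(res0$A$correlations$r), 0.2)

  # planted dosage slopes on the log2 scale: analytic r = s*sd_a /
  # sqrt(s^2 sd_a^2 + sigma^2); median over genes within 0.05 at n = 200
  slope <- 0.5; sigma <- 0.5
  n_genes <- 60
  amp_m <- matrix(rnorm(n_genes * 200), n_genes, 200,
                  dimnames = list(sprintf("g%02d", 1:n_genes), smap$sample))
  expr <- 2^(4 + slope * amp_m + matrix(rnorm(n_genes * 200, 0, sigma),
                                        n_genes, 200))
  dimnames(expr) <- dimnames(amp_m)
  res2 <- dna_rna_correlation(expr, amp_m, smap)
  # closed form for X ~ N(0,1), Y = exp(bX + tZ) with b = slope*ln2,
  # t = sigma*ln2: r = b / sqrt(exp(b^2 + t^2) - 1)
  b <- slope * log(2); tt <- sigma * log(2)
  r_expected <- b / sqrt(exp(b^2 + tt^2) - 1)
  expect_equal(median(res2$A$correlations$r), r_expected, tolerance = 0.05)

  # skip rules: < 3 samples or zero variance
  smap3 <- data.frame(sample = c("x1", "x2"), cancer = "B")
  amp3 <- matrix(c(1, 2), 1, 2, dimnames = list("g1", smap3$sample))
  fp3 <- matrix(c(10, 20), 1, 2, dimnames = dimnames(amp3))
  res3 <- dna_rna_correlation(fp3, amp3, smap3)
  expect_equal(res3$B$skipped, "g1")
  expect_null(res3$B$correlations)
})

test_that("Pearson r is invariant under affine transforms of either variable", {
  smap <- data.frame(sample = sprintf("s%02d", 1:50), cancer = "A")
  set.seed(8)
  amp <- matrix(rnorm(50), 1, 50, dimnames = list("g1", smap$sample))
  fp <- matrix(2^(3 + 0.7 * amp + rnorm(50, 0, 0.3)), 1, 50,
               dimnames = dimnames(amp))
  r0 <- dna_rna_correlation(fp, amp, smap)$A$correlations$r
  r1 <- dna_rna_correlation(fp, 3 * amp + 7, smap)$A$correlations$r
  expect_equal(r1, r0)
})

test_that("PCA overview separates distinct profiles and handles degeneracy", {
  catalogue <- data.frame(gene_id = sprintf("i%02d", 1:30),
                          class = "intergenic", nearest_coding_id = NA,
                          distance_bp = Inf, stringsAsFactors = FALSE)
  set.seed(12)
  muA <- rnorm(30, 4, 1.5)
  muB <- rnorm(30, 4, 1.5)
  mk <- function(mu, n) 2^(mu + matrix(rnorm(30 * n, 0, 0.4), 30, n))
  fp <- cbind(mk(muA, 25), mk(muB, 25))
  dimnames(fp) <- list(catalogue$gene_id, sprintf("s%02d", 1:50))
  res <- pca_overview(fp, catalogue)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_lte(sum(res$explained), 1 + 1e-12)

  skip_if_not_installed("cluster")
  lab <- rep(1:2, each = 25)
  sil <- cluster::silhouette(lab, dist(res$scores[, 1:2]))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  # replicated identical profile -> all scores zero
  fp_c <- matrix(rep(2^muA, 10), 30, 10,
                 dimnames = list(catalogue$gene_id, sprintf("c%d", 1:10)))
  res_c <- pca_overview(fp_c, catalogue)
  expect_equal(max(abs(res_c$scores)), 0)

  # full-rank reconstruction
  x <- t(log2(fp + 0.1))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  rec <- pc$x %*% t(pc$rotation) + matrix(pc$center, nrow(x), ncol(x),
                                          byrow = TRUE)
  expect_equal(max(abs(rec - x)), 0, tolerance = 1e-8)

  expect_error(pca_overview(fp[1, , drop = FALSE],
                            catalogue[1, , drop = FALSE]),
               "fewer than 2")
})
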