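#' Robust (median-of-ratios) size factors
#'
#' The size factor of sample j is the median, over genes with nonzero
#' counts in every sample, of the ratio between the gene's count in j and
#' its geometric mean count across samples.
#'
#' @param counts non-negative integer matrix, genes x samples
#' @return named positive numeric vector, one factor per sample
#' @export
size_factors <- function(counts) {
  .check_matrix(counts, "counts")
  eligible <- rowSums(counts > 0) == ncol(counts)
  if (!any(eligible))
    .stopf(paste("no gene has nonzero counts in every sample;",
                 "pre-filter the matrix to genes detected in all samples"))
  sub <- counts[eligible, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2, stats::median)
  stopifnot(all(sf > 0))
  sf
}

#' FPKM from fragment counts
#'
#' `fpkm[i,j] = counts[i,j] * 1e9 / (length[i] * N_j)` with the effective
#' library size `N_j = size_factor[j] * mean(colSums(counts))`. Anchoring
#' the robustly normalized library sizes at the cohort mean raw library
#' size keeps values on the familiar FPKM scale.
#'
#' @param counts genes x samples count matrix
#' @param gene_lengths bp per gene (mature length), named or in row order
#' @param sf per-sample size factors; computed with [size_factors()] when
#'   `NULL`
#' @return FPKM matrix with the dimensions and dimnames of `counts`
#' @export
fpkm_matrix <- function(counts, gene_lengths, sf = NULL) {
  .check_matrix(counts, "counts")
  if (!is.null(names(gene_lengths)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (length(gene_lengths) != nrow(counts) || anyNA(gene_lengths))
    .stopf("gene_lengths must cover every row of counts")
  if (any(gene_lengths <= 0)) .stopf("gene lengths must be positive")
  lib <- colSums(counts)
  if (any(lib == 0))
    .stopf("zero total counts in sample(s): %s",
           paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(sf)) sf <- size_factors(counts)
  n_eff <- sf[colnames(counts)] * mean(lib)
  fpkm <- sweep(counts * 1e9 / gene_lengths, 2, n_eff, "/")
  dimnames(fpkm) <- dimnames(counts)
  fpkm
}

#' Per-sample intergenic read fraction and top contributors
#'
#' For each sample, the fraction of gene-mapped fragments falling on
#' intergenic lncRNA loci. Per cancer type, the intergenic loci are ranked
#' by their summed counts and the top `top_k` contributors are reported
#' with their share of all gene-mapped fragments in that cancer. A
#' classical one-way ANOVA F-test across cancer labels on the per-sample
#' fractions is reported alongside.
#'
#' @param counts genes x samples count matrix
#' @param catalogue classified `lnc_catalogue`
#' @param sample_map data frame with columns `sample`, `cancer`
#' @param top_k number of top contributors per cancer (default 5)
#' @return list: `fraction` (named per-sample vector), `per_cancer` (data
#'   frame with the aggregate intergenic fraction and the summed top-k
#'   share per cancer), `contributors` (data frame: cancer, gene_id, rank,
#'   share), `anova` (list with `f` and `p`; `NULL` with fewer than two
#'   cancer types)
#' @export
intergenic_read_fraction <- function(counts, catalogue, sample_map,
                                     top_k = 5) {
  .check_matrix(counts, "counts")
  inter <- intersect(catalogue$gene_id[catalogue$class %in% "intergenic"],
                     rownames(counts))
  total <- colSums(counts)
  inter_counts <- if (length(inter))
    colSums(counts[inter, , drop = FALSE]) else rep(0, ncol(counts))
  frac <- ifelse(total > 0, inter_counts / total, 0)
  names(frac) <- colnames(counts)

  cancer_of <- sample_map$cancer[match(colnames(counts), sample_map$sample)]
  contributors <- NULL
  per_cancer <- NULL
  for (cc in unique(cancer_of)) {
    cols <- which(cancer_of == cc)
    tot_c <- sum(total[cols])
    if (length(inter) && tot_c > 0) {
      sums <- rowSums(counts[inter, cols, drop = FALSE])
      ord <- order(-sums, inter)
      k <- min(top_k, sum(sums > 0))
      top <- if (k > 0) ord[seq_len(k)] else integer(0)
      contributors <- rbind(contributors, if (k > 0) data.frame(
        cancer = cc, gene_id = inter[top], rank = seq_len(k),
        share = sums[top] / tot_c, stringsAsFactors = FALSE))
      per_cancer <- rbind(per_cancer, data.frame(
        cancer = cc, intergenic_fraction = sum(sums) / tot_c,
        topk_contribution = if (k > 0) sum(sums[top]) / tot_c else 0,
        stringsAsFactors = FALSE))
    } else {
      per_cancer <- rbind(per_cancer, data.frame(
        cancer = cc, intergenic_fraction = 0, topk_contribution = 0,
        stringsAsFactors = FALSE))
    }
  }
  anova <- NULL
  if (length(unique(cancer_of)) > 1) {
    fit <- stats::oneway.test(frac ~ factor(cancer_of), var.equal = TRUE)
    anova <- list(f = unname(fit$statistic), p = unname(fit$p.value))
  }
  list(fraction = frac, per_cancer = per_cancer,
       contributors = contributors, anova = anova)
}

#' Per-cancer DNA-RNA correlation for highly expressed genes
#'
#' Within each cancer type, for every gene whose mean FPKM exceeds
#' `min_mean_fpkm`, the Pearson correlation between per-sample copy-number
#' amplitude and FPKM. Genes with fewer than 3 informative samples or zero
#' variance in either variable are skipped and recorded.
#'
#' @param fpkm genes x samples FPKM matrix
#' @param cn_amplitudes genes x samples amplitude matrix (NA = no call)
#' @param sample_map data frame with columns `sample`, `cancer`
#' @param min_mean_fpkm within-cancer mean-FPKM filter (default 5)
#' @return list per cancer, each a list with `correlations` (data frame
#'   gene_id, r, n) and `skipped` (character vector of gene ids)
#' @export
dna_rna_correlation <- function(fpkm, cn_amplitudes, sample_map,
                                min_mean_fpkm = 5) {
  .check_matrix(fpkm, "fpkm")
  common <- intersect(rownames(fpkm), rownames(cn_amplitudes))
  cancer_of <- sample_map$cancer[match(colnames(fpkm), sample_map$sample)]
  out <- list()
  for (cc in unique(cancer_of)) {
    cols <- colnames(fpkm)[cancer_of == cc]
    cols <- intersect(cols, colnames(cn_amplitudes))
    sub <- fpkm[common, cols, drop = FALSE]
    genes <- common[rowMeans(sub) > min_mean_fpkm]
    res <- NULL
    skipped <- character(0)
    for (g in genes) {
      a <- cn_amplitudes[g, cols]
      e <- sub[g, ]
      ok <- !is.na(a)
      if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(e[ok]) == 0) {
        skipped <- c(skipped, g)
        next
      }
      res <- rbind(res, data.frame(gene_id = g,
                                   r = stats::cor(a[ok], e[ok]),
                                   n = sum(ok), stringsAsFactors = FALSE))
    }
    out[[cc]] <- list(correlations = res, skipped = skipped)
  }
  out
}

#' PCA overview on intergenic lncRNA expression
#'
#' Principal components of `log2(FPKM + pseudo)` over intergenic lncRNAs
#' expressed above `expr_threshold` in at least one sample. The input is
#' gene-centred but not unit-scaled.
#'
#' @param fpkm genes x samples FPKM matrix
#' @param catalogue classified `lnc_catalogue`
#' @param expr_threshold max-FPKM inclusion threshold (default 5)
#' @param pseudo pseudo-count before log transform (default 0.1)
#' @return list: `scores` (samples x components), `explained` (fraction of
#'   variance per component, non-increasing), `features` (gene ids used)
#' @export
pca_overview <- function(fpkm, catalogue, expr_threshold = 5, pseudo = 0.1) {
  .check_matrix(fpkm, "fpkm")
  inter <- intersect(catalogue$gene_id[catalogue$class %in% "intergenic"],
                     rownames(fpkm))
  feats <- inter[apply(fpkm[inter, , drop = FALSE], 1, max) > expr_threshold]
  if (length(feats) < 2)
    .stopf("fewer than 2 intergenic lncRNAs above FPKM %s", expr_threshold)
  x <- t(log2(fpkm[feats, , drop = FALSE] + pseudo))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x, explained = ev / sum(ev), features = feats)
}
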