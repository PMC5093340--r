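# Independent brute-force oracles and fixture builders shared across tests.
# These deliberately avoid the package's own code paths (GenomicRanges,
# vectorized rank sums) so agreement is a real cross-check.

# gap in bp between two 0-based half-open spans; 0 on overlap
oracle_gap <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2))

# O(n^2) all-pairs genic/intergenic classification
oracle_classify <- function(models, lnc_ids, threshold = 5000) {
  coding <- models[models$is_coding, , drop = FALSE]
  out <- data.frame(gene_id = lnc_ids, class = NA_character_,
                    nearest_coding_id = NA_character_, distance_bp = Inf,
                    stringsAsFactors = FALSE)
  for (i in seq_along(lnc_ids)) {
    q <- models[models$gene_id == lnc_ids[i], ]
    best_d <- Inf; best_id <- NA_character_
    best_start <- Inf
    for (j in seq_len(nrow(coding))) {
      cj <- coding[j, ]
      if (cj$chrom != q$chrom) next
      d <- oracle_gap(q$start, q$end, cj$start, cj$end)
      better <- d < best_d ||
        (d == best_d && (cj$start < best_start ||
                           (cj$start == best_start && cj$gene_id < best_id)))
      if (better) { best_d <- d; best_id <- cj$gene_id; best_start <- cj$start }
    }
    out$distance_bp[i] <- best_d
    out$nearest_coding_id[i] <- best_id
  }
  out$class <- ifelse(out$distance_bp < threshold, "genic", "intergenic")
  out
}

# exhaustive neighbour scan over all coding genes
oracle_neighbours <- function(query_id, models, window = 1e5) {
  q <- models[models$gene_id == query_id, ]
  coding <- models[models$is_coding & models$gene_id != query_id &
                     models$chrom == q$chrom, , drop = FALSE]
  if (!nrow(coding))
    return(list(upstream = NA_character_, downstream = NA_character_,
                within = character(0)))
  gap <- mapply(function(s, e) oracle_gap(q$start, q$end, s, e),
                coding$start, coding$end)
  ord <- order(gap, coding$start, coding$gene_id)
  pick <- function(sel) if (any(sel)) {
    o <- ord[sel[ord]]; coding$gene_id[o[1]]
  } else NA_character_
  list(upstream = pick(coding$end <= q$start),
       downstream = pick(coding$start >= q$end),
       within = coding$gene_id[ord][gap[ord] <= window])
}

# brute-force minimum-amplitude copy-number mapping
oracle_cn_map <- function(segments, models, min_segment = 1e4) {
  samples <- sort(unique(segments$sample))
  amp <- matrix(NA_real_, nrow(models), length(samples),
                dimnames = list(models$gene_id, samples))
  for (k in seq_len(nrow(segments))) {
    s <- segments[k, ]
    if (s$end - s$start < min_segment) next
    for (i in seq_len(nrow(models))) {
      g <- models[i, ]
      if (g$chrom != s$chrom) next
      if (max(g$start, s$start) < min(g$end, s$end)) {  # overlap
        cur <- amp[g$gene_id, s$sample]
        amp[g$gene_id, s$sample] <- if (is.na(cur)) s$amplitude
          else min(cur, s$amplitude)
      }
    }
  }
  amp
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y); N <- length(pooled); n1 <- length(x)
  rk <- rank(pooled)
  wobs <- sum(rk[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  cmb <- utils::combn(N, n1)
  W <- colSums(matrix(rk[cmb], nrow = n1))
  mean(abs(W - mu) >= abs(wobs - mu) - 1e-9)
}

# random gene-model fixture: coding and non-coding genes scattered over a
# few chromosomes (plain data.frame, no package constructors)
random_models <- function(n, seed, chroms = c("c1", "c2"),
                          span = c(500, 20000), max_pos = 2e6) {
  set.seed(seed)
  start <- floor(runif(n, 0, max_pos))
  width <- floor(runif(n, span[1], span[2]))
  coding <- runif(n) < 0.5
  df <- data.frame(
    gene_id = sprintf("G%03d", seq_len(n)),
    gene_name = sprintf("G%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotypes = ifelse(coding, "protein_coding", "lincRNA"),
    mature_length = pmax(200, floor(width * 0.3)),
    is_coding = coding, stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

# small simulated cohort reused by several suites (kept modest for speed)
small_sim <- function(seed = 11, planted = TRUE) {
  cfg <- sim_config(seed = seed, cancers = c(A = 60, B = 60, C = 60),
                    n_coding = 100, n_lnc = 300, n_events = 4)
  if (planted)
    cfg <- plant_targets(cfg, 6, effect_log2 = 3, n_cancers = 2,
                         mediation = "mixed")
  ann <- simulate_annotation(cfg)
  coh <- simulate_cohort(cfg, ann)
  fp <- fpkm_matrix(coh$counts,
                    stats::setNames(ann$models$mature_length,
                                    ann$models$gene_id))
  list(cfg = cfg, ann = ann, coh = coh, fpkm = fp)
}

# hand-written GTF fixture with a hand-computed expectation table.
# Coordinates below are 1-based inclusive as in the file; the expected
# table is in internal 0-based half-open coordinates.
fixture_gtf_lines <- function() c(
  '# fixture',
  'c1\tt\tgene\t1\t300\t.\t+\t.\tgene_id "GA"; gene_name "geneA";',
  'c1\tt\ttranscript\t1\t300\t.\t+\t.\tgene_id "GA"; transcript_id "GA.1"; transcript_type "lincRNA";',
  'c1\tt\texon\t1\t100\t.\t+\t.\tgene_id "GA"; transcript_id "GA.1"; transcript_type "lincRNA";',
  'c1\tt\texon\t201\t300\t.\t+\t.\tgene_id "GA"; transcript_id "GA.1"; transcript_type "lincRNA";',
  'c1\tt\tgene\t1000\t2000\t.\t-\t.\tgene_id "GB"; gene_name "geneB";',
  'c1\tt\ttranscript\t1000\t1500\t.\t-\t.\tgene_id "GB"; transcript_id "GB.1"; transcript_type "antisense";',
  'c1\tt\texon\t1000\t1179\t.\t-\t.\tgene_id "GB"; transcript_id "GB.1"; transcript_type "antisense";',
  'c1\tt\ttranscript\t1000\t2000\t.\t-\t.\tgene_id "GB"; transcript_id "GB.2"; transcript_type "processed_transcript";',
  'c1\tt\texon\t1000\t1099\t.\t-\t.\tgene_id "GB"; transcript_id "GB.2"; transcript_type "processed_transcript";',
  'c1\tt\texon\t1851\t2000\t.\t-\t.\tgene_id "GB"; transcript_id "GB.2"; transcript_type "processed_transcript";',
  'c2\tt\tgene\t501\t4000\t.\t+\t.\tgene_id "GC"; gene_name "geneC";',
  'c2\tt\ttranscript\t501\t4000\t.\t+\t.\tgene_id "GC"; transcript_id "GC.1"; transcript_type "protein_coding";',
  'c2\tt\texon\t501\t1500\t.\t+\t.\tgene_id "GC"; transcript_id "GC.1"; transcript_type "protein_coding";',
  'c2\tt\texon\t3001\t4000\t.\t+\t.\tgene_id "GC"; transcript_id "GC.1"; transcript_type "protein_coding";',
  'c2\tt\ttranscript\t501\t1500\t.\t+\t.\tgene_id "GC"; transcript_id "GC.2"; transcript_type "lincRNA";',
  'c2\tt\texon\t501\t700\t.\t+\t.\tgene_id "GC"; transcript_id "GC.2"; transcript_type "lincRNA";'
)

# hand parsing of the fixture above:
#  GA: span 1..300 -> [0,300); exons 100 + 100 -> mature 200; lincRNA
#  GB: span 1000..2000 -> [999,2000); isoforms 180 and 100+150=250 -> 250
#  GC: span 501..4000 -> [500,4000); isoforms 1000+1000=2000 and 200 -> 2000
#      biotypes {protein_coding, lincRNA} -> coding
fixture_gtf_expected <- function() data.frame(
  gene_id = c("GA", "GB", "GC"),
  gene_name = c("geneA", "geneB", "geneC"),
  chrom = c("c1", "c1", "c2"),
  start = c(0L, 999L, 500L), end = c(300L, 2000L, 4000L),
  strand = c("+", "-", "+"),
  biotypes = c("lincRNA", "antisense,processed_transcript",
               "lincRNA,protein_coding"),
  mature_length = c(200, 250, 2000),
  is_coding = c(FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE)
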