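#' Configuration for the synthetic multi-cancer cohort generator
#'
#' Bundles every knob of the generator with validation. The defaults
#' describe the study conditions the screen's tests run under: six cancer
#' types of 100 samples, 2,000 lncRNA features with half the catalogue
#' genic, ten driver events mutated in 10% of samples, log-normal
#' expression (baseline log2-FPKM ~ N(3, 2), per-sample noise sd 0.5 in
#' log2 units) with dropout on the low-expressed half of the genes, a
#' copy-number dosage slope of 0.5 per log-ratio unit, and a host
#' co-expression of r = 0.9 for host-mediated planted targets.
#'
#' @param seed integer seed (mandatory; all randomness flows from it)
#' @param cancers named integer vector, cancer label -> number of samples
#' @param n_coding,n_lnc numbers of coding genes and lncRNAs
#' @param lnc_genic_fraction fraction of lncRNAs placed genic (within the
#'   5 kb rule of a designated coding host)
#' @param events named numeric vector, driver gene id -> per-cancer
#'   mutation frequency in (0, 1); `NULL` makes `n_events` events on the
#'   first coding genes at `event_frequency`
#' @param n_events,event_frequency used when `events` is `NULL`
#' @param planted data frame of planted targets with columns `feature`,
#'   `event`, `effect_log2`, `cancers` (comma-joined labels), `mediation`
#'   (`direct` or `via_host`); `NULL` for a null cohort
#' @param sigma per-sample expression noise sd (log2 units)
#' @param baseline_mean,baseline_sd per-gene baseline log2-FPKM
#'   distribution
#' @param zero_inflation dropout probability applied to low-expressed
#'   genes (baseline below `dropout_below`), after any planted effect
#' @param dropout_below baseline log2-FPKM under which dropout applies
#'   (default 1, i.e. genes under ~2 FPKM; zeros in bulk RNA-seq counts
#'   are confined to weakly expressed genes)
#' @param host_coexpr_r latent-factor correlation tying a lncRNA to its
#'   coding host for `via_host` targets
#' @param dosage_slope copy-number effect on log2 expression per
#'   log-ratio unit of amplitude
#' @param cancer_profile_sd sd of per-gene per-cancer mean offsets
#'   (inter-cancer expression differences)
#' @param cn_sd sd of the per-chromosome copy-number amplitude
#' @param decoy_segment_rate probability of adding a sub-10 kb decoy
#'   segment per sample and chromosome
#' @param silent_decoy_freq probability that a wild-type sample carries a
#'   silent (non-qualifying) record of a driver gene
#' @param lib_size_mean,lib_size_cv library-size log-normal parameters
#' @param genes_per_chrom,coding_spacing synthetic chromosome layout
#' @return validated object of class `sim_config`
#' @export
sim_config <- function(seed,
                       cancers = c(C1 = 100, C2 = 100, C3 = 100,
                                   C4 = 100, C5 = 100, C6 = 100),
                       n_coding = 400, n_lnc = 2000,
                       lnc_genic_fraction = 0.5,
                       events = NULL, n_events = 10,
                       event_frequency = 0.10,
                       planted = NULL,
                       sigma = 0.5, baseline_mean = 3, baseline_sd = 2,
                       zero_inflation = 0.1, dropout_below = 1,
                       host_coexpr_r = 0.9,
                       dosage_slope = 0.5, cancer_profile_sd = 0.5,
                       cn_sd = 0.3, decoy_segment_rate = 0.2,
                       silent_decoy_freq = 0.05,
                       lib_size_mean = 2e7, lib_size_cv = 0.2,
                       genes_per_chrom = 50, coding_spacing = 2e5) {
  if (missing(seed) || is.null(seed)) .stopf("sim_config requires a seed")
  if (is.null(names(cancers)) || any(cancers < 1))
    .stopf("cancers must be a named vector of positive sample counts")
  if (is.null(events)) {
    stopifnot(n_events >= 1, n_events <= n_coding)
    events <- stats::setNames(rep(event_frequency, n_events),
                              .coding_ids(seq_len(n_events)))
  }
  if (any(events <= 0 | events >= 1))
    .stopf("event frequencies must lie in (0, 1)")
  if (zero_inflation < 0 || zero_inflation >= 1)
    .stopf("zero_inflation must lie in [0, 1)")
  if (!is.null(planted)) {
    need <- c("feature", "event", "effect_log2", "cancers", "mediation")
    if (!all(need %in% colnames(planted)))
      .stopf("planted needs columns: %s", paste(need, collapse = ", "))
    if (any(!is.finite(planted$effect_log2)))
      .stopf("planted effects must be finite")
    if (any(!planted$mediation %in% c("direct", "via_host")))
      .stopf("mediation must be direct or via_host")
    if (any(!planted$event %in% names(events)))
      .stopf("planted event(s) not among configured events")
  }
  structure(list(
    seed = as.integer(seed), cancers = cancers, n_coding = n_coding,
    n_lnc = n_lnc, lnc_genic_fraction = lnc_genic_fraction,
    events = events, planted = planted, sigma = sigma,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    zero_inflation = zero_inflation, dropout_below = dropout_below,
    host_coexpr_r = host_coexpr_r,
    dosage_slope = dosage_slope, cancer_profile_sd = cancer_profile_sd,
    cn_sd = cn_sd, decoy_segment_rate = decoy_segment_rate,
    silent_decoy_freq = silent_decoy_freq, lib_size_mean = lib_size_mean,
    lib_size_cv = lib_size_cv, genes_per_chrom = genes_per_chrom,
    coding_spacing = coding_spacing), class = "sim_config")
}

#' @keywords internal
.coding_ids <- function(i) sprintf("CODING%04d", i)
#' @keywords internal
.lnc_ids <- function(i) sprintf("LNC%04d", i)

#' Plant association targets into a configuration
#'
#' Deterministically assigns `n_targets` planted targets over the
#' configured lncRNAs, events and cancers: target t sits on lncRNA t
#' (genic lncRNAs for `via_host` mediation), cycles through the events,
#' is active in `n_cancers` consecutive cancer labels starting at a
#' rotating offset, and alternates effect sign.
#'
#' @param config a [sim_config()]
#' @param n_targets number of planted targets
#' @param effect_log2 absolute planted effect (log2 units, default 3)
#' @param n_cancers number of affected cancers per target (default 2)
#' @param mediation `"direct"`, `"via_host"`, or `"mixed"` (alternating)
#' @return the config with its `planted` table filled in
#' @export
plant_targets <- function(config, n_targets, effect_log2 = 3,
                          n_cancers = 2, mediation = "direct") {
  stopifnot(inherits(config, "sim_config"), n_targets >= 1)
  n_genic <- round(config$lnc_genic_fraction * config$n_lnc)
  labels <- names(config$cancers)
  ev <- names(config$events)
  med <- switch(mediation,
                direct = rep("direct", n_targets),
                via_host = rep("via_host", n_targets),
                mixed = rep(c("direct", "via_host"), length.out = n_targets),
                .stopf("unknown mediation: %s", mediation))
  # via_host targets must sit on genic lncRNAs (they need a host)
  if (any(med == "via_host") && n_genic < sum(med == "via_host"))
    .stopf("not enough genic lncRNAs for via_host targets")
  feature <- character(n_targets)
  feature[med == "via_host"] <- .lnc_ids(seq_len(sum(med == "via_host")))
  feature[med == "direct"] <-
    .lnc_ids(n_genic + seq_len(sum(med == "direct")))
  if (max(n_genic + sum(med == "direct")) > config$n_lnc)
    .stopf("not enough intergenic lncRNAs for direct targets")
  rows <- lapply(seq_len(n_targets), function(t) {
    cc <- labels[(((t - 1) + seq_len(n_cancers) - 1) %% length(labels)) + 1]
    data.frame(feature = feature[t],
               event = ev[((t - 1) %% length(ev)) + 1],
               effect_log2 = effect_log2 * if (t %% 2 == 0) -1 else 1,
               cancers = paste(cc, collapse = ","),
               mediation = med[t], stringsAsFactors = FALSE)
  })
  config$planted <- do.call(rbind, rows)
  config
}

#' Generate the synthetic annotation
#'
#' Lays coding genes on synthetic chromosomes at fixed spacing and places
#' lncRNAs to realize the configured genic fraction under the 5 kb rule:
#' genic lncRNAs overlap a designated coding host (antisense/intronic),
#' intergenic ones sit at least 20 kb from any coding gene. The layout is
#' deterministic (no randomness is consumed). Optionally emits a
#' GENCODE-dialect GTF that round-trips through [load_gene_models()].
#'
#' @param config a [sim_config()]
#' @param gtf_path optional path; when given, the annotation is written
#'   there as GTF
#' @return list: `models` (a `gene_models` data frame), `host_map` (named
#'   character vector lncRNA -> designated host coding gene), `gtf_path`
#' @export
simulate_annotation <- function(config, gtf_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_coding <- config$n_coding
  n_lnc <- config$n_lnc
  n_genic <- round(config$lnc_genic_fraction * n_lnc)
  gpc <- config$genes_per_chrom
  spacing <- config$coding_spacing

  genic_layers <- if (n_genic > 0) ceiling(n_genic / n_coding) else 0
  if (genic_layers > 5)
    .stopf("infeasible spacing: too many genic lncRNAs per coding host")
  inter_layers <- if (n_lnc - n_genic > 0)
    ceiling((n_lnc - n_genic) / n_coding) else 0
  if (inter_layers > (spacing - 36000) / 3000)
    .stopf("infeasible spacing: too many intergenic lncRNAs per gap")

  ci <- seq_len(n_coding)
  c_chrom <- sprintf("chrS%d", (ci - 1) %/% gpc + 1)
  c_start <- 100000L + ((ci - 1) %% gpc) * as.integer(spacing)
  coding <- data.frame(
    gene_id = .coding_ids(ci), gene_name = .coding_ids(ci),
    chrom = c_chrom, start = c_start, end = c_start + 10000L,
    strand = "+", biotypes = "protein_coding", mature_length = 4000,
    is_coding = TRUE, stringsAsFactors = FALSE)

  host_map <- stats::setNames(rep(NA_character_, n_lnc), .lnc_ids(seq_len(n_lnc)))
  lnc <- NULL
  if (n_genic > 0) {
    j <- seq_len(n_genic)
    a <- ((j - 1) %% n_coding) + 1
    m <- (j - 1) %/% n_coding
    s <- coding$start[a] + 3000L + m * 1500L
    lnc <- data.frame(
      gene_id = .lnc_ids(j), gene_name = .lnc_ids(j),
      chrom = coding$chrom[a], start = s, end = s + 1200L, strand = "-",
      biotypes = ifelse(j %% 2 == 0, "sense_intronic", "antisense"),
      mature_length = 800, is_coding = FALSE, stringsAsFactors = FALSE)
    host_map[.lnc_ids(j)] <- coding$gene_id[a]
  }
  if (n_lnc > n_genic) {
    j <- seq_len(n_lnc - n_genic)
    a <- ((j - 1) %% n_coding) + 1
    k <- (j - 1) %/% n_coding
    s <- coding$end[a] + 20000L + k * 3000L
    inter <- data.frame(
      gene_id = .lnc_ids(n_genic + j), gene_name = .lnc_ids(n_genic + j),
      chrom = coding$chrom[a], start = s, end = s + 1000L, strand = "+",
      biotypes = "lincRNA", mature_length = 600, is_coding = FALSE,
      stringsAsFactors = FALSE)
    lnc <- rbind(lnc, inter)
    host_map[.lnc_ids(n_genic + j)] <- coding$gene_id[a]
  }
  models <- rbind(coding, lnc)
  models <- models[order(models$gene_id), ]
  rownames(models) <- NULL
  class(models) <- c("gene_models", "data.frame")

  if (!is.null(gtf_path)) .write_models_gtf(models, gtf_path)
  list(models = models, host_map = host_map, gtf_path = gtf_path)
}

# Emit a minimal GENCODE-dialect GTF (gene/transcript/exon rows, two exons
# per transcript reproducing the recorded mature length).
#' @keywords internal
.write_models_gtf <- function(models, path) {
  lines <- character(0)
  attr1 <- function(gid, extra = "")
    sprintf('gene_id "%s"; gene_name "%s";%s', gid, gid, extra)
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    bt <- .split_biotypes(g$biotypes)[[1]][1]
    tid <- paste0(g$gene_id, ".T1")
    half <- g$mature_length / 2
    ex1 <- c(g$start, g$start + half)              # 0-based half-open
    ex2 <- c(g$end - half, g$end)
    row <- function(type, s0, e0, extra = "") {
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s0 + 1, e0, g$strand, attr1(g$gene_id, extra))
    }
    tx_attr <- sprintf(' transcript_id "%s"; transcript_type "%s";', tid, bt)
    lines <- c(lines,
               row("gene", g$start, g$end),
               row("transcript", g$start, g$end, tx_attr),
               row("exon", ex1[1], ex1[2], tx_attr),
               row("exon", ex2[1], ex2[2], tx_attr))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a multi-cancer cohort
#'
#' Draws mutation status per event and cancer (exactly
#' `round(frequency * n)` mutated samples, chosen uniformly), emits
#' MAF-like records with qualifying classes (plus silent decoys on
#' wild-type samples), draws per-chromosome copy-number segments of at
#' least 10 kb together with sub-10 kb decoys, and builds expression as
#'
#' `log2 FPKM = baseline + cancer offset + dosage_slope * amplitude +
#'   planted effect (mutated samples of affected cancers) + N(0, sigma)`
#'
#' with host-mediated targets applying their effect to the coding host and
#' tying the lncRNA to it through a shared latent factor at the configured
#' correlation. Dropout is applied after the effects; fragment counts are
#' back-computed from FPKM through the package's own FPKM formula with
#' randomized library sizes, so the normalization path is exercised rather
#' than bypassed.
#'
#' @param config a [sim_config()]
#' @param annotation result of [simulate_annotation()] for the same config
#' @return object of class `sim_cohort`: list with `counts`, `fpkm_true`,
#'   `sample_map`, `maf`, `seg` (internal coordinates), `centroids`,
#'   `status_truth` (samples x events), `ground_truth`, `lib_sizes`,
#'   `config`
#' @export
simulate_cohort <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  models <- annotation$models
  host_map <- annotation$host_map
  genes <- models$gene_id
  n_genes <- length(genes)
  gi <- stats::setNames(seq_len(n_genes), genes)

  labels <- names(config$cancers)
  sample_map <- do.call(rbind, lapply(labels, function(l)
    data.frame(sample = sprintf("%s_S%03d", l, seq_len(config$cancers[[l]])),
               cancer = l, stringsAsFactors = FALSE)))
  samples <- sample_map$sample
  n_samp <- length(samples)
  cancer_of <- sample_map$cancer

  ## 1. mutation status + MAF records -----------------------------------
  ev_names <- names(config$events)
  status <- matrix(FALSE, n_samp, length(ev_names),
                   dimnames = list(samples, ev_names))
  maf <- NULL
  qual_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                    "Frame_Shift_Del", "Splice_Site")
  for (ev in ev_names) {
    for (l in labels) {
      idx <- which(cancer_of == l)
      n_mut <- round(config$events[[ev]] * length(idx))
      mut <- sort(sample(idx, n_mut))
      status[mut, ev] <- TRUE
      if (n_mut > 0) {
        cls <- sample(qual_classes, n_mut, replace = TRUE,
                      prob = c(0.6, 0.15, 0.15, 0.1))
        maf <- rbind(maf, data.frame(
          Tumor_Sample_Barcode = samples[mut], Hugo_Symbol = ev,
          Variant_Classification = cls,
          Variant_Type = ifelse(cls == "Frame_Shift_Del", "DEL", "SNP"),
          stringsAsFactors = FALSE))
      }
      wt <- setdiff(idx, mut)
      decoy <- wt[stats::runif(length(wt)) < config$silent_decoy_freq]
      if (length(decoy))
        maf <- rbind(maf, data.frame(
          Tumor_Sample_Barcode = samples[decoy], Hugo_Symbol = ev,
          Variant_Classification = "Silent", Variant_Type = "SNP",
          stringsAsFactors = FALSE))
    }
  }

  ## 2. copy number ------------------------------------------------------
  chroms <- unique(models$chrom)
  chrom_len <- vapply(chroms, function(ch)
    max(models$end[models$chrom == ch]) + 50000L, numeric(1))
  amp_chrom <- matrix(stats::rnorm(length(chroms) * n_samp, 0, config$cn_sd),
                      length(chroms), n_samp,
                      dimnames = list(chroms, samples))
  seg <- vector("list", n_samp)
  for (j in seq_len(n_samp)) {
    rows <- data.frame(sample = samples[j], chrom = chroms, start = 0L,
                       end = as.integer(chrom_len),
                       amplitude = amp_chrom[, j], stringsAsFactors = FALSE)
    add <- stats::runif(length(chroms)) < config$decoy_segment_rate
    if (any(add)) {
      pos <- floor(stats::runif(sum(add)) * (chrom_len[add] - 5000))
      rows <- rbind(rows, data.frame(
        sample = samples[j], chrom = chroms[add], start = as.integer(pos),
        end = as.integer(pos + 5000L),
        amplitude = stats::rnorm(sum(add), 0, 1), stringsAsFactors = FALSE))
    }
    seg[[j]] <- rows
  }
  seg <- do.call(rbind, seg)
  amp_truth <- amp_chrom[models$chrom, , drop = FALSE]
  rownames(amp_truth) <- genes

  ## 3. expression -------------------------------------------------------
  mu <- stats::rnorm(n_genes, config$baseline_mean, config$baseline_sd)
  names(mu) <- genes
  delta <- matrix(stats::rnorm(n_genes * length(labels), 0,
                               config$cancer_profile_sd),
                  n_genes, length(labels), dimnames = list(genes, labels))
  noise <- matrix(stats::rnorm(n_genes * n_samp, 0, config$sigma),
                  n_genes, n_samp, dimnames = list(genes, samples))
  L <- mu + delta[, cancer_of] + config$dosage_slope * amp_truth + noise
  dimnames(L) <- list(genes, samples)

  planted <- config$planted
  if (!is.null(planted) && nrow(planted)) {
    for (t in seq_len(nrow(planted))) {
      f <- planted$feature[t]
      ev <- planted$event[t]
      affected <- strsplit(planted$cancers[t], ",", fixed = TRUE)[[1]]
      on <- status[, ev] & cancer_of %in% affected
      if (planted$mediation[t] == "direct") {
        L[gi[f], on] <- L[gi[f], on] + planted$effect_log2[t]
      } else {
        host <- host_map[[f]]
        if (is.na(host)) .stopf("via_host target %s has no host", f)
        L[gi[host], on] <- L[gi[host], on] + planted$effect_log2[t]
        rho <- config$host_coexpr_r
        host_dev <- L[gi[host], ] - mu[host] - delta[host, cancer_of]
        L[gi[f], ] <- mu[f] + delta[f, cancer_of] + rho * host_dev +
          sqrt(1 - rho^2) * noise[gi[f], ]
      }
    }
  }

  fpkm <- 2^L
  pi_g <- ifelse(mu < config$dropout_below, config$zero_inflation, 0)
  drop <- matrix(stats::runif(n_genes * n_samp), n_genes, n_samp) <
    pi_g
  fpkm[drop] <- 0

  ## 4. counts via the FPKM formula with randomized library sizes --------
  cv <- config$lib_size_cv
  lib <- config$lib_size_mean *
    exp(stats::rnorm(n_samp, -cv^2 / 2, cv))
  names(lib) <- samples
  counts <- round(sweep(fpkm * models$mature_length, 2, lib / 1e9, "*"))
  storage.mode(counts) <- "integer"

  ## 5. centroids (per-cancer mean profiles over a coding panel) ---------
  panel <- .coding_ids(seq_len(min(50, config$n_coding)))
  centroids <- derive_centroids(fpkm[panel, , drop = FALSE], cancer_of)

  truth <- list(planted = planted, status = status,
                dosage_slope = config$dosage_slope,
                amp_truth = amp_truth, host_map = host_map,
                baseline = mu)
  structure(list(counts = counts, fpkm_true = fpkm,
                 sample_map = sample_map, maf = maf, seg = seg,
                 centroids = centroids, status_truth = status,
                 ground_truth = truth, lib_sizes = lib, config = config),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the formats the pipeline reads: counts TSV, sample-map
#' TSV, MAF-like TSV, SEG TSV (1-based inclusive on disk), centroid TSV
#' and a ground-truth TSV of the planted targets.
#'
#' @param cohort a `sim_cohort`
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(counts = file.path(dir, "counts.tsv"),
         sample_map = file.path(dir, "sample_map.tsv"),
         maf = file.path(dir, "mutations.maf.tsv"),
         seg = file.path(dir, "copy_number.seg.tsv"),
         centroids = file.path(dir, "centroids.tsv"),
         ground_truth = file.path(dir, "ground_truth.tsv"))
  .write_matrix_tsv(cohort$counts, p[["counts"]])
  write_tsv(cohort$sample_map, p[["sample_map"]])
  write_tsv(cohort$maf, p[["maf"]])
  seg_disk <- data.frame(Sample = cohort$seg$sample,
                         Chromosome = cohort$seg$chrom,
                         Start = cohort$seg$start + 1L,
                         End = cohort$seg$end,
                         Segment_Mean = cohort$seg$amplitude)
  write_tsv(seg_disk, p[["seg"]])
  .write_matrix_tsv(cohort$centroids, p[["centroids"]], id_col = "gene_id")
  gt <- cohort$ground_truth$planted
  if (is.null(gt))
    gt <- data.frame(feature = character(0), event = character(0),
                     effect_log2 = numeric(0), cancers = character(0),
                     mediation = character(0))
  write_tsv(gt, p[["ground_truth"]])
  invisible(p)
}

#' Hand-traceable worked-example cohort
#'
#' A fixed 2-cancer (A, B) x 20-sample cohort with 10 features and one
#' driver event, built from explicit deterministic values (no RNG):
#' feature F01 is induced eight-fold in the six mutated samples of each
#' cancer, features F02-F09 follow the shared null pattern
#' `b_i + 0.01 j`, and F10 is zero in every mutated sample (so it fails
#' the detectability filter despite perfect separation). Sample A_S18
#' carries only a silent record of the driver gene and must stay wild
#' type. The screen on this cohort yields exactly one consistent
#' association (F01, up, both cancers); the rank-level arithmetic is
#' documented in `inst/extdata/worked_example/derivation.md`.
#'
#' @return list: `counts`, `fpkm` (authored values), `gene_lengths`,
#'   `sample_map`, `maf`, `event` (a [driver_event()]), `mutated`
#'   (character vector of truly mutated samples)
#' @export
worked_example <- function() {
  features <- sprintf("F%02d", 1:10)
  samples <- c(sprintf("A_S%02d", 1:20), sprintf("B_S%02d", 1:20))
  sample_map <- data.frame(sample = samples,
                           cancer = rep(c("A", "B"), each = 20),
                           stringsAsFactors = FALSE)
  mut_a <- sprintf("A_S%02d", c(1, 4, 7, 10, 13, 16))
  mut_b <- sprintf("B_S%02d", c(2, 5, 8, 11, 14, 17))
  mutated <- c(mut_a, mut_b)

  j <- rep(1:20, 2)                      # within-cancer sample index
  fpkm <- matrix(0, 10, 40, dimnames = list(features, samples))
  for (i in 1:9) fpkm[i, ] <- i + 0.01 * j
  is_mut <- samples %in% mutated
  fpkm["F01", is_mut] <- 8 * fpkm["F01", is_mut]
  fpkm["F10", ] <- ifelse(is_mut, 0, 0.5 + 0.01 * j)

  # counts invert the FPKM formula at equal library sizes (1e8), so the
  # quantification path is exercised on re-screening
  gene_lengths <- stats::setNames(rep(1000, 10), features)
  counts <- round(fpkm * 100)
  storage.mode(counts) <- "integer"

  maf <- data.frame(
    Tumor_Sample_Barcode = c(mutated, "A_S18"),
    Hugo_Symbol = "DRIVER1",
    Variant_Classification = c(rep("Missense_Mutation", length(mutated)),
                               "Silent"),
    Variant_Type = "SNP", stringsAsFactors = FALSE)

  list(counts = counts, fpkm = fpkm, gene_lengths = gene_lengths,
       sample_map = sample_map, maf = maf, event = driver_event("DRIVER1"),
       mutated = mutated)
}
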