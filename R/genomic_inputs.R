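# Mapping from common MAF Variant_Classification strings to the internal
# closed vocabulary. Unknown input classes map to "other" and are excluded
# by the default driver-event filter.
.maf_class_table <- c(
  "Missense_Mutation"   = "missense",
  "Nonsense_Mutation"   = "nonsense",
  "Frame_Shift_Del"     = "frameshift_indel",
  "Frame_Shift_Ins"     = "frameshift_indel",
  "In_Frame_Del"        = "inframe_indel",
  "In_Frame_Ins"        = "inframe_indel",
  "Splice_Site"         = "splice_site",
  "Silent"              = "silent"
)

#' Variant-classification vocabulary mapping
#'
#' @return named character vector mapping MAF `Variant_Classification`
#'   strings to the internal classes (`missense`, `nonsense`,
#'   `frameshift_indel`, `inframe_indel`, `splice_site`, `silent`);
#'   anything absent from the table becomes `other`
#' @export
maf_class_table <- function() .maf_class_table

#' @keywords internal
.normalize_variant_class <- function(classification) {
  out <- unname(.maf_class_table[classification])
  out[is.na(out)] <- "other"
  out
}

#' Read somatic mutations from a MAF-like TSV
#'
#' Expects columns `Tumor_Sample_Barcode`, `Hugo_Symbol` and
#' `Variant_Classification`; `Variant_Type` (SNP/DEL/INS) is used to flag
#' indels when present, otherwise indel status is inferred from the
#' classification.
#'
#' @param path file path
#' @return data frame with columns `sample`, `gene`, `variant_class`
#'   (closed vocabulary) and `is_indel`
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_mutation_records(df)
}

#' Normalize an in-memory MAF-like table to mutation records
#'
#' @param df data frame with MAF columns (see [read_maf()])
#' @return data frame with columns `sample`, `gene`, `variant_class`,
#'   `is_indel`
#' @export
as_mutation_records <- function(df) {
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  if (!all(need %in% colnames(df)))
    .stopf("MAF lacks required columns: %s",
           paste(setdiff(need, colnames(df)), collapse = ", "))
  vc <- .normalize_variant_class(df$Variant_Classification)
  is_indel <- if ("Variant_Type" %in% colnames(df))
    df$Variant_Type %in% c("DEL", "INS")
  else vc %in% c("frameshift_indel", "inframe_indel")
  data.frame(sample = df$Tumor_Sample_Barcode, gene = df$Hugo_Symbol,
             variant_class = vc,
             is_indel = is_indel | vc %in% c("frameshift_indel",
                                             "inframe_indel"),
             stringsAsFactors = FALSE)
}

#' Define a driver mutational event
#'
#' The default class filter implements the screen's mutation rule: a
#' record counts when it is a missense or nonsense mutation, any indel, or
#' a splice-site mutation; silent and unrecognized classes do not.
#' Gain-of-function style subsets are expressed by supplying a custom
#' `class_filter` predicate.
#'
#' @param gene gene symbol the event is defined on
#' @param name event name (defaults to the gene symbol)
#' @param class_filter predicate `function(records) -> logical` over rows
#'   of a mutation-record data frame; `NULL` for the default rule
#' @param subset_label optional label (e.g. `"GOF"`) for restricted subsets
#' @return object of class `driver_event`
#' @export
driver_event <- function(gene, name = gene, class_filter = NULL,
                         subset_label = NULL) {
  if (is.null(class_filter)) class_filter <- default_class_filter
  structure(list(name = name, gene = gene, class_filter = class_filter,
                 subset_label = subset_label),
            class = "driver_event")
}

#' Default mutation-class rule
#'
#' @param records mutation-record data frame (`variant_class`, `is_indel`)
#' @return logical vector, TRUE for records that count as mutated
#' @export
default_class_filter <- function(records) {
  records$variant_class %in% c("missense", "nonsense", "frameshift_indel",
                               "inframe_indel", "splice_site") |
    records$is_indel
}

#' Per-sample mutation status for one event
#'
#' A sample is mutated iff at least one of its records for the event's
#' gene passes the event's class filter; samples absent from the records
#' are wild type. The `samples` vector defines the universe (typically the
#' samples with exome data).
#'
#' @param records mutation-record data frame from [read_maf()]
#' @param event a [driver_event()]
#' @param samples character vector of sample ids
#' @return named logical vector over `samples`
#' @export
mutation_status <- function(records, event, samples) {
  status <- stats::setNames(rep(FALSE, length(samples)), samples)
  rec <- records[records$gene == event$gene, , drop = FALSE]
  if (nrow(rec)) {
    hit <- rec$sample[event$class_filter(rec)]
    status[names(status) %in% hit] <- TRUE
  }
  status
}

#' @keywords internal
.status_matrix <- function(records, events, samples) {
  m <- vapply(events, function(e) mutation_status(records, e, samples),
              logical(length(samples)))
  dim(m) <- c(length(samples), length(events))
  dimnames(m) <- list(samples, vapply(events, `[[`, character(1), "name"))
  m
}

#' Select eligible driver events
#'
#' An event is eligible when its gene was called significantly mutated
#' (q < 0.05) in at least one cancer type, is mutated at a frequency
#' strictly above `freq_threshold` in at least one cancer type, and is a
#' census-listed cancer gene. The q-values come from external recurrence
#' callers and enter as a precomputed flag.
#'
#' @param eligibility data frame with columns `gene`,
#'   `q_significant_any_cancer` (logical), `max_frequency`, `in_census`
#'   (logical)
#' @param freq_threshold frequency cut-off (default 0.05, strict)
#' @return list of [driver_event()] objects for the eligible genes
#' @export
select_events <- function(eligibility, freq_threshold = 0.05) {
  keep <- eligibility$q_significant_any_cancer &
    eligibility$max_frequency > freq_threshold &
    eligibility$in_census
  lapply(eligibility$gene[keep], driver_event)
}

#' Read segmented copy number from a SEG-like TSV
#'
#' On-disk coordinates are 1-based inclusive and are converted to the
#' internal 0-based half-open convention.
#'
#' @param path file path with columns `Sample`, `Chromosome`, `Start`,
#'   `End`, `Segment_Mean`
#' @return data frame `sample`, `chrom`, `start`, `end`, `amplitude`
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
  if (!all(need %in% colnames(df)))
    .stopf("SEG lacks required columns: %s",
           paste(setdiff(need, colnames(df)), collapse = ", "))
  out <- data.frame(sample = df$Sample, chrom = as.character(df$Chromosome),
                    start = df$Start - 1L, end = df$End,
                    amplitude = df$Segment_Mean, stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) .stopf("SEG segment with end <= start")
  out
}

#' Gene-level copy-number amplitudes from segments
#'
#' Segments shorter than `min_segment` bp are excluded; each gene then
#' takes the minimum amplitude over all remaining segments overlapping its
#' span, per sample. Genes with no overlapping segment are NA. Overlapping
#' segments within one sample trigger a validation warning but are still
#' processed.
#'
#' @param segments data frame from [read_seg()] (internal coordinates)
#' @param models `gene_models` for the genes of interest
#' @param min_segment minimum segment length in bp (default 10000,
#'   inclusive: a segment of exactly 10 kb is kept)
#' @return numeric matrix, genes x samples, NA where no segment overlaps
#' @export
map_copy_number <- function(segments, models, min_segment = 1e4) {
  keep <- (segments$end - segments$start) >= min_segment
  seg <- segments[keep, , drop = FALSE]
  samples <- sort(unique(segments$sample))
  amp <- matrix(NA_real_, nrow(models), length(samples),
                dimnames = list(models$gene_id, samples))
  if (!nrow(seg)) return(amp)

  seg_gr <- GenomicRanges::GRanges(seg$chrom,
                                   IRanges::IRanges(seg$start + 1L, seg$end))
  gene_gr <- .models_granges(models)
  ov <- GenomicRanges::findOverlaps(gene_gr, seg_gr, ignore.strand = TRUE)
  if (length(ov)) {
    gi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    key <- paste(models$gene_id[gi], seg$sample[si], sep = "\r")
    mins <- tapply(seg$amplitude[si], key, min)
    parts <- strsplit(names(mins), "\r", fixed = TRUE)
    g <- vapply(parts, `[`, character(1), 1L)
    s <- vapply(parts, `[`, character(1), 2L)
    amp[cbind(g, s)] <- as.numeric(mins)
  }

  self <- GenomicRanges::findOverlaps(seg_gr, seg_gr, ignore.strand = TRUE)
  self <- self[S4Vectors::queryHits(self) < S4Vectors::subjectHits(self)]
  if (length(self) &&
      any(seg$sample[S4Vectors::queryHits(self)] ==
            seg$sample[S4Vectors::subjectHits(self)]))
    .warnf("overlapping copy-number segments within a sample; processed anyway")
  amp
}

#' Centroid-correlation subtype assignment
#'
#' Assigns each sample to the subtype whose centroid profile it correlates
#' with best (Pearson r), the PAM50-style rule. Ties are broken by centroid
#' column order with a warning; samples with zero variance over the
#' centroid genes are unassigned (NA).
#'
#' @param expr numeric vector (one sample, named by gene) or genes x
#'   samples matrix
#' @param centroids genes x subtypes matrix of centroid profiles
#' @return character vector of subtype labels (NA = unassigned)
#' @export
pam50_assign <- function(expr, centroids) {
  if (is.null(dim(expr))) expr <- cbind(sample = expr)
  genes <- intersect(rownames(centroids), rownames(expr))
  if (length(genes) < 2) .stopf("fewer than 2 centroid genes in expression")
  if (length(genes) < 0.8 * nrow(centroids))
    .warnf("only %d/%d centroid genes present in expression data",
           length(genes), nrow(centroids))
  e <- expr[genes, , drop = FALSE]
  ctr <- centroids[genes, , drop = FALSE]
  labels <- rep(NA_character_, ncol(e))
  names(labels) <- colnames(e)
  for (j in seq_len(ncol(e))) {
    v <- e[, j]
    if (stats::sd(v) == 0) next
    r <- apply(ctr, 2, function(cv)
      if (stats::sd(cv) == 0) -Inf else stats::cor(v, cv))
    best <- which(r == max(r))
    if (length(best) > 1)
      .warnf("subtype tie for sample %s; first of %s kept",
             colnames(e)[j], paste(colnames(ctr)[best], collapse = "/"))
    labels[j] <- colnames(ctr)[best[1]]
  }
  labels
}

#' Derive centroid profiles from labelled samples
#'
#' Mean `log2(FPKM + pseudo)` profile per label, the standard way of
#' turning a labelled training cohort into assignment centroids.
#'
#' @param fpkm genes x samples FPKM matrix
#' @param labels subtype label per sample (named or in column order)
#' @param pseudo pseudo-count (default 0.1)
#' @return genes x subtypes centroid matrix
#' @export
derive_centroids <- function(fpkm, labels, pseudo = 0.1) {
  if (!is.null(names(labels))) labels <- labels[colnames(fpkm)]
  x <- log2(fpkm + pseudo)
  out <- vapply(sort(unique(labels)), function(l)
    rowMeans(x[, labels == l, drop = FALSE]), numeric(nrow(fpkm)))
  rownames(out) <- rownames(fpkm)
  out
}
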