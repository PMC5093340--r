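#' Load gene models from a GENCODE-style GTF file
#'
#' Parses gene, transcript and exon records and collapses them to one model
#' per `gene_id`. The mature length of a gene is the maximum over its
#' isoforms of the summed exon lengths. GTF coordinates (1-based inclusive)
#' are converted to the package-internal 0-based half-open convention.
#'
#' @param gtf_path path to a GTF file carrying `gene_id`, `gene_name` and
#'   `transcript_type` attributes (GENCODE dialect, `key "value"` pairs)
#' @return a `gene_models` data frame with one row per gene: `gene_id`,
#'   `gene_name`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `biotypes` (comma-joined set of transcript biotypes), `mature_length`
#'   (bp) and `is_coding` (TRUE iff any transcript biotype is
#'   `protein_coding`)
#' @export
load_gene_models <- function(gtf_path) {
  if (!file.exists(gtf_path)) .stopf("GTF file not found: %s", gtf_path)
  .validate_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!all(c("type", "gene_id") %in% colnames(meta)))
    .stopf("GTF lacks required attributes (gene_id): %s", gtf_path)
  type <- as.character(meta$type)
  gene_id <- as.character(meta$gene_id)
  gene_name <- if ("gene_name" %in% colnames(meta))
    as.character(meta$gene_name) else gene_id
  tx_type <- if ("transcript_type" %in% colnames(meta))
    as.character(meta$transcript_type) else rep(NA_character_, length(gr))

  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))

  is_exon <- type == "exon"
  if (!any(is_exon)) .stopf("GTF has no exon records: %s", gtf_path)
  tx_id <- if ("transcript_id" %in% colnames(meta))
    as.character(meta$transcript_id) else gene_id

  # per-isoform mature length, then max per gene
  exon_len <- end0[is_exon] - start0[is_exon]
  iso_len <- tapply(exon_len, tx_id[is_exon], sum)
  iso_gene <- tapply(gene_id[is_exon], tx_id[is_exon], `[`, 1L)
  mature <- tapply(as.numeric(iso_len), iso_gene, max)

  # gene span: explicit gene rows when present, else the exon envelope
  span_of <- function(sel) {
    data.frame(
      gene_id = gene_id[sel], chrom = chrom[sel], start = start0[sel],
      end = end0[sel], strand = strand[sel], stringsAsFactors = FALSE
    )
  }
  if (any(type == "gene")) {
    genes <- span_of(type == "gene")
    genes <- genes[!duplicated(genes$gene_id), ]
  } else {
    ex <- span_of(is_exon)
    genes <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d) {
      data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                 start = min(d$start), end = max(d$end),
                 strand = d$strand[1], stringsAsFactors = FALSE)
    }))
  }
  rownames(genes) <- genes$gene_id

  # exons must sit inside their gene's span
  ex_gid <- gene_id[is_exon]
  known <- ex_gid %in% genes$gene_id
  if (any(known)) {
    g <- genes[ex_gid[known], ]
    bad <- start0[is_exon][known] < g$start | end0[is_exon][known] > g$end |
      chrom[is_exon][known] != g$chrom
    if (any(bad))
      .stopf("exon outside gene span for gene(s): %s",
             paste(unique(ex_gid[known][bad]), collapse = ", "))
  }

  has_tx <- !is.na(tx_type)
  biotypes <- vapply(
    split(tx_type[has_tx], gene_id[has_tx])[genes$gene_id],
    function(b) paste(sort(unique(b)), collapse = ","), character(1)
  )
  biotypes[is.na(biotypes)] <- ""
  names_map <- tapply(gene_name, gene_id, `[`, 1L)

  out <- data.frame(
    gene_id = genes$gene_id,
    gene_name = as.character(names_map[genes$gene_id]),
    chrom = genes$chrom,
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = genes$strand,
    biotypes = as.character(biotypes),
    mature_length = as.numeric(mature[genes$gene_id]),
    is_coding = grepl("(^|,)protein_coding(,|$)", biotypes),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  stopifnot(all(out$start < out$end), all(out$mature_length >= 1))
  class(out) <- c("gene_models", "data.frame")
  out
}

# Cheap structural pre-check so malformed records fail with a line number
#' @keywords internal
.validate_gtf_lines <- function(gtf_path) {
  lines <- readLines(gtf_path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(body)
  if (!length(idx)) .stopf("GTF file is empty: %s", gtf_path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    .stopf("malformed GTF record (expected 9 tab-separated fields) at line %d",
           idx[which(nf != 9L)[1]])
  attrs <- vapply(fields, `[`, character(1), 9L)
  bad <- !grepl('gene_id "[^"]+"', attrs)
  if (any(bad))
    .stopf("malformed attribute block (missing gene_id) at line %d",
           idx[which(bad)[1]])
  invisible(TRUE)
}

#' Build the filtered lncRNA catalogue
#'
#' A gene enters the catalogue iff all of its transcript biotypes belong to
#' the allowed set and its mature length reaches `min_length`. The default
#' biotype whitelist is antisense, lincRNA, processed_transcript,
#' sense_intronic, sense_overlapping and miRNA; since `protein_coding` is
#' never in the allowed set, coding genes are excluded by construction.
#'
#' @param models a `gene_models` data frame from [load_gene_models()]
#' @param allowed_biotypes character vector of admissible transcript biotypes
#' @param min_length minimum mature length in bp for the longest isoform
#' @return an (unclassified) `lnc_catalogue` data frame: `gene_id`, `class`,
#'   `nearest_coding_id`, `distance_bp` (the latter three `NA` until
#'   [classify_genic_intergenic()] is applied)
#' @seealso [classify_genic_intergenic()]
#' @export
build_lnc_catalogue <- function(models,
                                allowed_biotypes = c(
                                  "antisense", "lincRNA",
                                  "processed_transcript", "sense_intronic",
                                  "sense_overlapping", "miRNA"),
                                min_length = 200) {
  bt <- .split_biotypes(models$biotypes)
  ok_bt <- vapply(bt, function(b) length(b) > 0 && all(b %in% allowed_biotypes),
                  logical(1))
  keep <- ok_bt & models$mature_length >= min_length
  ids <- models$gene_id[keep]
  out <- data.frame(
    gene_id = ids,
    class = rep(NA_character_, length(ids)),
    nearest_coding_id = rep(NA_character_, length(ids)),
    distance_bp = rep(NA_real_, length(ids)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("lnc_catalogue", "data.frame")
  out
}

#' Classify catalogue lncRNAs as genic or intergenic
#'
#' Distance to the nearest coding gene is the strand-agnostic gap in bp
#' between gene spans (0 on any overlap). An lncRNA is genic when that
#' distance is strictly below `threshold`; a distance of exactly the
#' threshold, or an lncRNA on a chromosome without coding genes (infinite
#' distance), is intergenic. Ties between equidistant coding genes are
#' broken by smaller start coordinate, then lexicographic gene id.
#'
#' @param catalogue an `lnc_catalogue` from [build_lnc_catalogue()]
#' @param models the full `gene_models` set (the coding genes are taken from
#'   it; callers merging several coding annotations do so upstream)
#' @param threshold genic distance cut-off in bp (default 5000)
#' @return the catalogue with `class`, `nearest_coding_id` and `distance_bp`
#'   filled in
#' @export
classify_genic_intergenic <- function(catalogue, models, threshold = 5000) {
  coding <- models[models$is_coding, , drop = FALSE]
  lnc <- models[match(catalogue$gene_id, models$gene_id), , drop = FALSE]
  if (anyNA(lnc$gene_id))
    .stopf("catalogue gene(s) missing from models: %s",
           paste(catalogue$gene_id[is.na(lnc$gene_id)], collapse = ", "))

  catalogue$distance_bp <- Inf
  catalogue$nearest_coding_id <- NA_character_
  if (nrow(coding) > 0 && nrow(lnc) > 0) {
    q <- .models_granges(lnc)
    s <- .models_granges(coding)
    hits <- GenomicRanges::distanceToNearest(q, s, select = "all",
                                             ignore.strand = TRUE)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      d <- S4Vectors::mcols(hits)$distance
      # deterministic tie-break among equidistant nearest coding genes
      ord <- order(qh, d, coding$start[sh], coding$gene_id[sh])
      first <- !duplicated(qh[ord])
      qi <- qh[ord][first]
      catalogue$distance_bp[qi] <- as.numeric(d[ord][first])
      catalogue$nearest_coding_id[qi] <- coding$gene_id[sh[ord][first]]
    }
  }
  catalogue$class <- ifelse(catalogue$distance_bp < threshold,
                            "genic", "intergenic")
  catalogue
}

#' Coding-gene neighbourhood of a gene
#'
#' Reports the nearest coding gene with a span entirely to the left
#' (upstream in chromosome orientation, strand-agnostic) and entirely to the
#' right of the query span, plus every coding gene whose span gap to the
#' query is at most `window` bp (overlap counts as distance 0). Ties are
#' broken by smaller start coordinate, then lexicographic gene id.
#'
#' @param query_id gene id present in `models`
#' @param models a `gene_models` data frame
#' @param window neighbourhood size in bp (default 100000)
#' @return list with `query_id`, `upstream_coding`, `downstream_coding`
#'   (gene ids or `NA`) and `within_window` (character vector of coding gene
#'   ids, sorted by distance then tie-break order)
#' @export
neighbours <- function(query_id, models, window = 1e5) {
  i <- match(query_id, models$gene_id)
  if (is.na(i)) .stopf("unknown gene_id: %s", query_id)
  q <- models[i, ]
  cand <- models[models$is_coding & models$chrom == q$chrom &
                   models$gene_id != query_id, , drop = FALSE]
  if (nrow(cand) == 0)
    return(list(query_id = query_id, upstream_coding = NA_character_,
                downstream_coding = NA_character_,
                within_window = character(0)))
  gap <- .gap_bp(q$start, q$end, cand$start, cand$end)
  ord <- order(gap, cand$start, cand$gene_id)

  pick <- function(sel) {
    if (!any(sel)) return(NA_character_)
    o <- ord[sel[ord]]
    cand$gene_id[o[1]]
  }
  up <- pick(cand$end <= q$start)
  dn <- pick(cand$start >= q$end)
  ww <- cand$gene_id[ord][gap[ord] <= window]
  list(query_id = query_id, upstream_coding = up, downstream_coding = dn,
       within_window = ww)
}

#' Write a classified catalogue to TSV
#'
#' @param catalogue classified `lnc_catalogue`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_catalogue <- function(catalogue, path) {
  out <- as.data.frame(catalogue)
  out$distance_bp <- ifelse(is.infinite(out$distance_bp), "Inf",
                            format(out$distance_bp, trim = TRUE,
                                   scientific = FALSE))
  write_tsv(out, path)
}

#' Export catalogue loci as BED6
#'
#' BED is 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged.
#'
#' @param catalogue classified `lnc_catalogue`
#' @param models `gene_models` providing the coordinates
#' @param path output path
#' @return `path`, invisibly
#' @export
catalogue_to_bed <- function(catalogue, models, path) {
  m <- models[match(catalogue$gene_id, models$gene_id), ]
  bed <- data.frame(m$chrom, m$start, m$end, catalogue$gene_id, 0L, m$strand)
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
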