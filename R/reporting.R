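#' Assemble a run configuration
#'
#' Collects input paths, thresholds, mode flags and the seed for an
#' end-to-end run. The configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]) and its hash (computed
#' over everything except output location) is embedded in the header of
#' every output file.
#'
#' @param gtf,counts,sample_map,maf input file paths
#' @param seg optional SEG file path (copy-number outputs are marked
#'   absent without it)
#' @param events character vector of driver gene symbols to screen
#' @param out_dir output directory
#' @param seed integer seed for the permutation stages
#' @param p,lfc,detect_frac,pseudo,min_group,min_replication,same_direction
#'   screen thresholds, see [screen_thresholds()]
#' @param genic_threshold genic/intergenic distance cut-off in bp
#' @param neighbour_window proximal coding-gene window in bp
#' @param indep_p independence p-value line for the neighbour analysis
#' @param permutation_mode `"independent"` or `"joint"`, see
#'   [permute_within_cancer()]
#' @param replicates permutation replicates for [run_permutation()]
#' @return object of class `run_config`
#' @export
run_config <- function(gtf, counts, sample_map, maf, seg = NULL,
                       events, out_dir = ".", seed = 1,
                       p = 0.001, lfc = 1, detect_frac = 0.10,
                       pseudo = 0.1, min_group = 3, min_replication = 2,
                       same_direction = TRUE, genic_threshold = 5000,
                       neighbour_window = 1e5, indep_p = 0.01,
                       permutation_mode = "independent", replicates = 1) {
  cfg <- list(gtf = gtf, counts = counts, sample_map = sample_map,
              maf = maf, seg = seg, events = as.character(events),
              out_dir = out_dir, seed = as.integer(seed),
              p = p, lfc = lfc, detect_frac = detect_frac, pseudo = pseudo,
              min_group = min_group, min_replication = min_replication,
              same_direction = same_direction,
              genic_threshold = genic_threshold,
              neighbour_window = neighbour_window, indep_p = indep_p,
              permutation_mode = permutation_mode,
              replicates = as.integer(replicates))
  stopifnot(cfg$p > 0, cfg$lfc >= 0, cfg$genic_threshold > 0,
            cfg$neighbour_window > 0, cfg$indep_p > 0,
            cfg$min_group >= 1, cfg$min_replication >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a `run_config`
#' @param path YAML path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$events <- as.character(raw$events)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Hash of a run configuration
#'
#' MD5 over the canonical YAML serialization of everything except the
#' output directory, so reruns against the same inputs and thresholds
#' carry the same hash in their output headers.
#'
#' @param config a `run_config`
#' @return 32-character hash string
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' @keywords internal
.thresholds_of <- function(config) {
  screen_thresholds(p = config$p, lfc = config$lfc,
                    detect_frac = config$detect_frac,
                    pseudo = config$pseudo, min_group = config$min_group,
                    min_replication = config$min_replication,
                    same_direction = config$same_direction)
}

# Load and cross-validate every input of a run.
#' @keywords internal
.load_inputs <- function(config) {
  for (f in c("gtf", "counts", "sample_map", "maf", "seg")) {
    path <- config[[f]]
    if (!is.null(path) && !file.exists(path))
      .stopf("%s input not found: %s", f, path)
  }
  models <- load_gene_models(config$gtf)
  catalogue <- classify_genic_intergenic(
    build_lnc_catalogue(models), models, threshold = config$genic_threshold)
  counts <- read_matrix_tsv(config$counts)
  sample_map <- read_tsv(config$sample_map)
  if (!all(c("sample", "cancer") %in% colnames(sample_map)))
    .stopf("sample map needs columns sample, cancer")
  missing <- setdiff(colnames(counts), sample_map$sample)
  if (length(missing))
    .stopf("samples in counts but not in sample map: %s",
           paste(missing, collapse = ", "))
  maf <- read_maf(config$maf)
  stray <- setdiff(unique(maf$sample), sample_map$sample)
  if (length(stray))
    .stopf("samples in MAF but not in sample map: %s",
           paste(stray, collapse = ", "))
  seg <- if (!is.null(config$seg)) read_seg(config$seg) else NULL

  sf <- size_factors(counts)
  fpkm <- fpkm_matrix(counts, stats::setNames(models$mature_length,
                                              models$gene_id)[rownames(counts)],
                      sf)
  events <- lapply(config$events, driver_event)
  status <- .status_matrix(maf, events, colnames(counts))
  list(models = models, catalogue = catalogue, counts = counts,
       sample_map = sample_map, maf = maf, seg = seg, fpkm = fpkm,
       size_factors = sf, status = status)
}

#' Run the full association screen from a configuration
#'
#' Loads and validates all inputs, quantifies FPKM, screens catalogue
#' lncRNAs together with the coding genes across cancers and events,
#' derives consistent associations and the proximal coding-gene
#' dependency of the lncRNA hits, and writes the result tables
#' (`screen.tsv`, `consistent.tsv`, `neighbours.tsv`, `overview.tsv`)
#' into the configured output directory, each headed by the config hash.
#'
#' @param config a [run_config()]
#' @return list (invisible): `screen` (full `driver_screen`),
#'   `consistent_lnc`, `neighbours`, `catalogue`, `overview`, `hash`,
#'   `paths`
#' @export
run_screen <- function(config) {
  inp <- .load_inputs(config)
  hash <- config_hash(config)
  th <- .thresholds_of(config)

  tab <- table(inp$sample_map$cancer)
  message("samples per cancer type: ",
          paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))

  lnc_ids <- intersect(inp$catalogue$gene_id, rownames(inp$fpkm))
  coding_ids <- intersect(inp$models$gene_id[inp$models$is_coding],
                          rownames(inp$fpkm))
  feats <- c(lnc_ids, coding_ids)
  scr <- driver_screen(inp$fpkm[feats, , drop = FALSE], inp$sample_map,
                       inp$status, th)

  cons_lnc <- scr$consistent[scr$consistent$feature_id %in% lnc_ids, ,
                             drop = FALSE]
  nbr <- neighbour_dependency(cons_lnc, scr$records, inp$models, inp$fpkm,
                              inp$sample_map,
                              window = config$neighbour_window,
                              indep_p = config$indep_p,
                              pseudo = config$pseudo)
  cls <- genic_fraction(cons_lnc, inp$catalogue)
  message(sprintf(
    "attrition: %d tested, %d passing, %d consistent (lncRNA: %d; genic %d / intergenic %d)",
    nrow(scr$records), sum(scr$records$passes), nrow(scr$consistent),
    nrow(cons_lnc), cls[["genic"]], cls[["intergenic"]]))

  ov <- intergenic_read_fraction(inp$counts, inp$catalogue, inp$sample_map)
  overview <- data.frame(sample = names(ov$fraction),
                         intergenic_read_fraction = ov$fraction,
                         row.names = NULL)
  if (is.null(inp$seg))
    message("no SEG input: copy-number outputs absent")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(screen = file.path(config$out_dir, "screen.tsv"),
             consistent = file.path(config$out_dir, "consistent.tsv"),
             neighbours = file.path(config$out_dir, "neighbours.tsv"),
             overview = file.path(config$out_dir, "overview.tsv"))
  hdr <- paste0("config_hash: ", hash)
  write_tsv(scr$records, paths[["screen"]], header_lines = hdr)
  write_tsv(scr$consistent, paths[["consistent"]], header_lines = hdr)
  write_tsv(nbr, paths[["neighbours"]], header_lines = hdr)
  write_tsv(overview, paths[["overview"]], header_lines = hdr)

  invisible(list(screen = scr, consistent_lnc = cons_lnc, neighbours = nbr,
                 catalogue = inp$catalogue, overview = ov, hash = hash,
                 paths = paths))
}

#' Run the permutation null from a configuration
#'
#' Reruns the full screen on mutation labels permuted within each cancer
#' and writes `null.tsv` (one row per replicate) with the FDR estimate.
#' Per-cancer mutation counts before and after permutation are logged.
#'
#' @param config a [run_config()]
#' @return the [permutation_fdr()] result, invisibly
#' @export
run_permutation <- function(config) {
  inp <- .load_inputs(config)
  th <- .thresholds_of(config)
  lnc_ids <- intersect(inp$catalogue$gene_id, rownames(inp$fpkm))

  cancer_of <- inp$sample_map$cancer[match(rownames(inp$status),
                                           inp$sample_map$sample)]
  before <- stats::aggregate(inp$status, by = list(cancer = cancer_of), sum)
  message("per-cancer mutation counts (observed):")
  for (i in seq_len(nrow(before)))
    message("  ", paste(before[i, ], collapse = " "))

  fdr <- permutation_fdr(inp$fpkm[lnc_ids, , drop = FALSE], inp$sample_map,
                         inp$status, th, seed = config$seed,
                         replicates = config$replicates,
                         mode = config$permutation_mode)
  perm1 <- permute_within_cancer(inp$status, inp$sample_map,
                                 seed = config$seed,
                                 mode = config$permutation_mode)
  after <- stats::aggregate(perm1, by = list(cancer = cancer_of), sum)
  message("per-cancer mutation counts (first permutation):")
  for (i in seq_len(nrow(after)))
    message("  ", paste(after[i, ], collapse = " "))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(fdr$replicates, file.path(config$out_dir, "null.tsv"),
            header_lines = paste0("config_hash: ", config_hash(config)))
  invisible(fdr)
}

#' Event-by-cancer hit-count summary
#'
#' Tabulates the per-cancer passing association counts for every event
#' and the per-event consistent (replicated) counts.
#'
#' @param screen a `driver_screen` object
#' @param out_dir optional directory; when given, `summary_matrix.tsv`
#'   and `summary_events.tsv` are written there
#' @return list: `matrix` (event x cancer passing counts),
#'   `per_event` (data frame event, n_passing, n_consistent)
#' @export
summarize_screen <- function(screen, out_dir = NULL) {
  r <- screen$records
  events <- screen$events
  cancers <- sort(screen$cancers)
  m <- matrix(0L, length(events), length(cancers),
              dimnames = list(events, cancers))
  if (!is.null(r) && nrow(r)) {
    tab <- table(r$event[r$passes], r$cancer[r$passes])
    m[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  cons <- screen$consistent
  per_event <- data.frame(
    event = events,
    n_passing = as.integer(rowSums(m)),
    n_consistent = vapply(events, function(e)
      sum(cons$event == e), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_matrix_tsv(m, file.path(out_dir, "summary_matrix.tsv"),
                      id_col = "event")
    write_tsv(per_event, file.path(out_dir, "summary_events.tsv"))
  }
  list(matrix = m, per_event = per_event)
}
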