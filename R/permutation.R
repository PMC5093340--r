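#' Permute mutation labels within each cancer type
#'
#' For each cancer independently, the mutation-status vector of each event
#' is shuffled across that cancer's samples, preserving per-cancer
#' mutation counts exactly. In `"independent"` mode (default) each event
#' column gets its own permutation; `"joint"` mode applies one permutation
#' of the sample order to all events of a cancer.
#'
#' @param status samples x events logical matrix
#' @param sample_map data frame with columns `sample`, `cancer`
#' @param seed integer seed; when non-NULL the RNG is seeded before
#'   permuting, so identical seeds give identical permutations
#' @param mode `"independent"` or `"joint"`
#' @return permuted status matrix of the same shape and dimnames
#' @export
permute_within_cancer <- function(status, sample_map, seed = NULL,
                                  mode = c("independent", "joint")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  cancer_of <- sample_map$cancer[match(rownames(status), sample_map$sample)]
  if (anyNA(cancer_of)) .stopf("status rows missing from sample_map")
  out <- status
  for (cc in unique(cancer_of)) {
    idx <- which(cancer_of == cc)
    if (length(idx) < 2) next
    if (mode == "joint") {
      out[idx, ] <- status[idx[sample.int(length(idx))], , drop = FALSE]
    } else {
      for (ev in seq_len(ncol(status)))
        out[idx, ev] <- status[idx[sample.int(length(idx))], ev]
    }
  }
  out
}

#' Permutation-based FDR estimate for the consistent-association screen
#'
#' Runs the screen on the observed labels, then reruns it on labels
#' permuted within each cancer, and reports
#' `fdr = null consistent count / max(observed consistent count, 1)`.
#' With several replicates the estimate uses the mean null count. A
#' degenerate observed count of 0 is flagged.
#'
#' @param fpkm features x samples FPKM matrix
#' @param sample_map data frame with columns `sample`, `cancer`
#' @param status samples x events logical matrix (observed labels)
#' @param thresholds a [screen_thresholds()] object
#' @param seed integer seed; replicate r uses `seed + r - 1`
#' @param replicates number of permutation replicates (default 1, as in a
#'   single-shuffle null)
#' @param mode permutation mode, see [permute_within_cancer()]
#' @param observed optionally a precomputed `driver_screen` for the
#'   observed labels, to avoid recomputing it
#' @return object of class `permutation_fdr`: list with `replicates`
#'   (data frame: permutation_id, seed, null_consistent_count,
#'   observed_consistent_count, fdr_estimate, degenerate),
#'   `fdr_estimate` (pooled), `observed` (the observed `driver_screen`)
#' @export
permutation_fdr <- function(fpkm, sample_map, status,
                            thresholds = screen_thresholds(),
                            seed = 1, replicates = 1,
                            mode = c("independent", "joint"),
                            observed = NULL) {
  mode <- match.arg(mode)
  if (is.null(observed))
    observed <- driver_screen(fpkm, sample_map, status, thresholds)
  n_obs <- nrow(observed$consistent)

  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    s <- seed + r - 1
    perm <- permute_within_cancer(status, sample_map, seed = s, mode = mode)
    null <- driver_screen(fpkm, sample_map, perm, thresholds)
    n_null <- nrow(null$consistent)
    rows[[r]] <- data.frame(
      permutation_id = r, seed = s,
      null_consistent_count = n_null,
      observed_consistent_count = n_obs,
      fdr_estimate = n_null / max(n_obs, 1),
      degenerate = n_obs == 0, stringsAsFactors = FALSE)
  }
  rep_df <- do.call(rbind, rows)
  structure(list(replicates = rep_df,
                 fdr_estimate = mean(rep_df$null_consistent_count) /
                   max(n_obs, 1),
                 observed = observed),
            class = "permutation_fdr")
}

#' @export
print.permutation_fdr <- function(x, ...) {
  n_obs <- x$replicates$observed_consistent_count[1]
  cat("Within-cancer label-permutation FDR\n")
  cat(sprintf("  observed consistent associations: %d\n", n_obs))
  cat(sprintf("  null consistent counts: %s\n",
              paste(x$replicates$null_consistent_count, collapse = ", ")))
  cat(sprintf("  FDR estimate: %.4g%s\n", x$fdr_estimate,
              if (n_obs == 0) " (degenerate: observed count 0)" else ""))
  invisible(x)
}
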