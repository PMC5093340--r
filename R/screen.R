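#' Screening thresholds
#'
#' Container for the screen's tunable filters. Defaults implement the
#' inclusive per-cancer rule (uncorrected P < 0.001 and absolute log2
#' change > 1) combined with cross-cancer replication in at least two
#' cancer types; no per-cancer multiple-testing correction is applied,
#' replication is the error control.
#'
#' @param p two-sided rank-sum p-value cut-off (strict, default 0.001)
#' @param lfc absolute log2 group-ratio cut-off (strict, default 1)
#' @param detect_frac minimum fraction of samples with FPKM > 0 required
#'   in both groups (inclusive, default 0.10)
#' @param pseudo FPKM pseudo-count added before group means (default 0.1)
#' @param min_group minimum mutated and wild-type group size per cancer
#'   (default 3; cancers below it are skipped for that event)
#' @param min_replication minimum number of supporting cancers for a
#'   consistent association (default 2)
#' @param same_direction require a common direction of change across
#'   supporting cancers (default TRUE)
#' @return object of class `screen_thresholds`
#' @export
screen_thresholds <- function(p = 0.001, lfc = 1, detect_frac = 0.10,
                              pseudo = 0.1, min_group = 3,
                              min_replication = 2, same_direction = TRUE) {
  stopifnot(p > 0, lfc >= 0, detect_frac >= 0, pseudo > 0,
            min_group >= 1, min_replication >= 1)
  structure(list(p = p, lfc = lfc, detect_frac = detect_frac,
                 pseudo = pseudo, min_group = min_group,
                 min_replication = min_replication,
                 same_direction = same_direction),
            class = "screen_thresholds")
}

# Vectorized tie-corrected normal approximation of the Wilcoxon rank-sum
# test over the rows of X. Returns the two-sided p per row.
#   W    = rank sum of group 1 (mid-ranks)
#   mu   = n1 (N + 1) / 2
#   var  = n1 n2 / 12 * ((N + 1) - sum(t^3 - t) / (N (N - 1)))
#   z    = (|W - mu| - 1/2) / sd   (continuity corrected, floored at 0)
#   p    = 2 Phi(-z), clipped to <= 1
#' @keywords internal
.ranksum_rows <- function(X, mask) {
  n1 <- sum(mask)
  n2 <- sum(!mask)
  N <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1, ncol(X) == N)
  rk <- matrix(0, nrow(X), N)
  ties <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    v <- X[i, ]
    rk[i, ] <- rank(v)                      # mid-ranks
    t <- rle(sort(v))$lengths
    ties[i] <- sum(t^3 - t)
  }
  W <- rowSums(rk[, mask, drop = FALSE])
  mu <- n1 * (N + 1) / 2
  v <- n1 * n2 / 12 * ((N + 1) - ties / (N * (N - 1)))
  z <- pmax(abs(W - mu) - 0.5, 0) / sqrt(v)
  p <- 2 * stats::pnorm(-z)
  p[v <= 0] <- 1                            # all values identical
  pmin(p, 1)
}

#' Two-sided Wilcoxon rank-sum p-value (normal approximation)
#'
#' Mid-ranks for ties, tie-corrected variance, and a continuity correction
#' of 0.5, matching the classical approximate rank-sum test. Returns 1
#' when all values are identical across both groups.
#'
#' @param x,y numeric vectors (each nonempty)
#' @return two-sided p-value in (0, 1]
#' @export
rank_sum_p <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  X <- matrix(c(x, y), nrow = 1)
  mask <- c(rep(TRUE, length(x)), rep(FALSE, length(y)))
  .ranksum_rows(X, mask)[1]
}

#' Log2 expression ratio between groups
#'
#' `log2((mean(x) + pseudo) / (mean(y) + pseudo))`; the pseudo-count is
#' added to each group mean before the ratio to avoid division by zero.
#'
#' @param x_mut FPKM values of the mutated group
#' @param y_wt FPKM values of the wild-type group
#' @param pseudo pseudo-count (default 0.1)
#' @return log2 ratio (mutated over wild type)
#' @export
group_log2_ratio <- function(x_mut, y_wt, pseudo = 0.1) {
  log2((mean(x_mut) + pseudo) / (mean(y_wt) + pseudo))
}

#' Detectability filter
#'
#' A feature is detectable for a comparison iff the fraction of samples
#' with FPKM > 0 reaches `min_frac` (inclusive) in the mutated group and
#' in the wild-type group. Empty groups are never detectable.
#'
#' @param values per-sample FPKM values
#' @param mut_mask logical mask of mutated samples
#' @param min_frac minimum detectable fraction (default 0.10)
#' @return logical scalar
#' @export
detectable <- function(values, mut_mask, min_frac = 0.10) {
  n1 <- sum(mut_mask)
  n2 <- sum(!mut_mask)
  if (n1 == 0 || n2 == 0) return(FALSE)
  mean(values[mut_mask] > 0) >= min_frac && mean(values[!mut_mask] > 0) >= min_frac
}

# One cancer x one event: test every feature row of fpkm_sub.
# Precomputed ranks (rk, tie sums) may be passed to share work across
# events within a cancer.
#' @keywords internal
.screen_one <- function(fpkm_sub, status, event_name, cancer, th,
                        precomp = NULL) {
  n_mut <- sum(status)
  n_wt <- sum(!status)
  if (n_mut < th$min_group || n_wt < th$min_group) {
    message(sprintf("skipping %s in %s: %d mutated / %d wild type",
                    event_name, cancer, n_mut, n_wt))
    return(NULL)
  }
  if (is.null(precomp)) {
    p <- .ranksum_rows(fpkm_sub, status)
  } else {
    N <- length(status)
    W <- rowSums(precomp$rk[, status, drop = FALSE])
    mu <- n_mut * (N + 1) / 2
    v <- n_mut * n_wt / 12 * ((N + 1) - precomp$ties / (N * (N - 1)))
    z <- pmax(abs(W - mu) - 0.5, 0) / sqrt(v)
    p <- 2 * stats::pnorm(-z)
    p[v <= 0] <- 1
    p <- pmin(p, 1)
  }
  mean_mut <- rowMeans(fpkm_sub[, status, drop = FALSE])
  mean_wt <- rowMeans(fpkm_sub[, !status, drop = FALSE])
  l2 <- log2((mean_mut + th$pseudo) / (mean_wt + th$pseudo))
  det <- rowMeans(fpkm_sub[, status, drop = FALSE] > 0) >= th$detect_frac &
    rowMeans(fpkm_sub[, !status, drop = FALSE] > 0) >= th$detect_frac
  data.frame(
    feature_id = rownames(fpkm_sub), event = event_name, cancer = cancer,
    p_value = p, log2_ratio = l2, n_mut = n_mut, n_wt = n_wt,
    detectable = det,
    passes = det & p < th$p & abs(l2) > th$lfc,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-cancer association screen for one event
#'
#' Tests every feature of `fpkm` for differential expression between
#' mutated and wild-type samples of one cancer with the approximate
#' rank-sum test, and applies the detectability, p-value and fold-change
#' filters.
#'
#' @param fpkm features x samples FPKM matrix (this cancer's samples)
#' @param status logical mutation status per sample (column order)
#' @param event event name for the output records
#' @param cancer cancer label for the output records
#' @param thresholds a [screen_thresholds()] object
#' @return data frame of association records (one row per feature), or
#'   NULL when either group is smaller than `min_group`
#' @export
screen_cancer <- function(fpkm, status, event, cancer,
                          thresholds = screen_thresholds()) {
  .check_matrix(fpkm, "fpkm")
  stopifnot(length(status) == ncol(fpkm))
  .screen_one(fpkm, status, event, cancer, thresholds)
}

#' Pan-cancer driver-mutation association screen
#'
#' Runs the per-cancer rank-sum screen for every event in every cancer
#' type and collects the cross-cancer consistent associations. Feature
#' ranks are computed once per cancer and shared across events.
#'
#' @param fpkm features x samples FPKM matrix (subset rows to the feature
#'   set of interest, e.g. catalogue lncRNAs plus coding genes)
#' @param sample_map data frame with columns `sample`, `cancer`
#' @param status samples x events logical matrix (e.g. from
#'   [mutation_status()] per event); rownames are sample ids
#' @param thresholds a [screen_thresholds()] object
#' @return object of class `driver_screen`: list with `records` (all
#'   per-(feature, event, cancer) association records), `consistent`
#'   (see [consistent_associations()]), `thresholds`, `cancers`, `events`
#' @export
driver_screen <- function(fpkm, sample_map, status,
                          thresholds = screen_thresholds()) {
  .check_matrix(fpkm, "fpkm")
  .check_matrix(status * 1, "status")
  if (!all(colnames(fpkm) %in% sample_map$sample))
    .stopf("samples missing from sample_map: %s",
           paste(utils::head(setdiff(colnames(fpkm), sample_map$sample)),
                 collapse = ", "))
  screened <- intersect(colnames(fpkm), rownames(status))
  if (!length(screened)) .stopf("no overlap between fpkm samples and status")
  cancer_of <- sample_map$cancer[match(screened, sample_map$sample)]

  records <- vector("list", length(unique(cancer_of)) * ncol(status))
  k <- 0
  for (cc in unique(cancer_of)) {
    cols <- screened[cancer_of == cc]
    sub <- fpkm[, cols, drop = FALSE]
    pre <- list(rk = matrix(0, nrow(sub), ncol(sub)),
                ties = numeric(nrow(sub)))
    for (i in seq_len(nrow(sub))) {
      v <- sub[i, ]
      pre$rk[i, ] <- rank(v)
      t <- rle(sort(v))$lengths
      pre$ties[i] <- sum(t^3 - t)
    }
    for (ev in colnames(status)) {
      k <- k + 1
      records[[k]] <- .screen_one(sub, status[cols, ev], ev, cc,
                                  thresholds, precomp = pre)
    }
  }
  records <- do.call(rbind, records)
  consistent <- consistent_associations(
    records, min_replication = thresholds$min_replication,
    same_direction = thresholds$same_direction)
  structure(list(records = records, consistent = consistent,
                 thresholds = thresholds,
                 cancers = unique(cancer_of), events = colnames(status),
                 n_features = nrow(fpkm)),
            class = "driver_screen")
}

#' Cross-cancer consistent associations
#'
#' Groups passing records by (feature, event) and keeps pairs supported in
#' at least `min_replication` distinct cancer types, optionally requiring
#' a shared direction of change (sign of the log2 ratio).
#'
#' @param records association-record data frame (e.g. `$records` of a
#'   [driver_screen()] result)
#' @param min_replication minimum number of supporting cancers (default 2)
#' @param same_direction require one direction across supporting cancers
#'   (default TRUE); with FALSE, mixed-direction support is labelled
#'   `mixed`
#' @return data frame: `feature_id`, `event`, `direction` (`up`/`down`/
#'   `mixed`), `n_cancers`, `cancers` (comma-joined), `min_p`
#' @export
consistent_associations <- function(records, min_replication = 2,
                                    same_direction = TRUE) {
  empty <- data.frame(feature_id = character(0), event = character(0),
                      direction = character(0), n_cancers = integer(0),
                      cancers = character(0), min_p = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(records) || !nrow(records)) return(empty)
  hits <- records[records$passes, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  hits$direction <- ifelse(hits$log2_ratio > 0, "up", "down")
  key <- if (same_direction)
    paste(hits$feature_id, hits$event, hits$direction, sep = "\r")
  else paste(hits$feature_id, hits$event, sep = "\r")
  out <- lapply(split(hits, key), function(d) {
    cc <- sort(unique(d$cancer))
    if (length(cc) < min_replication) return(NULL)
    data.frame(
      feature_id = d$feature_id[1], event = d$event[1],
      direction = if (length(unique(d$direction)) == 1) d$direction[1]
        else "mixed",
      n_cancers = length(cc), cancers = paste(cc, collapse = ","),
      min_p = min(d$p_value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$feature_id, out$event), ]
  rownames(out) <- NULL
  out
}

#' @export
print.driver_screen <- function(x, ...) {
  cat("Pan-cancer driver-mutation association screen\n")
  cat(sprintf("  features: %d   events: %d   cancers: %d\n",
              x$n_features, length(x$events), length(x$cancers)))
  cat(sprintf("  records tested: %d\n",
              if (is.null(x$records)) 0L else nrow(x$records)))
  cat(sprintf("  per-cancer passing records: %d\n",
              if (is.null(x$records)) 0L else sum(x$records$passes)))
  cat(sprintf("  consistent associations (>=%d cancers%s): %d\n",
              x$thresholds$min_replication,
              if (x$thresholds$same_direction) ", same direction" else "",
              nrow(x$consistent)))
  invisible(x)
}

#' @export
summary.driver_screen <- function(object, ...) {
  r <- object$records
  att <- c(
    tested = if (is.null(r)) 0L else nrow(r),
    detectable = if (is.null(r)) 0L else sum(r$detectable),
    p_pass = if (is.null(r)) 0L else
      sum(r$detectable & r$p_value < object$thresholds$p),
    passing = if (is.null(r)) 0L else sum(r$passes),
    consistent = nrow(object$consistent)
  )
  out <- list(attrition = att,
              per_event = if (!is.null(r))
                table(event = r$event[r$passes], cancer = r$cancer[r$passes]),
              consistent = object$consistent,
              thresholds = object$thresholds)
  class(out) <- "summary.driver_screen"
  out
}

#' @export
print.summary.driver_screen <- function(x, ...) {
  cat("Filter attrition (records):\n")
  print(x$attrition)
  if (!is.null(x$per_event) && length(x$per_event)) {
    cat("\nPassing records per event and cancer:\n")
    print(x$per_event)
  }
  cat(sprintf("\nConsistent associations: %d\n", nrow(x$consistent)))
  if (nrow(x$consistent)) print(utils::head(x$consistent, 20))
  invisible(x)
}

#' Volcano-style plot of a screen
#'
#' Plots -log10 p against the log2 ratio for every tested record,
#' marking per-cancer passing records and the threshold lines.
#'
#' @param x a `driver_screen` object
#' @param ... passed to [graphics::plot()]
#' @return `x`, invisibly
#' @method plot driver_screen
#' @export
plot.driver_screen <- function(x, ...) {
  r <- x$records
  if (is.null(r) || !nrow(r)) {
    warning("nothing to plot")
    return(invisible(x))
  }
  col <- ifelse(r$passes, "firebrick", "grey60")
  graphics::plot(r$log2_ratio, -log10(r$p_value), pch = 16, cex = 0.4,
                 col = col, xlab = "log2 ratio (mutated / wild type)",
                 ylab = "-log10 P", ...)
  graphics::abline(h = -log10(x$thresholds$p), lty = 2)
  graphics::abline(v = c(-1, 1) * x$thresholds$lfc, lty = 2)
  invisible(x)
}
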