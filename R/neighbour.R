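#' Proximal coding-gene dependency of consistent lncRNA associations
#'
#' For each consistent lncRNA-event association, picks the strength cancer
#' (lowest lncRNA p among its passing cancers, ties by cancer-label
#' order), collects the candidate coding genes (closest up- and downstream
#' neighbours plus any coding gene within `window` bp), and looks up the
#' best (lowest-p) candidate association for the same event in that
#' cancer. The lncRNA is called independent when no candidate reaches
#' `indep_p`; candidates failing detectability in the strength cancer are
#' treated as having no p-value. Co-expression between the lncRNA and its
#' best candidate is the Pearson r of `log2(FPKM + pseudo)` across the
#' strength cancer's samples.
#'
#' @param consistent consistent-association data frame (lncRNA features),
#'   as returned by [consistent_associations()]
#' @param records full screen records including the coding genes (same
#'   events/cancers)
#' @param models `gene_models` covering lncRNAs and coding genes
#' @param fpkm features x samples FPKM matrix covering both
#' @param sample_map data frame with columns `sample`, `cancer`
#' @param window neighbourhood size in bp (default 100000)
#' @param indep_p independence p-value line (default 0.01): independent
#'   iff best coding p is missing or >= this value
#' @param pseudo pseudo-count for the co-expression transform (default 0.1)
#' @return data frame: `lnc_id`, `event`, `strength_cancer`, `lnc_min_p`,
#'   `best_coding_id`, `best_coding_p`, `coexpr_r`, `independent`
#' @export
neighbour_dependency <- function(consistent, records, models, fpkm,
                                 sample_map, window = 1e5, indep_p = 0.01,
                                 pseudo = 0.1) {
  if (!nrow(consistent))
    return(data.frame(lnc_id = character(0), event = character(0),
                      strength_cancer = character(0), lnc_min_p = numeric(0),
                      best_coding_id = character(0),
                      best_coding_p = numeric(0), coexpr_r = numeric(0),
                      independent = logical(0), stringsAsFactors = FALSE))
  out <- vector("list", nrow(consistent))
  for (i in seq_len(nrow(consistent))) {
    lnc <- consistent$feature_id[i]
    ev <- consistent$event[i]
    mine <- records[records$feature_id == lnc & records$event == ev &
                      records$passes, , drop = FALSE]
    mine <- mine[order(mine$p_value, mine$cancer), , drop = FALSE]
    sc <- mine$cancer[1]
    min_p <- mine$p_value[1]

    nb <- neighbours(lnc, models, window = window)
    cand <- unique(stats::na.omit(c(nb$upstream_coding, nb$downstream_coding,
                                    nb$within_window)))
    best_id <- NA_character_
    best_p <- NA_real_
    r <- NA_real_
    if (length(cand)) {
      cr <- records[records$feature_id %in% cand & records$event == ev &
                      records$cancer == sc & records$detectable, ,
                    drop = FALSE]
      if (nrow(cr)) {
        cr <- cr[order(cr$p_value, cr$feature_id), , drop = FALSE]
        best_id <- cr$feature_id[1]
        best_p <- cr$p_value[1]
        cols <- sample_map$sample[sample_map$cancer == sc]
        cols <- intersect(cols, colnames(fpkm))
        a <- log2(fpkm[lnc, cols] + pseudo)
        b <- log2(fpkm[best_id, cols] + pseudo)
        if (stats::sd(a) > 0 && stats::sd(b) > 0) r <- stats::cor(a, b)
      }
    }
    out[[i]] <- data.frame(
      lnc_id = lnc, event = ev, strength_cancer = sc, lnc_min_p = min_p,
      best_coding_id = best_id, best_coding_p = best_p, coexpr_r = r,
      independent = is.na(best_p) || best_p >= indep_p,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genic/intergenic breakdown of consistent associations
#'
#' @param consistent consistent-association data frame (lncRNA features)
#' @param catalogue classified `lnc_catalogue`
#' @return named integer vector with counts `genic`, `intergenic`, `total`
#' @export
genic_fraction <- function(consistent, catalogue) {
  cls <- catalogue$class[match(consistent$feature_id, catalogue$gene_id)]
  if (anyNA(cls))
    .stopf("feature(s) missing from catalogue: %s",
           paste(unique(consistent$feature_id[is.na(cls)]), collapse = ", "))
  c(genic = sum(cls == "genic"), intergenic = sum(cls == "intergenic"),
    total = length(cls))
}
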