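# Leave-one-out CR/AD classification by Pearson similarity of density
# pictures.

#' Reference density pictures for both groups
#'
#' Builds the cumulative AD and CR density pictures on a shared grid,
#' optionally excluding one held-out sample from both references (its cells
#' remain part of the embedding, only the reference pictures omit them).
#'
#' @param embedding embedded expression matrix.
#' @param grid a [density_grid()] built from the combined embedding.
#' @param exclude_sample patient id to hold out, or `NULL`.
#' @param smooth_sigma Gaussian smoothing width in bins.
#' @return list with `ad` and `cr` density matrices.
#' @export
build_reference_pictures <- function(embedding, grid, exclude_sample = NULL,
                                     smooth_sigma = 1) {
  keep <- if (is.null(exclude_sample)) rep(TRUE, nrow(embedding)) else
    embedding$patient_id != exclude_sample
  ad <- embedding[keep & embedding$group == "AD", , drop = FALSE]
  cr <- embedding[keep & embedding$group == "CR", , drop = FALSE]
  if (nrow(ad) == 0 || nrow(cr) == 0) {
    stop_hspc("excluding this sample empties a reference group",
              "hspcmap_protocol_error")
  }
  list(ad = density_matrix(ad, grid, smooth_sigma),
       cr = density_matrix(cr, grid, smooth_sigma))
}

#' Classify one sample against leave-one-out references
#'
#' Computes the Pearson coefficients of the held-out sample's density
#' picture with the cumulative CR and AD reference pictures (sample
#' excluded from both) and calls the sample CR when `r_vs_sum_CR` exceeds
#' `r_vs_sum_AD` by more than the tie tolerance, AD in the opposite case,
#' and `unclassified` on a tie. Degenerate (constant) pictures yield an
#' `unclassifiable` record instead of an error.
#'
#' @param embedding embedded expression matrix.
#' @param sample patient id to classify.
#' @param grid a [density_grid()]; built from the embedding when `NULL`.
#' @param tie_tol tie tolerance on the r difference.
#' @param smooth_sigma Gaussian smoothing width in bins.
#' @return one-row data.frame: `patient_id`, `group`, `r_vs_sum_ad`,
#'   `r_vs_sum_cr`, `call`, `reason`.
#' @export
loo_classify <- function(embedding, sample, grid = NULL, tie_tol = 1e-9,
                         smooth_sigma = 1) {
  if (!sample %in% embedding$patient_id) {
    stop_hspc(paste0("sample '", sample, "' not present in embedding"),
              "hspcmap_protocol_error")
  }
  if (is.null(grid)) grid <- density_grid(embedding)
  own <- embedding[embedding$patient_id == sample, , drop = FALSE]
  truth <- own$group[1]
  rec <- data.frame(patient_id = sample, group = truth,
                    r_vs_sum_ad = NA_real_, r_vs_sum_cr = NA_real_,
                    call = "unclassifiable", reason = NA_character_,
                    stringsAsFactors = FALSE)
  res <- tryCatch({
    refs <- build_reference_pictures(embedding, grid, sample, smooth_sigma)
    pic <- density_matrix(own, grid, smooth_sigma)
    list(r_ad = pearson_density(pic, refs$ad),
         r_cr = pearson_density(pic, refs$cr))
  }, hspcmap_sigma_error = function(e) e, hspcmap_protocol_error = function(e) e)
  if (inherits(res, "condition")) {
    rec$reason <- conditionMessage(res)
    return(rec)
  }
  rec$r_vs_sum_ad <- res$r_ad
  rec$r_vs_sum_cr <- res$r_cr
  diff <- res$r_cr - res$r_ad
  rec$call <- if (diff > tie_tol) "CR" else if (diff < -tie_tol) "AD" else
    "unclassified"
  rec
}

#' Leave-one-out classification table for a whole cohort
#'
#' One record per sample plus the inter-reference coefficient
#' `r(sum CR, sum AD)`. An optional exclusion list removes named samples
#' from the analysis (records and reference pictures) without recomputing
#' the embedding.
#'
#' @param embedding embedded expression matrix (>= 2 samples per group).
#' @param grid a [density_grid()]; built from the embedding when `NULL`.
#' @param tie_tol tie tolerance.
#' @param smooth_sigma Gaussian smoothing width in bins.
#' @param exclude_samples patient ids dropped from the analysis.
#' @return list of class `classification_table`: `records` (data.frame),
#'   `r_refs`, `excluded`.
#' @export
classification_table <- function(embedding, grid = NULL, tie_tol = 1e-9,
                                 smooth_sigma = 1,
                                 exclude_samples = NULL) {
  if (is.null(grid)) grid <- density_grid(embedding)
  sub <- embedding
  if (!is.null(exclude_samples)) {
    sub <- embedding[!embedding$patient_id %in% exclude_samples, ,
                     drop = FALSE]
  }
  meta <- unique(sub[, c("patient_id", "group")])
  if (any(table(meta$group) < 2)) {
    stop_hspc("need at least two samples per group", "hspcmap_protocol_error")
  }
  records <- do.call(rbind, lapply(meta$patient_id, function(id) {
    loo_classify(sub, id, grid, tie_tol, smooth_sigma)
  }))
  rownames(records) <- NULL
  refs <- build_reference_pictures(sub, grid, NULL, smooth_sigma)
  structure(list(records = records,
                 r_refs = pearson_density(refs$cr, refs$ad),
                 excluded = exclude_samples %||% character(0)),
            class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat("Leave-one-out CR/AD classification\n")
  cat(sprintf("  r(sum CR, sum AD) = %.3f\n", x$r_refs))
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  print(x$records, digits = 3)
  invisible(x)
}

#' Classification accuracy of a record table
#'
#' Fraction of samples whose call equals their true group; unclassified or
#' unclassifiable samples count as incorrect.
#'
#' @param table a `classification_table` or its `records` data.frame.
#' @return accuracy in \[0, 1\].
#' @export
classification_accuracy <- function(table) {
  rec <- if (inherits(table, "classification_table")) table$records else table
  mean(rec$call == rec$group)
}

#' Stability of the classification across embedding runs
#'
#' Recomputes the t-SNE embedding under each seed, classifies every sample
#' by the leave-one-out protocol, and reports per-sample call agreement
#' across runs.
#'
#' @param matrix merged (unembedded) expression matrix.
#' @param params an [embed_params()]; its seed is replaced per run.
#' @param seeds integer vector of embedding seeds (length >= 2).
#' @param n_bins,pad,smooth_sigma density-grid settings.
#' @param tie_tol tie tolerance.
#' @return list: `tables` (per-run classification tables), `agreement`
#'   (data.frame patient_id, agreement fraction with the modal call),
#'   `all_identical` (logical).
#' @export
stability_analysis <- function(matrix, params = embed_params(),
                               seeds = c(1L, 2L, 3L), n_bins = 100,
                               pad = 0.02, smooth_sigma = 1,
                               tie_tol = 1e-9) {
  if (length(seeds) < 2) {
    stop_hspc("need at least two seeds", "hspcmap_argument_error")
  }
  tables <- lapply(seeds, function(s) {
    p <- params; p$seed <- as.integer(s)
    emb <- tsne_embed(matrix, p)
    classification_table(emb, density_grid(emb, n_bins, pad),
                         tie_tol, smooth_sigma)
  })
  calls <- sapply(tables, function(tb) tb$records$call)
  ids <- tables[[1]]$records$patient_id
  agreement <- apply(calls, 1, function(cc) {
    tab <- table(cc)
    max(tab) / length(cc)
  })
  list(tables = tables,
       agreement = data.frame(patient_id = ids, agreement = agreement),
       all_identical = all(agreement == 1))
}
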