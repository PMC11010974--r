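# Biexponential scaling, cohort merge, PCA initialization and the
# Barnes-Hut t-SNE embedding.

#' Biexponential (arcsinh) intensity transform
#'
#' Inverse-hyperbolic-sine scaling with a per-channel cofactor: linear for
#' small intensities, logarithmic for large ones, odd-symmetric and defined
#' for negative inputs. For `x >> cofactor`,
#' `f(x) = asinh(x / c) ~ ln(2 x / c)`, so a tenfold intensity step maps to
#' a spacing of `ln(10)`.
#'
#' @param x raw intensities (any sign).
#' @param cofactor positive scale parameter; default 150.
#' @return scaled intensities of the same shape as `x`.
#' @export
biexp_transform <- function(x, cofactor = 150) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 ||
      !is.finite(cofactor) || cofactor <= 0) {
    stop_hspc("cofactor must be a positive number", "hspcmap_config_error")
  }
  asinh(x / cofactor)
}

#' Merge gated patient tables into one expression matrix
#'
#' Biexponentially scales the five analysis markers of every gated CD34+
#' table and stacks them into a single data.frame, with `patient_id` and
#' `group` appended to every row so the merged set can be split again after
#' embedding. Ground-truth side channels, when present, travel along.
#'
#' @param tables list of gated CellEventTables (one per patient).
#' @param config configuration list supplying the cofactor.
#' @return `expression_matrix` data.frame: scaled markers + annotations.
#' @export
merge_cohort <- function(tables, config = default_config()) {
  if (length(tables) < 2) {
    stop_hspc("need at least two patient tables to merge",
              "hspcmap_argument_error")
  }
  markers <- hspc_markers()
  parts <- lapply(tables, function(tab) {
    stopifnot(all(markers %in% names(tab)),
              all(c("patient_id", "group") %in% names(tab)))
    out <- as.data.frame(lapply(tab[markers], biexp_transform,
                                cofactor = config$cofactor),
                         check.names = FALSE)
    out$patient_id <- tab$patient_id
    out$group <- tab$group
    for (tc in grep("^\\.", names(tab), value = TRUE)) out[[tc]] <- tab[[tc]]
    out
  })
  merged <- do.call(rbind, parts)
  rownames(merged) <- NULL
  pg <- unique(merged[, c("patient_id", "group")])
  if (anyDuplicated(pg$patient_id)) {
    stop_hspc(paste0("patient id present in both groups: ",
                     paste(pg$patient_id[duplicated(pg$patient_id)],
                           collapse = ", ")),
              "hspcmap_metadata_error")
  }
  if (length(unique(merged$group)) < 2) {
    stop_hspc("both groups (CR and AD) must be represented",
              "hspcmap_metadata_error")
  }
  class(merged) <- c("expression_matrix", "data.frame")
  attr(merged, "cofactor") <- config$cofactor
  merged
}

#' Split a merged matrix back into per-patient tables
#' @param matrix an expression matrix (embedded or not).
#' @return named list of per-patient data.frames.
#' @export
split_by_patient <- function(matrix) {
  split(as.data.frame(matrix), matrix$patient_id)
}

#' Embedding parameters
#'
#' @param perplexity t-SNE perplexity (effective neighborhood size);
#'   default 70. Must satisfy `2 <= perplexity < (n_cells - 1) / 3`.
#' @param n_iter number of gradient iterations; default 3000.
#' @param pca_dims number of principal components retained as t-SNE input;
#'   default 50 (capped at the number of markers).
#' @param seed integer seed.
#' @param theta Barnes-Hut accuracy trade-off.
#' @return list of class `embed_params`.
#' @export
embed_params <- function(perplexity = 70, n_iter = 3000, pca_dims = 50,
                         seed = 1L, theta = 0.5) {
  if (perplexity < 2) {
    stop_hspc("perplexity must be >= 2", "hspcmap_parameter_error")
  }
  if (n_iter < 250) {
    stop_hspc("n_iter must be >= 250", "hspcmap_parameter_error")
  }
  structure(list(perplexity = perplexity, n_iter = n_iter,
                 pca_dims = pca_dims, seed = as.integer(seed),
                 theta = theta),
            class = "embed_params")
}

#' PCA initialization of the embedding
#'
#' Projects the scaled marker matrix onto its leading principal components
#' (at most `pca_dims`, capped at the number of features). Component signs
#' are fixed by convention — the loading of largest magnitude is made
#' positive — so the projection is fully deterministic. The first two
#' components, rescaled to standard deviation 1e-4, seed the t-SNE layout,
#' the established recipe for preserving global structure.
#'
#' @param x numeric matrix (or expression matrix) of scaled intensities.
#' @param pca_dims maximum number of retained components.
#' @return list with `scores` (n x k), `init` (n x 2 initial coordinates),
#'   `sdev` and `rotation`.
#' @export
pca_initialize <- function(x, pca_dims = 50) {
  if (is.data.frame(x)) x <- as.matrix(x[, hspc_markers(), drop = FALSE])
  if (ncol(x) < 2) {
    stop_hspc("need at least two feature columns", "hspcmap_argument_error")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (all(p$sdev < 1e-12)) {
    stop_hspc("input matrix is constant; PCA is degenerate",
              "hspcmap_degenerate_error")
  }
  k <- min(pca_dims, ncol(x))
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rotation <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)[, seq_len(k), drop = FALSE]
  init <- scores[, 1:2, drop = FALSE]
  init <- sweep(init, 2, apply(init, 2, stats::sd), `/`) * 1e-4
  list(scores = scores, init = init, sdev = p$sdev[seq_len(k)],
       rotation = rotation[, seq_len(k), drop = FALSE])
}

#' Barnes-Hut t-SNE embedding of the merged cohort
#'
#' Embeds the scaled marker space (via its PCA projection) into two
#' dimensions with the Barnes-Hut t-SNE implementation of \pkg{Rtsne},
#' initialized from the first two principal components. The embedding is
#' deterministic given the input and seed. Coordinates are appended to the
#' expression matrix as `tSNE1`/`tSNE2`; they are unitless and only locally
#' interpretable.
#'
#' @param matrix an expression matrix from [merge_cohort()].
#' @param params an [embed_params()] object.
#' @return the expression matrix with `tSNE1` and `tSNE2` columns.
#' @export
tsne_embed <- function(matrix, params = embed_params()) {
  n <- nrow(matrix)
  if (n - 1 < 3 * params$perplexity) {
    stop_hspc(sprintf(
      "too few cells (%d) for perplexity %g; largest admissible perplexity is %d",
      n, params$perplexity, floor((n - 1) / 3)),
      "hspcmap_parameter_error")
  }
  pca <- pca_initialize(matrix, params$pca_dims)
  fit <- with_seed(params$seed, Rtsne::Rtsne(
    pca$scores, dims = 2, perplexity = params$perplexity,
    theta = params$theta, max_iter = params$n_iter,
    Y_init = pca$init, pca = FALSE, check_duplicates = FALSE,
    verbose = FALSE, num_threads = 1))
  matrix$tSNE1 <- fit$Y[, 1]
  matrix$tSNE2 <- fit$Y[, 2]
  attr(matrix, "embed_params") <- params
  matrix
}

#' Split an embedded matrix into combined, CR-only and AD-only views
#'
#' The three views share one coordinate system; the CR and AD views
#' partition the combined set.
#'
#' @param matrix embedded expression matrix.
#' @return list with elements `all`, `cr`, `ad`.
#' @export
split_groups <- function(matrix) {
  list(all = matrix,
       cr = matrix[matrix$group == "CR", , drop = FALSE],
       ad = matrix[matrix$group == "AD", , drop = FALSE])
}

#' Same-label purity of embedding neighborhoods
#'
#' Mean fraction, over all cells, of a cell's `k` nearest embedding
#' neighbors that share its label — a simple quality score for how well
#' the embedding keeps ground-truth populations together.
#'
#' @param coords n x 2 matrix of embedding coordinates.
#' @param labels length-n label vector.
#' @param k neighborhood size; default 10.
#' @return scalar purity in \[0, 1\].
#' @export
knn_purity <- function(coords, labels, k = 10) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n > k, length(labels) == n)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  same <- vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    mean(labels[nb] == labels[i])
  }, numeric(1))
  mean(same)
}
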