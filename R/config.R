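#' Default pipeline configuration
#'
#' All tunables in one list: the arcsinh cofactor of the biexponential
#' scaling, t-SNE parameters (perplexity 70, 3000 iterations, 50 retained
#' PCA dimensions), the per-patient cell cap of 1000, the doublet ratio
#' window, raw-scale marker thresholds, the density-grid specification used
#' for the Pearson comparison, the tie tolerance of the classification rule
#' and the three scatter-plane gate polygons of the pre-gating sequence.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  rect <- function(x, y, x0, x1, y0, y1) {
    list(x = x, y = y,
         vertices = list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
  }
  list(
    cofactor = 150,
    perplexity = 70,
    iterations = 3000,
    pca_dims = 50,
    cell_cap = 1000,
    doublet_max_deviation = 0.3,
    tie_tol = 1e-9,
    thresholds = default_thresholds(),
    grid = list(n_bins = 100, pad = 0.02, smooth_sigma = 1),
    gates = list(
      fsc_ssc = rect("FSC-A", "SSC-A", 20000, 262144, 0, 262144),
      cd45_ssc = rect("CD45", "SSC-A", 500, 262144, 0, 262144),
      goi = rect("CD34", "SSC-A", 0, 262144, 0, 60000)
    ),
    tsne_gates = NULL,
    seed = 1L
  )
}

deep_merge <- function(base, override) {
  for (k in names(override)) {
    if (is.null(override[[k]])) next
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- deep_merge(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON, a YAML subset) config file, fills every missing
#' key from [default_config()] and validates the result. An empty or `NULL`
#' path yields the full default configuration. Unknown top-level keys and
#' malformed values raise a config error naming the offending keys.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides optional named list merged on top of the file.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path) %||% list()
    if (!is.list(user)) {
      stop_hspc("config file must contain a YAML mapping",
                "hspcmap_config_error")
    }
  }
  user <- deep_merge(user, overrides)
  cfg <- deep_merge(default_config(), user)
  # YAML represents named vectors as maps; coerce threshold maps back
  if (is.list(cfg$thresholds$positive)) {
    cfg$thresholds$positive <- unlist(cfg$thresholds$positive)
  }
  validate_config(cfg, extra_keys = setdiff(names(user),
                                            names(default_config())))
  cfg
}

validate_config <- function(cfg, extra_keys = character(0)) {
  if (length(extra_keys) > 0) {
    stop_hspc(paste0("unknown configuration keys: ",
                     paste(extra_keys, collapse = ", ")),
              "hspcmap_config_error")
  }
  bad <- character(0)
  num_pos <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      bad <<- c(bad, key)
    }
  }
  for (k in c("cofactor", "perplexity", "iterations", "pca_dims",
              "cell_cap", "doublet_max_deviation")) num_pos(k)
  if (is.numeric(cfg$perplexity) && cfg$perplexity < 2) bad <- c(bad, "perplexity")
  if (is.numeric(cfg$iterations) && cfg$iterations < 250) bad <- c(bad, "iterations")
  if (!is.numeric(cfg$tie_tol) || cfg$tie_tol < 0) bad <- c(bad, "tie_tol")
  g <- cfg$grid
  if (!is.list(g) || !is.numeric(g$n_bins) || g$n_bins < 8 ||
      !is.numeric(g$pad) || g$pad < 0 ||
      !is.numeric(g$smooth_sigma) || g$smooth_sigma < 0) {
    bad <- c(bad, "grid")
  }
  th <- cfg$thresholds
  if (!is.list(th) || is.null(th$positive) ||
      !all(hspc_markers() %in% names(th$positive))) {
    bad <- c(bad, "thresholds")
  } else if (th$cd123_low_upper <= th$positive[["CD123"]]) {
    bad <- c(bad, "thresholds$cd123_low_upper")
  }
  for (gn in names(cfg$gates)) {
    gt <- cfg$gates[[gn]]
    v <- gt$vertices
    ok <- is.list(v) && length(v) >= 3 &&
      all(vapply(v, function(p) is.numeric(p) && length(p) == 2, logical(1)))
    if (ok) {
      vx <- vapply(v, `[`, numeric(1), 1)
      vy <- vapply(v, `[`, numeric(1), 2)
      ok <- is_simple_polygon(vx, vy)
    }
    if (!ok) bad <- c(bad, paste0("gates$", gn))
  }
  if (length(bad) > 0) {
    stop_hspc(paste0("invalid configuration values for: ",
                     paste(unique(bad), collapse = ", ")),
              "hspcmap_config_error")
  }
  invisible(cfg)
}

#' Marker thresholds on the scaled intensity axis
#'
#' Converts the raw-scale cutoffs of the configuration to the biexponential
#' (arcsinh) scale on which gate-level marker means are compared, including
#' the upper bound of the CD123 "low" (weakly positive) band.
#'
#' @param config a configuration list, default [default_config()].
#' @return list with `positive` (named scaled cutoffs) and
#'   `cd123_low_upper`.
#' @export
marker_thresholds <- function(config = default_config()) {
  th <- config$thresholds
  list(positive = biexp_transform(th$positive, config$cofactor),
       cd123_low_upper = biexp_transform(th$cd123_low_upper, config$cofactor))
}
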