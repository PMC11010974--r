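# Fixed-grid density pictures of the embedding plane and the Pearson
# similarity between them.

#' Build a shared density grid
#'
#' The grid is the bounding box of the combined embedding, padded by a
#' fraction of the span on each side, divided into `n_bins` bins per axis.
#' Every picture entering one comparison must be binned on the same grid.
#'
#' @param coords two-column matrix/data.frame of embedding coordinates, or
#'   an embedded expression matrix (columns `tSNE1`, `tSNE2`).
#' @param n_bins bins per axis (>= 8); default 100.
#' @param pad fractional padding of the bounding box; default 0.02.
#' @return object of class `density_grid`.
#' @export
density_grid <- function(coords, n_bins = 100, pad = 0.02) {
  stopifnot(n_bins >= 8, pad >= 0)
  coords <- grid_coords(coords)
  lim <- function(v) {
    r <- range(v)
    span <- diff(r)
    if (span == 0) span <- max(abs(r[1]), 1)
    r + c(-1, 1) * pad * span
  }
  xlim <- lim(coords[, 1]); ylim <- lim(coords[, 2])
  structure(list(
    xlim = xlim, ylim = ylim, n_bins = as.integer(n_bins),
    xbreaks = seq(xlim[1], xlim[2], length.out = n_bins + 1),
    ybreaks = seq(ylim[1], ylim[2], length.out = n_bins + 1)),
    class = "density_grid")
}

grid_coords <- function(coords) {
  if (is.data.frame(coords) && all(c("tSNE1", "tSNE2") %in% names(coords))) {
    coords <- coords[, c("tSNE1", "tSNE2")]
  }
  as.matrix(coords)
}

#' Pixel-density matrix of an embedding subset
#'
#' Bins the coordinates into the shared grid (cells exactly on the upper
#' boundary fall into the edge bin) and optionally applies mass-preserving
#' Gaussian smoothing. The entry sum always equals the number of
#' contributing cells.
#'
#' @param coords coordinates of the subset (see [density_grid()]).
#' @param grid a `density_grid`.
#' @param smooth_sigma Gaussian smoothing width in bins; 0 disables
#'   smoothing.
#' @return `n_bins` x `n_bins` matrix (rows = x bins, columns = y bins)
#'   with attributes `n_cells` and `grid`.
#' @export
density_matrix <- function(coords, grid, smooth_sigma = 0) {
  stopifnot(inherits(grid, "density_grid"))
  coords <- grid_coords(coords)
  n <- nrow(coords)
  nb <- grid$n_bins
  mat <- matrix(0, nb, nb)
  if (n > 0) {
    if (any(coords[, 1] < grid$xlim[1] | coords[, 1] > grid$xlim[2] |
            coords[, 2] < grid$ylim[1] | coords[, 2] > grid$ylim[2])) {
      stop_hspc(paste0("coordinates fall outside the density grid; ",
                       "build the grid from the combined embedding"),
                "hspcmap_grid_error")
    }
    ix <- findInterval(coords[, 1], grid$xbreaks, rightmost.closed = TRUE)
    iy <- findInterval(coords[, 2], grid$ybreaks, rightmost.closed = TRUE)
    mat <- matrix(tabulate(ix + (iy - 1L) * nb, nbins = nb * nb), nb, nb)
  }
  if (smooth_sigma > 0 && n > 0) mat <- gaussian_smooth(mat, smooth_sigma)
  attr(mat, "n_cells") <- n
  attr(mat, "grid") <- grid
  mat
}

# Separable Gaussian convolution with reflecting boundaries: mass that
# would leave the grid is folded back, so the operation is linear and
# conserves the entry sum (up to floating-point rounding). Linearity keeps
# smoothed group pictures exactly additive.
gaussian_smooth <- function(mat, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  reflect <- function(idx, n) {
    period <- 2L * n
    r <- (idx - 1L) %% period
    r[r < 0] <- r[r < 0] + period
    ifelse(r < n, r + 1L, period - r)
  }
  conv1 <- function(m) {
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (off in seq_along(k)) {
      src <- reflect(seq_len(nr) + (off - half - 1L), nr)
      out <- out + k[off] * m[src, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(mat))))
}

#' Pearson similarity of two density pictures
#'
#' The product-moment correlation of the pixel densities, computed from the
#' picture sums: `r = cov(A, B) / (sigma_A sigma_B)` with
#' `cov(A, B) = sum(A_j B_j) - sum(A_j) sum(B_j) / N` and
#' `sigma_X = sqrt(sum(X_j^2) - sum(X_j)^2 / N)` over the N pixels.
#' `r = 1` for identical pictures; `r = -1` for maximally different ones
#' (complementary support). Invariant under positive affine rescaling of
#' either picture.
#'
#' @param a,b density matrices on the same grid.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_density <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) != length(b)) {
    stop_hspc("pictures must share one grid (equal pixel counts)",
              "hspcmap_grid_error")
  }
  n <- length(a)
  var_a <- sum(a * a) - sum(a)^2 / n
  var_b <- sum(b * b) - sum(b)^2 / n
  if (var_a <= 0 || var_b <= 0) {
    stop_hspc("constant picture: correlation undefined (sigma = 0)",
              "hspcmap_sigma_error")
  }
  cov_ab <- sum(a * b) - sum(a) * sum(b) / n
  # single sqrt of the product: keeps r(A, A) exactly 1 in floating point
  r <- cov_ab / sqrt(var_a * var_b)
  min(1, max(-1, r))
}
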