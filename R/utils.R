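# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' then restores the previous RNG state, so that seeded operations do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

stop_hspc <- function(msg, class, ...) {
  stop(structure(class = c(class, "hspcmap_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Classifies points against a simple polygon using the even-odd (ray
#' crossing) rule. Points lying exactly on a polygon edge or vertex are
#' counted as inside, the convention used by every gate in this package.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param vx,vy numeric vectors of polygon vertex coordinates (implicitly
#'   closed: the last vertex connects back to the first).
#' @return logical vector, `TRUE` for points inside or on the boundary.
#' @export
point_in_polygon <- function(px, py, vx, vy) {
  stopifnot(length(px) == length(py), length(vx) == length(vy),
            length(vx) >= 3)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  sc <- max(abs(c(vx, vy, 1)))
  tol <- 1e-9 * sc * sc
  j <- length(vx)
  for (i in seq_along(vx)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
      py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
    on_edge <- on_edge | (abs(cross) <= tol & within)
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside | on_edge
}

# TRUE when the closed polygon has no self-intersections (shared endpoints
# of adjacent edges excepted).
is_simple_polygon <- function(vx, vy) {
  n <- length(vx)
  if (n < 3) return(FALSE)
  seg <- cbind(vx, vy, c(vx[-1], vx[1]), c(vy[-1], vy[1]))
  intersects <- function(a, b) {
    d1 <- sign((b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1]))
    d2 <- sign((b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1]))
    d3 <- sign((a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1]))
    d4 <- sign((a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1]))
    d1 != d2 && d3 != d4
  }
  for (i in seq_len(n - 2)) {
    for (k in seq(i + 2, n)) {
      if (i == 1 && k == n) next  # adjacent through closure
      if (intersects(seg[i, ], seg[k, ])) return(FALSE)
    }
  }
  TRUE
}

# Columns of a CellEventTable that hold measured channels (everything that
# is not per-event metadata or a test-only ground-truth side channel).
event_channels <- function(table) {
  nm <- names(table)
  nm[!startsWith(nm, ".") & !nm %in% c("patient_id", "group")]
}
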