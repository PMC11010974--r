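# Polygon gates in the embedding plane, marker summaries per gate and
# phenotype assignment from gate-level marker means.

#' Construct a gate set on the embedding plane
#'
#' @param gates named list; each element a numeric matrix (or list of
#'   length-2 vectors) of polygon vertices in (tSNE1, tSNE2) coordinates.
#' @param drawn_on provenance tag recording which subset the gates were
#'   drawn on (conventionally the CR view).
#' @return object of class `tsne_gate_set`.
#' @export
tsne_gate_set <- function(gates, drawn_on = "CR") {
  if (is.null(names(gates)) || anyDuplicated(names(gates))) {
    stop_hspc("gates must have unique names", "hspcmap_gate_error")
  }
  gates <- lapply(names(gates), function(nm) {
    polygon_gate(nm, "tSNE1", "tSNE2", gates[[nm]])
  })
  names(gates) <- vapply(gates, `[[`, character(1), "name")
  structure(list(gates = gates, drawn_on = drawn_on),
            class = "tsne_gate_set")
}

#' Write / read a gate set as YAML
#' @param gate_set a [tsne_gate_set()].
#' @param path YAML file path.
#' @return `path` (write) or a `tsne_gate_set` (read).
#' @export
write_gate_set <- function(gate_set, path) {
  out <- list(drawn_on = gate_set$drawn_on,
              gates = lapply(gate_set$gates, function(g) {
                lapply(seq_len(nrow(g$vertices)),
                       function(i) as.numeric(g$vertices[i, ]))
              }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_gate_set
#' @export
read_gate_set <- function(path) {
  raw <- yaml::read_yaml(path)
  tsne_gate_set(raw$gates, drawn_on = raw$drawn_on %||% "CR")
}

#' Assign every cell to its containing gate
#'
#' Gates are transferred across data subsets unchanged: membership depends
#' only on coordinates and vertices, never on group labels. Cells outside
#' all polygons are labeled `"ungated"`; a cell inside two gates raises an
#' ambiguity error naming the overlapping pair (gates must be disjoint).
#'
#' @param matrix embedded expression matrix.
#' @param gate_set a [tsne_gate_set()].
#' @return character vector of gate labels, one per cell.
#' @export
assign_gate_membership <- function(matrix, gate_set) {
  stopifnot(inherits(gate_set, "tsne_gate_set"),
            all(c("tSNE1", "tSNE2") %in% names(matrix)))
  label <- rep("ungated", nrow(matrix))
  for (g in gate_set$gates) {
    inside <- point_in_polygon(matrix$tSNE1, matrix$tSNE2,
                               g$vertices[, 1], g$vertices[, 2])
    clash <- inside & label != "ungated"
    if (any(clash)) {
      stop_hspc(paste0("overlapping gates contain the same cell: '",
                       label[which(clash)[1]], "' and '", g$name, "'"),
                "hspcmap_gate_error")
    }
    label[inside] <- g$name
  }
  label
}

#' Five-number marker summary of one gate
#'
#' Summarizes the scaled intensities of every analysis marker within one
#' gate, separately per group (count, mean, median, quartiles, whiskers at
#' 1.5 IQR), together with the gate's CR/AD cell counts, the CR:AD ratio of
#' the within-group percentage distributions, and the phenotype assigned
#' from the pooled gate-level marker means.
#'
#' @param matrix embedded expression matrix.
#' @param membership gate labels from [assign_gate_membership()].
#' @param gate gate name.
#' @param thresholds scaled thresholds from [marker_thresholds()].
#' @return list: `stats` (marker x group data.frame), `n_cr`, `n_ad`,
#'   `pct_cr`, `pct_ad`, `ratio` (NA-flagged when the AD percentage is
#'   zero), `ad_dominated`, `cell_type`.
#' @export
summarize_gate <- function(matrix, membership, gate,
                           thresholds = marker_thresholds()) {
  inside <- membership == gate
  if (!any(inside)) {
    stop_hspc(paste0("gate '", gate, "' is empty"), "hspcmap_gate_error")
  }
  sub <- matrix[inside, , drop = FALSE]
  rows <- list()
  for (m in hspc_markers()) {
    for (grp in c("CR", "AD")) {
      v <- sub[[m]][sub$group == grp]
      if (length(v) == 0) {
        rows[[paste(m, grp)]] <- data.frame(
          marker = m, group = grp, n = 0L, mean = NA_real_,
          median = NA_real_, q1 = NA_real_, q3 = NA_real_,
          whisker_lo = NA_real_, whisker_hi = NA_real_)
        next
      }
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      rows[[paste(m, grp)]] <- data.frame(
        marker = m, group = grp, n = length(v), mean = mean(v),
        median = q[2], q1 = q[1], q3 = q[3],
        whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
        whisker_hi = max(v[v <= q[3] + 1.5 * iqr]))
    }
  }
  stats_df <- do.call(rbind, rows)
  rownames(stats_df) <- NULL
  n_cr_total <- sum(matrix$group == "CR")
  n_ad_total <- sum(matrix$group == "AD")
  n_cr <- sum(sub$group == "CR"); n_ad <- sum(sub$group == "AD")
  pct_cr <- if (n_cr_total > 0) 100 * n_cr / n_cr_total else 0
  pct_ad <- if (n_ad_total > 0) 100 * n_ad / n_ad_total else 0
  ratio <- if (pct_ad == 0) NA_real_ else pct_cr / pct_ad
  means <- vapply(hspc_markers(), function(m) mean(sub[[m]]), numeric(1))
  list(stats = stats_df, n_cr = n_cr, n_ad = n_ad,
       pct_cr = pct_cr, pct_ad = pct_ad, ratio = ratio,
       ad_dominated = !is.na(ratio) && ratio < 1,
       cell_type = classify_hspc(means, thresholds))
}

#' Assign an HSPC phenotype from gate-level marker means
#'
#' Implements the antigen-combination decision table on the scaled marker
#' means of one gate: CD38- gates are HSC/MPP (CD45RA-) or CLP (CD45RA+);
#' CD38+ CD45RA- gates are MEP (CD123-), CMP (CD123 low, i.e. weakly
#' positive) or Other (CD123 bright); CD38+ CD45RA+ gates are GMP when
#' CD123 is positive and Other otherwise. Every combination maps to exactly
#' one label. A CD34 mean below threshold triggers an inconsistency warning
#' (cells are pre-gated CD34+) but still yields a label.
#'
#' @param means named numeric vector of scaled marker means; must contain
#'   CD34, CD38, CD45RA and CD123.
#' @param thresholds scaled thresholds from [marker_thresholds()].
#' @return one of `"HSC/MPP"`, `"CLP"`, `"CMP"`, `"MEP"`, `"GMP"`,
#'   `"Other"`.
#' @export
classify_hspc <- function(means, thresholds = marker_thresholds()) {
  need <- c("CD34", "CD38", "CD45RA", "CD123")
  if (!all(need %in% names(means)) || any(is.na(means[need]))) {
    stop_hspc("means for CD34, CD38, CD45RA and CD123 are required",
              "hspcmap_argument_error")
  }
  pos <- thresholds$positive
  if (means[["CD34"]] <= pos[["CD34"]]) {
    warning("gate-level CD34 mean below threshold despite CD34+ pre-gating",
            call. = FALSE)
  }
  cd38 <- means[["CD38"]] > pos[["CD38"]]
  cd45ra <- means[["CD45RA"]] > pos[["CD45RA"]]
  cd123 <- means[["CD123"]]
  if (!cd38) {
    if (cd45ra) "CLP" else "HSC/MPP"
  } else if (!cd45ra) {
    if (cd123 <= pos[["CD123"]]) "MEP"
    else if (cd123 <= thresholds$cd123_low_upper) "CMP"
    else "Other"
  } else {
    if (cd123 > pos[["CD123"]]) "GMP" else "Other"
  }
}

#' Summary table over all gates
#'
#' @param matrix embedded expression matrix.
#' @param membership gate labels.
#' @param gate_set a [tsne_gate_set()].
#' @param thresholds scaled thresholds.
#' @return data.frame with one row per gate: counts, within-group
#'   percentages, CR:AD ratio and assigned cell type. Empty gates are
#'   flagged and excluded.
#' @export
summarize_gates <- function(matrix, membership, gate_set,
                            thresholds = marker_thresholds()) {
  rows <- lapply(names(gate_set$gates), function(g) {
    if (!any(membership == g)) {
      return(data.frame(gate = g, n = 0L, n_cr = 0L, n_ad = 0L,
                        pct_cr = 0, pct_ad = 0, ratio = NA_real_,
                        cell_type = NA_character_, empty = TRUE))
    }
    s <- summarize_gate(matrix, membership, g, thresholds)
    data.frame(gate = g, n = s$n_cr + s$n_ad, n_cr = s$n_cr, n_ad = s$n_ad,
               pct_cr = s$pct_cr, pct_ad = s$pct_ad, ratio = s$ratio,
               cell_type = s$cell_type, empty = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group composition by assigned cell type
#'
#' Percentage of gated cells of each phenotype within each group (gate
#' types propagated to member cells); percentages sum to 100 within each
#' group, the unallocated phenotype included as `Other`.
#'
#' @param matrix embedded expression matrix.
#' @param membership gate labels.
#' @param gate_summary output of [summarize_gates()].
#' @return data.frame: group, cell_type, n, percent.
#' @export
composition_report <- function(matrix, membership, gate_summary) {
  types <- stats::setNames(gate_summary$cell_type, gate_summary$gate)
  gated <- membership != "ungated"
  cell_type <- types[membership[gated]]
  grp <- matrix$group[gated]
  rows <- list()
  for (g in unique(grp)) {
    tab <- table(cell_type[grp == g])
    tot <- sum(tab)
    for (ct in names(tab)) {
      rows[[paste(g, ct)]] <- data.frame(
        group = g, cell_type = ct, n = as.integer(tab[[ct]]),
        percent = 100 * tab[[ct]] / tot)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# TRUE when two convex polygons overlap: vertex containment either way or
# any pair of crossing edges.
polygons_overlap <- function(va, vb) {
  if (any(point_in_polygon(va[, 1], va[, 2], vb[, 1], vb[, 2])) ||
      any(point_in_polygon(vb[, 1], vb[, 2], va[, 1], va[, 2]))) {
    return(TRUE)
  }
  ea <- cbind(va, rbind(va[-1, , drop = FALSE], va[1, , drop = FALSE]))
  eb <- cbind(vb, rbind(vb[-1, , drop = FALSE], vb[1, , drop = FALSE]))
  orient <- function(seg, px, py) {
    sign((seg[3] - seg[1]) * (py - seg[2]) - (seg[4] - seg[2]) * (px - seg[1]))
  }
  crosses <- function(a, b) {
    orient(b, a[1], a[2]) != orient(b, a[3], a[4]) &&
      orient(a, b[1], b[2]) != orient(a, b[3], b[4])
  }
  for (i in seq_len(nrow(ea))) {
    for (j in seq_len(nrow(eb))) {
      if (crosses(ea[i, ], eb[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' Propose gates from local density maxima (convenience, non-canonical)
#'
#' A rough automatic stand-in for manually drawn density-based gates:
#' above-floor bins of a smoothed density picture are assigned to their
#' local maximum by steepest-ascent hill climbing on the 8-neighborhood,
#' and each basin becomes the convex hull of its bins. Intended for
#' synthetic reference embeddings with well-separated islands; hulls of
#' adjacent basins can overlap, in which case the smaller basin is dropped.
#'
#' @param picture smoothed density matrix from [density_matrix()].
#' @param grid the matching [density_grid()].
#' @param floor_frac bins below `floor_frac * max(picture)` are ungated.
#' @param min_bins basins smaller than this are discarded.
#' @return a [tsne_gate_set()] with provenance `"density-peaks"`.
#' @export
propose_gates <- function(picture, grid, floor_frac = 0.02, min_bins = 4) {
  nb <- grid$n_bins
  floor_v <- floor_frac * max(picture)
  lab <- matrix(0L, nb, nb)
  peak_of <- function(i, j) {
    repeat {
      best_i <- i; best_j <- j; best_v <- picture[i, j]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nb && jj >= 1 && jj <= nb &&
            picture[ii, jj] > best_v) {
          best_v <- picture[ii, jj]; best_i <- ii; best_j <- jj
        }
      }
      if (best_i == i && best_j == j) return(c(i, j))
      i <- best_i; j <- best_j
    }
  }
  peaks <- list()
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (picture[i, j] <= floor_v) next
    p <- peak_of(i, j)
    key <- paste(p, collapse = ",")
    if (is.null(peaks[[key]])) peaks[[key]] <- length(peaks) + 1L
    lab[i, j] <- peaks[[key]]
  }
  xc <- (grid$xbreaks[-1] + grid$xbreaks[-(nb + 1)]) / 2
  yc <- (grid$ybreaks[-1] + grid$ybreaks[-(nb + 1)]) / 2
  dx <- diff(grid$xbreaks[1:2]) / 2; dy <- diff(grid$ybreaks[1:2]) / 2
  gates <- list()
  for (lv in sort(unique(lab[lab > 0]))) {
    idx <- which(lab == lv, arr.ind = TRUE)
    if (nrow(idx) < min_bins) next
    px <- c(xc[idx[, 1]] - dx, xc[idx[, 1]] + dx,
            xc[idx[, 1]] - dx, xc[idx[, 1]] + dx)
    py <- c(yc[idx[, 2]] - dy, yc[idx[, 2]] - dy,
            yc[idx[, 2]] + dy, yc[idx[, 2]] + dy)
    hull <- grDevices::chull(px, py)
    gates[[sprintf("gate %d", length(gates) + 1L)]] <-
      cbind(px[hull], py[hull])
  }
  if (length(gates) == 0) {
    stop_hspc("no density basin exceeds the floor", "hspcmap_gate_error")
  }
  # drop smaller basins whose hull overlaps an earlier (larger) one
  keep <- rep(TRUE, length(gates))
  sizes <- vapply(gates, nrow, integer(1))
  ord <- order(-sizes)
  centers <- lapply(gates, function(v) colMeans(v))
  for (a_i in seq_along(ord)) {
    for (b_i in seq_len(a_i - 1)) {
      a <- ord[a_i]; b <- ord[b_i]
      if (!keep[b]) next
      if (polygons_overlap(gates[[a]], gates[[b]])) keep[a] <- FALSE
    }
  }
  tsne_gate_set(gates[keep], drawn_on = "density-peaks")
}
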