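# Six-step pre-gating: scatter gate, CD45/SSC gate, doublet exclusion,
# viability, gate of interest, CD34 selection — then the per-patient cap.

#' Construct a polygon gate
#'
#' @param name gate label.
#' @param x_channel,y_channel channel names defining the gating plane.
#' @param vertices numeric matrix (or list of length-2 vectors) of ordered
#'   polygon vertices; the polygon is implicitly closed and must be simple
#'   with at least three vertices.
#' @return object of class `polygon_gate`.
#' @export
polygon_gate <- function(name, x_channel, y_channel, vertices) {
  if (is.list(vertices)) {
    vertices <- do.call(rbind, lapply(vertices, as.numeric))
  }
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2) {
    stop_hspc("a polygon gate needs at least 3 (x, y) vertices",
              "hspcmap_gate_error")
  }
  if (!is_simple_polygon(vertices[, 1], vertices[, 2])) {
    stop_hspc(paste0("gate '", name, "' is self-intersecting"),
              "hspcmap_gate_error")
  }
  structure(list(name = name, x_channel = x_channel, y_channel = y_channel,
                 vertices = unname(vertices)),
            class = "polygon_gate")
}

#' Apply a polygon gate to an event table
#'
#' Retains exactly the events whose (x, y) coordinates lie inside or on the
#' boundary of the gate polygon (even-odd rule).
#'
#' @param table CellEventTable.
#' @param gate a [polygon_gate()].
#' @return the gated CellEventTable.
#' @export
apply_polygon_gate <- function(table, gate) {
  stopifnot(inherits(gate, "polygon_gate"))
  for (ch in c(gate$x_channel, gate$y_channel)) {
    if (!ch %in% names(table)) {
      stop_hspc(paste0("gate channel '", ch, "' missing from event table"),
                "hspcmap_channel_error")
    }
  }
  keep <- point_in_polygon(table[[gate$x_channel]], table[[gate$y_channel]],
                           gate$vertices[, 1], gate$vertices[, 2])
  table[keep, , drop = FALSE]
}

#' Exclude doublets by the FSC-A/FSC-H ratio
#'
#' Retains events whose FSC-A lies within `(1 +/- max_deviation) * FSC-H`,
#' the standard ratio convention for singlet discrimination. Events with
#' nonpositive FSC-H are dropped and counted in the `n_nonpositive_fsch`
#' attribute of the result.
#'
#' @param table CellEventTable with FSC-A and FSC-H channels.
#' @param max_deviation allowed fractional deviation of the ratio from 1.
#' @return the filtered CellEventTable.
#' @export
exclude_doublets <- function(table, max_deviation = 0.3) {
  for (ch in c("FSC-A", "FSC-H")) {
    if (!ch %in% names(table)) {
      stop_hspc(paste0("channel '", ch, "' missing"), "hspcmap_channel_error")
    }
  }
  h <- table[["FSC-H"]]
  valid <- h > 0
  ratio <- table[["FSC-A"]] / h
  keep <- valid & ratio >= 1 - max_deviation & ratio <= 1 + max_deviation
  out <- table[keep, , drop = FALSE]
  attr(out, "n_nonpositive_fsch") <- sum(!valid)
  out
}

#' Select viable events
#'
#' Retains events with viability-dye intensity strictly below the dead
#' threshold; events exactly at the threshold are conservatively treated as
#' dead.
#'
#' @param table CellEventTable with a Viability channel.
#' @param threshold dead threshold on the raw viability intensity.
#' @return the filtered CellEventTable.
#' @export
select_viable <- function(table, threshold = default_thresholds()$viability_dead) {
  if (!"Viability" %in% names(table)) {
    stop_hspc("Viability channel missing", "hspcmap_channel_error")
  }
  table[table[["Viability"]] < threshold, , drop = FALSE]
}

#' Gate of interest and CD34 selection
#'
#' Applies the GOI polygon (CD34 vs SSC-A by default, excluding the
#' high-side-scatter granulocyte population) and then retains events with
#' CD34 intensity strictly above the threshold.
#'
#' @param table CellEventTable.
#' @param goi_gate a [polygon_gate()].
#' @param cd34_threshold raw CD34 positivity cutoff.
#' @return the filtered CellEventTable.
#' @export
select_cd34_positive <- function(table, goi_gate,
                                 cd34_threshold = default_thresholds()$cd34) {
  out <- apply_polygon_gate(table, goi_gate)
  out[out[["CD34"]] > cd34_threshold, , drop = FALSE]
}

#' Cap the number of cells per patient
#'
#' Patients with more than `cap` events contribute a uniformly random
#' subset of exactly `cap` events (reproducible under `seed`, original
#' event order preserved); smaller tables pass through unchanged.
#'
#' @param table CellEventTable.
#' @param cap maximum number of events (>= 1).
#' @param seed integer seed for the subsampling.
#' @return the (possibly subsampled) CellEventTable.
#' @export
cap_cells <- function(table, cap = 1000, seed = 1L) {
  stopifnot(cap >= 1)
  if (nrow(table) <= cap) return(table)
  idx <- sort(with_seed(seed, sample.int(nrow(table), cap)))
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

gate_from_config <- function(cfg_gate, name) {
  polygon_gate(name, cfg_gate$x, cfg_gate$y, cfg_gate$vertices)
}

#' Run the full six-step pre-gating sequence
#'
#' Steps, in fixed order: (1) FSC vs SSC gate, (2) CD45 vs SSC gate,
#' (3) doublet exclusion, (4) viability check, (5) gate of interest
#' excluding granulocytes, (6) CD34+ selection — followed by the random
#' per-patient cell cap. Intermediate counts are returned as a gate
#' sequence report whose counts are non-increasing by construction.
#'
#' @param table CellEventTable of one patient.
#' @param config configuration list (see [default_config()]).
#' @param seed seed for the cell cap subsampling.
#' @return list with `events` (the gated, capped CellEventTable) and
#'   `report` (data.frame: step, name, n_in, n_out).
#' @export
pregate <- function(table, config = default_config(), seed = 1L) {
  steps <- list()
  note <- function(step, name, n_in, n_out) {
    steps[[length(steps) + 1]] <<- data.frame(
      step = step, name = name, n_in = n_in, n_out = n_out)
  }
  cur <- table
  g1 <- gate_from_config(config$gates$fsc_ssc, "FSC vs SSC")
  nxt <- apply_polygon_gate(cur, g1); note(1, g1$name, nrow(cur), nrow(nxt)); cur <- nxt
  g2 <- gate_from_config(config$gates$cd45_ssc, "CD45 vs SSC")
  nxt <- apply_polygon_gate(cur, g2); note(2, g2$name, nrow(cur), nrow(nxt)); cur <- nxt
  nxt <- exclude_doublets(cur, config$doublet_max_deviation)
  note(3, "doublet exclusion", nrow(cur), nrow(nxt)); cur <- nxt
  nxt <- select_viable(cur, config$thresholds$viability_dead)
  note(4, "viability", nrow(cur), nrow(nxt)); cur <- nxt
  goi <- gate_from_config(config$gates$goi, "gate of interest")
  nxt <- apply_polygon_gate(cur, goi); note(5, goi$name, nrow(cur), nrow(nxt)); cur <- nxt
  nxt <- cur[cur[["CD34"]] > config$thresholds$cd34, , drop = FALSE]
  note(6, "CD34+ selection", nrow(cur), nrow(nxt)); cur <- nxt
  nxt <- cap_cells(cur, config$cell_cap, seed)
  note(7, "cell cap", nrow(cur), nrow(nxt)); cur <- nxt
  rownames(cur) <- NULL
  list(events = cur, report = do.call(rbind, steps))
}
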