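unit_square <- function() polygon_gate("sq", "FSC-A", "SSC-A",
                                       rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))

ev_tab <- function(x, y) data.frame(`FSC-A` = x, `SSC-A` = y,
                                    check.names = FALSE)

test_that("polygon gating follows the even-odd rule with inclusive boundary", {
  g <- unit_square()
  tab <- ev_tab(c(0.5, 2, 1, 0, 0.5), c(0.5, 2, 0.5, 0, 1))
  kept <- apply_polygon_gate(tab, g)
  # interior kept, exterior dropped, edges and vertices kept
  expect_equal(kept$`FSC-A`, c(0.5, 1, 0, 0.5))
  expect_error(apply_polygon_gate(data.frame(a = 1), g),
               class = "hspcmap_channel_error")
  expect_error(polygon_gate("bad", "x", "y", rbind(c(0, 0), c(1, 1))),
               class = "hspcmap_gate_error")
  expect_error(polygon_gate("bowtie", "x", "y",
                            rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               class = "hspcmap_gate_error")
})

test_that("gated fraction matches the polygon's area (Monte Carlo)", {
  set.seed(31)
  tab <- ev_tab(runif(1e4, 0, 2), runif(1e4, 0, 2))
  kept <- apply_polygon_gate(tab, unit_square())
  expect_lt(abs(nrow(kept) / 1e4 - 0.25), 0.02)
})

test_that("doublet exclusion removes injected doublets, keeps singlets", {
  tab <- data.frame(`FSC-A` = c(100, 200, 95, 50), `FSC-H` = c(100, 100, 100, -1),
                    check.names = FALSE)
  out <- exclude_doublets(tab, 0.3)
  expect_equal(out$`FSC-A`, c(100, 95))
  expect_equal(attr(out, "n_nonpositive_fsch"), 1)

  ev <- sample_subtype_events(default_profiles()$GMP, 2e4, seed = 5,
                              doublet_fraction = 0.05)
  out2 <- exclude_doublets(ev, 0.3)
  removed <- !seq_len(nrow(ev)) %in% which(
    ev$`FSC-A` / ev$`FSC-H` >= 0.7 & ev$`FSC-A` / ev$`FSC-H` <= 1.3)
  expect_gte(mean(removed[ev$.doublet]), 0.95)       # doublets removed
  expect_lte(mean(removed[!ev$.doublet]), 0.05)      # singlets kept
  expect_gte(mean(out2$.doublet == FALSE), 0.99)
})

test_that("viability gate drops dead cells with a strict-below convention", {
  thr <- default_thresholds()$viability_dead
  tab <- data.frame(Viability = c(thr, thr - 1, thr + 1))
  expect_equal(select_viable(tab, thr)$Viability, thr - 1)

  ev <- sample_subtype_events(default_profiles()$GMP, 1e4, seed = 6,
                              dead_fraction = 0.05)
  out <- select_viable(ev, thr)
  expect_gte(1 - sum(out$.dead) / sum(ev$.dead), 0.95)
  live <- sample_subtype_events(default_profiles()$GMP, 1000, seed = 7)
  expect_equal(nrow(select_viable(live, thr)), 1000)
})

test_that("GOI and CD34 selection keep blasts and reject granulocytes", {
  cfg <- default_config()
  goi <- hspcmap:::gate_from_config(cfg$gates$goi, "goi")
  blasts <- sample_subtype_events(default_profiles()$LEUK_BLAST, 5000, seed = 8)
  expect_gte(nrow(select_cd34_positive(blasts, goi)) / 5000, 0.95)

  gran <- sample_subtype_events(hspcmap:::background_profiles()$GRAN, 5000,
                                seed = 9)
  expect_lte(nrow(apply_polygon_gate(gran, goi)) / 5000, 0.05)

  low <- data.frame(CD34 = c(10, 1000), `SSC-A` = c(100, 100),
                    check.names = FALSE)
  expect_equal(select_cd34_positive(low, goi, 500)$CD34, 1000)
})

test_that("cell cap subsamples reproducibly and only above the cap", {
  ev <- sample_subtype_events(default_profiles()$GMP, 5000, seed = 10)
  capped <- cap_cells(ev, 1000, seed = 3)
  expect_equal(nrow(capped), 1000)
  expect_identical(capped, cap_cells(ev, 1000, seed = 3))
  small <- ev[1:129, ]
  expect_identical(cap_cells(small, 1000, seed = 3), small)
})

test_that("the six-step sequence is monotone and recovers CD34+ cells", {
  spec <- small_spec(n_cr = 1, n_ad = 1, cells = c(8000, 8000))
  tab <- generate_patient(spec, "CR", "p", seed = 12)
  cfg <- default_config()
  cfg$cell_cap <- 1e9   # inspect recovery before capping
  res <- pregate(tab, cfg)
  expect_true(all(res$report$n_out <= res$report$n_in))
  expect_true(all(diff(res$report$n_out) <= 0))
  expect_identical(res$report$n_in[-1], res$report$n_out[-nrow(res$report)])

  truth_pos <- tab$.subtype %in% hspc_subtypes() & !tab$.doublet & !tab$.dead
  kept_key <- paste(res$events$CD34, res$events$`SSC-A`)
  all_key <- paste(tab$CD34, tab$`SSC-A`)
  kept <- all_key %in% kept_key
  sens <- mean(kept[truth_pos])
  spec_ <- 1 - mean(kept[!truth_pos])
  expect_gte(sens, 0.90)
  expect_gte(spec_, 0.90)
})
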