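test_that("gate membership is containment-based and transfer-invariant", {
  emb <- toy_embedding(seed = 71)
  gates <- toy_gates()
  membership <- assign_gate_membership(emb, gates)
  # cells are gated by their generating cluster's square
  gated <- membership != "ungated"
  expect_gt(mean(gated), 0.95)
  expect_true(all(membership[gated] == emb$.subtype[gated]))
  # transfer: membership of a subset equals the subset of the membership
  ad <- emb$group == "AD"
  expect_identical(assign_gate_membership(emb[ad, ], gates), membership[ad])
})

test_that("overlapping gates raise an ambiguity error naming the pair", {
  emb <- toy_embedding(seed = 72)
  overlapping <- tsne_gate_set(list(
    g1 = rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5)),
    g2 = rbind(c(-1, -1), c(6, -1), c(6, 6), c(-1, 6))))
  err <- expect_error(assign_gate_membership(emb, overlapping),
                      class = "hspcmap_gate_error")
  expect_match(conditionMessage(err), "g1")
  expect_match(conditionMessage(err), "g2")
  expect_error(tsne_gate_set(list(a = rbind(c(0, 0), c(1, 1), c(0, 1)),
                                  a = rbind(c(2, 2), c(3, 3), c(2, 3)))),
               class = "hspcmap_gate_error")
})

test_that("gate sets round-trip through YAML", {
  gates <- toy_gates()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_gate_set(gates, f)
  back <- read_gate_set(f)
  expect_equal(names(back$gates), names(gates$gates))
  for (nm in names(gates$gates)) {
    expect_equal(back$gates[[nm]]$vertices, gates$gates[[nm]]$vertices)
  }
})

test_that("gate summaries report five-number statistics and group balance", {
  emb <- toy_embedding(seed = 73, n_per_patient = 400)
  gates <- toy_gates()
  membership <- assign_gate_membership(emb, gates)
  s <- summarize_gate(emb, membership, "GMP")
  expect_equal(s$n_cr + s$n_ad, sum(membership == "GMP"))
  expect_identical(s$cell_type, "GMP")

  # marker means of a pure-profile gate match the generating profile
  prof <- default_profiles()$GMP
  gmp_rows <- membership == "GMP"
  for (m in hspc_markers()) {
    v <- emb[[m]][gmp_rows]
    mu_expected <- mean(biexp_transform(
      sample_subtype_events(prof, 2e4, seed = 74)[[m]], 150))
    expect_lt(abs(s$stats$mean[s$stats$marker == m & s$stats$group == "CR"] -
                    mu_expected), 4 * sd(v) / sqrt(s$n_cr), label = m)
  }

  # degenerate gate: identical cells have zero interquartile range
  const <- emb[rep(which(gmp_rows)[1], 10), ]
  mem_c <- rep("only", 10)
  sc <- summarize_gate(const, mem_c, "only")
  expect_true(all(sc$stats$q3 - sc$stats$q1 == 0, na.rm = TRUE))

  expect_error(summarize_gate(emb, membership, "no-such-gate"),
               class = "hspcmap_gate_error")
})

test_that("AD-dominated gates are flagged through the percentage ratio", {
  emb <- toy_embedding(seed = 75, n_per_patient = 300,
                       ad_mixture = ad_mixture_at_effect(1))
  membership <- assign_gate_membership(emb, toy_gates())
  s <- summarize_gate(emb, membership, "LEUK_BLAST")
  expect_true(s$ad_dominated)
  expect_lt(s$ratio, 1)
  s2 <- summarize_gate(emb, membership, "CMP")
  expect_false(s2$ad_dominated)
})

test_that("the decision table is total and matches the named combinations", {
  th <- marker_thresholds()
  hi <- function(m) th$positive[[m]] + 1
  lo <- function(m) th$positive[[m]] - 1
  mk <- function(cd38, cd45ra, cd123) {
    c(CD34 = hi("CD34"), CD38 = cd38, CD45RA = cd45ra, CD123 = cd123)
  }
  low123 <- (th$positive[["CD123"]] + th$cd123_low_upper) / 2
  bright123 <- th$cd123_low_upper + 1

  expect_identical(classify_hspc(mk(lo("CD38"), lo("CD45RA"), lo("CD123"))),
                   "HSC/MPP")
  expect_identical(classify_hspc(mk(lo("CD38"), hi("CD45RA"), lo("CD123"))),
                   "CLP")
  expect_identical(classify_hspc(mk(hi("CD38"), lo("CD45RA"), low123)),
                   "CMP")
  expect_identical(classify_hspc(mk(hi("CD38"), lo("CD45RA"), lo("CD123"))),
                   "MEP")
  expect_identical(classify_hspc(mk(hi("CD38"), hi("CD45RA"), bright123)),
                   "GMP")
  expect_identical(classify_hspc(mk(hi("CD38"), hi("CD45RA"), lo("CD123"))),
                   "Other")

  # totality: every +/-/low combination yields exactly one known label
  labels <- character(0)
  for (cd38 in c(lo("CD38"), hi("CD38"))) {
    for (cd45ra in c(lo("CD45RA"), hi("CD45RA"))) {
      for (cd123 in c(lo("CD123"), low123, bright123)) {
        lab <- classify_hspc(mk(cd38, cd45ra, cd123))
        expect_length(lab, 1)
        labels <- c(labels, lab)
      }
    }
  }
  expect_true(all(labels %in% c("HSC/MPP", "CLP", "CMP", "MEP", "GMP",
                                "Other")))
  expect_setequal(unique(labels), c("HSC/MPP", "CLP", "CMP", "MEP", "GMP",
                                    "Other"))

  expect_warning(classify_hspc(c(CD34 = 0, CD38 = hi("CD38"),
                                 CD45RA = lo("CD45RA"),
                                 CD123 = lo("CD123"))),
                 "CD34")
  expect_error(classify_hspc(c(CD34 = 1)), class = "hspcmap_argument_error")
})

test_that("composition percentages sum to 100 and recover the mixture", {
  mix <- c(GMP = 0.45, CMP = 0.25, MEP = 0.20, HSC_MPP = 0.10)
  emb <- toy_embedding(seed = 76, n_per_patient = 2000, n_cr = 3, n_ad = 2,
                       cr_mixture = mix, ad_mixture = mix)
  gates <- toy_gates()
  membership <- assign_gate_membership(emb, gates)
  gs <- summarize_gates(emb, membership, gates)
  comp <- composition_report(emb, membership, gs)
  for (g in unique(comp$group)) {
    expect_equal(sum(comp$percent[comp$group == g]), 100, tolerance = 0.01)
  }
  gmp_cr <- comp$percent[comp$group == "CR" & comp$cell_type == "GMP"]
  expect_lt(abs(gmp_cr - 45), 2)

  # single-phenotype cohort reports 100% of that phenotype
  solo <- toy_embedding(seed = 77, n_per_patient = 100, n_cr = 2, n_ad = 1,
                        cr_mixture = c(HSC_MPP = 1),
                        ad_mixture = c(HSC_MPP = 1))
  mem_s <- assign_gate_membership(solo, gates)
  gs_s <- summarize_gates(solo, mem_s, gates)
  comp_s <- composition_report(solo, mem_s, gs_s)
  expect_true(all(comp_s$cell_type == "HSC/MPP"))
  expect_true(all(abs(comp_s$percent - 100) < 1e-9))
})

test_that("density-peak gate proposal finds separated islands", {
  emb <- toy_embedding(seed = 78, n_per_patient = 600,
                       cr_mixture = c(HSC_MPP = 0.4, GMP = 0.4, OTHER = 0.2),
                       ad_mixture = c(HSC_MPP = 0.4, GMP = 0.4, OTHER = 0.2))
  grid <- density_grid(emb, n_bins = 64)
  pic <- density_matrix(emb, grid, smooth_sigma = 1.5)
  gset <- propose_gates(pic, grid)
  expect_gte(length(gset$gates), 3)
  membership <- assign_gate_membership(emb, gset)  # disjoint by construction
  gated <- membership != "ungated"
  expect_gt(mean(gated), 0.8)
  # each proposed gate is dominated by one true population
  for (g in names(gset$gates)) {
    tab <- table(emb$.subtype[membership == g])
    expect_gt(max(tab) / sum(tab), 0.9)
  }
})
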