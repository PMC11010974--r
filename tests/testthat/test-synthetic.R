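test_that("subtype event sampling honors counts, channels and edge cases", {
  gmp <- default_profiles()$GMP
  empty <- sample_subtype_events(gmp, 0)
  expect_equal(nrow(empty), 0)
  expect_true(all(hspc_channels() %in% names(empty)))
  expect_error(sample_subtype_events(gmp, -1), class = "hspcmap_argument_error")

  flat <- subtype_profile("GMP", gmp$marker_means, marker_cvs = 0)
  ev <- sample_subtype_events(flat, 1000, seed = 3)
  for (ch in hspc_channels()) {
    expect_true(all(ev[[ch]] == gmp$marker_means[[ch]]), info = ch)
  }
})

test_that("HSC/MPP events are CD38-negative at the generator's threshold", {
  ev <- sample_subtype_events(default_profiles()$HSC_MPP, 1e4, seed = 7)
  frac_neg <- mean(ev$CD38 < default_thresholds()$positive[["CD38"]])
  expect_gte(frac_neg, 0.95)
})

test_that("intended positivity separates from thresholds for all profiles", {
  th <- default_thresholds()
  for (p in default_profiles()) {
    ev <- sample_subtype_events(p, 4000, seed = 17)
    for (m in names(p$positivity)) {
      frac_pos <- mean(ev[[m]] > th$positive[[m]])
      if (p$positivity[[m]] == "+") {
        expect_gte(frac_pos, 0.95)
      } else if (p$positivity[[m]] == "-") {
        expect_lte(frac_pos, 0.05)
      } else {  # low: above negative cutoff, below the low upper bound
        expect_gte(mean(ev[[m]] > th$positive[[m]] &
                          ev[[m]] <= th$cd123_low_upper), 0.75)
      }
    }
  }
})

test_that("patient generation follows the mixture", {
  spec <- cohort_spec(n_cr = 2, n_ad = 2, cells_per_patient = c(500, 500),
                      cr_mixture = c(GMP = 1), cd34_fraction = 1,
                      doublet_fraction = 0, dead_fraction = 0)
  tab <- generate_patient(spec, "CR", "p1", seed = 1)
  expect_equal(nrow(tab), 500)
  expect_true(all(tab$.subtype == "GMP"))
  expect_true(all(tab$patient_id == "p1" & tab$group == "CR"))

  mix <- c(GMP = 0.45, CMP = 0.25, MEP = 0.3)
  spec2 <- cohort_spec(cr_mixture = mix, cd34_fraction = 1,
                       cells_per_patient = c(1e5, 1e5),
                       doublet_fraction = 0, dead_fraction = 0)
  tab2 <- generate_patient(spec2, "CR", "p2", seed = 2, n_events = 1e5)
  expect_lt(abs(mean(tab2$.subtype == "GMP") - 0.45), 0.01)

  expect_error(generate_patient(spec, "XX", "p", 1),
               class = "hspcmap_argument_error")
})

test_that("mixture recovery is binomial-consistent at large n", {
  mix <- default_cr_mixture()
  spec <- cohort_spec(cr_mixture = mix, cd34_fraction = 1,
                      doublet_fraction = 0, dead_fraction = 0)
  tab <- generate_patient(spec, "CR", "p", seed = 9, n_events = 1e5)
  for (s in names(mix)) {
    p <- mix[[s]]
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(mean(tab$.subtype == s) - p), 3 * se + 1e-12, label = s)
  }
})

test_that("cohort generation is deterministic and respects the spec", {
  spec <- small_spec(n_cr = 12, n_ad = 9, cells = c(129, 2000), seed = 4)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_length(a$tables, 21)
  expect_true(all(a$metadata$n_events >= 129 & a$metadata$n_events <= 2000))
  expect_identical(generate_patient(spec, "AD", "x", 77),
                   generate_patient(spec, "AD", "x", 77))
})

test_that("AD enrichment shifts pooled CD34+ marker means in the expected direction", {
  spec <- cohort_spec(cd34_fraction = 1, doublet_fraction = 0,
                      dead_fraction = 0)
  cr <- generate_patient(spec, "CR", "cr", seed = 21, n_events = 2e4)
  ad <- generate_patient(spec, "AD", "ad", seed = 22, n_events = 2e4)
  expect_lt(mean(ad$CD38), mean(cr$CD38))
  expect_gt(mean(ad$CD45RA), mean(cr$CD45RA))
  expect_gt(mean(ad$CD123), mean(cr$CD123))
  expect_gt(mean(ad$`PD-L1`), mean(cr$`PD-L1`))
})

test_that("spec validation rejects malformed mixtures and counts", {
  expect_error(cohort_spec(cr_mixture = c(GMP = 0.7, CMP = 0.2)),
               class = "hspcmap_spec_error")
  expect_error(cohort_spec(cr_mixture = c(GMP = 1.2, CMP = -0.2)),
               class = "hspcmap_spec_error")
  expect_error(cohort_spec(n_cr = 1, n_ad = 0), class = "hspcmap_spec_error")
  expect_error(cohort_spec(cells_per_patient = c(0, 10)),
               class = "hspcmap_spec_error")
})
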