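# Leave-one-out classification on constructed embeddings (no t-SNE needed:
# the protocol only consumes coordinates and labels) plus one real embedded
# cohort from the shared fixture.

blob_embedding <- function(n_cr = 12, n_ad = 9, cells = 150, sep = 10,
                           seed = 81, overlap = 0) {
  set.seed(seed)
  mk <- function(id, grp) {
    ctr <- if (grp == "CR") c(0, 0) else c(sep, sep)
    # `overlap` mixes a fraction of the other group's location in
    other <- c(sep, sep) - ctr
    flip <- runif(cells) < overlap
    base <- t(vapply(flip, function(f) if (f) other else ctr, numeric(2)))
    data.frame(tSNE1 = base[, 1] + rnorm(cells),
               tSNE2 = base[, 2] + rnorm(cells),
               patient_id = id, group = grp, stringsAsFactors = FALSE)
  }
  tabs <- c(lapply(seq_len(n_cr), function(i) mk(sprintf("CR%02d", i), "CR")),
            lapply(seq_len(n_ad), function(i) mk(sprintf("AD%02d", i), "AD")))
  do.call(rbind, tabs)
}

test_that("reference pictures respect exclusion and reconstruct the whole", {
  emb <- blob_embedding(n_cr = 4, n_ad = 3, seed = 82)
  grid <- density_grid(emb, n_bins = 64)
  full <- build_reference_pictures(emb, grid, smooth_sigma = 0)
  expect_equal(sum(full$cr), sum(emb$group == "CR"))
  expect_equal(sum(full$ad), sum(emb$group == "AD"))

  held <- "CR02"
  refs <- build_reference_pictures(emb, grid, held, smooth_sigma = 0)
  n_held <- sum(emb$patient_id == held)
  expect_equal(sum(full$cr) - sum(refs$cr), n_held)
  expect_identical(as.vector(refs$ad), as.vector(full$ad))

  own <- density_matrix(emb[emb$patient_id == held, ], grid)
  combined <- density_matrix(emb, grid)
  expect_equal(as.vector(refs$ad + refs$cr + own), as.vector(combined),
               tolerance = 1e-12)

  solo <- emb[emb$group == "AD" | emb$patient_id == held, ]
  expect_error(build_reference_pictures(solo, grid, held),
               class = "hspcmap_protocol_error")
})

test_that("the call rule follows the sign of the r difference, ties abstain", {
  emb <- blob_embedding(n_cr = 3, n_ad = 3, seed = 83)
  grid <- density_grid(emb, n_bins = 64)
  rec <- loo_classify(emb, "CR01", grid)
  expect_gt(rec$r_vs_sum_cr, rec$r_vs_sum_ad)   # e.g. 0.46 vs 0.17 -> CR
  expect_identical(rec$call, "CR")
  rec_ad <- loo_classify(emb, "AD02", grid)
  expect_identical(rec_ad$call, "AD")

  # exact tie: AD reference constructed as exactly twice the CR reference
  set.seed(84)
  pat <- data.frame(tSNE1 = rnorm(100), tSNE2 = rnorm(100))
  tie <- rbind(
    cbind(pat, patient_id = "N", group = "CR"),
    cbind(pat + 5, patient_id = "CRref", group = "CR"),
    cbind(rbind(pat + 5, pat + 5), patient_id = "ADref", group = "AD"))
  g2 <- density_grid(tie, n_bins = 32)
  rec_tie <- loo_classify(tie, "N", g2, smooth_sigma = 0)
  expect_equal(rec_tie$r_vs_sum_cr, rec_tie$r_vs_sum_ad)
  expect_identical(rec_tie$call, "unclassified")

  expect_error(loo_classify(emb, "nobody", grid),
               class = "hspcmap_protocol_error")
})

test_that("cohort-level table yields one record per sample plus reference r", {
  emb <- blob_embedding(n_cr = 12, n_ad = 9, seed = 85)
  ct <- classification_table(emb)
  expect_equal(nrow(ct$records), 21)
  expect_true(all(ct$records$call == ct$records$group))
  expect_equal(classification_accuracy(ct), 1)
  expect_true(ct$r_refs >= -1 && ct$r_refs <= 1)

  # exclusion variant: records and reference r change, embedding untouched
  ct2 <- classification_table(emb, exclude_samples = c("AD01", "AD02"))
  expect_equal(nrow(ct2$records), 19)
  expect_false(any(c("AD01", "AD02") %in% ct2$records$patient_id))
  expect_error(classification_table(blob_embedding(n_cr = 1, n_ad = 5)),
               class = "hspcmap_protocol_error")
})

test_that("at zero separation the calls sit near chance", {
  emb <- blob_embedding(n_cr = 6, n_ad = 6, seed = 86, overlap = 0.5)
  ct <- classification_table(emb)
  expect_gte(classification_accuracy(ct), 0)
  expect_lte(classification_accuracy(ct), 0.85)
})

test_that("calls on a separated real embedding are grid-resolution robust", {
  emb <- separated_embedding()
  calls <- lapply(c(64, 100, 128), function(nb) {
    classification_table(emb, density_grid(emb, n_bins = nb))$records$call
  })
  expect_identical(calls[[1]], calls[[2]])
  expect_identical(calls[[2]], calls[[3]])
  expect_equal(classification_accuracy(
    classification_table(emb)), 1)
})

test_that("stability analysis reports agreement across embedding seeds", {
  merged <- gated_merged(small_spec(n_cr = 3, n_ad = 3, seed = 19,
                                    cells = c(300, 900)))
  st <- stability_analysis(merged,
                           embed_params(perplexity = 15, n_iter = 300),
                           seeds = c(5L, 6L))
  expect_equal(nrow(st$agreement), 6)
  expect_true(all(st$agreement$agreement >= 0 & st$agreement$agreement <= 1))
  expect_true(st$all_identical)

  st_same <- stability_analysis(merged,
                                embed_params(perplexity = 15, n_iter = 300),
                                seeds = c(9L, 9L))
  expect_identical(st_same$tables[[1]]$records, st_same$tables[[2]]$records)
  expect_error(stability_analysis(merged, seeds = 1L),
               class = "hspcmap_argument_error")
})
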