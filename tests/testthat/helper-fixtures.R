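# Shared fixtures. Expensive objects (t-SNE embeddings) are computed once
# per test run and cached; all sizes here are deliberately small versions
# of the default study conditions so the suite stays fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small cohort spec: same structure as the defaults, desk-sized counts.
small_spec <- function(n_cr = 5, n_ad = 4, effect = 1, seed = 11,
                       cells = c(400, 1600), cd34_fraction = 0.3, ...) {
  cohort_spec(n_cr = n_cr, n_ad = n_ad, cells_per_patient = cells,
              ad_mixture = ad_mixture_at_effect(effect),
              cd34_fraction = cd34_fraction, seed = seed, ...)
}

# Generate, pregate and merge a cohort; returns the merged (unembedded)
# expression matrix.
gated_merged <- function(spec, config = default_config()) {
  co <- generate_cohort(spec)
  gated <- lapply(seq_along(co$tables), function(i) {
    pregate(co$tables[[i]], config, seed = 1000 + i)$events
  })
  merge_cohort(gated, config)
}

# One fully separated embedded cohort, reused by several files.
separated_embedding <- function() {
  cached("separated_embedding", {
    merged <- gated_merged(small_spec())
    tsne_embed(merged, embed_params(perplexity = 30, n_iter = 600, seed = 42))
  })
}

# A hand-built "embedding" with subtype clusters at fixed centers: real
# marker draws from the generator profiles, coordinates assigned by
# subtype, no t-SNE involved. Gates are squares around the centers.
toy_centers <- function() {
  list(HSC_MPP = c(0, 0), CLP = c(10, 0), CMP = c(0, 10), MEP = c(10, 10),
       GMP = c(20, 0), LEUK_BLAST = c(20, 10), OTHER = c(0, 20))
}

toy_embedding <- function(n_per_patient = 200,
                          cr_mixture = default_cr_mixture(),
                          ad_mixture = default_ad_mixture(),
                          n_cr = 3, n_ad = 2, seed = 5, spread = 1) {
  set.seed(seed)
  profiles <- default_profiles()
  centers <- toy_centers()
  cfg <- default_config()
  one <- function(id, group, mixture) {
    counts <- as.vector(stats::rmultinom(1, n_per_patient, mixture))
    names(counts) <- names(mixture)
    parts <- lapply(names(counts)[counts > 0], function(s) {
      ev <- sample_subtype_events(profiles[[s]], counts[[s]])
      sc <- as.data.frame(lapply(ev[hspc_markers()], biexp_transform,
                                 cofactor = cfg$cofactor),
                          check.names = FALSE)
      sc$patient_id <- id
      sc$group <- group
      sc$.subtype <- s
      ctr <- centers[[s]]
      sc$tSNE1 <- ctr[1] + rnorm(nrow(sc), sd = spread)
      sc$tSNE2 <- ctr[2] + rnorm(nrow(sc), sd = spread)
      sc
    })
    do.call(rbind, parts)
  }
  tabs <- c(
    lapply(seq_len(n_cr), function(i) one(sprintf("CR%02d", i), "CR", cr_mixture)),
    lapply(seq_len(n_ad), function(i) one(sprintf("AD%02d", i), "AD", ad_mixture)))
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

toy_gates <- function(half = 4.5) {
  centers <- toy_centers()
  sq <- function(c_) {
    rbind(c_ + c(-half, -half), c_ + c(half, -half),
          c_ + c(half, half), c_ + c(-half, half))
  }
  tsne_gate_set(lapply(centers, sq))
}
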