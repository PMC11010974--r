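#!/usr/bin/env Rscript
# Stage 3 — merge all gated CD34+ cells, scale biexponentially (arcsinh,
# cofactor 150) and embed with PCA-initialized Barnes-Hut t-SNE
# (perplexity 70, 3000 iterations).

source("analysis/common.R")

t0 <- Sys.time()
run_pipeline(out_dir, study_config, study_spec, stages = "embed",
             seed = study_seed)
cat(sprintf("embedding took %s\n", format(Sys.time() - t0)))

emb <- read.csv(file.path(out_dir, "embed", "embedding.csv"),
                check.names = FALSE)
cat(sprintf("embedded %d cells from %d patients\n", nrow(emb),
            length(unique(emb$patient_id))))

# ground-truth neighborhood purity (generator side channel, not used by
# the pipeline itself)
if (".subtype" %in% names(emb)) {
  set.seed(1)
  idx <- sort(sample.int(nrow(emb), min(2000, nrow(emb))))
  pur <- knn_purity(emb[idx, c("tSNE1", "tSNE2")], emb$.subtype[idx], k = 10)
  cat(sprintf("10-NN same-subtype purity (2000-cell subsample): %.3f\n", pur))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  grid <- density_grid(emb, study_config$grid$n_bins, study_config$grid$pad)
  views <- split_groups(emb)
  for (v in names(views)) {
    pic <- density_matrix(views[[v]], grid, study_config$grid$smooth_sigma)
    ggplot2::ggsave(file.path(fig_dir, paste0("density_", v, ".png")),
                    plot_density_picture(pic, grid, title = toupper(v)),
                    width = 5, height = 4, dpi = 150)
  }
  cat("density plots written to", fig_dir, "\n")
}
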