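---
title: "Methods: t-SNE immunophenotyping and density-picture classification of CD34+ cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: t-SNE immunophenotyping and density-picture classification of CD34+ cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bone-marrow samples from patients with acute myeloid leukemia (AML) or
myelodysplastic syndromes (MDS) contain a CD34+ compartment that mixes
normal hematopoietic stem and progenitor cells (HSPCs) with leukemic
blasts, including leukemic stem cells (LSCs, typically CD34+CD38−). A
five-marker flow-cytometry panel — CD34, CD38, CD45RA, CD123 and PD-L1 —
resolves the canonical HSPC hierarchy and, when reduced to two dimensions
with t-SNE, separates leukemia-related populations from normal
progenitors. `hspcmap` implements that workflow end to end and adds a
quantitative sample-level read-out: a patient's whole t-SNE density
pattern is compared against cumulative remission (CR) and active-disease
(AD) reference patterns with a Pearson coefficient, giving a one-number
CR-versus-AD call per sample.

## Pipeline

1. **Pre-gating** (`pregate()`): six fixed steps — FSC-A/SSC-A scatter
   gate, CD45/SSC gate, doublet exclusion, viability check, a gate of
   interest excluding granulocytes, and CD34+ selection — followed by a
   random cap of 1000 cells per patient so no single sample dominates the
   map.
2. **Scaling and merge** (`merge_cohort()`): fluorescence is scaled
   biexponentially; all patients' gated cells are stacked with patient and
   group annotations so the combined embedding can be split back into
   per-patient and per-group views.
3. **Embedding** (`tsne_embed()`): Barnes–Hut t-SNE (via `Rtsne`) on the
   PCA projection of the scaled markers, initialized from the first two
   principal components.
4. **Embedding-plane gating** (`assign_gate_membership()`,
   `summarize_gate()`, `classify_hspc()`): disjoint polygon gates in the
   (tSNE1, tSNE2) plane, five-number marker summaries per gate and group,
   and phenotype assignment from gate-level marker means.
5. **Similarity classification** (`classification_table()`): per-sample
   leave-one-out Pearson comparison of density pictures.

## Models and formulas

**Biexponential scaling.** Implemented as the inverse hyperbolic sine with
a per-channel cofactor $c$ (default 150):
$f(x) = \operatorname{asinh}(x/c)$. The transform is odd, linear near
zero, and logarithmic at scale ($f(10^6 c) - f(10^5 c) \to \ln 10$), which
the tests assert analytically. A cofactor of 150 places the positive/
negative boundaries of the synthetic populations in the transform's
transition region, the usual practice for conventional fluorophores. The
exact biexponential family (e.g. logicle) used for the original display
scaling is not specified anywhere we could anchor to, so the analytically
transparent arcsinh parametrization is the package's choice.

**PCA initialization.** t-SNE input is the projection onto up to 50
principal components — with five markers this cap is inactive, but it is
retained for generality. The first two components, rescaled to standard
deviation $10^{-4}$, seed the layout; this preserves global structure
that random initialization scrambles. Component signs are fixed by making
each component's largest-magnitude loading positive, so the whole
embedding is a deterministic function of the data and the seed.

**t-SNE parameters.** Perplexity 70, 3000 gradient iterations,
Barnes–Hut $\theta = 0.5$, single-threaded. Learning rate and
exaggeration stay at the `Rtsne` defaults and are recorded in the run
log. Embedding coordinates are unitless; plots omit axis labels, and no
step of the pipeline interprets embedding distances metrically —
densities and gate membership only.

**Density pictures.** Each picture is a 2-D histogram of an embedding
subset on a shared grid: the combined embedding's bounding box padded by
2% per side, 100×100 bins (cells on the outer boundary fall into edge
bins). Optional Gaussian smoothing (default width 1 bin, kernel truncated
at $4\sigma$) uses reflecting boundaries, which keeps the operation
linear and mass-conserving — so group pictures stay exactly additive and
the entry sum always equals the cell count, both asserted in the tests.
Pictures are compared unnormalized (the coefficient below is scale
invariant); rendering normalizes each plot to its own maximum.

**Pearson coefficient.** For pictures $A, B$ with $N$ pixels,

$$r(A,B) = \frac{\mathrm{cov}_{A,B}}{\sigma_A\,\sigma_B},\qquad
\mathrm{cov}_{A,B} = \sum_j A_j B_j - \frac{\sum_j A_j \sum_j B_j}{N},\qquad
\sigma_X = \sqrt{\textstyle\sum_j X_j^2 - \frac{(\sum_j X_j)^2}{N}}.$$

$r = 1$ for identical pictures and $r = -1$ for maximally different ones
(complementary support). The implementation computes
$\mathrm{cov}/\sqrt{\sigma_A^2\sigma_B^2}$ with a single square root:
in IEEE arithmetic $\sqrt{v \cdot v} = v$, so $r(A,A)$ is exactly 1 in
floating point, where the two-square-root form can miss by one ulp.
Constant pictures ($\sigma = 0$) raise an error; the classification layer
converts it into an `unclassifiable` record. An independent
`stats::cor()` oracle bounds the absolute disagreement below $10^{-12}$
over 1000 random picture pairs.

**Leave-one-out protocol.** Every sample is held out in turn: its cells
remain in the embedding (the merge-then-split reading of the protocol)
but are removed from both cumulative reference pictures $\Sigma CR$ and
$\Sigma AD$. The call is CR when
$r_{\Sigma CR,N} - r_{\Sigma AD,N}$ exceeds the tie tolerance
($10^{-9}$), AD when it falls below the negative tolerance, and
`unclassified` on a tie — abstention is preferred over a forced call. A
strict re-embed-without-the-sample variant was considered and rejected: a
sample absent from the embedding has no coordinates, so its density
picture cannot be formed without an out-of-sample embedding method, which
is outside this package's scope. Removing listed samples from the
analysis without recomputing the embedding (the re-analysis pattern used
for atypical samples) is available through `exclude_samples`.

## Phenotype decision table

Gate-level mean scaled intensities are compared to fixed cutoffs
(classification operates on gate means, not per-cell calls):

| CD38 | CD45RA | CD123            | label   |
|------|--------|------------------|---------|
| −    | −      | any              | HSC/MPP |
| −    | +      | any              | CLP     |
| +    | −      | −                | MEP     |
| +    | −      | low              | CMP     |
| +    | −      | bright           | Other   |
| +    | +      | + (incl. low)    | GMP     |
| +    | +      | −                | Other   |

"Low" means weakly positive: above the negative cutoff but at most the
low upper bound. HSC and MPP are merged because their separation needs
CD90, which the panel lacks. The CLP rule (CD38− CD45RA+) is kept as the
protocol defines it even though canonical CLP definitions are CD38+ —
fidelity to the protocol wins over textbook immunology here. The table is
total: an exhaustive enumeration test maps every +/−/low combination to
exactly one label. A gate whose CD34 mean falls below threshold triggers
an inconsistency warning, since cells were pre-gated CD34+.

## The synthetic cohort generator

No patient-level data are distributable, so the generator is a
first-class, tested module that emulates the statistical structure the
analysis assumes:

* **Populations.** Seven CD34+ profiles — HSC/MPP, CLP, CMP, MEP, GMP,
  `LEUK_BLAST` (LSC-like: CD34 bright, CD38−, strong CD45RA/CD123
  co-expression, PD-L1 high) and `OTHER` (aberrant CD38+CD45RA+CD123−,
  unallocatable by the decision table) — plus background lymphocytes,
  monocytes, granulocytes and debris so the pre-gating has real work to
  do. Under the decision table, a pure `LEUK_BLAST` gate reads as CLP
  (CD38−CD45RA+), which is exactly how an LSC-like population surfaces in
  this scheme.
* **Noise model.** Each channel is log-normal around the profile mean
  with a per-channel CV (default 0.5 for fluorescence): fluorescence is
  strictly positive with a heavy right tail. FSC-A is tied to FSC-H by a
  multiplicative singlet ratio (CV 0.1); 5% of events are doublets
  (FSC-A ≈ 2×FSC-H) and 5% are dead (viability dye above threshold).
  Profile means give the default thresholds ≥95% positive/negative
  separation.
* **Cohort structure.** Defaults mirror the study design: 12 CR and 9 AD
  patients; per-patient totals drawn log-uniformly over [129, 207994] so
  CD34+ counts span orders of magnitude; CR composition mirrors the
  published remission compartment (GMP-dominated, large unallocated
  fraction); the AD mixture enriches CD38− and CD45RA+/CD123+/PD-L1-high
  populations. `ad_mixture_at_effect(e)` interpolates from the CR mixture
  (e = 0) to a fully leukemic mixture (e = 1), the knob used in the
  parameter-recovery tests.
* **Ground truth.** Per-event subtype/doublet/dead labels travel in
  dot-prefixed side-channel columns that the pipeline never reads and the
  FCS writer never exports; only tests consume them.

What the generator does **not** emulate: spectral spillover and
compensation, batch or time drift, acquisition artifacts, inter-patient
variation of population locations (all patients share one profile set),
and the continuous differentiation gradients that make real t-SNE maps
smear between islands. Passing tests therefore demonstrate correctness of
the pipeline's mechanics and recoverability of planted structure — not
clinical performance on real marrow samples, where population overlap is
far larger.

## Numerical and design choices

* **Doublet rule**: FSC-A within (1 ± 0.3)×FSC-H; the protocol names the
  step but not the rule, and the ratio window is the standard convention.
  Events with nonpositive FSC-H are dropped and counted separately.
* **Viability boundary**: events exactly at threshold count as dead
  (strictly-below retention) — a conservative convention fixed for
  testability.
* **Gate-of-interest plane**: CD34 vs SSC-A, with granulocytes excluded
  by an SSC ceiling; the original gates were drawn manually, so the
  shipped scatter-plane gates are rectangles matched to the synthetic
  profiles.
* **Point-in-polygon**: even-odd rule with boundary-inclusive membership,
  one convention for scatter-plane and embedding-plane gates alike.
* **Embedding-plane gates**: config-supplied, versioned polygons in
  production use; `propose_gates()` is a clearly non-canonical
  convenience that derives candidate gates from local density maxima by
  steepest-ascent basin assignment and convex hulls (overlapping hulls
  drop the smaller basin).
* **Marker thresholds**: the numeric +/− limits are not published;
  configuration values are calibrated once against the generator's
  profiles (raw 500 for every marker, CD123 low band up to 2000, arcsinh
  scale via the cofactor) and never adjusted per analysis.
* **Percentage ratios**: the CR:AD ratio of a gate uses within-group
  percentages, so unequal group sizes do not bias gate coloring.
* **Ties**: `unclassified` rather than a forced call, tolerance
  $10^{-9}$ on the r difference.

## Problem sizes used by the tests

The suite runs scaled-down versions of the study conditions, chosen once
as desk-scale: unit tests use cohorts of 4–11 patients with hundreds of
events each; embedding tests run perplexity 15–30 with 300–600
iterations. The parameter-recovery property keeps the full 12 + 9 cohort
structure at 129–1500 events per patient across five effect sizes × three
embedding seeds; its monotonicity assertion allows a single discordant
call (1/63) between adjacent effect sizes, since per-sample calls are
discrete. The `analysis/` drivers run the default configuration
(perplexity 70, 3000 iterations) on 21 patients with up to 8000 events
each, ~7000 embedded cells in total.

## Known limitations

* The FCS reader covers list-mode float/double files of the kind the
  package writes plus plain vendor files; integer data types, multi-data-
  set files and delimiter escaping are out of scope.
* `propose_gates()` is a convenience for synthetic reference embeddings;
  on real data with touching islands, manual gate curation remains
  necessary (the automatic basins have no biologically meaningful
  borders).
* Classification quality is bounded by the reference pictures: with few
  or heterogeneous AD samples the AD reference is diffuse and AD calls
  lean on small r differences — the abstention band exists for exactly
  that case.
* New samples cannot be projected into an existing map; every
  classification run re-embeds the full cohort.
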