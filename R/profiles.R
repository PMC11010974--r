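#' Analysis markers and channels
#'
#' The five fluorescence markers entering the embedding and phenotype
#' assignment, and the full channel set carried by every event table:
#' the five markers plus CD45, the viability dye channel and the three
#' scatter channels.
#'
#' @return character vector of channel names.
#' @export
hspc_markers <- function() c("CD34", "CD38", "CD45RA", "CD123", "PD-L1")

#' @rdname hspc_markers
#' @export
hspc_channels <- function() {
  c(hspc_markers(), "CD45", "Viability", "FSC-A", "FSC-H", "SSC-A")
}

#' HSPC subtype names known to the generator
#' @return character vector of subtype labels.
#' @export
hspc_subtypes <- function() {
  c("HSC_MPP", "CLP", "CMP", "MEP", "GMP", "LEUK_BLAST", "OTHER")
}

#' Construct a subtype fluorescence profile
#'
#' A profile fixes, for one cell population, the arithmetic mean and the
#' coefficient of variation of every channel on the raw fluorescence scale
#' (arbitrary units), together with the intended `+`/`-`/`low` call of each
#' analysis marker. Events are drawn log-normally around these means, the
#' standard model for strictly positive, right-skewed fluorescence
#' intensities.
#'
#' @param name subtype label (one of [hspc_subtypes()] or a background
#'   population name).
#' @param marker_means named numeric vector over [hspc_channels()], raw a.u.
#' @param marker_cvs named numeric vector of coefficients of variation; a
#'   scalar is recycled. For `FSC-A` the value is interpreted as the spread
#'   of the FSC-A/FSC-H singlet ratio, which ties the two channels together.
#' @param positivity named character vector (`+`, `-` or `low`) over the
#'   analysis markers; `NULL` for background (non-HSPC) populations.
#' @param decision_label the phenotype label the marker-threshold decision
#'   table is expected to assign to a pure gate of this profile.
#' @return an object of class `subtype_profile`.
#' @export
subtype_profile <- function(name, marker_means, marker_cvs = 0.5,
                            positivity = NULL, decision_label = NA_character_) {
  ch <- hspc_channels()
  if (!all(ch %in% names(marker_means))) {
    stop_hspc(paste0("profile '", name, "' must define all channels: ",
                     paste(setdiff(ch, names(marker_means)), collapse = ", ")),
              "hspcmap_profile_error")
  }
  marker_means <- marker_means[ch]
  if (any(marker_means < 0)) {
    stop_hspc("marker means must be nonnegative", "hspcmap_profile_error")
  }
  if (length(marker_cvs) == 1) {
    marker_cvs <- stats::setNames(rep(marker_cvs, length(ch)), ch)
  }
  if (!all(ch %in% names(marker_cvs))) {
    stop_hspc("marker_cvs must cover all channels", "hspcmap_profile_error")
  }
  structure(list(name = name, marker_means = marker_means,
                 marker_cvs = marker_cvs[ch], positivity = positivity,
                 decision_label = decision_label),
            class = "subtype_profile")
}

#' Default HSPC subtype profiles
#'
#' Ships one profile per antigen combination of the HSPC hierarchy
#' (HSC/MPP, CLP, CMP, MEP, GMP) plus two disease-related populations:
#' `LEUK_BLAST`, a leukemic-stem-cell-like signature (CD34 bright, CD38
#' negative, strong CD45RA/CD123 co-expression, high PD-L1), and `OTHER`,
#' an aberrant CD38+CD45RA+CD123- population that the decision table cannot
#' allocate to a named type. Means are chosen so that the default raw
#' thresholds (see [default_thresholds()]) separate intended positive from
#' negative populations with comfortable margin under the default CVs.
#'
#' @return named list of `subtype_profile` objects.
#' @export
default_profiles <- function() {
  mk <- function(cd34, cd38, cd45ra, cd123, pdl1, cd45, fsc, ssc) {
    c(CD34 = cd34, CD38 = cd38, CD45RA = cd45ra, CD123 = cd123,
      `PD-L1` = pdl1, CD45 = cd45, Viability = 100,
      `FSC-A` = fsc, `FSC-H` = fsc, `SSC-A` = ssc)
  }
  cvs <- function(fluor = 0.5, scatter = 0.25, ratio = 0.1) {
    c(CD34 = fluor, CD38 = fluor, CD45RA = fluor, CD123 = fluor,
      `PD-L1` = fluor, CD45 = 0.4, Viability = 0.5,
      `FSC-A` = ratio, `FSC-H` = scatter, `SSC-A` = scatter)
  }
  pos <- function(cd38, cd45ra, cd123, pdl1) {
    c(CD34 = "+", CD38 = cd38, CD45RA = cd45ra, CD123 = cd123,
      `PD-L1` = pdl1)
  }
  list(
    HSC_MPP = subtype_profile("HSC_MPP",
      mk(6000, 60, 60, 60, 150, 8000, 55000, 20000),
      cvs(), pos("-", "-", "-", "-"), "HSC/MPP"),
    CLP = subtype_profile("CLP",
      mk(5000, 60, 4000, 60, 150, 8000, 52000, 18000),
      cvs(), pos("-", "+", "-", "-"), "CLP"),
    CMP = subtype_profile("CMP",
      mk(4000, 4000, 60, 900, 200, 8000, 55000, 22000),
      cvs(fluor = 0.45), pos("+", "-", "low", "-"), "CMP"),
    MEP = subtype_profile("MEP",
      mk(4000, 4000, 60, 60, 150, 8000, 54000, 21000),
      cvs(), pos("+", "-", "-", "-"), "MEP"),
    GMP = subtype_profile("GMP",
      mk(3500, 5000, 4000, 4000, 800, 8000, 56000, 25000),
      cvs(), pos("+", "+", "+", "low"), "GMP"),
    LEUK_BLAST = subtype_profile("LEUK_BLAST",
      mk(9000, 60, 6000, 6000, 8000, 3000, 60000, 24000),
      cvs(fluor = 0.35), pos("-", "+", "+", "+"), "CLP"),
    OTHER = subtype_profile("OTHER",
      mk(1500, 5000, 5000, 70, 3000, 6000, 52000, 23000),
      cvs(), pos("+", "+", "-", "+"), "Other")
  )
}

# Non-CD34 white-blood-cell populations plus debris; these only exist so
# that the six-step pre-gating has realistic material to remove.
background_profiles <- function() {
  mk <- function(cd34, cd38, cd45ra, cd123, pdl1, cd45, viab, fsc, ssc) {
    c(CD34 = cd34, CD38 = cd38, CD45RA = cd45ra, CD123 = cd123,
      `PD-L1` = pdl1, CD45 = cd45, Viability = viab,
      `FSC-A` = fsc, `FSC-H` = fsc, `SSC-A` = ssc)
  }
  cvs <- c(CD34 = 0.5, CD38 = 0.5, CD45RA = 0.5, CD123 = 0.5,
           `PD-L1` = 0.5, CD45 = 0.4, Viability = 0.5,
           `FSC-A` = 0.1, `FSC-H` = 0.25, `SSC-A` = 0.25)
  gr_cvs <- cvs; gr_cvs[["SSC-A"]] <- 0.2
  list(
    LYMPH = subtype_profile("LYMPH",
      mk(40, 800, 3000, 50, 80, 15000, 100, 45000, 12000), cvs),
    MONO = subtype_profile("MONO",
      mk(40, 2000, 400, 2000, 300, 12000, 100, 70000, 45000), cvs),
    GRAN = subtype_profile("GRAN",
      mk(40, 1000, 300, 600, 200, 6000, 100, 75000, 120000), gr_cvs),
    DEBRIS = subtype_profile("DEBRIS",
      mk(30, 30, 30, 30, 30, 30, 2500, 8000, 5000), cvs)
  )
}

#' Default raw-scale thresholds
#'
#' Positive/negative cutoffs on the raw fluorescence scale for each analysis
#' marker, the upper bound of the CD123 "low" (weakly positive) band, and
#' the viability-dye intensity above which an event is considered dead.
#'
#' @return list with elements `positive` (named numeric), `cd123_low_upper`,
#'   `viability_dead` and `cd34` (the CD34 selection threshold).
#' @export
default_thresholds <- function() {
  list(
    positive = c(CD34 = 500, CD38 = 500, CD45RA = 500, CD123 = 500,
                 `PD-L1` = 500),
    cd123_low_upper = 2000,
    viability_dead = 1000,
    cd34 = 500
  )
}

#' Default group mixtures over HSPC subtypes
#'
#' The remission (CR) mixture mirrors the published composition of the CD34+
#' compartment in remission marrow (GMP-dominated with a large unallocated
#' fraction); the active-disease (AD) default enriches the CD38- and
#' CD45RA+/CD123+/PD-L1-high leukemia-related profiles.
#'
#' `ad_mixture_at_effect()` interpolates linearly between the CR mixture
#' (effect 0) and a fully separated leukemic mixture (effect 1), the knob
#' used by the parameter-recovery analyses.
#'
#' @return named numeric vector over [hspc_subtypes()] summing to 1.
#' @export
default_cr_mixture <- function() {
  c(HSC_MPP = 0.007, CLP = 0.012, CMP = 0.094, MEP = 0.114, GMP = 0.446,
    LEUK_BLAST = 0.010, OTHER = 0.317)
}

#' @rdname default_cr_mixture
#' @export
default_ad_mixture <- function() {
  c(HSC_MPP = 0.043, CLP = 0.041, CMP = 0.047, MEP = 0.137, GMP = 0.370,
    LEUK_BLAST = 0.100, OTHER = 0.262)
}

#' @rdname default_cr_mixture
#' @export
separated_ad_mixture <- function() {
  c(HSC_MPP = 0.15, CLP = 0, CMP = 0, MEP = 0, GMP = 0.15,
    LEUK_BLAST = 0.60, OTHER = 0.10)
}

#' @rdname default_cr_mixture
#' @param effect number in \[0, 1\]; 0 reproduces the CR mixture, 1 the
#'   fully separated leukemic mixture.
#' @export
ad_mixture_at_effect <- function(effect) {
  stopifnot(is.numeric(effect), effect >= 0, effect <= 1)
  (1 - effect) * default_cr_mixture() + effect * separated_ad_mixture()
}
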