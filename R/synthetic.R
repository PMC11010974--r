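#' Specify a synthetic cohort
#'
#' A cohort spec fixes everything the generator needs: group sizes, the
#' range of total white-blood-cell events per patient (drawn log-uniformly,
#' so per-patient CD34+ counts span orders of magnitude as they do in real
#' marrow aspirates), the subtype mixtures of the CD34+ compartment in each
#' group, the CD34+ fraction of all events, the injected doublet and dead
#' fractions, and the master seed. Generation is a pure function of the
#' spec: the same spec always yields bit-identical cohorts.
#'
#' @param n_cr,n_ad number of remission (CR) and active-disease (AD)
#'   patients; defaults mirror the 12 + 9 study design.
#' @param cells_per_patient length-2 range of total events per patient.
#' @param cr_mixture,ad_mixture named nonnegative vectors over
#'   [hspc_subtypes()] summing to 1.
#' @param cd34_fraction expected fraction of events in the CD34+
#'   compartment (the rest are background populations and debris).
#' @param doublet_fraction,dead_fraction injected artefact fractions.
#' @param seed master integer seed.
#' @param profiles list of subtype profiles, by default
#'   [default_profiles()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cr = 12, n_ad = 9,
                        cells_per_patient = c(129, 207994),
                        cr_mixture = default_cr_mixture(),
                        ad_mixture = default_ad_mixture(),
                        cd34_fraction = 0.2,
                        doublet_fraction = 0.05,
                        dead_fraction = 0.05,
                        seed = 1L,
                        profiles = default_profiles()) {
  check_mix <- function(m, what) {
    if (is.null(names(m)) || !all(names(m) %in% hspc_subtypes())) {
      stop_hspc(paste(what, "must be named over hspc_subtypes()"),
                "hspcmap_spec_error")
    }
    if (any(m < 0) || abs(sum(m) - 1) > 1e-9) {
      stop_hspc(paste(what, "proportions must be nonnegative and sum to 1"),
                "hspcmap_spec_error")
    }
    full <- stats::setNames(numeric(length(hspc_subtypes())), hspc_subtypes())
    full[names(m)] <- m
    full
  }
  if (n_cr + n_ad < 2) {
    stop_hspc("need at least two patients in total", "hspcmap_spec_error")
  }
  if (length(cells_per_patient) != 2 || min(cells_per_patient) < 1 ||
      cells_per_patient[2] < cells_per_patient[1]) {
    stop_hspc("cells_per_patient must be an increasing range with min >= 1",
              "hspcmap_spec_error")
  }
  stopifnot(cd34_fraction > 0, cd34_fraction <= 1,
            doublet_fraction >= 0, doublet_fraction < 1,
            dead_fraction >= 0, dead_fraction < 1)
  structure(list(n_cr = as.integer(n_cr), n_ad = as.integer(n_ad),
                 cells_per_patient = as.numeric(cells_per_patient),
                 cr_mixture = check_mix(cr_mixture, "cr_mixture"),
                 ad_mixture = check_mix(ad_mixture, "ad_mixture"),
                 cd34_fraction = cd34_fraction,
                 doublet_fraction = doublet_fraction,
                 dead_fraction = dead_fraction,
                 seed = as.integer(seed), profiles = profiles),
            class = "cohort_spec")
}

#' Draw raw events from one subtype profile
#'
#' Each fluorescence and scatter channel is drawn log-normally with the
#' profile's arithmetic mean and coefficient of variation (a CV of zero
#' collapses the distribution to the mean exactly). FSC-A is tied to FSC-H
#' through a multiplicative singlet ratio; events flagged as doublets get
#' their FSC-A inflated to about twice FSC-H, and events flagged as dead get
#' a viability-dye intensity drawn above the dead threshold.
#'
#' @param profile a [subtype_profile()].
#' @param n number of events (>= 0).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param doublet_fraction,dead_fraction artefact fractions.
#' @param dead_mean mean viability-dye intensity of dead events.
#' @return data.frame with the full channel set plus ground-truth side
#'   channels `.subtype`, `.doublet`, `.dead` (never consumed by the
#'   pipeline; used by tests only).
#' @export
sample_subtype_events <- function(profile, n, seed = NULL,
                                  doublet_fraction = 0, dead_fraction = 0,
                                  dead_mean = 5000) {
  stopifnot(inherits(profile, "subtype_profile"))
  if (length(n) != 1 || is.na(n) || n < 0) {
    stop_hspc("n must be a single nonnegative count", "hspcmap_argument_error")
  }
  n <- as.integer(n)
  draw <- function() {
    ch <- hspc_channels()
    out <- matrix(0, nrow = n, ncol = length(ch),
                  dimnames = list(NULL, ch))
    lnorm <- function(mean, cv, n) {
      if (cv <= 0 || mean <= 0) return(rep(mean, n))
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
    }
    for (c_ in setdiff(ch, "FSC-A")) {
      out[, c_] <- lnorm(profile$marker_means[[c_]],
                         profile$marker_cvs[[c_]], n)
    }
    ratio_cv <- profile$marker_cvs[["FSC-A"]]
    ratio <- if (ratio_cv > 0) {
      stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + ratio_cv^2)))
    } else rep(1, n)
    doublet <- stats::runif(n) < doublet_fraction
    ratio[doublet] <- 2 * ratio[doublet]
    out[, "FSC-A"] <- out[, "FSC-H"] * ratio
    dead <- stats::runif(n) < dead_fraction
    if (any(dead)) {
      out[dead, "Viability"] <- lnorm(dead_mean, 0.3, sum(dead))
    }
    df <- as.data.frame(out, check.names = FALSE)
    df$.subtype <- rep(profile$name, n)
    df$.doublet <- doublet
    df$.dead <- dead
    df
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate one synthetic patient
#'
#' The total event count is drawn log-uniformly from the spec's
#' `cells_per_patient` range; the CD34+ compartment is a multinomial draw
#' from the group's subtype mixture and the remainder is filled with
#' background populations (lymphocytes, monocytes, granulocytes, debris).
#' Every event carries the patient id and group label.
#'
#' @param spec a [cohort_spec()].
#' @param group `"CR"` or `"AD"`.
#' @param patient_id label stamped on every event.
#' @param seed integer seed; generation is deterministic given
#'   `(spec, group, patient_id, seed)`.
#' @param n_events optional fixed total event count overriding the draw.
#' @return a CellEventTable: data.frame of channels + `patient_id`, `group`
#'   and ground-truth side channels.
#' @export
generate_patient <- function(spec, group, patient_id, seed,
                             n_events = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% c("CR", "AD")) {
    stop_hspc(paste0("unknown group label '", group, "'"),
              "hspcmap_argument_error")
  }
  mixture <- if (group == "CR") spec$cr_mixture else spec$ad_mixture
  with_seed(seed, {
    if (is.null(n_events)) {
      lo <- log(spec$cells_per_patient[1]); hi <- log(spec$cells_per_patient[2])
      n_events <- as.integer(round(exp(stats::runif(1, lo, hi))))
      n_events <- max(min(n_events, spec$cells_per_patient[2]),
                      spec$cells_per_patient[1])
    }
    n_cd34 <- stats::rbinom(1, n_events, spec$cd34_fraction)
    sub_counts <- as.vector(stats::rmultinom(1, n_cd34, mixture))
    names(sub_counts) <- names(mixture)
    bg_mix <- c(LYMPH = 0.50, MONO = 0.15, GRAN = 0.25, DEBRIS = 0.10)
    bg_counts <- as.vector(stats::rmultinom(1, n_events - n_cd34, bg_mix))
    names(bg_counts) <- names(bg_mix)
    bg <- background_profiles()
    parts <- list()
    for (s in names(sub_counts)) {
      if (sub_counts[[s]] > 0) {
        parts[[s]] <- sample_subtype_events(
          spec$profiles[[s]], sub_counts[[s]],
          doublet_fraction = spec$doublet_fraction,
          dead_fraction = spec$dead_fraction)
      }
    }
    for (s in names(bg_counts)) {
      if (bg_counts[[s]] > 0) {
        parts[[s]] <- sample_subtype_events(
          bg[[s]], bg_counts[[s]],
          doublet_fraction = spec$doublet_fraction,
          dead_fraction = if (s == "DEBRIS") 0 else spec$dead_fraction)
      }
    }
    tab <- do.call(rbind, parts)
    rownames(tab) <- NULL
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    rownames(tab) <- NULL
    tab$patient_id <- rep(patient_id, nrow(tab))
    tab$group <- rep(group, nrow(tab))
    tab
  })
}

#' Generate a full synthetic cohort
#'
#' Produces `n_cr + n_ad` patient tables with per-patient seeds derived
#' deterministically from the spec's master seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `tables` (named list of CellEventTables) and
#'   `metadata` (data.frame: patient_id, group, n_events, seed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cr + spec$n_ad
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1, n))
  ids <- c(sprintf("CR%02d", seq_len(spec$n_cr)),
           sprintf("AD%02d", seq_len(spec$n_ad)))
  groups <- c(rep("CR", spec$n_cr), rep("AD", spec$n_ad))
  tables <- vector("list", n)
  names(tables) <- ids
  for (i in seq_len(n)) {
    tables[[i]] <- generate_patient(spec, groups[i], ids[i], seeds[i])
  }
  metadata <- data.frame(patient_id = ids, group = groups,
                         n_events = vapply(tables, nrow, integer(1)),
                         seed = seeds, stringsAsFactors = FALSE)
  rownames(metadata) <- NULL
  list(tables = tables, metadata = metadata)
}
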