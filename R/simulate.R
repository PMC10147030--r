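# Per-genotype substream seeding: genotype g of a run seeded with `seed`
# draws from set.seed((seed + 7919 * g) mod (2^31 - 1)), so adding genotypes
# to a config never perturbs the data of existing ones.
genotype_seed <- function(seed, g) {
  as.integer((as.numeric(seed) + 7919 * g) %% 2147483647)
}

#' Configuration for a synthetic fertilization trial
#'
#' Describes a completely randomized orchard trial: genotypes x fertilization
#' treatments x replicate plants measured repeatedly over months after
#' planting. Heights follow a two-level Gaussian model,
#' `height = baseline + replicate_intercept + monthly_growth[treatment] * t
#' + measurement_noise`, truncated at 0. Fruiting onset is drawn per
#' replicate from a per-season Bernoulli hazard, starting at
#' `min_fruit_season` (juvenile plants do not fruit before it).
#'
#' @param n_genotypes number of genotypes (accessions) to simulate.
#' @param species species label attached to all records.
#' @param treatments character vector of fertilization regimes.
#' @param n_replicates replicate plants per treatment (default 5, the
#'   trial's design).
#' @param timepoints_months strictly increasing measurement months.
#' @param baseline_height_cm mean planting-time height (cm).
#' @param monthly_growth_cm named vector, treatment -> mean growth (cm/month).
#' @param replicate_sd_cm SD of the per-plant random intercept (cm).
#' @param measurement_sd_cm SD of the per-measurement noise (cm).
#' @param fruit_onset_hazard named vector, treatment -> per-season
#'   probability of fruiting onset, in \[0, 1\].
#' @param min_fruit_season earliest season in which fruiting can start
#'   (default 2).
#' @param seed integer seed; identical (config, seed) gives identical data.
#' @return list of class `trial_sim_config`.
#' @seealso [simulate_trial()], [sim_preset()]
#' @export
trial_sim_config <- function(n_genotypes = 1,
                             species = "Synthetic species",
                             treatments = c("control", "conventional", "organic"),
                             n_replicates = 5,
                             timepoints_months = c(3, 6, 9, 12, 15, 18),
                             baseline_height_cm = 60,
                             monthly_growth_cm = c(control = 8,
                                                   conventional = 10,
                                                   organic = 11),
                             replicate_sd_cm = 5,
                             measurement_sd_cm = 5,
                             fruit_onset_hazard = c(control = 0.9,
                                                    conventional = 0.9,
                                                    organic = 0.9),
                             min_fruit_season = 2,
                             seed = 1) {
  if (!is_scalar_number(n_genotypes) || n_genotypes < 1)
    validation_error("n_genotypes must be >= 1")
  if (length(treatments) < 1 || anyDuplicated(treatments))
    validation_error("treatments must be distinct names")
  if (!is_scalar_number(n_replicates) || n_replicates < 1)
    validation_error("n_replicates must be >= 1")
  if (length(timepoints_months) < 1 || any(diff(timepoints_months) <= 0) ||
      any(timepoints_months < 0))
    validation_error("timepoints_months must be non-negative and strictly increasing")
  if (replicate_sd_cm < 0 || measurement_sd_cm < 0)
    validation_error("standard deviations must be non-negative")
  if (!all(treatments %in% names(monthly_growth_cm)))
    validation_error("monthly_growth_cm must name every treatment")
  if (!all(treatments %in% names(fruit_onset_hazard)))
    validation_error("fruit_onset_hazard must name every treatment")
  if (any(fruit_onset_hazard < 0 | fruit_onset_hazard > 1))
    validation_error("fruit_onset_hazard values must be probabilities in [0, 1]")
  if (!is_scalar_number(min_fruit_season) || min_fruit_season < 1)
    validation_error("min_fruit_season must be >= 1")
  if (!is_scalar_number(seed)) validation_error("seed must be a single integer")
  structure(
    list(n_genotypes = as.integer(n_genotypes), species = species,
         treatments = treatments, n_replicates = as.integer(n_replicates),
         timepoints_months = timepoints_months,
         baseline_height_cm = baseline_height_cm,
         monthly_growth_cm = monthly_growth_cm[treatments],
         replicate_sd_cm = replicate_sd_cm,
         measurement_sd_cm = measurement_sd_cm,
         fruit_onset_hazard = fruit_onset_hazard[treatments],
         min_fruit_season = as.integer(min_fruit_season),
         seed = as.integer(seed)),
    class = "trial_sim_config"
  )
}

#' Trial-simulation presets anchored to the pilot-trial scales
#'
#' Three presets with 18-month heights and fruiting onsets on the scale of
#' the pilot orchard trial: `"rosa-like"` (four genotypes, final heights
#' around 2.3-3.3 m, onset from season 2), `"cornus-like"` (one genotype,
#' 0.8-1.25 m, no fruiting within the simulated horizon) and
#' `"sambucus-like"` (nine genotypes, up to about 2.45 m, onset from season
#' 2). Variance parameters are plausible scales, not fitted values.
#'
#' @param name preset name.
#' @param seed seed passed to the config.
#' @return a [trial_sim_config()].
#' @export
sim_preset <- function(name = c("rosa-like", "cornus-like", "sambucus-like"),
                       seed = 1) {
  name <- match.arg(name)
  switch(name,
    "rosa-like" = trial_sim_config(
      n_genotypes = 4, species = "Rosa-like shrub",
      baseline_height_cm = 30,
      monthly_growth_cm = c(control = 12, conventional = 13, organic = 15),
      replicate_sd_cm = 15, measurement_sd_cm = 8,
      fruit_onset_hazard = c(control = 0.9, conventional = 0.9, organic = 0.9),
      min_fruit_season = 2, seed = seed),
    "cornus-like" = trial_sim_config(
      n_genotypes = 1, species = "Cornus-like tree",
      baseline_height_cm = 20,
      monthly_growth_cm = c(control = 3.5, conventional = 5.8, organic = 4.7),
      replicate_sd_cm = 8, measurement_sd_cm = 5,
      fruit_onset_hazard = c(control = 0, conventional = 0, organic = 0),
      min_fruit_season = 2, seed = seed),
    "sambucus-like" = trial_sim_config(
      n_genotypes = 9, species = "Sambucus-like shrub",
      baseline_height_cm = 25,
      monthly_growth_cm = c(control = 8, conventional = 12.2, organic = 10),
      replicate_sd_cm = 12, measurement_sd_cm = 8,
      fruit_onset_hazard = c(control = 0.9, conventional = 0.9, organic = 0.9),
      min_fruit_season = 2, seed = seed)
  )
}

#' Simulate a fertilization trial
#'
#' Generates a [trial_dataset()] under the two-level Gaussian growth model of
#' [trial_sim_config()]. Fully reproducible: the same config (including its
#' seed) always yields the identical dataset, and each genotype draws from
#' its own substream so extending `n_genotypes` leaves earlier genotypes'
#' records unchanged.
#'
#' @param config a [trial_sim_config()].
#' @return a [trial_dataset()] with `fruiting` flags.
#' @export
#' @examples
#' d <- simulate_trial(sim_preset("rosa-like", seed = 42))
#' head(d)
simulate_trial <- function(config) {
  if (!inherits(config, "trial_sim_config"))
    validation_error("config must be a trial_sim_config")
  tp <- config$timepoints_months
  seasons <- growing_season(tp)
  max_season <- max(seasons)
  rows <- vector("list", config$n_genotypes)
  for (g in seq_len(config$n_genotypes)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(genotype_seed(config$seed, g))
    acc <- sprintf("SYN-%02d", g)
    grows <- list()
    for (trt in config$treatments) {
      for (rep_i in seq_len(config$n_replicates)) {
        intercept <- stats::rnorm(1, 0, config$replicate_sd_cm)
        noise <- stats::rnorm(length(tp), 0, config$measurement_sd_cm)
        h <- pmax(0, config$baseline_height_cm + intercept +
                       config$monthly_growth_cm[[trt]] * tp + noise)
        onset <- NA_integer_
        haz <- config$fruit_onset_hazard[[trt]]
        if (config$min_fruit_season <= max_season) {
          for (s in config$min_fruit_season:max_season) {
            if (stats::runif(1) < haz) { onset <- s; break }
          }
        }
        fruiting <- !is.na(onset) & seasons >= onset
        grows[[length(grows) + 1L]] <- data.frame(
          species = config$species, accession = acc, treatment = trt,
          replicate = rep_i, months_after_planting = tp, height_cm = h,
          fruiting = fruiting, stringsAsFactors = FALSE)
      }
    }
    rows[[g]] <- do.call(rbind, grows)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  trial_dataset(do.call(rbind, rows))
}

#' Configuration for synthetic species raw profiles
#'
#' Generating distributions (truncated Gaussians) for the quantitative
#' rubric attributes, plus fruit-onset and molecular-authentication
#' settings. If `target_scores` names rubric attributes, the corresponding
#' distribution means are re-centred at the middle of the rubric band for
#' that score (the top open band is centred half the previous band's width
#' above its lower bound), so small-SD draws recover the target score.
#'
#' @param species character vector of species names (one profile each).
#' @param n_genotypes genotypes per species.
#' @param dist named list of distributions, each `list(mean, sd, min, max)`,
#'   for `rooting_pct`, `aa_rsa_pct`, `tpc`, `height_18m`,
#'   `growth_rate_6_18`. Draws are truncated to \[min, max\].
#' @param fruit_onset_season season of first fruiting given to every
#'   genotype (`NA` = never fruits).
#' @param genetically_distinct logical flag given to every genotype.
#' @param target_scores optional named integer vector (rubric attribute ->
#'   intended score 0-5) overriding distribution means / onset / flag.
#' @param scales rubric scales used to locate target bands.
#' @param seed integer seed.
#' @return list of class `profile_sim_config`.
#' @export
profile_sim_config <- function(species = "Synthetic species",
                               n_genotypes = 5,
                               dist = list(
                                 rooting_pct = list(mean = 60, sd = 10, min = 0, max = 100),
                                 aa_rsa_pct = list(mean = 80, sd = 8, min = 0, max = 100),
                                 tpc = list(mean = 120, sd = 25, min = 0, max = Inf),
                                 height_18m = list(mean = 2, sd = 0.4, min = 0, max = Inf),
                                 growth_rate_6_18 = list(mean = 25, sd = 8, min = 0, max = Inf)),
                               fruit_onset_season = 2,
                               genetically_distinct = TRUE,
                               target_scores = NULL,
                               scales = default_scales(),
                               seed = 1) {
  needed <- c("rooting_pct", "aa_rsa_pct", "tpc", "height_18m", "growth_rate_6_18")
  if (!all(needed %in% names(dist)))
    validation_error(sprintf("dist must define: %s", paste(needed, collapse = ", ")))
  for (nm in needed) {
    d <- dist[[nm]]
    if (!all(c("mean", "sd", "min", "max") %in% names(d)) || d$sd < 0 ||
        d$min > d$max)
      validation_error(sprintf("dist$%s needs mean, sd >= 0, min <= max", nm))
  }
  if (!is_scalar_number(n_genotypes) || n_genotypes < 1)
    validation_error("n_genotypes must be >= 1")
  cfg <- structure(
    list(species = species, n_genotypes = as.integer(n_genotypes),
         dist = dist[needed], fruit_onset_season = fruit_onset_season,
         genetically_distinct = genetically_distinct,
         target_scores = target_scores, scales = scales,
         seed = as.integer(seed)),
    class = "profile_sim_config"
  )
  if (!is.null(target_scores)) cfg <- apply_target_scores(cfg)
  cfg
}

# map a rubric attribute id to the measurement field it is generated from
attr_to_field <- c(rooting_pct = "rooting_pct", antioxidant_aa_pct = "aa_rsa_pct",
                   tpc_mgGAE_100g = "tpc", tree_height_18m_m = "height_18m",
                   growth_rate_pct = "growth_rate_6_18")

band_centre <- function(scale, score) {
  b <- scale$bands
  i <- match(score, b$score)
  if (is.na(i))
    validation_error(sprintf("%s: score %d has no band (missing data scores 0)",
                             scale$attribute_id, score))
  lo <- b$lower[i]; hi <- b$upper[i]
  if (is.finite(hi)) return((lo + hi) / 2)
  prev_width <- if (i > 1 && is.finite(b$upper[i - 1]) && is.finite(b$lower[i - 1]))
    b$upper[i - 1] - b$lower[i - 1] else lo
  lo + prev_width / 2
}

apply_target_scores <- function(cfg) {
  ts <- cfg$target_scores
  bad <- setdiff(names(ts), rubric_attributes())
  if (length(bad) > 0)
    validation_error(sprintf("unknown target attribute(s): %s",
                             paste(bad, collapse = ", ")))
  for (id in names(ts)) {
    s <- as.integer(ts[[id]])
    if (s < 0 || s > 5) validation_error("target scores must lie in 0..5")
    if (id == "molecular_auth") {
      if (!s %in% c(0L, 5L))
        validation_error("molecular_auth admits only scores 0 and 5")
      cfg$genetically_distinct <- s == 5L
    } else if (id == "fruit_onset") {
      cfg$fruit_onset_season <- switch(as.character(s), "5" = 2L, "4" = 3L,
                                       "3" = 4L, "2" = 5L, "1" = 6L,
                                       "0" = NA_integer_)
    } else {
      field <- attr_to_field[[id]]
      scale <- cfg$scales[[id]]
      if (s == 0L && !0L %in% scale$bands$score) {
        # "not grown": reachable only through a missing measurement
        cfg$dist[[field]]$mean <- NA_real_
        next
      }
      centre <- band_centre(scale, s)
      d <- cfg$dist[[field]]
      if (centre < d$min || centre > d$max)
        validation_error(sprintf(
          "target score %d for %s needs values near %g, outside bounds [%g, %g]",
          s, id, centre, d$min, d$max))
      cfg$dist[[field]]$mean <- centre
    }
  }
  cfg
}

#' Simulate species raw profiles
#'
#' Draws genotype measurements from the configured truncated Gaussian
#' distributions, one [species_profile()] per species name, each genotype on
#' its own seeded substream.
#'
#' @param config a [profile_sim_config()].
#' @return list of [species_profile()] objects.
#' @export
#' @examples
#' cfg <- profile_sim_config(target_scores = c(rooting_pct = 4), seed = 7)
#' score_species(simulate_profiles(cfg)[[1]])$scores[["rooting_pct"]]
simulate_profiles <- function(config) {
  if (!inherits(config, "profile_sim_config"))
    validation_error("config must be a profile_sim_config")
  draw <- function(d) {
    if (is.na(d$mean)) return(NA_real_)
    min(max(stats::rnorm(1, d$mean, d$sd), d$min), d$max)
  }
  lapply(seq_along(config$species), function(si) {
    genotypes <- lapply(seq_len(config$n_genotypes), function(g) {
      set.seed(genotype_seed(config$seed + 131071 * (si - 1), g))
      genotype_measurements(
        accession = sprintf("SYN-%s-%02d", si, g),
        rooting_pct = draw(config$dist$rooting_pct),
        aa_rsa_pct = draw(config$dist$aa_rsa_pct),
        tpc = draw(config$dist$tpc),
        height_18m = draw(config$dist$height_18m),
        growth_rate_6_18 = draw(config$dist$growth_rate_6_18),
        fruit_onset_season = config$fruit_onset_season,
        genetically_distinct = config$genetically_distinct)
    })
    species_profile(config$species[si], genotypes)
  })
}
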