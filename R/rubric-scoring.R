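#' Raw measurements for one genotype (accession)
#'
#' One wild-collected population sample (genotype), identified by its IPEN
#' accession, with its raw quantitative evaluation data. Any field may be
#' missing (`NA`); missing fields score 0 downstream. Accession strings are
#' stored verbatim after whitespace trimming — IPEN identifiers contain a
#' comma (e.g. `"GR-1-BBGK-19,191"`), so keep them quoted in CSV files.
#'
#' @param accession accession identifier (non-empty string).
#' @param rooting_pct rooting frequency of cuttings, percent in \[0, 100\].
#' @param aa_rsa_pct antioxidant activity as percent radical scavenging
#'   activity, in \[0, 100\].
#' @param tpc total phenolic content, mg GAE/100 g, non-negative.
#' @param height_18m juvenile tree height at 18 months after planting, m.
#' @param growth_rate_6_18 percent height increase from 6 to 18 months
#'   (may exceed 100).
#' @param fruit_onset_season first growing season with fruit production
#'   (positive integer), or `NA` if none observed.
#' @param genetically_distinct logical: molecular authentication established
#'   a distinct genetic identity.
#' @return object of class `genotype_measurements`.
#' @export
genotype_measurements <- function(accession,
                                  rooting_pct = NA_real_,
                                  aa_rsa_pct = NA_real_,
                                  tpc = NA_real_,
                                  height_18m = NA_real_,
                                  growth_rate_6_18 = NA_real_,
                                  fruit_onset_season = NA_integer_,
                                  genetically_distinct = NA) {
  if (!is.character(accession) || length(accession) != 1L)
    validation_error("accession must be a single string")
  accession <- trimws(accession)
  if (!nzchar(accession)) validation_error("accession must be non-empty")

  chk_pct <- function(x, what) {
    if (!is.na(x) && (!is.numeric(x) || x < 0 || x > 100))
      validation_error(sprintf("%s (%s) must be in [0, 100], got %s",
                               what, accession, format(x)))
    as.numeric(x)
  }
  chk_nonneg <- function(x, what) {
    if (!is.na(x) && (!is.numeric(x) || x < 0))
      validation_error(sprintf("%s (%s) must be non-negative, got %s",
                               what, accession, format(x)))
    as.numeric(x)
  }
  if (!is.na(fruit_onset_season) &&
      (fruit_onset_season < 1 || fruit_onset_season != floor(fruit_onset_season)))
    validation_error(sprintf("fruit_onset_season (%s) must be a positive integer",
                             accession))
  if (!is.na(genetically_distinct) && !is.logical(genetically_distinct))
    validation_error(sprintf("genetically_distinct (%s) must be logical", accession))

  structure(
    list(accession = accession,
         rooting_pct = chk_pct(rooting_pct, "rooting_pct"),
         aa_rsa_pct = chk_pct(aa_rsa_pct, "aa_rsa_pct"),
         tpc = chk_nonneg(tpc, "tpc"),
         height_18m = chk_nonneg(height_18m, "height_18m"),
         growth_rate_6_18 = as.numeric(growth_rate_6_18),
         fruit_onset_season = if (is.na(fruit_onset_season)) NA_integer_
                              else as.integer(fruit_onset_season),
         genetically_distinct = as.logical(genetically_distinct)),
    class = "genotype_measurements"
  )
}

#' Species-level raw profile
#'
#' Bundles the genotypes evaluated for one species. Species-level scoring
#' averages the quantitative measurements across genotypes with data, takes
#' the earliest fruit-onset season, and requires all molecularly assessed
#' genotypes to be distinct.
#'
#' @param species_name species name (non-empty string).
#' @param genotypes list of [genotype_measurements()] (at least one).
#' @return object of class `species_profile`.
#' @export
species_profile <- function(species_name, genotypes) {
  if (!is.character(species_name) || length(species_name) != 1L ||
      !nzchar(trimws(species_name)))
    validation_error("species_name must be a non-empty string")
  if (inherits(genotypes, "genotype_measurements")) genotypes <- list(genotypes)
  if (!is.list(genotypes) || length(genotypes) == 0L)
    validation_error(sprintf("species %s: at least one genotype required",
                             species_name))
  ok <- vapply(genotypes, inherits, logical(1), "genotype_measurements")
  if (!all(ok))
    validation_error("genotypes must all be genotype_measurements objects")
  structure(list(species_name = trimws(species_name), genotypes = genotypes),
            class = "species_profile")
}

# Species-level raw aggregates: mean across genotypes with data for the
# quantitative attributes, earliest season for fruit onset, and (for
# molecular authentication) TRUE iff every assessed genotype is distinct.
aggregate_profile <- function(profile) {
  stopifnot(inherits(profile, "species_profile"))
  g <- profile$genotypes
  pull <- function(field) vapply(g, function(x) as.numeric(x[[field]] %||% NA_real_),
                                 numeric(1))
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  onset <- pull("fruit_onset_season")
  distinct <- vapply(g, function(x) x$genetically_distinct, logical(1))
  list(
    molecular_auth = if (all(is.na(distinct))) NA else all(distinct[!is.na(distinct)]),
    rooting_pct = mean_or_na(pull("rooting_pct")),
    antioxidant_aa_pct = mean_or_na(pull("aa_rsa_pct")),
    tpc_mgGAE_100g = mean_or_na(pull("tpc")),
    tree_height_18m_m = mean_or_na(pull("height_18m")),
    growth_rate_pct = mean_or_na(pull("growth_rate_6_18")),
    fruit_onset = if (all(is.na(onset))) NA_real_ else min(onset, na.rm = TRUE)
  )
}

#' Multifaceted-potential percentage from a rubric total
#'
#' Expresses a rubric total as percent of the 35-point maximum (7 attributes
#' x 5 points), rounded to one decimal, half away from zero. Totals 34, 33,
#' 32 and 26 give 97.1, 94.3, 91.4 and 74.3.
#'
#' @param total integer total in 0..`max_total`.
#' @param max_total maximum attainable total (default 35).
#' @return percentage with one decimal.
#' @export
potential_percentage <- function(total, max_total = 35L) {
  if (!is.numeric(total) || any(is.na(total)) ||
      any(total < 0) || any(total > max_total) || any(total != floor(total)))
    validation_error(sprintf("total must be an integer in 0..%d", max_total))
  round_half_away(100 * total / max_total, 1)
}

#' Score a species profile on the multifaceted rubric
#'
#' Aggregates the raw genotype measurements to species level and scores each
#' of the seven rubric attributes, returning a score card with the total out
#' of 35 and the percent-of-maximum.
#'
#' @param profile a [species_profile()].
#' @param scales named list of the seven [attribute_scale] objects
#'   (default [default_scales()]).
#' @return object of class `multifaceted_scorecard` with fields
#'   `species_name`, `scores` (named integer vector of length 7), `total`,
#'   `max_total` (35) and `percentage`.
#' @export
#' @examples
#' p <- species_profile("Rosa canina", list(
#'   genotype_measurements("GR-1-BBGK-19,191", rooting_pct = 55,
#'     aa_rsa_pct = 90, tpc = 160, height_18m = 2.3,
#'     growth_rate_6_18 = 21, fruit_onset_season = 2,
#'     genetically_distinct = TRUE)))
#' score_species(p)
score_species <- function(profile, scales = default_scales()) {
  stopifnot(inherits(profile, "species_profile"))
  ids <- rubric_attributes()
  if (!all(ids %in% names(scales)))
    validation_error(sprintf("scales must cover all attributes: missing %s",
                             paste(setdiff(ids, names(scales)), collapse = ", ")))
  agg <- aggregate_profile(profile)
  scores <- vapply(ids, function(id) score_value(scales[[id]], agg[[id]]),
                   integer(1))
  new_multifaceted_scorecard(profile$species_name, scores)
}

new_multifaceted_scorecard <- function(species_name, scores) {
  ids <- rubric_attributes()
  stopifnot(identical(sort(names(scores)), sort(ids)))
  scores <- as.integer(scores[ids])
  names(scores) <- ids
  total <- sum(scores)
  structure(
    list(species_name = species_name, scores = scores, total = total,
         max_total = 35L, percentage = potential_percentage(total)),
    class = "multifaceted_scorecard"
  )
}

#' @export
print.multifaceted_scorecard <- function(x, ...) {
  cat(sprintf("<multifaceted_scorecard> %s: total %d/%d (%.1f%%)\n",
              x$species_name, x$total, x$max_total, x$percentage))
  print(x$scores)
  invisible(x)
}

#' Rank species by multifaceted potential
#'
#' Combines score cards into one comparison table, sorted by descending
#' percentage with ties broken alphabetically by species name.
#'
#' @param cards list of `multifaceted_scorecard` objects (distinct species).
#' @return data.frame with one row per species: the seven attribute scores,
#'   `total` and `percentage`.
#' @export
compare_species <- function(cards) {
  if (inherits(cards, "multifaceted_scorecard")) cards <- list(cards)
  if (!is.list(cards) || length(cards) == 0L)
    validation_error("need at least one score card")
  ok <- vapply(cards, inherits, logical(1), "multifaceted_scorecard")
  if (!all(ok)) validation_error("cards must be multifaceted_scorecard objects")
  species <- vapply(cards, `[[`, character(1), "species_name")
  if (anyDuplicated(species))
    validation_error(sprintf("duplicate species names: %s",
                             paste(unique(species[duplicated(species)]),
                                   collapse = ", ")))
  tab <- do.call(rbind, lapply(cards, function(cd) {
    cbind(data.frame(species = cd$species_name, stringsAsFactors = FALSE),
          as.data.frame(as.list(cd$scores)),
          data.frame(total = cd$total, percentage = cd$percentage))
  }))
  tab <- tab[order(-tab$percentage, tab$species), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
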