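#' Attribute specification of the feasibility-for-exploitation index
#'
#' The index assesses 12 attributes per species, each on a scoring scale
#' with a maximum of 6 but — for some attributes — a restricted admissible
#' set (e.g. existing cultivations is all-or-nothing at \{0, 6\}; water
#' demand admits only \{0, 1, 3, 6\}). The maximum total is 72.
#'
#' @return data-frame-free named list: for each attribute id, the integer
#'   vector of admissible scores.
#' @export
feasibility_specs <- function() {
  full <- 0:6
  list(
    existing_cultivations        = c(0L, 6L),
    threat_category              = full,
    protection_status            = c(0L, 4L, 5L, 6L),
    ex_situ_conservation         = full,
    distribution                 = full,
    commercial_products          = full,
    known_propagation            = c(0L, 3L, 5L, 6L),
    vegetative_propagation_success = full,
    seed_germination_success     = full,
    cultivation_needs            = c(0L, 3L, 5L, 6L),
    existing_cultivation_protocols = full,
    water_demand                 = c(0L, 1L, 3L, 6L)
  )
}

#' Feasibility percentage from a total score
#'
#' Percent of the 72-point maximum, one decimal, rounded half away from
#' zero: 52 gives 72.2, 45 gives 62.5, 40 gives 55.6.
#'
#' @param total integer total in 0..72.
#' @return percentage with one decimal.
#' @export
feasibility_percentage <- function(total) {
  if (!is.numeric(total) || any(is.na(total)) ||
      any(total < 0) || any(total > 72) || any(total != floor(total)))
    validation_error("feasibility total must be an integer in 0..72")
  round_half_away(100 * total / 72, 1)
}

#' Validate a 12-attribute feasibility score vector
#'
#' Checks that all 12 attributes are present and that each score lies in
#' its attribute's admissible set, then computes the total (max 72) and the
#' feasibility percentage.
#'
#' @param scores named numeric/integer vector or list: attribute id -> score.
#' @param specs admissible-score sets, default [feasibility_specs()].
#' @param species_name optional species label carried into the card.
#' @param sources optional named character vector: attribute id -> free-text
#'   data source citation.
#' @return object of class `feasibility_scorecard` with fields
#'   `species_name`, `scores`, `total`, `max_total` (72), `percentage`,
#'   `sources`.
#' @export
#' @examples
#' validate_scorecard(c(
#'   existing_cultivations = 6, threat_category = 1, protection_status = 0,
#'   ex_situ_conservation = 6, distribution = 0, commercial_products = 6,
#'   known_propagation = 6, vegetative_propagation_success = 6,
#'   seed_germination_success = 6, cultivation_needs = 6,
#'   existing_cultivation_protocols = 6, water_demand = 3),
#'   species_name = "Rosa canina")  # total 52, 72.2%
validate_scorecard <- function(scores, specs = feasibility_specs(),
                               species_name = NA_character_,
                               sources = NULL) {
  scores <- unlist(scores)
  ids <- names(specs)
  missing <- setdiff(ids, names(scores))
  if (length(missing) > 0)
    validation_error(sprintf("missing feasibility attribute(s): %s",
                             paste(missing, collapse = ", ")))
  extra <- setdiff(names(scores), ids)
  if (length(extra) > 0)
    validation_error(sprintf("unknown feasibility attribute(s): %s",
                             paste(extra, collapse = ", ")))
  scores <- scores[ids]
  for (id in ids) {
    s <- scores[[id]]
    if (is.na(s) || s != floor(s) || !(s %in% specs[[id]]))
      validation_error(sprintf(
        "attribute %s: score %s not in admissible set {%s}",
        id, format(s), paste(specs[[id]], collapse = ", ")))
  }
  scores <- as.integer(scores)
  names(scores) <- ids
  total <- sum(scores)
  structure(
    list(species_name = species_name, scores = scores, total = total,
         max_total = 72L, percentage = feasibility_percentage(total),
         sources = sources),
    class = "feasibility_scorecard"
  )
}

#' @export
print.feasibility_scorecard <- function(x, ...) {
  cat(sprintf("<feasibility_scorecard> %s: total %d/%d (%.1f%%)\n",
              x$species_name, x$total, x$max_total, x$percentage))
  print(x$scores)
  invisible(x)
}

#' Default readiness-timescale band table
#'
#' Only the two bands printed in the source framework are defined:
#' "already achieved" strictly above 70%, and "achievable in short-term"
#' strictly above 55% up to and including 70%. Everything at or below 55%
#' is reported as unclassified by this framework rather than being forced
#' into an invented lower band.
#'
#' @return data.frame with columns `band`, `label`, `lower` (exclusive),
#'   `upper` (inclusive), ordered from best to worst.
#' @export
default_readiness_bands <- function() {
  data.frame(
    band = c("already_achieved", "achievable_short_term", "unclassified_below_55"),
    label = c("Already achieved (>70%)",
              "Achievable in short-term (>55-70%)",
              "Unclassified by this framework (<=55%)"),
    lower = c(70, 55, -Inf),
    upper = c(Inf, 70, 55),
    stringsAsFactors = FALSE
  )
}

#' Classify a feasibility percentage into a readiness-timescale band
#'
#' Band bounds are strict at the lower end: 72.2% and 70.8% are "already
#' achieved", 70.0% falls into "achievable in short-term", and 55.0% falls
#' below the short-term band.
#'
#' @param percentage feasibility percentage in \[0, 100\].
#' @param bands band table as in [default_readiness_bands()]; overridable.
#' @param species_name optional species label.
#' @return object of class `readiness_assessment` with fields
#'   `species_name`, `percentage`, `band`, `band_label`.
#' @export
classify_readiness <- function(percentage, bands = default_readiness_bands(),
                               species_name = NA_character_) {
  if (!is_scalar_number(percentage) || percentage < 0 || percentage > 100)
    validation_error("percentage must be a single number in [0, 100]")
  hit <- which(percentage > bands$lower & percentage <= bands$upper)
  if (length(hit) != 1L)
    validation_error(sprintf("band table does not classify %.1f%% uniquely",
                             percentage))
  structure(
    list(species_name = species_name, percentage = percentage,
         band = bands$band[hit], band_label = bands$label[hit]),
    class = "readiness_assessment"
  )
}

#' @export
print.readiness_assessment <- function(x, ...) {
  cat(sprintf("<readiness_assessment> %s: %.1f%% -> %s\n",
              x$species_name, x$percentage, x$band_label))
  invisible(x)
}

#' Feasibility and readiness report table
#'
#' One row per species: the 12 attribute scores, total, percentage,
#' readiness band and label, and (if given) data sources, sorted by
#' descending percentage.
#'
#' @param cards list of `feasibility_scorecard` objects.
#' @param bands readiness band table (default [default_readiness_bands()]).
#' @return data.frame report.
#' @export
readiness_report <- function(cards, bands = default_readiness_bands()) {
  if (inherits(cards, "feasibility_scorecard")) cards <- list(cards)
  if (!is.list(cards) || length(cards) == 0L)
    validation_error("need at least one feasibility score card")
  ok <- vapply(cards, inherits, logical(1), "feasibility_scorecard")
  if (!all(ok)) validation_error("cards must be feasibility_scorecard objects")
  rows <- lapply(cards, function(cd) {
    rd <- classify_readiness(cd$percentage, bands, cd$species_name)
    src <- if (is.null(cd$sources)) "" else
      paste(names(cd$sources), unlist(cd$sources), sep = ": ", collapse = "; ")
    cbind(data.frame(species = cd$species_name, stringsAsFactors = FALSE),
          as.data.frame(as.list(cd$scores)),
          data.frame(total = cd$total, percentage = cd$percentage,
                     band = rd$band, band_label = rd$band_label,
                     sources = src, stringsAsFactors = FALSE))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$percentage, tab$species), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
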