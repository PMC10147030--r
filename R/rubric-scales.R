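#' Ordinal scoring scales for the multifaceted-potential rubric
#'
#' An `attribute_scale` maps a raw measurement to an ordinal score in 0..5.
#' Numeric scales carry a banded partition of the non-negative reals; the
#' molecular-authentication scale is boolean (0 or 5); the fruit-onset scale
#' maps the growing-season index of first fruiting to a score. A missing
#' measurement always scores 0 ("no data / not evaluated").
#'
#' Band endpoints follow the rubric's printed convention: a plain endpoint is
#' included in the band, a strict (">") lower endpoint is excluded, so the
#' rooting bands are `[0,5) [5,20] (20,30] (30,50] (50,70] (70,Inf)`.
#'
#' @param attribute_id one of `"molecular_auth"`, `"rooting_pct"`,
#'   `"antioxidant_aa_pct"`, `"tpc_mgGAE_100g"`, `"tree_height_18m_m"`,
#'   `"growth_rate_pct"`, `"fruit_onset"`.
#' @param bands for numeric scales, a data.frame with columns `score`,
#'   `lower`, `upper`, `lower_closed`, `upper_closed`; ignored otherwise.
#' @param type `"numeric"`, `"boolean"` or `"season"`.
#' @return an object of class `attribute_scale`.
#' @seealso [default_scales()], [score_value()]
#' @export
attribute_scale <- function(attribute_id,
                            bands = NULL,
                            type = c("numeric", "boolean", "season")) {
  type <- match.arg(type)
  attribute_id <- match.arg(attribute_id, rubric_attributes())
  if (type == "numeric") {
    needed <- c("score", "lower", "upper", "lower_closed", "upper_closed")
    if (!is.data.frame(bands) || !all(needed %in% names(bands)))
      validation_error("numeric scale needs bands with columns score, lower, upper, lower_closed, upper_closed")
    bands <- bands[order(bands$score), needed, drop = FALSE]
    rownames(bands) <- NULL
    if (anyDuplicated(bands$score))
      validation_error(sprintf("duplicate band scores for %s", attribute_id))
    if (any(bands$score < 0 | bands$score > 5))
      validation_error("band scores must lie in 0..5")
    if (any(bands$upper < bands$lower))
      validation_error("band upper bound below its lower bound")
    # ordered by score means ordered by value: successive bands must abut
    # without overlap and without gaps over the scale's domain
    if (nrow(bands) > 1) {
      for (i in seq_len(nrow(bands) - 1)) {
        hi <- bands$upper[i]; lo <- bands$lower[i + 1]
        if (hi != lo || (bands$upper_closed[i] && bands$lower_closed[i + 1]) ||
            (!bands$upper_closed[i] && !bands$lower_closed[i + 1]))
          validation_error(sprintf(
            "bands for %s must partition the domain: band %d/%d boundary mismatch",
            attribute_id, bands$score[i], bands$score[i + 1]))
      }
    }
  } else {
    bands <- NULL
  }
  structure(
    list(attribute_id = attribute_id, type = type, bands = bands,
         max_score = 5L),
    class = "attribute_scale"
  )
}

#' @export
print.attribute_scale <- function(x, ...) {
  cat(sprintf("<attribute_scale> %s (%s, max score %d)\n",
              x$attribute_id, x$type, x$max_score))
  if (x$type == "numeric") {
    b <- x$bands
    lab <- sprintf("%s%s, %s%s",
                   ifelse(b$lower_closed, "[", "("), format(b$lower),
                   format(b$upper), ifelse(b$upper_closed, "]", ")"))
    cat(paste0("  score ", b$score, ": ", lab, collapse = "\n"), "\n")
  } else if (x$type == "boolean") {
    cat("  FALSE -> 0, TRUE -> 5, missing -> 0\n")
  } else {
    cat("  season <= 2 -> 5, 3 -> 4, 4 -> 3, 5 -> 2, >= 6 -> 1, none -> 0\n")
  }
  invisible(x)
}

#' Attribute identifiers of the multifaceted rubric
#'
#' @return character vector of the seven rubric attribute ids, in the order
#'   used by score cards: molecular authentication, rooting percentage,
#'   antioxidant activity (%RSA), total phenolic content (mg GAE/100 g),
#'   juvenile tree height at 18 months (m), height-increase rate 6-18 months
#'   (%), and onset of fruit production (growing season index).
#' @export
rubric_attributes <- function() {
  c("molecular_auth", "rooting_pct", "antioxidant_aa_pct", "tpc_mgGAE_100g",
    "tree_height_18m_m", "growth_rate_pct", "fruit_onset")
}

numeric_bands <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(score = as.integer(r[[1]]), lower = r[[2]], upper = r[[3]],
               lower_closed = r[[4]], upper_closed = r[[5]])
  }))
}

#' Default rubric scales
#'
#' The seven scoring scales of the multifaceted-potential rubric. Numeric
#' bands use the closed-at-plain-end / open-at-">"-end convention, e.g.
#' rooting `< 5` scores 0, `5-20` scores 1, `> 20-30` scores 2, and so on up
#' to `> 70` scoring 5. Total phenolic content above the top printed band
#' (200 mg GAE/100 g) is clamped to score 5 to keep the scale monotone.
#' Tree height and growth rate reserve score 0 for plants that failed to
#' establish (missing measurement, or height exactly 0).
#'
#' @return named list of seven [attribute_scale] objects, in
#'   [rubric_attributes()] order.
#' @export
#' @examples
#' sc <- default_scales()
#' score_value(sc$rooting_pct, 72)   # 5
#' score_value(sc$tpc_mgGAE_100g, 19.99) # 0
default_scales <- function() {
  scales <- list(
    molecular_auth = attribute_scale("molecular_auth", type = "boolean"),
    rooting_pct = attribute_scale("rooting_pct", numeric_bands(
      list(0, 0, 5, TRUE, FALSE),
      list(1, 5, 20, TRUE, TRUE),
      list(2, 20, 30, FALSE, TRUE),
      list(3, 30, 50, FALSE, TRUE),
      list(4, 50, 70, FALSE, TRUE),
      list(5, 70, Inf, FALSE, FALSE))),
    antioxidant_aa_pct = attribute_scale("antioxidant_aa_pct", numeric_bands(
      list(0, 0, 5, TRUE, FALSE),
      list(1, 5, 20, TRUE, TRUE),
      list(2, 20, 40, FALSE, TRUE),
      list(3, 40, 65, FALSE, TRUE),
      list(4, 65, 85, FALSE, TRUE),
      list(5, 85, Inf, FALSE, FALSE))),
    tpc_mgGAE_100g = attribute_scale("tpc_mgGAE_100g", numeric_bands(
      list(0, 0, 20, TRUE, FALSE),
      list(1, 20, 50, TRUE, TRUE),
      list(2, 50, 80, FALSE, TRUE),
      list(3, 80, 100, FALSE, TRUE),
      list(4, 100, 150, FALSE, TRUE),
      # printed top band is >150-200; values beyond 200 clamp to 5
      list(5, 150, Inf, FALSE, FALSE))),
    tree_height_18m_m = attribute_scale("tree_height_18m_m", numeric_bands(
      list(0, 0, 0, TRUE, TRUE),          # failed to establish
      list(1, 0, 0.5, FALSE, FALSE),
      list(2, 0.5, 1, TRUE, TRUE),
      list(3, 1, 1.5, FALSE, TRUE),
      list(4, 1.5, 2, FALSE, TRUE),
      list(5, 2, Inf, FALSE, FALSE))),
    growth_rate_pct = attribute_scale("growth_rate_pct", numeric_bands(
      # score 0 ("not established") is reached only via a missing value
      list(1, 0, 5, TRUE, FALSE),
      list(2, 5, 10, TRUE, TRUE),
      list(3, 10, 15, FALSE, TRUE),
      list(4, 15, 20, FALSE, TRUE),
      list(5, 20, Inf, FALSE, FALSE))),
    fruit_onset = attribute_scale("fruit_onset", type = "season")
  )
  scales[rubric_attributes()]
}

#' Score a raw value on a rubric scale
#'
#' Maps one raw measurement to its ordinal 0-5 score. Missing values (`NULL`
#' or `NA`) score 0 on every scale. Boolean scales accept only logical input;
#' numeric scales only non-negative numbers; the fruit-onset scale a positive
#' whole growing-season index.
#'
#' @param scale an [attribute_scale].
#' @param raw the raw value: number, logical, or `NA`/`NULL` for missing.
#' @return integer score in 0..5.
#' @export
#' @examples
#' score_value(default_scales()$fruit_onset, 2)  # fruiting in season 2 -> 5
score_value <- function(scale, raw) {
  stopifnot(inherits(scale, "attribute_scale"))
  if (is.null(raw) || (length(raw) == 1L && is.na(raw))) return(0L)
  if (length(raw) != 1L) validation_error("raw must be a single value")

  if (scale$type == "boolean") {
    if (!is.logical(raw))
      type_error(sprintf("%s expects a logical value, got %s",
                         scale$attribute_id, class(raw)[1]))
    return(if (isTRUE(raw)) 5L else 0L)
  }
  if (is.logical(raw))
    type_error(sprintf("%s expects a numeric value, got logical",
                       scale$attribute_id))
  if (!is.numeric(raw))
    type_error(sprintf("%s expects a numeric value, got %s",
                       scale$attribute_id, class(raw)[1]))

  if (scale$type == "season") {
    if (raw < 1 || raw != floor(raw))
      validation_error("fruit-onset season must be a positive whole number")
    return(if (raw <= 2) 5L else if (raw == 3) 4L else if (raw == 4) 3L
           else if (raw == 5) 2L else 1L)
  }

  if (raw < 0)
    validation_error(sprintf("%s: negative raw value %g not allowed",
                             scale$attribute_id, raw))
  b <- scale$bands
  in_band <- (raw > b$lower | (b$lower_closed & raw == b$lower)) &
             (raw < b$upper | (b$upper_closed & raw == b$upper))
  hit <- which(in_band)
  if (length(hit) != 1L)
    validation_error(sprintf("%s: value %g matches %d bands (scale misconfigured)",
                             scale$attribute_id, raw, length(hit)))
  as.integer(b$score[hit])
}
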