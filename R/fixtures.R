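#' Bundled reference evaluation of the four focal species
#'
#' Machine-readable copy of the published reference evaluation that anchors
#' this package's checks: the 12-attribute feasibility score vectors of the
#' four focal neglected and underutilized species (Rosa canina, Sambucus
#' nigra, Cornus mas, Amelanchier ovalis), their feasibility totals out of
#' 72, their multifaceted-potential totals out of 35, and the default rubric
#' scales.
#'
#' @return list with components `feasibility_scores` (named list: species ->
#'   named integer vector over the 12 attributes), `feasibility_totals`,
#'   `multifaceted_totals` (named integer vectors), and `scales`
#'   ([default_scales()]).
#' @export
#' @examples
#' fx <- reference_fixtures()
#' sum(fx$feasibility_scores$rosa_canina)  # 52
reference_fixtures <- function() {
  path <- system.file("extdata", "feasibility_scores.csv", package = "nupeval",
                      mustWork = TRUE)
  scores <- read_feasibility_scores(path)
  list(
    feasibility_scores = scores,
    feasibility_totals = c(rosa_canina = 52L, sambucus_nigra = 51L,
                           cornus_mas = 45L, amelanchier_ovalis = 40L),
    multifaceted_totals = c(amelanchier_ovalis = 34L, rosa_canina = 33L,
                            sambucus_nigra = 32L, cornus_mas = 26L),
    scales = default_scales()
  )
}
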