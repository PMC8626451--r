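#' Demographics of the template-construction cohort
#'
#' Age and gender distribution of the normal-participant cohort underlying
#' the published Chinese-population FDG-PET template release: counts per
#' gender and age band, together with the selection bookkeeping (initially
#' selected participants, subjects removed by SSD re-filtering, and the
#' final cohort size used for the released templates).
#'
#' @return A list with elements `demographics` (data.frame with columns
#'   `gender`, `ageBand`, `count`), `nSelected` (119), `nExcluded` (3, the
#'   subjects removed by the three-sigma SSD rule) and `nFinal` (116).
#' @examples
#' d <- cohortDemographics()
#' sum(d$demographics$count) == d$nFinal
#' @export
cohortDemographics <- function() {
  demographics <- data.frame(
    gender = rep(c("male", "female"), each = 3L),
    ageBand = rep(c("20-40", "41-60", "61-81"), 2L),
    count = c(16L, 36L, 25L, 9L, 27L, 3L))
  list(demographics = demographics, nSelected = 119L, nExcluded = 3L,
       nFinal = 116L)
}
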