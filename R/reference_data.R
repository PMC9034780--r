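#' Published per-area sCRACM summary values
#'
#' Reference summary table for the seven characterized input pathways to
#' V2M thick-tufted L5 neurons (VISp, V2M, RSPg, ACA, ORB, ATN, LP):
#' animal and cell counts, compartment input proportions, per-compartment
#' proportional charges (pC), full-field total charge mean and SEM (pC),
#' and soma depths (um). These are the printed summary values of the
#' original recordings (raw sweeps were not deposited); they serve as
#' inputs for cross-area aggregation and anatomy-function comparisons.
#'
#' @return A data frame with one row per input area.
#' @examples
#' tab <- published_area_summaries()
#' sum(tab$total_pc)  # 35.64 pC grand total
#' @export
published_area_summaries <- function() {
  utils::read.csv(system.file("extdata", "area_summaries_published.csv",
                              package = "scracm", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
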