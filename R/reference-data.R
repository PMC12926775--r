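#' Published reference estimates from the four-participant case series
#'
#' Participant-level results reported for a longitudinal cluster-scanning
#' case series of four patients (two logopenic-variant PPA, one posterior
#' cortical atrophy, one semantic-variant PPA), shipped as plain-text CSVs:
#' estimated marginal means of ROI thickness by timepoint (`"emm"`),
#' estimated declines with confidence intervals and percent change
#' (`"change"`), core-minus-control interaction contrasts (`"interaction"`),
#' and bootstrap plateau scan counts (`"plateau"`). These tables serve as
#' arithmetic-consistency material and as generating truth for parameter-
#' recovery simulations; the underlying MRI data are not distributed.
#'
#' @param which One of `"emm"`, `"change"`, `"interaction"`, `"plateau"`.
#' @return A data frame.
#' @export
reference_estimates <- function(which = c("emm", "change", "interaction",
                                          "plateau")) {
  which <- match.arg(which)
  path <- system.file("extdata", sprintf("reference_%s.csv", which),
                      package = "clusterscan", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
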