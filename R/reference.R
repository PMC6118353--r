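#' Published cross-ecosystem reference means
#'
#' The published per-type means and standard errors of the 19 food-web
#' metrics from the cross-ecosystem field survey of foundation
#' species-dominated (FS), bare-area (BA) and random-removal (RR) food
#' webs that this pipeline models (29 FS and 29 BA webs over seven
#' ecosystems).  Used as reference input for consistency checks of the
#' survey's headline ratios (e.g. species richness 2.1 times higher and
#' link density 1.6 times higher under foundation species, connectance
#' 0.75 times lower); the raw web matrices themselves were never
#' deposited.
#'
#' @return data frame with columns `metric`, `fs_mean`, `fs_se`,
#'   `ba_mean`, `ba_se`, `rr_mean`, `rr_se`, one row per metric of
#'   [metric_names()].
#' @export
reference_metric_means <- function() {
  path <- system.file("extdata", "published_metric_means.csv",
                      package = "foundweb", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
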