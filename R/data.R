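# Bundled example dispersion tables: published dispersion statistics for
# storm-tide disaster losses in China's five main coastal provinces,
# 2011-2015.  The raw loss panels behind them are not redistributed; the
# dispersions are the direct inputs to the relational-degree stage.

#' Bundled storm-tide disaster-loss dispersion tables
#'
#' Two published dispersion tables from a storm-tide disaster-loss study
#' of China's five main coastal provinces over 2011-2015:
#' \describe{
#'   \item{indicators}{reference-mode vector: dispersion between direct
#'     economic losses and six loss indicators (mariculture, coastal
#'     engineering, death toll, ship, collapsed home losses, storm surge
#'     frequency).}
#'   \item{provinces}{pairwise-mode 5 x 5 symmetric matrix: dispersion
#'     between every pair of provinces (Jiangsu, Zhejiang, Fujian,
#'     Guangdong, Guangxi) across seven indicators.}
#' }
#' Feed either into [epsilon_from_dispersions()] to obtain the
#' relational degrees and rankings.
#'
#' @param which `"indicators"` or `"provinces"`.
#' @return named numeric vector (`"indicators"`) or symmetric matrix
#'   (`"provinces"`).
#' @examples
#' round(epsilon_from_dispersions(
#'   storm_tide_dispersions("indicators"), "reference")$degrees, 4)
#' @export
storm_tide_dispersions <- function(which = c("indicators", "provinces")) {
  which <- match.arg(which)
  if (which == "indicators") {
    read_dispersion_table(
      system.file("extdata", "storm_tide_indicator_dispersions.csv",
                  package = "greypanel", mustWork = TRUE),
      mode = "reference")
  } else {
    read_dispersion_table(
      system.file("extdata", "storm_tide_province_dispersions.csv",
                  package = "greypanel", mustWork = TRUE),
      mode = "pairwise")
  }
}
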