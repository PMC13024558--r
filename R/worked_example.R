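# Bundled worked example for the severity-regression metrics.

#' Worked example: actual vs predicted Hoehn & Yahr stages
#'
#' Ten subject-level (actual, predicted) severity pairs bundled with the
#' package as a worked example for [regression_metrics()]: they reproduce
#' the headline accuracy profile of a gradient-boosted severity model
#' (MAE 0.158, RMSE 0.241, R-squared 0.953, Spearman rho 0.921).
#'
#' @return Data frame with columns `case`, `actual_hy`, `predicted_hy`.
#' @examples
#' ex <- severity_worked_example()
#' regression_metrics(ex$actual_hy, ex$predicted_hy)
#' @export
severity_worked_example <- function() {
  utils::read.csv(system.file("extdata", "severity_worked_example.csv",
                              package = "gaitxai"))
}
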