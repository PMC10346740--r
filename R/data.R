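#' Bundled field-trial validation counts
#'
#' Small plain-text datasets from a grazing-sheep field trial, bundled so
#' the evaluation metrics have their reference inputs available offline.
#'
#' * `field_step_counts()`: per-trial total step counts — manual video count
#'   (`true`), a plain peak-detection pedometer (`pred_peak`), and the
#'   behavior-classified algorithm (`pred_behavior`). Two sessions each for
#'   four sheep.
#' * `running_shake_counts()`: per-day running-step counts (`run_true`,
#'   `run_pred_peak`, `run_pred_behavior`) and leg-shake detection counts
#'   (`shake_detections`, `shake_errors`).
#' * `k_sweep_errors()`: signed running-step prediction errors for eight
#'   running episodes at each candidate scale factor `K` (the calibration
#'   sweep that selected K = 2.1).
#'
#' @return A data.frame.
#' @export
field_step_counts <- function() {
  utils::read.csv(system.file("extdata", "field_step_counts.csv",
                              package = "sheepstep"))
}

#' @rdname field_step_counts
#' @export
running_shake_counts <- function() {
  utils::read.csv(system.file("extdata", "running_shake_counts.csv",
                              package = "sheepstep"))
}

#' @rdname field_step_counts
#' @export
k_sweep_errors <- function() {
  utils::read.csv(system.file("extdata", "k_sweep_errors.csv",
                              package = "sheepstep"))
}
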