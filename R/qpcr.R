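#' Relative quantification arithmetic (ddCt method)
#'
#' `compute_delta_ct()` normalises a target gene's cycle threshold (CT) to a
#' housekeeping gene measured in the same sample:
#' \eqn{\Delta C_T = C_T^{target} - C_T^{reference}}. `compute_rq()` then
#' normalises a sample's \eqn{\Delta C_T} to a calibrator sample and converts
#' to a relative quantity:
#' \eqn{RQ = 2^{-(\Delta C_T^{sample} - \Delta C_T^{calibrator})} = 2^{-\Delta\Delta C_T}}.
#' RQ is a fold expression relative to the calibrator and is always strictly
#' positive; lower CT means more transcript.
#'
#' Both functions are vectorised and recycle their arguments like ordinary
#' R arithmetic.
#'
#' @param target_ct,reference_ct cycle-threshold values of the target and the
#'   housekeeping (e.g. GAPDH) gene. Must be finite.
#' @return `compute_delta_ct()`: the \eqn{\Delta C_T} value(s).
#' @examples
#' compute_delta_ct(25, 20)            # 5
#' compute_rq(5, 3)                    # ddCt = 2, RQ = 0.25
#' compute_rq(compute_delta_ct(25, 20), compute_delta_ct(27, 20))
#' @export
compute_delta_ct <- function(target_ct, reference_ct) {
  check_finite(target_ct, "target_ct")
  check_finite(reference_ct, "reference_ct")
  target_ct - reference_ct
}

#' @rdname compute_delta_ct
#' @param sample_delta_ct,calibrator_delta_ct \eqn{\Delta C_T} values of the
#'   sample of interest and the calibrator sample. Must be finite.
#' @return `compute_rq()`: the relative quantity \eqn{2^{-\Delta\Delta C_T}},
#'   strictly positive.
#' @export
compute_rq <- function(sample_delta_ct, calibrator_delta_ct) {
  check_finite(sample_delta_ct, "sample_delta_ct")
  check_finite(calibrator_delta_ct, "calibrator_delta_ct")
  2^(-(sample_delta_ct - calibrator_delta_ct))
}

# invalid-measurement guard shared by the CT arithmetic
check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("invalid measurement: `", what, "` must be finite numeric")
  invisible(x)
}
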