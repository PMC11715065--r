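#' Dosing regimen
#'
#' An ordered table of dose events.  Every event is delivered as a
#' zero-order (constant-rate) input; a "bolus" is simply a short infusion.
#' The study administrations were dabigatran over 1 min and idarucizumab
#' over 0.5 min, so those are the default durations used by the convenience
#' constructors.
#'
#' @param drug Character vector, each `"dabigatran"` or `"idarucizumab"`.
#' @param start Event start times (min, `>= 0`).
#' @param amount Dose amounts (mg for dabigatran; idarucizumab amounts are
#'   unit-normalised by the reversal-effect model, so only timing and
#'   duration matter).
#' @param duration Zero-order input durations (min, `> 0`).
#'
#' @return A `regimen` object: a data frame with columns `drug`, `start`,
#'   `amount`, `duration`, sorted by start time.
#' @export
#' @examples
#' regimen(drug = c("dabigatran", "idarucizumab"),
#'         start = c(0, 120), amount = c(280, 1050),
#'         duration = c(1, 0.5))
regimen <- function(drug = character(0), start = numeric(0),
                    amount = numeric(0), duration = numeric(0)) {
  n <- length(drug)
  if (length(start) != n || length(amount) != n || length(duration) != n)
    stop("regimen: 'drug', 'start', 'amount', 'duration' must have equal length",
         call. = FALSE)
  if (n == 0L) {
    out <- data.frame(drug = character(0), start = numeric(0),
                      amount = numeric(0), duration = numeric(0))
    class(out) <- c("regimen", "data.frame")
    return(out)
  }
  if (!all(drug %in% c("dabigatran", "idarucizumab")))
    stop("regimen: 'drug' must be 'dabigatran' or 'idarucizumab'",
         call. = FALSE)
  if (any(!is.finite(start)) || any(start < 0))
    stop("regimen: start times must be non-negative", call. = FALSE)
  if (any(!is.finite(amount)) || any(amount < 0))
    stop("regimen: amounts must be non-negative", call. = FALSE)
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("regimen: durations must be positive (use a short duration for a bolus)",
         call. = FALSE)
  out <- data.frame(drug = drug, start = start, amount = amount,
                    duration = duration)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("regimen", "data.frame")
  out
}

#' @describeIn regimen The study regimen for one subject: dabigatran
#'   `dabi_mgkg` mg/kg over 1 min at time 0 and (optionally) idarucizumab
#'   at `ida_time` min over 0.5 min.
#' @param weight Subject body weight (kg).
#' @param dabi_mgkg Dabigatran dose (mg/kg).
#' @param ida_mgkg Idarucizumab dose (mg/kg); `NULL` to omit.
#' @param ida_time Idarucizumab administration time (min).
#' @param dabi_duration,ida_duration Input durations (min).
#' @export
study_regimen <- function(weight, dabi_mgkg = 4, ida_mgkg = 15,
                          ida_time = 120, dabi_duration = 1,
                          ida_duration = 0.5) {
  if (is.null(ida_mgkg)) {
    regimen("dabigatran", 0, dabi_mgkg * weight, dabi_duration)
  } else {
    regimen(c("dabigatran", "idarucizumab"),
            c(0, ida_time),
            c(dabi_mgkg * weight, ida_mgkg * weight),
            c(dabi_duration, ida_duration))
  }
}
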