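#' Generate a virtual cohort
#'
#' Simulates a study dataset from a [population_model()] under a
#' [study_design()]: subject weights are drawn uniformly from the design's
#' range, per-subject random effects `eta ~ N(0, omega)` (diagonal,
#' log-scale) perturb the allometrically scaled typical values, true
#' trajectories come from the closed-form model, and observations apply the
#' combined residual model `y = f * (1 + eps_prop) + eps_add` with
#' independent normal errors per channel.  Observations that sample
#' negative are truncated at zero and flagged (`TRUNC = 1`) rather than
#' resampled, so the error model stays visible in the output.
#'
#' @param pop A [population_model()].
#' @param design A [study_design()].
#' @param seed Integer seed; the dataset is a deterministic function of
#'   `(pop, design, seed)`.
#'
#' @return A `study_dataset`: a data frame in long format with
#'   NONMEM-style columns `ID`, `TIME`, `EVID`, `CMT`, `AMT`, `RATE`,
#'   `DV`, `DVID`, `MDV`, `TRUNC`, `WT`.  Dose rows have `EVID = 1`
#'   (`CMT` 1 = dabigatran central, 4 = reversal compartment); observation
#'   rows have `EVID = 0` and `DVID` 1 (concentration, mg/L) or 2 (R-time,
#'   min).  The sampled random effects are attached as attribute `etas`
#'   (one row per subject), convenient for simulation studies.
#' @export
#' @examples
#' dat <- generate_cohort(default_population(), sheep_design(), seed = 1)
#' table(dat$EVID, dat$DVID)
generate_cohort <- function(pop, design, seed = 1) {
  stopifnot(inherits(pop, "population_model"),
            inherits(design, "study_design"))
  set.seed(seed)
  rows <- vector("list", design$n_subjects)
  etas <- matrix(0, design$n_subjects, length(pop$omega),
                 dimnames = list(NULL, names(pop$omega)))
  for (i in seq_len(design$n_subjects)) {
    wt <- stats::runif(1, design$weight_range[1], design$weight_range[2])
    eta <- if (length(pop$omega)) {
      stats::setNames(stats::rnorm(length(pop$omega), 0, sqrt(pop$omega)),
                      names(pop$omega))
    } else numeric(0)
    if (length(eta)) etas[i, ] <- eta
    pars <- individual_parameters(pop, wt, eta)
    reg <- study_regimen(wt, dabi_mgkg = design$dabi_mgkg,
                         ida_mgkg = design$ida_mgkg,
                         ida_time = design$ida_time,
                         dabi_duration = design$dabi_duration,
                         ida_duration = design$ida_duration)
    tt <- sort(unique(c(design$times_conc, design$times_r)))
    sim <- simulate_subject(pars, reg, tt)

    obs <- function(times, channel) {
      f <- if (channel == 1L) sim$C1[match(times, tt)] else sim$R[match(times, tt)]
      sp <- if (channel == 1L) pop$sigma[["conc_prop"]] else pop$sigma[["r_prop"]]
      sa <- if (channel == 1L) pop$sigma[["conc_add"]] else pop$sigma[["r_add"]]
      y <- f * (1 + stats::rnorm(length(f), 0, sp)) +
        stats::rnorm(length(f), 0, sa)
      trunc <- as.integer(y < 0)
      data.frame(ID = i, TIME = times, EVID = 0L, CMT = 1L, AMT = NA_real_,
                 RATE = NA_real_, DV = pmax(y, 0), DVID = channel,
                 MDV = 0L, TRUNC = trunc, WT = wt)
    }
    dose <- data.frame(
      ID = i, TIME = reg$start, EVID = 1L,
      CMT = ifelse(reg$drug == "dabigatran", 1L, 4L),
      AMT = reg$amount, RATE = reg$amount / reg$duration,
      DV = NA_real_, DVID = 0L, MDV = 1L, TRUNC = 0L, WT = wt)
    sub <- rbind(dose, obs(design$times_conc, 1L), obs(design$times_r, 2L))
    sub <- sub[order(sub$TIME, sub$EVID == 0L, sub$DVID), , drop = FALSE]
    rows[[i]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study_dataset", "data.frame")
  attr(out, "etas") <- etas   # true random effects, for simulation studies
  out
}
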