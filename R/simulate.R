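# Closed-form simulation of the linear disposition system.
#
# Every input is a zero-order infusion, so C1, C2 (and by convolution the
# effect-site concentration) are finite sums of truncated exponentials
#   coef * exp(-lambda * (t - onset)) * [t >= onset],  lambda >= 0.
# Each infusion on [t0, t1] is the superposition of an infusion switched on
# at t0 forever minus one switched on at t1.  Terms are kept in a small
# data frame and evaluated vectorised; this is the fast path used inside
# the mixed-effects inner loops.  deSolve integration of the same system is
# available as an independent path (method = "ode").

.biexp <- function(pk) {
  k10 <- pk$CL / pk$V1
  k12 <- pk$Q / pk$V1
  k21 <- pk$Q / pk$V2
  s <- k10 + k12 + k21
  disc <- sqrt(max(s * s - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  # repeated roots cannot occur for distinct positive rate constants except
  # on a measure-zero set; nudge to keep coefficients finite
  if ((alpha - beta) < 1e-12 * alpha) beta <- beta * (1 - 1e-9)
  list(alpha = alpha, beta = beta, k21 = k21, k12 = k12)
}

# exponential-term bookkeeping -------------------------------------------

.terms_new <- function() {
  data.frame(coef = numeric(0), lambda = numeric(0), onset = numeric(0))
}

.terms_add <- function(terms, coef, lambda, onset) {
  rbind(terms, data.frame(coef = coef, lambda = lambda, onset = onset))
}

# unit-bolus C1 coefficients: C1 = sum(A * exp(-lambda t)) per mg
.c1_unit_coefs <- function(pk) {
  bi <- .biexp(pk)
  with(bi, list(
    lambda = c(alpha, beta),
    A = c((alpha - k21) / (pk$V1 * (alpha - beta)),
          (k21 - beta) / (pk$V1 * (alpha - beta)))
  ))
}

# unit-bolus peripheral amount coefficients: a2 = sum(B * exp(-lambda t))
.a2_unit_coefs <- function(pk) {
  bi <- .biexp(pk)
  with(bi, list(
    lambda = c(alpha, beta),
    B = c(-k12 / (alpha - beta), k12 / (alpha - beta))
  ))
}

# terms for the response of a unit-coefficient set to the regimen's
# zero-order inputs (events: start, amount, duration)
.infusion_terms <- function(events, lambda, coefs) {
  terms <- .terms_new()
  for (i in seq_len(nrow(events))) {
    r0 <- events$amount[i] / events$duration[i]
    if (r0 == 0) next
    for (edge in 1:2) {
      t_on <- if (edge == 1) events$start[i] else events$start[i] + events$duration[i]
      sgn <- if (edge == 1) 1 else -1
      # infusion-forever response: r0 * sum(coef/lambda * (1 - exp(-lambda d)))
      terms <- .terms_add(terms, sgn * r0 * sum(coefs / lambda), 0, t_on)
      terms <- .terms_add(terms, -sgn * r0 * coefs / lambda, lambda, t_on)
    }
  }
  terms
}

.eval_terms <- function(terms, times) {
  if (nrow(terms) == 0L) return(numeric(length(times)))
  d <- outer(times, terms$onset, "-")
  active <- d >= 0
  v <- exp(-sweep(pmax(d, 0), 2, terms$lambda, "*"))
  v[!active] <- 0
  drop(v %*% terms$coef)
}

# integral of each term from its onset to t (for cumulative elimination)
.integrate_terms <- function(terms, times) {
  if (nrow(terms) == 0L) return(numeric(length(times)))
  d <- pmax(outer(times, terms$onset, "-"), 0)
  out <- numeric(length(times))
  for (k in seq_len(nrow(terms))) {
    lam <- terms$lambda[k]
    ik <- if (lam == 0) d[, k] else (1 - exp(-lam * d[, k])) / lam
    out <- out + terms$coef[k] * ik
  }
  out
}

# first-order convolution of a term set with rate ke:
# (a e^{-lam d}) * ke e^{-ke t}  ->  a ke/(ke-lam) (e^{-lam d} - e^{-ke d})
.convolve_terms <- function(terms, ke) {
  if (nrow(terms) == 0L) return(terms)
  # avoid the resonant case ke == lambda (error from the nudge is O(1e-7))
  if (any(abs(ke - terms$lambda) < 1e-8 * ke)) ke <- ke * (1 + 1e-7)
  w <- ke / (ke - terms$lambda)
  out <- data.frame(coef = c(terms$coef * w, -terms$coef * w),
                    lambda = c(terms$lambda, rep(ke, nrow(terms))),
                    onset = c(terms$onset, terms$onset))
  out
}

.check_times <- function(times) {
  if (!is.numeric(times) || length(times) == 0L || any(!is.finite(times)))
    stop("'times' must be a finite numeric vector", call. = FALSE)
  if (any(times < 0))
    stop("'times' must be non-negative", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  times
}

# reversal-effect compartment amount (unit input per idarucizumab event)
.ida_amount_terms <- function(events, K, DUR) {
  terms <- .terms_new()
  for (i in seq_len(nrow(events))) {
    r0 <- 1 / DUR
    for (edge in 1:2) {
      t_on <- if (edge == 1) events$start[i] else events$start[i] + DUR
      sgn <- if (edge == 1) 1 else -1
      terms <- .terms_add(terms, sgn * r0 / K, 0, t_on)
      terms <- .terms_add(terms, -sgn * r0 / K, K, t_on)
    }
  }
  terms
}

#' Simulate dabigatran concentrations for one subject
#'
#' Solves the two-compartment disposition model with zero-order inputs into
#' the central compartment, the effect-site concentration
#' `dCe/dt = keo (C1 - Ce)`, and (if the regimen contains idarucizumab
#' events) the unit-normalised reversal-effect compartment.
#'
#' Two evaluation paths are provided.  The default closed form superposes
#' truncated-exponential solutions of the linear system and is exact up to
#' floating point; `method = "ode"` integrates the same equations with an
#' adaptive stiff-capable solver ([deSolve::lsoda()]) and serves as an
#' independent numerical check.
#'
#' @param pk Subject-level [pk_parameters()].
#' @param reg A [regimen()].
#' @param times Strictly increasing, non-negative evaluation grid (min).
#' @param ida [ida_parameters()]; needed only when the regimen contains
#'   idarucizumab events (defaults from [default_population()]).
#' @param method `"closed"` (default) or `"ode"`.
#'
#' @return A data frame of class `pkpd_sim` with columns `time`, `C1`, `C2`
#'   (mg/L), `Ce` (mg/L), `C_ida` (unit-normalised reversal-compartment
#'   amount) and `eliminated` (cumulative mg cleared).
#' @export
#' @examples
#' pk <- pk_parameters(0.0453, 0.268, 2.94, 9.51, 1.04)
#' reg <- study_regimen(weight = 70, ida_mgkg = NULL)
#' simulate_pk(pk, reg, times = c(5, 15, 30, 60, 90, 120))
simulate_pk <- function(pk, reg, times, ida = NULL,
                        method = c("closed", "ode")) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(reg, "regimen"))
  method <- match.arg(method)
  times <- .check_times(times)
  if (is.null(ida)) ida <- .default_ida()
  if (method == "ode")
    return(.simulate_ode(pk, reg, times, ida))
  dabi <- reg[reg$drug == "dabigatran", , drop = FALSE]
  idae <- reg[reg$drug == "idarucizumab", , drop = FALSE]

  ke <- keo(pk)
  uc <- .c1_unit_coefs(pk)
  c1_terms <- .infusion_terms(dabi, uc$lambda, uc$A)
  a2c <- .a2_unit_coefs(pk)
  a2_terms <- .infusion_terms(dabi, a2c$lambda, a2c$B)
  ce_terms <- .convolve_terms(c1_terms, ke)

  c1 <- .eval_terms(c1_terms, times)
  c2 <- .eval_terms(a2_terms, times) / pk$V2
  ce <- .eval_terms(ce_terms, times)
  elim <- pk$CL * .integrate_terms(c1_terms, times)
  cida <- if (nrow(idae)) {
    .eval_terms(.ida_amount_terms(idae, ida$K_IDA, ida$DUR_IDA), times)
  } else numeric(length(times))

  out <- data.frame(time = times, C1 = pmax(c1, 0), C2 = pmax(c2, 0),
                    Ce = pmax(ce, 0), C_ida = pmax(cida, 0),
                    eliminated = elim)
  class(out) <- c("pkpd_sim", "data.frame")
  out
}

# ODE path: amounts a1, a2, effect-site concentration, reversal amount and
# cumulative elimination, integrated piecewise between event edges so the
# input rate is constant within each segment.
.simulate_ode <- function(pk, reg, times, ida) {
  ke <- keo(pk)
  edges <- sort(unique(c(0, reg$start, reg$start + reg$duration, times)))
  rate_at <- function(t, drug) {
    ev <- reg[reg$drug == drug & reg$start <= t & t < reg$start + reg$duration,
              , drop = FALSE]
    if (drug == "idarucizumab") {
      if (nrow(ev)) sum(1 / ev$duration) else 0   # unit-normalised input
    } else {
      if (nrow(ev)) sum(ev$amount / ev$duration) else 0
    }
  }
  deriv <- function(t, y, p) {
    c1 <- y[1] / pk$V1
    c2 <- y[2] / pk$V2
    list(c(p$r_dabi + pk$Q * (c2 - c1) - pk$CL * c1,
           pk$Q * (c1 - c2),
           ke * (c1 - y[3]),
           p$r_ida - ida$K_IDA * y[4],
           pk$CL * c1))
  }
  y <- c(a1 = 0, a2 = 0, ce = 0, a_ida = 0, elim = 0)
  res <- matrix(NA_real_, length(times), 5)
  for (s in seq_len(length(edges) - 1L)) {
    t0 <- edges[s]; t1 <- edges[s + 1L]
    mid <- (t0 + t1) / 2
    p <- list(r_dabi = rate_at(mid, "dabigatran"),
              r_ida = rate_at(mid, "idarucizumab"))
    grid <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    sol <- deSolve::lsoda(y, grid, deriv, p, rtol = 1e-10, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed between t = ", t0, " and t = ", t1,
           " (lsoda istate ", attr(sol, "istate")[1], ")", call. = FALSE)
    keep <- match(times[times > t0 & times <= t1], sol[, 1])
    if (length(keep))
      res[times > t0 & times <= t1, ] <- sol[keep, -1, drop = FALSE]
    y <- sol[nrow(sol), -1]
  }
  at0 <- times == 0
  if (any(at0)) res[at0, ] <- 0
  out <- data.frame(time = times,
                    C1 = pmax(res[, 1] / pk$V1, 0),
                    C2 = pmax(res[, 2] / pk$V2, 0),
                    Ce = pmax(res[, 3], 0),
                    C_ida = pmax(res[, 4], 0),
                    eliminated = res[, 5])
  class(out) <- c("pkpd_sim", "data.frame")
  out
}

#' Effect-site concentration from a sampled plasma trajectory
#'
#' First-order lag `dCe/dt = keo (C1 - Ce)` applied to a plasma
#' concentration trajectory sampled on a grid, assuming `C1` is piecewise
#' linear between grid points (the update within each interval is exact for
#' a linear segment).  For model-based simulation [simulate_pk()] computes
#' the effect site in closed form; this helper serves arbitrary sampled
#' inputs.
#'
#' @param times Strictly increasing time grid (min).
#' @param c1 Plasma concentrations on `times` (mg/L).
#' @param keo Equilibration rate constant (1/min).
#' @param ce0 Initial effect-site concentration (default 0).
#'
#' @return Numeric vector of effect-site concentrations on `times`.
#' @export
effect_site <- function(times, c1, keo, ce0 = 0) {
  if (!is.numeric(keo) || length(keo) != 1L || keo <= 0)
    stop("effect_site: 'keo' must be a single positive number", call. = FALSE)
  times <- .check_times(times)
  if (length(c1) != length(times))
    stop("effect_site: 'c1' and 'times' lengths differ", call. = FALSE)
  ce <- numeric(length(times))
  ce[1] <- ce0
  for (k in seq_len(length(times) - 1L)) {
    h <- times[k + 1L] - times[k]
    s <- (c1[k + 1L] - c1[k]) / h
    e <- exp(-keo * h)
    ce[k + 1L] <- ce[k] * e + c1[k] * (1 - e) + s * (h - (1 - e) / keo)
  }
  ce
}

#' Sigmoid Emax reaction-time response to dabigatran
#'
#' `R = E0 + Emax * Ce^N / (Ce50^N + Ce^N)`: baseline reaction time plus a
#' saturating drug effect, monotone in `Ce` and bounded by `E0 + Emax`.
#'
#' @param ce Effect-site concentration(s), mg/L, `>= 0`.
#' @param pd [pd_parameters()].
#'
#' @return Reaction time(s), min.
#' @export
#' @examples
#' pd <- pd_parameters(E0 = 6, Emax = 180, Ce50 = 64.2, N = 1)
#' emax_response(64.2, pd)  # E0 + Emax/2
emax_response <- function(ce, pd) {
  stopifnot(inherits(pd, "pd_parameters"))
  if (any(!is.finite(ce)) || any(ce < 0))
    stop("emax_response: 'ce' must be non-negative", call. = FALSE)
  cn <- ce^pd$N
  pd$E0 + pd$Emax * cn / (pd$Ce50^pd$N + cn)
}

#' Idarucizumab reversal-effect trajectory
#'
#' Unit amount enters the reversal-effect compartment as a zero-order input
#' over `DUR_IDA` at each idarucizumab dose time and is eliminated at rate
#' `K_IDA`; the effect on reaction time is `-SLOPE_IDA` times the
#' compartment amount (always `<= 0`, zero before the first dose and
#' washing out after it).
#'
#' @param reg A [regimen()] (only its idarucizumab events are used).
#' @param ida [ida_parameters()].
#' @param times Strictly increasing evaluation grid (min).
#'
#' @return Numeric vector of reversal effects (min, `<= 0`).
#' @export
idarucizumab_effect <- function(reg, ida, times) {
  stopifnot(inherits(reg, "regimen"), inherits(ida, "ida_parameters"))
  times <- .check_times(times)
  ev <- reg[reg$drug == "idarucizumab", , drop = FALSE]
  if (nrow(ev) == 0L) return(numeric(length(times)))
  amt <- .eval_terms(.ida_amount_terms(ev, ida$K_IDA, ida$DUR_IDA), times)
  -ida$SLOPE_IDA * pmax(amt, 0)
}

#' Predicted reaction time from a simulated trajectory
#'
#' The observed reaction time is the sum of the dabigatran effect (sigmoid
#' Emax of the effect-site concentration) and the idarucizumab reversal
#' effect, floored at zero (reaction times are physically non-negative).
#'
#' @param sim A `pkpd_sim` data frame from [simulate_pk()] (columns `Ce`
#'   and `C_ida` are used).
#' @param pd [pd_parameters()].
#' @param ida [ida_parameters()] (supplies `SLOPE_IDA`).
#'
#' @return `sim` with an added column `R` (min).
#' @export
predict_r_time <- function(sim, pd, ida) {
  stopifnot(inherits(sim, "pkpd_sim"), inherits(pd, "pd_parameters"),
            inherits(ida, "ida_parameters"))
  sim$R <- pmax(emax_response(sim$Ce, pd) - ida$SLOPE_IDA * sim$C_ida, 0)
  sim
}

#' Simulate all model channels for one subject
#'
#' Convenience wrapper: [simulate_pk()] followed by [predict_r_time()]
#' using a subject-level parameter set from [individual_parameters()].
#'
#' @param pars Output of [individual_parameters()] (elements `pk`, `pd`,
#'   `ida`).
#' @param reg A [regimen()].
#' @param times Evaluation grid (min).
#' @param method Passed to [simulate_pk()].
#'
#' @return A `pkpd_sim` data frame including the `R` channel.
#' @export
simulate_subject <- function(pars, reg, times, method = c("closed", "ode")) {
  sim <- simulate_pk(pars$pk, reg, times, ida = pars$ida,
                     method = match.arg(method))
  predict_r_time(sim, pars$pd, pars$ida)
}

#' Mass balance of a simulated trajectory
#'
#' For the closed-form or ODE paths, the drug administered up to each time
#' must equal drug in body (central + peripheral) plus drug eliminated.
#'
#' @param sim A `pkpd_sim` from [simulate_pk()].
#' @param pk The [pk_parameters()] used to produce it.
#' @param reg The [regimen()] used to produce it.
#'
#' @return Data frame with columns `time`, `administered`, `accounted`
#'   (A1 + A2 + eliminated) and `relative_error`.
#' @export
mass_balance <- function(sim, pk, reg) {
  dabi <- reg[reg$drug == "dabigatran", , drop = FALSE]
  adm <- vapply(sim$time, function(t) {
    if (nrow(dabi) == 0L) return(0)
    frac <- pmin(pmax((t - dabi$start) / dabi$duration, 0), 1)
    sum(dabi$amount * frac)
  }, numeric(1))
  acc <- sim$C1 * pk$V1 + sim$C2 * pk$V2 + sim$eliminated
  data.frame(time = sim$time, administered = adm, accounted = acc,
             relative_error = ifelse(adm > 0, abs(acc - adm) / adm, abs(acc)))
}
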