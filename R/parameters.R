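#' Disposition (pharmacokinetic) parameters
#'
#' Container for the two-compartment dabigatran disposition parameters plus
#' the plasma--effect-site equilibration half-time.  All values are typical
#' (population) values standardised to a 70 kg body weight; use
#' [individual_parameters()] to obtain subject-level values.
#'
#' @param CL Clearance (L/min per 70 kg).
#' @param Q Intercompartment clearance (L/min per 70 kg).
#' @param V1 Central volume of distribution (L per 70 kg).
#' @param V2 Peripheral volume of distribution (L per 70 kg).
#' @param t_half_keo Plasma--effect-site equilibration half-time (min).
#'   The rate constant is `keo = log(2) / t_half_keo`.
#'
#' @return An object of class `pk_parameters` (named list).
#' @seealso [pd_parameters()], [ida_parameters()], [simulate_pk()]
#' @export
#' @examples
#' pk_parameters(CL = 0.0453, Q = 0.268, V1 = 2.94, V2 = 9.51,
#'               t_half_keo = 1.04)
pk_parameters <- function(CL, Q, V1, V2, t_half_keo) {
  p <- list(CL = CL, Q = Q, V1 = V1, V2 = V2, t_half_keo = t_half_keo)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("pk_parameters: '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  structure(p, class = "pk_parameters")
}

#' @describeIn pk_parameters Equilibration rate constant keo (1/min).
#' @param pk A `pk_parameters` object.
#' @export
keo <- function(pk) log(2) / pk$t_half_keo

#' Sigmoid Emax response parameters for reaction time
#'
#' Parameters of the sigmoid Emax model linking dabigatran effect-site
#' concentration to thromboelastographic reaction time (R-time).
#'
#' @param E0 Baseline reaction time (min), `>= 0`.
#' @param Emax Maximum drug-induced increase in reaction time (min).
#' @param Ce50 Effect-site concentration at half-maximal effect (mg/L).
#' @param N Hill coefficient (dimensionless steepness).
#'
#' @return An object of class `pd_parameters`.
#' @export
pd_parameters <- function(E0, Emax, Ce50, N = 1) {
  if (!is.numeric(E0) || length(E0) != 1L || E0 < 0)
    stop("pd_parameters: 'E0' must be a single non-negative number",
         call. = FALSE)
  for (nm in c("Emax", "Ce50", "N")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("pd_parameters: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(list(E0 = E0, Emax = Emax, Ce50 = Ce50, N = N),
            class = "pd_parameters")
}

#' Idarucizumab reversal-effect parameters
#'
#' The reversal agent is modelled empirically: each idarucizumab dose puts a
#' unit amount into a reversal-effect compartment as a zero-order input of
#' duration `DUR_IDA`; the compartment empties with first-order rate
#' `K_IDA`, and its (unit-normalised) amount lowers R-time linearly with
#' slope `SLOPE_IDA`.  Because the input is unit-normalised, dose
#' proportionality across idarucizumab dose levels is not assumed.
#'
#' @param K_IDA First-order elimination rate constant (1/min).
#' @param DUR_IDA Zero-order input duration (min).
#' @param SLOPE_IDA R-time decrease per unit reversal-compartment amount
#'   (min per unit).
#'
#' @return An object of class `ida_parameters`.
#' @export
ida_parameters <- function(K_IDA, DUR_IDA, SLOPE_IDA) {
  p <- list(K_IDA = K_IDA, DUR_IDA = DUR_IDA, SLOPE_IDA = SLOPE_IDA)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("ida_parameters: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(p, class = "ida_parameters")
}

#' Allometric scaling of a standardised parameter
#'
#' Scales a parameter standardised to the 70 kg reference weight to a
#' subject of weight `w` by the power law `p_std * (w / 70)^exponent`.
#' Clearances use exponent 0.75 and distribution volumes exponent 1.
#'
#' @param p_std Standardised parameter value (per 70 kg).
#' @param w Subject body weight (kg).
#' @param exponent Allometric exponent (0.75 for clearances, 1 for volumes).
#' @param w_std Reference weight (kg); 70 by convention.
#'
#' @return The subject-scale parameter value.
#' @export
#' @examples
#' scale_parameter(0.0453, 35, 0.75)   # clearance for a 35 kg sheep
scale_parameter <- function(p_std, w, exponent, w_std = 70) {
  if (any(p_std <= 0) || !all(is.finite(p_std)))
    stop("scale_parameter: 'p_std' must be positive", call. = FALSE)
  if (any(w <= 0) || !all(is.finite(w)))
    stop("scale_parameter: 'w' must be positive", call. = FALSE)
  p_std * (w / w_std)^exponent
}

# Allometric exponents by parameter name; parameters absent here are not
# weight-scaled (equilibration half-time and all PD/reversal parameters).
.allometric_exponents <- c(CL = 0.75, Q = 0.75, V1 = 1, V2 = 1)

#' Subject-level parameters from population values and random effects
#'
#' Combines allometric weight scaling with exponential (log-normal)
#' between-subject random effects: each parameter is
#' `typical * (w/70)^exp * exp(eta)`.  Clearances scale with exponent 0.75,
#' volumes with exponent 1; the equilibration half-time and all
#' pharmacodynamic parameters are not weight-scaled.
#'
#' @param pop A [population_model()].
#' @param weight Subject body weight (kg).
#' @param eta Named numeric vector of log-scale random effects.  Names must
#'   be parameter names of the model (e.g. `"CL"`, `"E0"`); missing names
#'   default to zero (population-typical subject).
#'
#' @return A named list with elements `pk` (`pk_parameters`), `pd`
#'   (`pd_parameters`) and `ida` (`ida_parameters`) at subject scale.
#' @export
#' @examples
#' pop <- default_population()
#' individual_parameters(pop, weight = 50, eta = c(CL = 0.3))$pk$CL
individual_parameters <- function(pop, weight, eta = numeric(0)) {
  stopifnot(inherits(pop, "population_model"))
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0)
    stop("individual_parameters: 'weight' must be a single positive number",
         call. = FALSE)
  th <- theta_vector(pop)
  if (length(eta)) {
    if (is.null(names(eta)) || any(!nzchar(names(eta))))
      stop("individual_parameters: 'eta' must be a named vector", call. = FALSE)
    unknown <- setdiff(names(eta), names(th))
    if (length(unknown))
      stop("individual_parameters: unknown eta key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- th
  for (nm in names(th)) {
    ex <- unname(.allometric_exponents[nm])
    val <- if (!is.na(ex)) scale_parameter(th[[nm]], weight, ex) else th[[nm]]
    e <- if (nm %in% names(eta)) eta[[nm]] else 0
    out[[nm]] <- val * exp(e)
  }
  list(
    pk = pk_parameters(out[["CL"]], out[["Q"]], out[["V1"]], out[["V2"]],
                       out[["t_half_keo"]]),
    pd = pd_parameters(out[["E0"]], out[["Emax"]], out[["Ce50"]], out[["N"]]),
    ida = ida_parameters(out[["K_IDA"]], out[["DUR_IDA"]], out[["SLOPE_IDA"]])
  )
}
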