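#' Dominant growth exponent of the mean-field insertion system
#'
#' The mean-field growth law couples membrane area and active insertion
#' sites: `dA/dt = kIns * n`, `dn/dt = kOn * A - n / tau`. Its dominant
#' eigenvalue `lambda` is the positive root of
#' `lambda^2 + lambda / tau = kOn * kIns`, so area grows asymptotically as
#' `exp(lambda * t)` with doubling time `log(2) / lambda`.
#'
#' @param kOn initiation rate per area (um^-2 s^-1).
#' @param kIns insertion rate per event (um^2 s^-1).
#' @param tau mean event duration (s).
#' @return the dominant exponent lambda (s^-1).
#' @export
growthRate <- function(kOn, kIns, tau) {
  stopifnot(kOn >= 0, kIns > 0, tau > 0)
  (-1 / tau + sqrt(1 / tau^2 + 4 * kOn * kIns)) / 2
}

#' Mean event duration implied by a doubling time
#'
#' Inverts the growth law: given the initiation and insertion rates and a
#' target doubling time, returns the mean event duration
#' `tau = lambda / (kOn * kIns - lambda^2)` with `lambda = log(2)/tDouble`,
#' the unique tau making lambda the dominant eigenvalue of the mean-field
#' system. Feasibility requires `kOn * kIns > lambda^2`: slower kinetics
#' cannot reach the requested growth rate for any event duration.
#'
#' @param kOn initiation rate per area (um^-2 s^-1).
#' @param kIns insertion rate per event (um^2 s^-1).
#' @param tDouble doubling time (s).
#' @return mean event duration tau (s).
#' @examples
#' solveTau(0.004, 0.00064, 90 * 60)  # ~50 s
#' @export
solveTau <- function(kOn, kIns, tDouble) {
  stopifnot(kOn > 0, kIns > 0, tDouble > 0)
  lambda <- log(2) / tDouble
  if (kOn * kIns <= lambda^2)
    stop(sprintf(
      "infeasible kinetics: kOn*kIns = %.3g <= (log(2)/tDouble)^2 = %.3g; growth cannot reach the requested rate",
      kOn * kIns, lambda^2))
  lambda / (kOn * kIns - lambda^2)
}

#' Exact mean-field trajectory
#'
#' Solves the linear mean-field system `dA/dt = kIns * n`,
#' `dn/dt = kOn * A - n / tau` exactly through the eigendecomposition of
#' its 2 x 2 matrix (the matrix exponential in closed form), not by time
#' discretization. The two eigenvalues are always real and distinct.
#'
#' @param A0 initial cylindrical membrane area (um^2).
#' @param n0 initial number of active insertion sites.
#' @param params a [KineticParams-class].
#' @param times evaluation times (s).
#' @return data.frame with columns `t`, `A`, `n`.
#' @examples
#' p <- kineticParams(0.004, 0.00064, tDouble = 5400)
#' ## start on the dominant eigenvector: area doubles exactly at tDouble
#' A0 <- 6.283; n0 <- steadySiteConcentration(p) * A0
#' meanfieldTrajectory(A0, n0, p, c(0, 5400))
#' @export
meanfieldTrajectory <- function(A0, n0, params, times) {
  stopifnot(A0 > 0, n0 >= 0)
  kon <- params@kOn; kins <- params@kIns; tu <- params@tau
  disc <- sqrt(1 / tu^2 + 4 * kon * kins)
  l1 <- (-1 / tu + disc) / 2   # dominant
  l2 <- (-1 / tu - disc) / 2
  # eigenvectors of [[0, kins], [kon, -1/tau]]: (kins, l) for eigenvalue l
  # solve (A0, n0) = c1*(kins, l1) + c2*(kins, l2)
  det <- kins * (l2 - l1)
  c1 <- (A0 * l2 - n0 * kins) / det
  c2 <- -(A0 * l1 - n0 * kins) / det
  e1 <- exp(l1 * times); e2 <- exp(l2 * times)
  data.frame(t = times,
             A = c1 * kins * e1 + c2 * kins * e2,
             n = c1 * l1 * e1 + c2 * l2 * e2)
}

#' Steady-state concentration of insertion sites
#'
#' Along the dominant eigenvector the site concentration is constant:
#' `n / A = lambda / kIns`. For the headline kinetics (kOn = 0.004,
#' kIns = 0.00064, 90 min doubling) this is ~0.20 sites per um^2.
#'
#' @param params a [KineticParams-class].
#' @return sites per um^2.
#' @export
steadySiteConcentration <- function(params)
  growthRate(params@kOn, params@kIns, params@tau) / params@kIns

#' Sample insertion-event initiations and durations
#'
#' One kinetic Monte Carlo step of the event process: the number of new
#' initiations in `dt` is Poisson with mean `kOn * area * dt`, and each new
#' event receives an exponentially distributed duration with mean `tau`.
#' Positions (assigned by the caller) are uniform over the cylindrical
#' surface.
#'
#' @param area current cylindrical area (um^2).
#' @param dt time step (s).
#' @param params a [KineticParams-class].
#' @return list with `count` (number of initiations) and `durations`
#'   (numeric vector of sampled event durations, s).
#' @export
sampleEvents <- function(area, dt, params) {
  stopifnot(area >= 0, dt > 0)
  n <- rpois(1L, params@kOn * area * dt)
  list(count = n, durations = rexp(n, rate = 1 / params@tau))
}

#' Simulation time step from the kinetic rates
#'
#' `dt = min(tau / 20, 1 / (20 * kOn * area), dtMax)`: twenty steps per mean
#' event duration and per mean initiation interval, so the exponential
#' duration distribution and the Poisson initiation process are finely
#' sampled, capped at `dtMax` (default 0.5 s).
#'
#' @param params a [KineticParams-class].
#' @param area current cylindrical area (um^2).
#' @param dtMax upper cap on the step (s).
#' @return time step (s).
#' @export
timeStep <- function(params, area, dtMax = 0.5)
  min(params@tau / 20, 1 / (20 * params@kOn * area), dtMax)
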