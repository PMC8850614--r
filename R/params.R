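#' Physical parameters of the self-propelled particle model
#'
#' Bundles the parameters of the spatial dynamics: `N` agents self-propelled at
#' speed `v0`, interacting (alignment and soft-core repulsion) within range
#' `r_int`, with angular noise intensity `sigma` (rad per square-root time) and
#' alignment relaxation time `tau`, in a periodic square arena of side `L`,
#' integrated with step `dt`.
#'
#' The pair (`sigma`, `tau`) can equivalently be given through the two
#' dimensionless control parameters of the model: the Peclet number
#' `Pe = v0 / (r_int * sigma^2)` (persistence of individual motion) and the
#' coupling strength `g = 1 / (tau * sigma^2)` (alignment relative to noise).
#' If `L` is missing it is computed from the packing fraction
#' `phi_pack = N * pi * r_int^2 / (4 * L^2)`.
#'
#' The default integration step is
#' `min(0.1, tau / 20, 0.02 * r_int / v0)`: it resolves the alignment
#' relaxation at strong coupling and keeps the deterministic per-step
#' displacement well below the interaction range. The factor 20 on the
#' relaxation time is empirical: at very strong coupling (g = 1024) a step
#' of `tau / 10` produces spurious cohesion — the polarized homogeneous
#' state acquires large step-induced clusters — which vanishes from
#' `tau / 20` down, while genuinely clustered states are insensitive.
#'
#' @param N number of agents (integer, >= 1).
#' @param v0 self-propulsion speed.
#' @param r_int interaction range (alignment, repulsion and contact share it).
#' @param sigma,tau angular noise intensity and alignment relaxation time;
#'   supply either these or (`pe`, `g`).
#' @param pe,g dimensionless Peclet number and coupling strength.
#' @param phi_pack packing fraction used to derive `L` when `L` is `NULL`.
#' @param L arena side length; derived from `phi_pack` if `NULL`.
#' @param dt integration step; a stability-based default is chosen if `NULL`.
#' @return An object of class `abp_params` (a named list) with fields
#'   `N, v0, r_int, sigma, tau, L, dt` and derived `pe`, `g`, `phi_pack`.
#' @examples
#' p <- abp_params(N = 2500, pe = 32, g = 1)
#' p$L # about 80.9 at packing fraction 0.3
#' @export
abp_params <- function(N, v0 = 0.2, r_int = 1, sigma = NULL, tau = NULL,
                       pe = NULL, g = NULL, phi_pack = 0.3, L = NULL,
                       dt = NULL) {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != round(N))
    stop("N must be a positive integer", call. = FALSE)
  if (!is.numeric(r_int) || length(r_int) != 1 || !is.finite(r_int) || r_int <= 0)
    stop("r_int must be a positive number", call. = FALSE)
  # v0 = 0 is admitted as the static variant (frozen positions, useful for
  # contagion-on-fixed-graph checks); the dimensionless view then has Pe = 0
  if (!is.numeric(v0) || length(v0) != 1 || !is.finite(v0) || v0 < 0)
    stop("v0 must be a non-negative number", call. = FALSE)
  if (is.null(sigma) != is.null(tau))
    stop("supply both sigma and tau, or neither", call. = FALSE)
  if (is.null(sigma)) {
    if (is.null(pe) || is.null(g))
      stop("supply either (sigma, tau) or (pe, g)", call. = FALSE)
    st <- dimensionless_to_physical(pe, g, v0 = v0, r_int = r_int)
    sigma <- st$sigma
    tau <- st$tau
  }
  if (sigma <= 0 || tau <= 0)
    stop("sigma and tau must be positive", call. = FALSE)
  if (is.null(L)) {
    L <- arena_side_from_packing(N, r_int = r_int, phi_pack = phi_pack)
  }
  if (L <= 0) stop("L must be positive", call. = FALSE)
  if (is.null(dt)) {
    dt <- min(0.1, tau / 20, if (v0 > 0) 0.02 * r_int / v0 else Inf)
  }
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  dl <- if (v0 > 0) {
    physical_to_dimensionless(sigma, tau, v0 = v0, r_int = r_int)
  } else {
    list(pe = 0, g = 1 / (tau * sigma^2))
  }
  structure(
    list(N = as.integer(N), v0 = v0, r_int = r_int, sigma = sigma, tau = tau,
         L = L, dt = dt, pe = dl$pe, g = dl$g,
         phi_pack = packing_fraction(N, r_int, L)),
    class = "abp_params"
  )
}

#' @export
print.abp_params <- function(x, ...) {
  cat(sprintf(
    "<abp_params> N=%d v0=%g r_int=%g sigma=%.5g tau=%.5g L=%.4g dt=%g\n",
    x$N, x$v0, x$r_int, x$sigma, x$tau, x$L, x$dt))
  cat(sprintf("  Pe=%.5g g=%.5g packing=%.4g\n", x$pe, x$g, x$phi_pack))
  invisible(x)
}

#' Convert dimensionless control parameters to noise and relaxation time
#'
#' Inverts the definitions `Pe = v0 / (r_int * sigma^2)` and
#' `g = 1 / (tau * sigma^2)`, giving `sigma = sqrt(v0 / (r_int * Pe))` and
#' `tau = 1 / (g * sigma^2)`.
#'
#' @param pe Peclet number (> 0).
#' @param g coupling strength (> 0).
#' @param v0 self-propulsion speed (> 0).
#' @param r_int interaction range (> 0).
#' @return A list with components `sigma` and `tau`.
#' @examples
#' dimensionless_to_physical(32, 1, v0 = 0.2, r_int = 1) # sigma^2 = 0.00625
#' @export
dimensionless_to_physical <- function(pe, g, v0 = 0.2, r_int = 1) {
  vals <- c(pe = pe, g = g, v0 = v0, r_int = r_int)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all arguments must be positive and finite", call. = FALSE)
  sigma2 <- v0 / (r_int * pe)
  list(sigma = sqrt(sigma2), tau = 1 / (g * sigma2))
}

#' @rdname dimensionless_to_physical
#' @param sigma angular noise intensity (> 0).
#' @param tau alignment relaxation time (> 0).
#' @export
physical_to_dimensionless <- function(sigma, tau, v0 = 0.2, r_int = 1) {
  vals <- c(sigma = sigma, tau = tau, v0 = v0, r_int = r_int)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all arguments must be positive and finite", call. = FALSE)
  list(pe = v0 / (r_int * sigma^2), g = 1 / (tau * sigma^2))
}

#' Arena side length for a prescribed packing fraction
#'
#' Solves `phi_pack = N * pi * r_int^2 / (4 * L^2)` for `L`.
#'
#' @param N number of agents.
#' @param r_int interaction range.
#' @param phi_pack packing fraction in (0, 1).
#' @return The arena side length `L`.
#' @examples
#' arena_side_from_packing(10000, 1, 0.3) # about 161.8
#' @export
arena_side_from_packing <- function(N, r_int = 1, phi_pack = 0.3) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  if (!is.finite(phi_pack) || phi_pack <= 0 || phi_pack >= 1)
    stop("phi_pack must lie in (0, 1)", call. = FALSE)
  sqrt(N * pi * r_int^2 / (4 * phi_pack))
}

#' @rdname arena_side_from_packing
#' @param L arena side length.
#' @export
packing_fraction <- function(N, r_int, L) N * pi * r_int^2 / (4 * L^2)

#' SIR contagion parameters
#'
#' The contagion is parameterized by the base transmission rate `beta_b`
#' (per unit time, per infected contact) and the recovery rate `gamma`.
#' Two derived views are carried along: the infection-lifetime transmissibility
#' `theta = beta_b / gamma` and the mean infectious duration
#' `t_inf = 1 / gamma`.
#'
#' @param beta_b base transmission rate (>= 0).
#' @param gamma recovery rate (> 0).
#' @return An object of class `sir_params`.
#' @examples
#' sir_params_from_theta(2, 20) # beta_b = 0.1, gamma = 0.05
#' @export
sir_params <- function(beta_b, gamma) {
  if (!is.finite(beta_b) || beta_b < 0)
    stop("beta_b must be >= 0", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0)
    stop("gamma must be > 0", call. = FALSE)
  structure(
    list(beta_b = beta_b, gamma = gamma,
         theta = beta_b / gamma, t_inf = 1 / gamma),
    class = "sir_params"
  )
}

#' @rdname sir_params
#' @param theta infection-lifetime transmissibility `beta_b / gamma` (>= 0).
#' @param t_inf mean infectious duration `1 / gamma` (> 0).
#' @export
sir_params_from_theta <- function(theta, t_inf) {
  if (!is.finite(theta) || theta < 0)
    stop("theta must be >= 0", call. = FALSE)
  if (!is.finite(t_inf) || t_inf <= 0)
    stop("t_inf must be > 0", call. = FALSE)
  sir_params(beta_b = theta / t_inf, gamma = 1 / t_inf)
}

#' @export
print.sir_params <- function(x, ...) {
  cat(sprintf("<sir_params> beta_b=%g gamma=%g (theta=%g, t_inf=%g)\n",
              x$beta_b, x$gamma, x$theta, x$t_inf))
  invisible(x)
}
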