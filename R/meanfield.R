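#' Effective basic reproduction number from measured contact statistics
#'
#' Homogeneous-mixing baseline for states without persistent spatial
#' structure: the per-contact transmission probability is linearized as
#' `beta_b * mean_contact_duration`, and an agent accrues
#' `mean_contact_rate / gamma` contacts over its infectious period, giving
#' `R0 = (beta_b * mean_contact_duration) * (mean_contact_rate / gamma)`.
#' The linearization presumes `beta_b * mean_contact_duration` well below 1;
#' a warning is emitted above 0.5.
#'
#' @param beta_b base transmission rate.
#' @param gamma recovery rate.
#' @param stats a [contact_statistics()] result (or any list with
#'   `mean_contact_rate` and `mean_contact_duration`).
#' @return Dimensionless `R0 >= 0`.
#' @examples
#' st <- tibble::tibble(mean_contact_rate = 1, mean_contact_duration = 1)
#' effective_R0(0.1, 0.05, st) # 2
#' @export
effective_R0 <- function(beta_b, gamma, stats) {
  stopifnot(beta_b >= 0, gamma > 0)
  p_contact <- beta_b * stats$mean_contact_duration
  if (p_contact > 0.5)
    warning("beta_b * mean_contact_duration > 0.5: linearized per-contact ",
            "probability is unreliable", call. = FALSE)
  p_contact * stats$mean_contact_rate / gamma
}

#' Final outbreak size under homogeneous mixing
#'
#' Solves the classical final-size relation
#' `r_inf = 1 - s0 * exp(-R0 * r_inf)` for the eventual recovered fraction,
#' taking the largest root in `[i0, 1]` by bracketed root-finding (tolerance
#' 1e-10). Continuous and non-decreasing in `R0`; equals `i0` at `R0 = 0`
#' (only the seeds recover) and tends to 1 as `R0` grows.
#'
#' @param R0 basic reproduction number (vectorized, >= 0).
#' @param i0 initial infected fraction.
#' @param s0 initial susceptible fraction (defaults to `1 - i0`).
#' @return Recovered fraction(s) in `[i0, 1]`.
#' @examples
#' final_size(2, i0 = 1e-9) # about 0.7968
#' @export
final_size <- function(R0, i0 = 0, s0 = 1 - i0) {
  stopifnot(all(R0 >= 0), i0 >= 0, s0 >= 0, s0 + i0 <= 1)
  one <- function(r0) {
    f <- function(r) r - 1 + s0 * exp(-r0 * r)
    lo <- i0
    flo <- f(lo)
    if (abs(flo) < 1e-12) {
      # r = i0 is itself a root; a larger root exists iff f dips negative
      lo2 <- lo + 1e-8
      if (lo2 >= 1 || f(lo2) >= 0) return(lo)
      lo <- lo2
    } else if (flo > 0) {
      return(lo) # guard: cannot occur for s0 + i0 <= 1
    }
    uniroot(f, c(lo, 1), tol = 1e-10)$root
  }
  vapply(R0, one, numeric(1))
}


#' Append the homogeneous-mixing prediction to a sweep summary
#'
#' Convenience for comparing measured sweep means with the mean-field
#' baseline: computes `R0` per sweep point from the supplied contact
#' statistics via [effective_R0()] and adds a `meanfield_prediction` column
#' with [final_size()].
#'
#' @param sweep a [theta_sweep()] / [tinf_sweep()] result.
#' @param stats a [contact_statistics()] result measured on the same
#'   collective state.
#' @return The sweep with an extra `meanfield_prediction` column.
#' @export
meanfield_prediction <- function(sweep, stats) {
  r0 <- purrr::map2_dbl(sweep$theta, sweep$t_inf, function(th, ti) {
    ep <- sir_params_from_theta(th, ti)
    suppressWarnings(effective_R0(ep$beta_b, ep$gamma, stats))
  })
  sweep$meanfield_prediction <- final_size(r0, i0 = sweep$seed_fraction[1])
  sweep
}
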