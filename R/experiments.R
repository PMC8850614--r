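#' Burn in a set of independent stationary spatial states
#'
#' Convenience wrapper producing `n_states` independently converged states
#' (fresh random initial condition and noise stream per replicate), the raw
#' material for replicate outbreak ensembles.
#'
#' @param params an [abp_params()] object.
#' @param n_states number of independent replicates.
#' @param seed integer master seed; replicate seeds derive from it.
#' @param ... passed to [run_burn_in()] (`window`, `tol`, `t_max`, ...).
#' @return A list of `swarm_burnin` objects.
#' @export
burn_in_states <- function(params, n_states = 5, seed = 1, ...) {
  purrr::map(seq_len(n_states), function(s) {
    run_burn_in(params, seed = derive_seed(seed, paste0("state-", s)), ...)
  })
}

#' Replicate outbreak ensemble at one parameter point
#'
#' The measurement protocol: burn in `n_states` independent stationary spatial
#' states (or reuse the ones supplied), then start `n_outbreaks` contagion
#' processes on each, every outbreak seeded with a fresh random 1% (by
#' default) of the agents. Reports per-run final recovered fractions and
#' their mean and standard deviation. Runs that hit the time cap are kept in
#' the run table, flagged, and by default excluded from the mean.
#'
#' @param params an [abp_params()] object.
#' @param ep a [sir_params()] object.
#' @param n_states number of independent stationary states.
#' @param n_outbreaks outbreaks started on each state.
#' @param seed_fraction fraction of agents infected at the start of each
#'   outbreak.
#' @param states optional list of burned-in states (`swarm_burnin` objects or
#'   [particle_state()]s); burned fresh when `NULL`.
#' @param exclude_unfinished drop unfinished runs from the summary mean/sd.
#' @param seed integer master seed.
#' @param burnin named list of arguments forwarded to [run_burn_in()].
#' @param outbreak named list of arguments forwarded to [run_outbreak()].
#' @return An object of class `swarm_ensemble`: list with `runs` (one row per
#'   outbreak), `summary` (one row), `states`, `params`, `ep`.
#' @export
run_ensemble <- function(params, ep, n_states = 5, n_outbreaks = 10,
                         seed_fraction = 0.01, states = NULL,
                         exclude_unfinished = TRUE, seed = 1,
                         burnin = list(), outbreak = list()) {
  if (is.null(states)) {
    states <- do.call(burn_in_states,
                      c(list(params = params, n_states = n_states,
                             seed = seed), burnin))
  }
  states <- purrr::map(states, function(s) if (inherits(s, "swarm_burnin")) s$state else s)
  n_states <- length(states)
  n_seed <- max(1L, round(seed_fraction * params$N))
  runs <- purrr::map_dfr(seq_len(n_states), function(si) {
    purrr::map_dfr(seq_len(n_outbreaks), function(oi) {
      tag <- paste0("s", si, "-o", oi)
      st <- seed_infections(states[[si]], n_seed = n_seed, mode = "random",
                            seed = derive_seed(seed, paste0("seeding-", tag)))
      ob <- do.call(run_outbreak,
                    c(list(state = st, params = params, ep = ep,
                           seed = derive_seed(seed, paste0("outbreak-", tag))),
                      outbreak))
      dplyr::bind_cols(tibble::tibble(state_id = si, outbreak_id = oi),
                       ob$final)
    })
  })
  used <- if (exclude_unfinished) dplyr::filter(runs, .data$finished) else runs
  summary <- tibble::tibble(
    pe = params$pe, g = params$g, theta = ep$theta, t_inf = ep$t_inf,
    mean_rho_r = mean(used$rho_r_final),
    sd_rho_r = if (nrow(used) > 1) sd(used$rho_r_final) else 0,
    n_runs = nrow(runs),
    n_unfinished = sum(!runs$finished),
    seed_fraction = n_seed / params$N
  )
  structure(
    list(runs = runs, summary = summary, states = states, params = params,
         ep = ep, seed = seed),
    class = "swarm_ensemble"
  )
}

#' @export
print.swarm_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<swarm_ensemble> (Pe=%g, g=%g, theta=%g, t_inf=%g): mean rho_R=%.4f sd=%.4f (%d runs, %d unfinished)\n",
    s$pe, s$g, s$theta, s$t_inf, s$mean_rho_r, s$sd_rho_r, s$n_runs,
    s$n_unfinished))
  invisible(x)
}

#' @method tidy swarm_ensemble
#' @export
tidy.swarm_ensemble <- function(x, ...) x$runs

#' @method glance swarm_ensemble
#' @export
glance.swarm_ensemble <- function(x, ...) x$summary

sweep_core <- function(params, eps, axis, axis_values, n_states, n_outbreaks,
                       seed_fraction, states, seed, burnin, outbreak, ...) {
  if (is.null(states)) {
    states <- do.call(burn_in_states,
                      c(list(params = params, n_states = n_states,
                             seed = seed), burnin))
  }
  ens <- purrr::map(eps, function(ep) {
    run_ensemble(params, ep, n_states = n_states, n_outbreaks = n_outbreaks,
                 seed_fraction = seed_fraction, states = states,
                 seed = derive_seed(seed, paste0(axis, "-", ep$theta, "-", ep$t_inf)),
                 outbreak = outbreak, ...)
  })
  out <- purrr::map_dfr(ens, glance)
  attr(out, "runs") <- purrr::map2_dfr(ens, axis_values, function(e, v) {
    dplyr::mutate(e$runs, !!axis := v, .before = 1)
  })
  attr(out, "axis") <- axis
  attr(out, "states") <- states
  class(out) <- c("swarm_sweep", class(tibble::tibble()))
  out
}

#' Sweep the epidemic parameters at a fixed collective state
#'
#' `theta_sweep()` varies the infection-lifetime transmissibility at fixed
#' infectious duration `t_inf`; `tinf_sweep()` varies the infectious duration
#' at fixed `theta`. The same burned-in stationary states are reused across
#' all points of a sweep (the spatial and epidemic processes are independent),
#' and each point is measured with [run_ensemble()]. The integration step is
#' auto-reduced per point via [contagion_dt()].
#'
#' @param params an [abp_params()] object.
#' @param theta_values,tinf_values ordered vectors of sweep values.
#' @param t_inf,theta the fixed epidemic parameter.
#' @inheritParams run_ensemble
#' @param ... passed on to [run_ensemble()].
#' @return A `swarm_sweep` tibble: one row per sweep point with
#'   `pe, g, theta, t_inf, mean_rho_r, sd_rho_r, n_runs, n_unfinished`,
#'   plus the per-run table in `attr(, "runs")`.
#' @export
theta_sweep <- function(params, theta_values, t_inf, n_states = 5,
                        n_outbreaks = 10, seed_fraction = 0.01, states = NULL,
                        seed = 1, burnin = list(), outbreak = list(), ...) {
  stopifnot(all(theta_values >= 0), !is.unsorted(theta_values))
  eps <- purrr::map(theta_values, sir_params_from_theta, t_inf = t_inf)
  sweep_core(params, eps, "theta", theta_values, n_states, n_outbreaks,
             seed_fraction, states, seed, burnin, outbreak, ...)
}

#' @rdname theta_sweep
#' @export
tinf_sweep <- function(params, tinf_values, theta, n_states = 5,
                       n_outbreaks = 10, seed_fraction = 0.01, states = NULL,
                       seed = 1, burnin = list(), outbreak = list(), ...) {
  stopifnot(all(tinf_values > 0), !is.unsorted(tinf_values))
  eps <- purrr::map(tinf_values, function(ti) sir_params_from_theta(theta, ti))
  sweep_core(params, eps, "t_inf", tinf_values, n_states, n_outbreaks,
             seed_fraction, states, seed, burnin, outbreak, ...)
}

#' @method tidy swarm_sweep
#' @export
tidy.swarm_sweep <- function(x, ...) attr(x, "runs")

#' Estimate the outbreak onset along a sweep
#'
#' The onset is the smallest sweep value whose ensemble mean final recovered
#' fraction exceeds `threshold_multiple` times the seeding fraction — i.e.
#' the first point where the outbreak clearly grows beyond its seeds.
#'
#' @param sweep a [theta_sweep()] / [tinf_sweep()] result.
#' @param threshold_multiple multiple of the seed fraction (> 1).
#' @param seed_fraction seeding fraction; defaults to the sweep's own.
#' @return The onset value, or `NA` if the threshold is never exceeded.
#' @export
estimate_onset <- function(sweep, threshold_multiple = 5,
                           seed_fraction = NULL) {
  stopifnot(threshold_multiple > 1)
  axis <- attr(sweep, "axis")
  vals <- sweep[[axis]]
  if (is.unsorted(vals)) stop("sweep must be ordered along its axis",
                              call. = FALSE)
  seed_fraction <- seed_fraction %||% sweep$seed_fraction[1]
  hit <- which(sweep$mean_rho_r > threshold_multiple * seed_fraction)
  if (length(hit) == 0) return(NA_real_)
  vals[min(hit)]
}
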