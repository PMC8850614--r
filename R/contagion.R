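#' Per-step infection probability of a susceptible agent
#'
#' With `k` infected contacts, the pairwise transmissions are treated as
#' independent and the per-step probability is the linear sum
#' `min(1, k * beta_b * dt)`. A warning is emitted when the linearized value
#' exceeds 0.1 (the sum rule presumes probabilities well below 1; reduce `dt`).
#'
#' @param k number of infected contacts (vectorized).
#' @param beta_b base transmission rate.
#' @param dt time step.
#' @return Probability in `[0, 1]`.
#' @examples
#' infection_probability(3, beta_b = 0.1, dt = 0.1) # 0.03
#' @export
infection_probability <- function(k, beta_b, dt) {
  stopifnot(all(k >= 0), beta_b >= 0, dt > 0)
  p <- k * beta_b * dt
  if (any(p > 0.1))
    warning("linearized infection probability exceeds 0.1; reduce dt",
            call. = FALSE)
  pmin(1, p)
}

#' Auto-reduced time step for coupled contagion runs
#'
#' The contagion shares the spatial integration step, further constrained so
#' that `gamma * dt <= 0.1` and the per-contact probability
#' `beta_b * dt <= 0.1`. Needed for short infectious durations (for example
#' `t_inf = 0.01` at `theta = 2` gives `beta_b = 200`).
#'
#' @param params an [abp_params()] object.
#' @param ep a [sir_params()] object.
#' @return The time step to use for an outbreak run.
#' @export
contagion_dt <- function(params, ep) {
  dt <- min(params$dt, 0.1 / ep$gamma)
  if (ep$beta_b > 0) dt <- min(dt, 0.1 / ep$beta_b)
  dt
}

#' Seed initial infections
#'
#' All agents must be susceptible beforehand. In `random` mode, `n_seed`
#' distinct agents drawn uniformly become infected; in `localized` mode, the
#' `n_seed` agents nearest (minimum-image) to `anchor` become infected.
#'
#' @param state a [particle_state()].
#' @param n_seed number of initial infections (<= N).
#' @param mode `"random"` or `"localized"`.
#' @param anchor length-2 position for `localized` mode (defaults to the box
#'   center).
#' @param seed optional integer seed for the random draw.
#' @param L arena side; defaults to the state attribute.
#' @return The state with a `sir` factor column (levels S, I, R).
#' @examples
#' p <- abp_params(N = 100, pe = 32, g = 1)
#' st <- seed_infections(init_particles(p, seed = 1), n_seed = 1, seed = 2)
#' table(st$sir)
#' @export
seed_infections <- function(state, n_seed, mode = c("random", "localized"),
                            anchor = NULL, seed = NULL, L = NULL) {
  mode <- match.arg(mode)
  n <- nrow(state)
  if (n_seed > n) stop("n_seed exceeds the number of agents", call. = FALSE)
  if ("sir" %in% names(state) && any(state$sir != "S"))
    stop("all agents must be susceptible before seeding", call. = FALSE)
  L <- state_L(state, L)
  idx <- if (mode == "random") {
    with_seed_if(seed, sample.int(n, n_seed))
  } else {
    anchor <- anchor %||% c(L / 2, L / 2)
    d <- minimum_image(cbind(state$x, state$y), anchor, L)
    order(d[, 1]^2 + d[, 2]^2)[seq_len(n_seed)]
  }
  code <- integer(n)
  code[idx] <- 1L
  state$sir <- int_to_sir(code)
  state
}

#' One synchronous SIR transition step on a fixed contact graph
#'
#' Reference implementation of the transition rule: every susceptible agent
#' counts its infected contacts `k` in the pre-step state and becomes infected
#' with probability [infection_probability()]`(k, beta_b, dt)`; every pre-step
#' infected agent recovers with probability `gamma * dt`. All transitions are
#' evaluated against the pre-step state and applied simultaneously, so agents
#' infected in a step neither transmit nor recover within it. The compiled
#' outbreak loop applies the same rule each integration step.
#'
#' @param state a [particle_state()] with a `sir` column.
#' @param graph contact graph from [build_contact_graph()].
#' @param ep a [sir_params()] object.
#' @param dt time step; must satisfy `gamma * dt < 1`.
#' @param seed optional integer seed for the transition draws.
#' @return The state with updated `sir`.
#' @export
contagion_step <- function(state, graph, ep, dt, seed = NULL) {
  if (!"sir" %in% names(state))
    stop("state carries no sir column; seed infections first", call. = FALSE)
  if (ep$gamma * dt >= 1)
    stop("gamma * dt >= 1: step too coarse for recovery", call. = FALSE)
  code <- sir_to_int(state$sir)
  n <- length(code)
  k <- integer(n)
  if (nrow(graph) > 0) {
    inf_i <- code[graph$i] == 1L & code[graph$j] == 0L
    inf_j <- code[graph$j] == 1L & code[graph$i] == 0L
    k <- tabulate(c(graph$j[inf_i], graph$i[inf_j]), nbins = n)
  }
  with_seed_if(seed, {
    p_inf <- suppressWarnings(infection_probability(k, ep$beta_b, dt))
    new_i <- code == 0L & runif(n) < p_inf
    new_r <- code == 1L & runif(n) < ep$gamma * dt
    code[new_i] <- 1L
    code[new_r] <- 2L
  })
  state$sir <- int_to_sir(code)
  state
}

#' Run one SIR outbreak coupled to the spatial dynamics
#'
#' Alternates spatial integration and synchronous contagion steps — the
#' contagion acting each step on the contact graph of the current positions —
#' until no infected agents remain or the time cap is reached. Spatial noise,
#' infection draws and recovery draws use independent random streams derived
#' from `seed`, so the spatial trajectory is unchanged by epidemic parameters.
#'
#' @param state a [particle_state()] with at least one infected agent (see
#'   [seed_infections()]).
#' @param params an [abp_params()] object.
#' @param ep a [sir_params()] object.
#' @param dt time step; defaults to [contagion_dt()].
#' @param record_every time between recorded frames; defaults to
#'   `max(dt, min(1, t_inf))`.
#' @param t_max time cap for absorption; defaults to `50 * t_inf + 5000`.
#' @param seed integer seed for the run.
#' @return An object of class `swarm_outbreak`: list with `final` (one-row
#'   tibble: `rho_r_final`, `rho_i_peak`, `duration`, `finished`,
#'   `n_prob_capped`), `series`, `state`, `params`, `ep`, `dt`, `seed`.
#' @examples
#' \donttest{
#' p <- abp_params(N = 400, pe = 32, g = 1)
#' st <- seed_infections(init_particles(p, seed = 1), n_seed = 4, seed = 2)
#' ob <- run_outbreak(st, p, sir_params_from_theta(2, 20), seed = 3)
#' glance(ob)
#' }
#' @export
run_outbreak <- function(state, params, ep, dt = NULL, record_every = NULL,
                         t_max = NULL, seed = NULL) {
  if (!"sir" %in% names(state) || !any(state$sir == "I"))
    stop("state must contain at least one infected agent", call. = FALSE)
  seed <- seed %||% 1L
  dt <- dt %||% contagion_dt(params, ep)
  t_max <- t_max %||% (50 * ep$t_inf + 5000)
  record_every <- record_every %||% max(dt, min(1, ep$t_inf))
  n <- nrow(state)
  n_steps <- ceiling(t_max / dt)
  t0 <- attr(state, "time") %||% 0
  out <- simulate_core(
    state, params, n_steps = n_steps, dt = dt, contagion = TRUE, ep = ep,
    record_every_steps = max(1L, round(record_every / dt)),
    stop_when_extinct = TRUE,
    seed_spatial = derive_seed(seed, "outbreak-spatial"),
    seed_infect = derive_seed(seed, "outbreak-infect"),
    seed_recover = derive_seed(seed, "outbreak-recover")
  )
  raw <- out$raw
  finished <- isTRUE(raw$extinct)
  final <- tibble::tibble(
    rho_r_final = raw$n_r / n,
    rho_i_peak = raw$peak_n_i / n,
    duration = raw$t_end - t0,
    finished = finished,
    n_prob_capped = raw$n_capped
  )
  if (raw$n_linear_warn > 0)
    warning(sprintf(
      "linearized infection probability exceeded 0.1 in %g draws; dt may be too coarse",
      raw$n_linear_warn), call. = FALSE)
  structure(
    list(final = final, series = out$series, state = out$state,
         params = params, ep = ep, dt = dt, seed = seed),
    class = "swarm_outbreak"
  )
}

#' @export
print.swarm_outbreak <- function(x, ...) {
  f <- x$final
  cat(sprintf(
    "<swarm_outbreak> rho_R(inf)=%.4f peak rho_I=%.4f duration=%.4g finished=%s\n",
    f$rho_r_final, f$rho_i_peak, f$duration, f$finished))
  invisible(x)
}

#' @method tidy swarm_outbreak
#' @export
tidy.swarm_outbreak <- function(x, ...) x$series

#' @method glance swarm_outbreak
#' @export
glance.swarm_outbreak <- function(x, ...) x$final
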