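#' Alignment rate of one agent toward its neighbors
#'
#' The heading of agent i relaxes at rate
#' `(1 / tau) * mean(wrap_angle(theta_j - theta_i))`, the mean running over
#' the interaction set `S_i` of all agents within range — *including the
#' focal agent itself*, whose wrapped self-difference is zero but who counts
#' in the divisor. With k neighbors the rate is therefore
#' `sum(wrap_angle(theta_j - theta_i)) / ((k + 1) * tau)`; an isolated agent
#' feels no torque. The self-inclusive average weakens the effective
#' alignment of sparsely connected agents relative to a neighbors-only mean,
#' and is what places the disorder-order boundary between g = 1 and g = 2 at
#' Pe = 32 (a neighbors-only mean orders the g = 1 state).
#'
#' @param theta_i heading of the focal agent (radians).
#' @param neighbor_thetas headings of the neighbors (excluding the focal
#'   agent; may be empty).
#' @param tau alignment relaxation time (> 0).
#' @return The angular rate (radians per unit time).
#' @examples
#' alignment_rate(0, pi / 2, tau = 160) # pi / 640: divisor counts self
#' @export
alignment_rate <- function(theta_i, neighbor_thetas, tau) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  k <- length(neighbor_thetas)
  if (k == 0) return(0)
  sum(wrap_angle(neighbor_thetas - theta_i)) / ((k + 1) * tau)
}

#' Soft-core repulsion force on one agent
#'
#' Sums, over the neighbors j of agent i, the pair force
#' `((r_int - |r_ji|) / r_int) * r_ji / |r_ji|` with `r_ji = r_i - r_j` the
#' minimum-image displacement from j to i: a linear soft-core push away from
#' each neighbor, vanishing at separation `r_int`. For exactly coincident
#' particles the direction is drawn uniformly at random with magnitude 1
#' (the pair force is singular at zero distance).
#'
#' @param state a [particle_state()].
#' @param i focal agent index (1-based).
#' @param graph contact graph from [build_contact_graph()].
#' @param r_int interaction range.
#' @param L arena side; defaults to the state attribute.
#' @return Length-2 numeric force vector (units of speed, overdamped).
#' @export
repulsion_force <- function(state, i, graph, r_int, L = NULL) {
  L <- state_L(state, L)
  nb <- c(graph$j[graph$i == i], graph$i[graph$j == i])
  f <- c(0, 0)
  for (j in nb) {
    d <- as.vector(minimum_image(c(state$x[i], state$y[i]),
                                 c(state$x[j], state$y[j]), L))
    dn <- sqrt(sum(d^2))
    if (dn > 0) {
      f <- f + (r_int - dn) / r_int * d / dn
    } else {
      ang <- runif(1, -pi, pi)
      f <- f + c(cos(ang), sin(ang))
    }
  }
  f
}

# shared wrapper around the compiled loop
simulate_core <- function(state, params, n_steps, dt,
                          contagion = FALSE, ep = NULL,
                          record_every_steps = 1L,
                          stop_when_extinct = FALSE,
                          seed_spatial = NULL, seed_infect = NULL,
                          seed_recover = NULL) {
  L <- state_L(state)
  sir <- if ("sir" %in% names(state)) sir_to_int(state$sir) else
    integer(nrow(state))
  res <- cpp_simulate(
    state$x, state$y, state$theta, sir,
    params$v0, params$r_int, params$sigma, params$tau, L, dt,
    as.integer(n_steps),
    contagion, if (contagion) ep$beta_b else 0, if (contagion) ep$gamma else 1,
    as.double(seed_spatial %||% 1), as.double(seed_infect %||% 2),
    as.double(seed_recover %||% 3),
    as.integer(max(1L, record_every_steps)), stop_when_extinct,
    as.double(attr(state, "time") %||% 0)
  )
  new_state <- particle_state(
    tibble::tibble(id = state$id, x = res$x, y = res$y, theta = res$theta,
                   sir = int_to_sir(res$sir)),
    L = L, time = res$t_end
  )
  if (!contagion) new_state$sir <- NULL
  series <- tibble::as_tibble(res$series)
  list(state = new_state, series = series, raw = res)
}

#' Advance the spatial dynamics
#'
#' Integrates the overdamped equations of motion with the explicit
#' Euler-Maruyama scheme: headings receive the alignment drift plus
#' `sigma * sqrt(dt)` Gaussian increments, positions advance with the
#' self-propulsion velocity plus repulsion forces, both evaluated from the
#' state at the start of each step (synchronous update). Positions and
#' headings stay wrapped in `[0, L)^2` and `[-pi, pi)`.
#'
#' `step_particles()` takes a fixed number of steps; `simulate_motion()` runs
#' for a time span and also returns the recorded order-parameter series.
#'
#' @param state a [particle_state()].
#' @param params an [abp_params()] object.
#' @param n_steps number of integration steps.
#' @param seed integer seed for the angular-noise stream.
#' @return `step_particles()`: the advanced `particle_state`.
#' @export
step_particles <- function(state, params, n_steps = 1, seed = NULL) {
  simulate_core(state, params, n_steps = n_steps, dt = params$dt,
                record_every_steps = n_steps,
                seed_spatial = seed %||% derive_seed(0, "spatial"))$state
}

#' @rdname step_particles
#' @param t_sim simulated time span.
#' @param record_every time between recorded frames of
#'   `(t, n_s, n_i, n_r, phi, lambda)`.
#' @return `simulate_motion()`: a list with elements `state` (final
#'   `particle_state`) and `series` (tibble of recorded observables).
#' @export
simulate_motion <- function(state, params, t_sim, record_every = 1,
                            seed = NULL) {
  n_steps <- max(1L, ceiling(t_sim / params$dt))
  rec <- max(1L, round(record_every / params$dt))
  out <- simulate_core(state, params, n_steps = n_steps, dt = params$dt,
                       record_every_steps = rec,
                       seed_spatial = seed %||% derive_seed(0, "spatial"))
  out[c("state", "series")]
}

#' Relax the spatial dynamics to a statistically stationary state
#'
#' Starting from `state` (or a fresh uniform random configuration), integrates
#' the motion until the means of the polarization `phi` and largest-cluster
#' fraction `lambda` over two consecutive windows of `window` time units each
#' differ by less than `tol`, or until `t_max` is reached. The returned object
#' flags whether the criterion was met; hitting the cap is not an error.
#'
#' @param params an [abp_params()] object.
#' @param state optional starting [particle_state()]; drawn uniformly at
#'   random when `NULL`.
#' @param window window length (time units) for the stationarity comparison.
#' @param tol tolerance on the change of windowed means of `phi` and `lambda`.
#' @param t_min minimum burn-in time before the criterion may fire; the
#'   default `min(2500, max(25 * tau, 3 * L / v0))` covers both timescales on
#'   which a random initial condition relaxes. The ordering instability has a
#'   long quiescent plateau (order parameters near zero, drifting less than
#'   any practical tolerance) before polarization takes off — its duration
#'   grows with the alignment relaxation time `tau` — and even strongly
#'   coupled states need a few box-crossing times `L / v0` for locally
#'   ordered clusters to align globally. Consecutive-window agreement alone
#'   stops far too early in both regimes.
#' @param t_max hard cap on the burn-in duration (time units).
#' @param record_every time between recorded observable frames.
#' @param seed integer seed (initial condition and noise streams derive from
#'   it).
#' @return An object of class `swarm_burnin`: a list with `state`, `series`,
#'   `converged`, `t_end` and `params`.
#' @examples
#' \donttest{
#' p <- abp_params(N = 400, pe = 32, g = 1)
#' b <- run_burn_in(p, t_max = 300, seed = 1)
#' glance(b)
#' }
#' @export
run_burn_in <- function(params, state = NULL, window = 200, tol = 0.05,
                        t_min = NULL, t_max = 5000, record_every = 1,
                        seed = NULL) {
  seed <- seed %||% 1L
  if (is.null(t_min)) {
    cross <- if (params$v0 > 0) 3 * params$L / params$v0 else 0
    t_min <- min(2500, max(25 * params$tau, cross))
  }
  if (is.null(state)) state <- init_particles(params, seed = derive_seed(seed, "init"))
  steps_per_window <- max(1L, ceiling(window / params$dt))
  rec <- max(1L, round(record_every / params$dt))
  series <- list()
  prev_mean <- NULL
  converged <- FALSE
  t_done <- 0
  chunk <- 0L
  while (t_done < t_max - 1e-9 && !converged) {
    chunk <- chunk + 1L
    steps_left <- max(1L, ceiling((t_max - t_done) / params$dt - 1e-9))
    n_this <- min(steps_per_window, steps_left)
    out <- simulate_core(
      state, params, n_steps = n_this, dt = params$dt,
      record_every_steps = rec,
      seed_spatial = derive_seed(seed, paste0("burnin-chunk-", chunk))
    )
    state <- out$state
    s <- out$series[-1, , drop = FALSE] # drop duplicated initial frame
    series[[chunk]] <- s
    cur_mean <- c(phi = mean(s$phi), lambda = mean(s$lambda))
    t_done <- t_done + n_this * params$dt
    # compare only complete windows: a short tail chunk at the cap carries
    # too few frames for a meaningful stationarity verdict
    if (n_this == steps_per_window && !is.null(prev_mean) &&
        t_done >= t_min && all(abs(cur_mean - prev_mean) < tol)) {
      converged <- TRUE
    }
    prev_mean <- cur_mean
  }
  structure(
    list(state = state, series = dplyr::bind_rows(series),
         converged = converged, t_end = t_done, params = params,
         window = window, tol = tol),
    class = "swarm_burnin"
  )
}

#' @export
print.swarm_burnin <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<swarm_burnin> t_end=%.4g converged=%s phi_bar=%.3f lambda_bar=%.3f\n",
    x$t_end, x$converged, g$phi_bar, g$lambda_bar))
  invisible(x)
}

#' @method tidy swarm_burnin
#' @export
tidy.swarm_burnin <- function(x, ...) x$series

#' @method glance swarm_burnin
#' @export
glance.swarm_burnin <- function(x, ...) {
  w <- x$window
  last <- dplyr::filter(x$series, .data$t > max(.data$t) - w)
  tibble::tibble(phi_bar = mean(last$phi), lambda_bar = mean(last$lambda),
                 converged = x$converged, t_end = x$t_end)
}
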