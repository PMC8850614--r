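#' Wrap angles into [-pi, pi)
#'
#' Applies the modified modulo `mod(x + pi, 2*pi) - pi`, mapping any finite
#' angle to the half-open interval `[-pi, pi)` while preserving its value
#' modulo `2*pi`. Used for headings and for heading differences in the
#' alignment interaction.
#'
#' @param x numeric vector of angles (radians).
#' @return Angles wrapped into `[-pi, pi)`.
#' @examples
#' wrap_angle(c(0, 3 * pi / 2, pi)) # 0, -pi/2, -pi
#' @export
wrap_angle <- function(x) {
  if (any(!is.finite(x))) stop("angles must be finite", call. = FALSE)
  y <- ((x + pi) %% (2 * pi)) - pi
  y[y >= pi] <- -pi # guard floating-point seam
  y
}

#' Minimum-image displacement in a periodic square box
#'
#' Component-wise displacement `r_i - r_j` shifted by multiples of `L` into
#' `[-L/2, L/2)`, so that its norm is the true periodic distance.
#'
#' @param r_i,r_j positions: length-2 vectors or 2-column matrices with rows
#'   matched (recycled if one side is a single position).
#' @param L arena side length.
#' @return A 2-column matrix of displacement vectors (one row per pair).
#' @examples
#' minimum_image(c(0.5, 0), c(9.5, 0), L = 10) # (1, 0)
#' @export
minimum_image <- function(r_i, r_j, L) {
  a <- rbind(r_i)
  b <- rbind(r_j)
  if (ncol(a) != 2 || ncol(b) != 2)
    stop("positions must have two coordinates", call. = FALSE)
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
    else if (nrow(b) == 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
    else stop("incompatible numbers of positions", call. = FALSE)
  }
  d <- ((a - b + L / 2) %% L) - L / 2
  dimnames(d) <- NULL
  d
}

#' Particle state construction and random initialization
#'
#' A particle state is a tibble with one row per agent and columns `id`, `x`,
#' `y` (positions in `[0, L)`), `theta` (heading in `[-pi, pi)`) and optionally
#' `sir` (a factor with levels S, I, R). The arena side and elapsed time are
#' carried as attributes `L` and `time`.
#'
#' `init_particles()` draws positions uniformly in the box and headings
#' uniformly in `[-pi, pi)` — the unbiased initial condition used before
#' burn-in.
#'
#' @param df data frame with columns `x`, `y`, `theta` (and optionally `id`,
#'   `sir`).
#' @param L arena side length.
#' @param time elapsed simulation time attached to the state.
#' @return A tibble of class `particle_state`.
#' @examples
#' p <- abp_params(N = 100, pe = 32, g = 1)
#' st <- init_particles(p, seed = 1)
#' @export
particle_state <- function(df, L, time = 0) {
  stopifnot(is.data.frame(df), all(c("x", "y", "theta") %in% names(df)))
  n <- nrow(df)
  if (n < 1) stop("state must contain at least one agent", call. = FALSE)
  out <- tibble::as_tibble(df)
  if (!"id" %in% names(out)) out$id <- seq_len(n)
  out$x <- out$x %% L
  out$y <- out$y %% L
  out$theta <- wrap_angle(out$theta)
  if ("sir" %in% names(out)) out$sir <- int_to_sir(sir_to_int(out$sir))
  cols <- intersect(c("id", "x", "y", "theta", "sir"), names(out))
  out <- out[, cols]
  attr(out, "L") <- L
  attr(out, "time") <- time
  class(out) <- c("particle_state", class(tibble::tibble()))
  out
}

#' @rdname particle_state
#' @param params an [abp_params()] object.
#' @param seed optional integer seed for the draw (uses the current RNG state
#'   if `NULL`).
#' @export
init_particles <- function(params, seed = NULL) {
  n <- params$N
  with_seed_if(seed, {
    particle_state(
      tibble::tibble(
        x = runif(n, 0, params$L),
        y = runif(n, 0, params$L),
        theta = runif(n, -pi, pi)
      ),
      L = params$L, time = 0
    )
  })
}

#' @export
print.particle_state <- function(x, ...) {
  cat(sprintf("<particle_state> N=%d L=%.4g time=%.4g\n",
              nrow(x), attr(x, "L"), attr(x, "time")))
  NextMethod()
}

state_L <- function(state, L = NULL) {
  L <- L %||% attr(state, "L")
  if (is.null(L)) stop("arena side L not given and not found on the state",
                       call. = FALSE)
  L
}

#' Build the proximity contact graph of a particle state
#'
#' Two agents are in contact when their minimum-image distance is at most
#' `r_int` (inclusive). Pairs are found with an exact cell-list search
#' (cell size >= `r_int`, one-ring stencil), which returns the identical edge
#' set to an all-pairs scan.
#'
#' @param state a [particle_state()] (or any data frame with `x`, `y`).
#' @param r_int interaction range.
#' @param L arena side; defaults to the state attribute.
#' @return A tibble of class `contact_graph` with columns `i`, `j` (1-based
#'   agent indices, `i < j`) and `dist`, plus attributes `N`, `r_int`, `L`.
#' @examples
#' p <- abp_params(N = 50, pe = 32, g = 1)
#' g <- build_contact_graph(init_particles(p, seed = 1), r_int = 1)
#' @export
build_contact_graph <- function(state, r_int, L = NULL) {
  L <- state_L(state, L)
  if (r_int >= L / 2)
    stop("r_int must be < L/2 (minimum-image ambiguity)", call. = FALSE)
  res <- cpp_contact_pairs(state$x, state$y, L, r_int)
  out <- tibble::tibble(i = res$i, j = res$j, dist = res$dist)
  attr(out, "N") <- nrow(state)
  attr(out, "r_int") <- r_int
  attr(out, "L") <- L
  class(out) <- c("contact_graph", class(tibble::tibble()))
  out
}

# per-agent neighbor index lists from a contact graph
graph_neighbor_list <- function(graph, N = attr(graph, "N")) {
  nb <- vector("list", N)
  if (nrow(graph) > 0) {
    sp <- split(c(graph$j, graph$i), factor(c(graph$i, graph$j), levels = seq_len(N)))
    nb <- lapply(sp, as.integer)
  } else {
    nb <- replicate(N, integer(0), simplify = FALSE)
  }
  nb
}
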