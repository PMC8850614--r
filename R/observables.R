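#' Polarization order parameter
#'
#' The modulus of the mean heading unit vector,
#' `phi = |sum(cos theta, sin theta)| / N`: 1 when all agents head the same
#' way, near 0 for isotropic headings. Invariant under global rotation and
#' agent permutation.
#'
#' @param theta numeric vector of headings (radians); must be non-empty.
#' @return Polarization in `[0, 1]`.
#' @examples
#' polarization(rep(0.7, 10)) # 1
#' polarization(c(0, pi))     # 0
#' @export
polarization <- function(theta) {
  if (length(theta) == 0) stop("empty heading vector", call. = FALSE)
  sqrt(sum(cos(theta))^2 + sum(sin(theta))^2) / length(theta)
}

#' Largest-cluster fraction
#'
#' Clusters are the connected components of the contact graph (all agents
#' within `r_int` of any other member, transitively). Returns the size of the
#' largest component divided by `N`: `1/N` for a fully dispersed state, 1 when
#' a single cluster spans the system.
#'
#' @param graph a [build_contact_graph()] result (or any data frame with
#'   columns `i`, `j`).
#' @param N number of agents; defaults to the graph attribute.
#' @return Fraction in `[1/N, 1]`.
#' @export
largest_cluster_fraction <- function(graph, N = attr(graph, "N")) {
  if (is.null(N)) stop("N not given and not found on the graph", call. = FALSE)
  if (nrow(graph) == 0) return(1 / N)
  g <- igraph::graph_from_edgelist(cbind(graph$i, graph$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, N - igraph::vcount(g)))
  max(igraph::components(g)$csize) / N
}

#' Order parameters of a particle state
#'
#' @param state a [particle_state()].
#' @param params an [abp_params()] object (for `r_int`).
#' @return One-row tibble with `phi` and `lambda`.
#' @export
order_parameters <- function(state, params) {
  g <- build_contact_graph(state, r_int = params$r_int)
  tibble::tibble(phi = polarization(state$theta),
                 lambda = largest_cluster_fraction(g, nrow(state)))
}

# members of the largest connected component (integer indices)
largest_cluster_members <- function(graph, N = attr(graph, "N")) {
  if (nrow(graph) == 0) return(1L)
  g <- igraph::graph_from_edgelist(cbind(graph$i, graph$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, N - igraph::vcount(g)))
  comp <- igraph::components(g)
  which(comp$membership == which.max(comp$csize))
}

#' Elongation of the largest cluster relative to the mean heading
#'
#' Operationalizes the band/cluster distinction: the largest cluster's
#' coordinates are unwrapped by the minimum image around their periodic
#' (circular-mean) center, the gyration tensor is diagonalized, and the
#' principal axis is compared with the cluster's mean heading. The returned
#' value is `ecc * cos(2 * psi)` where `ecc` is the tensor eccentricity
#' `(l1 - l2) / (l1 + l2)` and `psi` the angle between the principal axis and
#' the mean heading: positive means elongated along the heading (clusters),
#' negative means elongated perpendicular to it (bands).
#'
#' @param state a [particle_state()].
#' @param graph contact graph of the state.
#' @param L arena side; defaults to the state attribute.
#' @return Signed elongation in `[-1, 1]`.
#' @export
cluster_anisotropy <- function(state, graph, L = NULL) {
  L <- state_L(state, L)
  mem <- largest_cluster_members(graph, nrow(state))
  if (length(mem) < 2) return(0)
  x <- state$x[mem]
  y <- state$y[mem]
  # circular-mean center per coordinate, then minimum-image displacements
  cmean <- function(u) {
    a <- 2 * pi * u / L
    (atan2(mean(sin(a)), mean(cos(a))) %% (2 * pi)) * L / (2 * pi)
  }
  dx <- minimum_image(cbind(x, y), c(cmean(x), cmean(y)), L)
  gxx <- mean(dx[, 1]^2); gyy <- mean(dx[, 2]^2); gxy <- mean(dx[, 1] * dx[, 2])
  tr <- gxx + gyy
  if (tr <= 0) return(0)
  disc <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  ecc <- (l1 - l2) / tr
  # principal axis angle of the gyration tensor
  axis <- 0.5 * atan2(2 * gxy, gxx - gyy)
  mu <- atan2(mean(sin(state$theta[mem])), mean(cos(state$theta[mem])))
  ecc * cos(2 * (axis - mu))
}

#' Classify a collective state from time-averaged order parameters
#'
#' Labels follow the phase diagram of the model: `D` (disordered) when the
#' time-averaged polarization is below `phi_c`; otherwise `OH` (ordered
#' homogeneous) when the largest-cluster fraction is below `lambda_c`;
#' otherwise `OB` (ordered with bands, largest cluster elongated perpendicular
#' to the mean heading, `anisotropy < 0`) or `OC` (ordered with clusters,
#' elongated along the heading). The thresholds default to the wide gaps
#' between regimes (`phi_c = 0.5`, `lambda_c = 0.2`) and are exposed because
#' the region boundaries are not sharp.
#'
#' @param phi_bar time-averaged polarization in `[0, 1]`.
#' @param lambda_bar time-averaged largest-cluster fraction in `[0, 1]`.
#' @param anisotropy signed elongation from [cluster_anisotropy()].
#' @param phi_c,lambda_c classification thresholds.
#' @return One of `"D"`, `"OB"`, `"OC"`, `"OH"`.
#' @export
classify_state <- function(phi_bar, lambda_bar, anisotropy,
                           phi_c = 0.5, lambda_c = 0.2) {
  check_fraction(phi_bar, "phi_bar")
  check_fraction(lambda_bar, "lambda_bar")
  if (phi_bar < phi_c) return("D")
  if (lambda_bar < lambda_c) return("OH")
  if (anisotropy < 0) "OB" else "OC"
}

#' Measure and classify the collective state over a stationary window
#'
#' Runs the spatial dynamics for `t_measure` time units from `state`
#' (assumed already burned in), averages `phi` and `lambda` over the recorded
#' frames, computes the final-frame cluster anisotropy and applies
#' [classify_state()].
#'
#' @inheritParams simulate_motion
#' @param t_measure measurement window (time units).
#' @param phi_c,lambda_c thresholds passed to [classify_state()].
#' @return One-row tibble: `phi_bar`, `lambda_bar`, `anisotropy`, `label`.
#' @export
measure_state <- function(state, params, t_measure = 100, record_every = 1,
                          phi_c = 0.5, lambda_c = 0.2, seed = NULL) {
  run <- simulate_motion(state, params, t_sim = t_measure,
                         record_every = record_every, seed = seed)
  g <- build_contact_graph(run$state, r_int = params$r_int)
  ani <- cluster_anisotropy(run$state, g)
  phi_bar <- mean(run$series$phi)
  lam_bar <- mean(run$series$lambda)
  tibble::tibble(
    phi_bar = phi_bar, lambda_bar = lam_bar, anisotropy = ani,
    label = classify_state(phi_bar, lam_bar, ani, phi_c, lambda_c)
  )
}

#' Binned density field of a particle state
#'
#' Bins agents on an `n_bins x n_bins` grid over the periodic arena and
#' smooths the total counts with a periodic Gaussian kernel of width
#' `smooth_width` (a length). The infected layer keeps the raw per-bin counts
#' of agents in state I; it is meaningful only on bins where that count is
#' positive. Smoothing conserves total mass.
#'
#' @param state a [particle_state()] (with or without a `sir` column).
#' @param n_bins number of bins per side (>= 2).
#' @param smooth_width Gaussian kernel width in length units; defaults to two
#'   bin widths. Use 0 to skip smoothing.
#' @param L arena side; defaults to the state attribute.
#' @return An object of class `density_grid`: list with matrices `total`
#'   (raw counts), `total_smooth`, `infected` (raw counts), the bin `edges`,
#'   and the parameters used.
#' @export
render_density_grid <- function(state, n_bins = 64, smooth_width = NULL,
                                L = NULL) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  L <- state_L(state, L)
  h <- L / n_bins
  smooth_width <- smooth_width %||% (2 * h)
  ix <- pmin(n_bins, floor(state$x / h) + 1L)
  iy <- pmin(n_bins, floor(state$y / h) + 1L)
  bin <- (iy - 1L) * n_bins + ix
  total <- matrix(tabulate(bin, nbins = n_bins^2), n_bins, n_bins)
  infected <- matrix(0L, n_bins, n_bins)
  if ("sir" %in% names(state)) {
    inf <- state$sir == "I"
    if (any(inf))
      infected <- matrix(tabulate(bin[inf], nbins = n_bins^2), n_bins, n_bins)
  }
  total_smooth <- if (smooth_width > 0) {
    periodic_gaussian_smooth(total, h, smooth_width)
  } else {
    total
  }
  structure(
    list(total = total, total_smooth = total_smooth, infected = infected,
         edges = seq(0, L, length.out = n_bins + 1), n_bins = n_bins,
         smooth_width = smooth_width, L = L),
    class = "density_grid"
  )
}

# circular (wrap-around) convolution with a normalized Gaussian kernel
periodic_gaussian_smooth <- function(m, h, width) {
  nb <- nrow(m)
  off <- h * (seq_len(nb) - 1)
  dmin <- pmin(off, nb * h - off) # periodic distance of bin centers to bin 1
  k1 <- exp(-dmin^2 / (2 * width^2))
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  out <- Re(stats::fft(stats::fft(m) * stats::fft(kern), inverse = TRUE)) / nb^2
  # kernel is centered on bin (1,1); result is aligned with the input grid
  out
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d bins over L=%.4g, smooth width %.3g\n",
              x$n_bins, x$n_bins, x$L, x$smooth_width))
  invisible(x)
}

#' Contact rate and contact duration from a graph sequence
#'
#' A contact event is a maximal run of consecutive frames over which a given
#' pair remains an edge. The mean contact duration is the mean run length
#' times `dt`; the mean contact rate counts event onsets (a pair becoming an
#' edge after not being one, i.e. from the second frame on) experienced per
#' agent per unit time — each pair onset involves two agents and counts for
#' both. These are the emergent quantities that set the effective transmission
#' rate `beta = beta_b * nu * dt` of the mean-field picture.
#'
#' @param graphs time-ordered list of contact graphs (equal agent count,
#'   frames `dt` apart).
#' @param dt time between frames.
#' @return One-row tibble of class `contact_stats`:
#'   `mean_contact_rate`, `mean_contact_duration`, `n_events`.
#' @export
contact_statistics <- function(graphs, dt) {
  if (length(graphs) < 2) stop("need at least two frames", call. = FALSE)
  N <- attr(graphs[[1]], "N")
  if (is.null(N)) stop("graphs must carry an N attribute", call. = FALSE)
  frames <- purrr::map2_dfr(graphs, seq_along(graphs), function(g, f) {
    tibble::tibble(key = (g$i - 1) * N + g$j, frame = f)
  })
  n_frames <- length(graphs)
  if (nrow(frames) == 0) {
    return(tibble::tibble(mean_contact_rate = 0, mean_contact_duration = 0,
                          n_events = 0L))
  }
  runs <- frames |>
    dplyr::arrange(.data$key, .data$frame) |>
    dplyr::group_by(.data$key) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$frame) != 1L))) |>
    dplyr::group_by(.data$key, .data$run) |>
    dplyr::summarise(len = dplyr::n(), start = min(.data$frame),
                     .groups = "drop")
  onsets <- sum(runs$start > 1)
  tibble::tibble(
    mean_contact_rate = 2 * onsets / N / ((n_frames - 1) * dt),
    mean_contact_duration = mean(runs$len) * dt,
    n_events = nrow(runs)
  )
}
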