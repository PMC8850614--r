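test_that("polarization: limits, symmetry cases, invariances", {
  expect_equal(polarization(rep(1.3, 7)), 1, tolerance = 1e-12)
  expect_equal(polarization(c(0.4, 0.4 + pi)), 0, tolerance = 1e-12)
  expect_equal(polarization(c(0, pi / 2, pi, 3 * pi / 2)), 0,
               tolerance = 1e-12)
  expect_error(polarization(numeric(0)), "empty")
  set.seed(5)
  th <- runif(200, -pi, pi)
  phi0 <- polarization(th)
  expect_gte(phi0, 0)
  expect_lte(phi0, 1)
  # global rotation and permutation invariance
  for (rot in c(0.3, -2, 5)) {
    expect_equal(polarization(th + rot), phi0, tolerance = 1e-12)
  }
  expect_equal(polarization(sample(th)), phi0, tolerance = 1e-12)
})

test_that("largest-cluster fraction uses transitive closure semantics", {
  # all pairwise distances above r_int: fully dispersed
  st <- lattice_state(5, spacing = 2)
  g <- build_contact_graph(st, r_int = 1)
  expect_equal(largest_cluster_fraction(g, 25), 1 / 25)
  # a chain with spacing 0.9 r_int is a single cluster
  st <- particle_state(
    data.frame(x = 1 + 0.9 * (0:9), y = 1, theta = 0), L = 30)
  g <- build_contact_graph(st, r_int = 1)
  expect_equal(largest_cluster_fraction(g, 10), 1)
  # components {3, 2} of 5
  st <- particle_state(
    data.frame(x = c(1, 1.5, 2, 8, 8.5), y = 1, theta = 0), L = 20)
  g <- build_contact_graph(st, r_int = 1)
  expect_equal(largest_cluster_fraction(g, 5), 0.6)
})

test_that("lambda is permutation/translation invariant and grows with edges", {
  p <- abp_params(N = 60, pe = 32, g = 8)
  st <- init_particles(p, seed = 8)
  g <- build_contact_graph(st, r_int = 1)
  lam <- largest_cluster_fraction(g, 60)
  # periodic translation leaves the components unchanged
  st2 <- particle_state(
    data.frame(x = st$x + 17.3, y = st$y + 5.1, theta = st$theta), L = p$L)
  g2 <- build_contact_graph(st2, r_int = 1)
  expect_equal(largest_cluster_fraction(g2, 60), lam, tolerance = 1e-12)
  # agreement with the compiled union-find used in the run loop
  expect_equal(
    swarmsir:::cpp_largest_component_fraction(g$i, g$j, 60), lam,
    tolerance = 1e-12)
  # adding any edge cannot shrink the largest component
  for (rep in 1:20) {
    extra <- sort(sample(60, 2))
    g3 <- g
    g3[nrow(g3) + 1, c("i", "j")] <- as.list(extra)
    expect_gte(largest_cluster_fraction(g3, 60), lam)
  }
})

test_that("density grid bins, conserves mass and smooths periodically", {
  # uniform lattice: every bin holds the same count
  st <- lattice_state(8, spacing = 1) # L = 8, one agent per unit cell
  dg <- render_density_grid(st, n_bins = 4, smooth_width = 0, L = 8)
  expect_true(all(dg$total == 4))
  expect_equal(sum(dg$total), 64)
  # all agents in one bin; smoothing conserves mass
  st2 <- particle_state(
    data.frame(x = rep(2.1, 50), y = rep(6.3, 50), theta = 0), L = 16)
  dg2 <- render_density_grid(st2, n_bins = 8, smooth_width = 2)
  expect_equal(max(dg2$total), 50)
  expect_equal(sum(dg2$total_smooth), 50, tolerance = 1e-9)
  # periodic shift-equivariance: wrapping the cluster across the edge gives
  # the same smoothed field up to the same cyclic shift
  shift <- 8 # integer multiple of the bin width (bin width 2, 4 bins)
  st3 <- particle_state(
    data.frame(x = (st2$x + shift) %% 16, y = st2$y, theta = 0), L = 16)
  dg3 <- render_density_grid(st3, n_bins = 8, smooth_width = 2)
  rolled <- dg2$total_smooth[c(5:8, 1:4), ] # shift of 4 bins in x
  expect_equal(dg3$total_smooth, rolled, tolerance = 1e-9)
  # infected layer reports raw counts where present
  st2$sir <- factor(c("I", rep("S", 49)), levels = c("S", "I", "R"))
  dg4 <- render_density_grid(st2, n_bins = 8, smooth_width = 2)
  expect_equal(sum(dg4$infected), 1)
  expect_true(all(dg4$infected <= dg4$total))
})

test_that("contact statistics: onsets and maximal run durations", {
  mk_graph <- function(edges, n) {
    g <- tibble::tibble(i = edges[, 1], j = edges[, 2])
    attr(g, "N") <- n
    g
  }
  e <- cbind(1L, 2L)
  none <- matrix(integer(0), 0, 2)
  # static pair over 6 frames: no onsets after frame 1, duration = window
  gs <- replicate(6, mk_graph(e, 4), simplify = FALSE)
  cs <- contact_statistics(gs, dt = 0.5)
  expect_equal(cs$mean_contact_rate, 0)
  expect_equal(cs$mean_contact_duration, 6 * 0.5)
  # flickering pair on alternate frames: k events of one frame each
  gs <- lapply(1:8, function(f) mk_graph(if (f %% 2 == 1) e else none, 4))
  cs <- contact_statistics(gs, dt = 0.5)
  expect_equal(cs$n_events, 4L)
  expect_equal(cs$mean_contact_duration, 0.5)
  # onsets: events starting after frame 1 (3 of the 4), both agents count
  expect_equal(cs$mean_contact_rate, 2 * 3 / 4 / (7 * 0.5))
})

test_that("head-on crossing time matches the chord formula", {
  # two agents crossing on the same line at relative speed 2 v0: contact
  # lasts 2 r_int / (2 v0). Self-propulsion must dominate the soft-core
  # repulsion (|F| <= 1 per pair) or the pair stalls instead of crossing;
  # at v0 = 5 the repulsive correction to the chord time is ~1%.
  v0 <- 5
  p <- abp_params(N = 2, v0 = v0, r_int = 1, sigma = 1e-300, tau = 1e6,
                  L = 40, dt = 0.02)
  st <- particle_state(
    data.frame(x = c(10, 14), y = 5, theta = c(0, -pi)), L = 40)
  graphs <- list()
  for (f in 1:100) {
    graphs[[f]] <- build_contact_graph(st, r_int = 1)
    st <- step_particles(st, p, n_steps = 1, seed = f)
  }
  cs <- contact_statistics(graphs, dt = p$dt)
  expect_equal(cs$n_events, 1L)
  expect_lt(abs(cs$mean_contact_duration - 2 * 1 / (2 * v0)), 2 * p$dt)
})

test_that("state classification thresholds and band/cluster split", {
  expect_equal(classify_state(0.2, 0.5, 0.3), "D")
  expect_equal(classify_state(0.9, 0.05, 0.3), "OH")
  expect_equal(classify_state(0.9, 0.6, -0.4), "OB")
  expect_equal(classify_state(0.9, 0.6, 0.4), "OC")
  expect_error(classify_state(1.2, 0.5, 0), "phi_bar")
  expect_error(classify_state(0.5, -0.1, 0), "lambda_bar")
})

test_that("cluster anisotropy separates stripes across vs along the heading", {
  # dense stripe along y (perpendicular to the +x heading): band-like
  set.seed(31)
  band <- particle_state(data.frame(
    x = runif(300, 9, 11), y = runif(300, 0, 30), theta = 0), L = 30)
  g <- build_contact_graph(band, r_int = 1)
  expect_lt(cluster_anisotropy(band, g), 0)
  # the same stripe along x (parallel to the heading): cluster-like
  clus <- particle_state(data.frame(
    x = band$y, y = band$x, theta = 0), L = 30)
  g2 <- build_contact_graph(clus, r_int = 1)
  expect_gt(cluster_anisotropy(clus, g2), 0)
})
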