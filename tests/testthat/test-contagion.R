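test_that("infection probability is the capped linear sum over contacts", {
  expect_equal(infection_probability(1, beta_b = 0.3, dt = 0.1), 0.03)
  expect_equal(infection_probability(0, beta_b = 5, dt = 0.1), 0)
  expect_equal(infection_probability(3, beta_b = 0.1, dt = 0.1), 0.03,
               tolerance = 1e-14)
  expect_warning(p <- infection_probability(30, beta_b = 1, dt = 0.1),
                 "reduce dt")
  expect_equal(p, 1) # capped
})

test_that("contagion dt auto-reduces for fast recovery and transmission", {
  p <- abp_params(N = 10, pe = 32, g = 1)
  expect_equal(contagion_dt(p, sir_params_from_theta(2, 20)), 0.1)
  ep <- sir_params_from_theta(2, 0.01) # gamma = 100, beta_b = 200
  expect_equal(contagion_dt(p, ep), 0.1 / 200)
  expect_lte(ep$gamma * contagion_dt(p, ep), 0.1)
})

test_that("seeding infects the requested agents", {
  p <- abp_params(N = 200, pe = 32, g = 1)
  st <- init_particles(p, seed = 1)
  s1 <- seed_infections(st, n_seed = 2, seed = 2)
  expect_equal(sum(s1$sir == "I"), 2)
  expect_equal(sum(s1$sir == "S"), 198)
  # localized seeding picks the agents nearest the anchor
  anchor <- c(p$L / 2, p$L / 2)
  s2 <- seed_infections(st, n_seed = 10, mode = "localized", anchor = anchor)
  d <- minimum_image(cbind(st$x, st$y), anchor, p$L)
  r2 <- d[, 1]^2 + d[, 2]^2
  expect_setequal(which(s2$sir == "I"), order(r2)[1:10])
  # all agents seeded
  s3 <- seed_infections(st, n_seed = 200, seed = 3)
  expect_true(all(s3$sir == "I"))
  expect_error(seed_infections(st, n_seed = 201), "exceeds")
  expect_error(seed_infections(s1, n_seed = 1), "susceptible")
})

test_that("synchronous step: no transmission without beta, R absorbing", {
  st <- lattice_state(4, spacing = 1) # fully connected by range-1 chain
  g <- build_contact_graph(st, r_int = 1)
  st$sir <- factor(rep(c("I", "S"), 8), levels = c("S", "I", "R"))
  ep0 <- sir_params(beta_b = 0, gamma = 0.5)
  out <- contagion_step(st, g, ep0, dt = 0.1, seed = 1)
  expect_equal(sum(out$sir == "S"), 8) # nobody newly infected
  # all-R state is frozen forever
  st$sir <- factor(rep("R", 16), levels = c("S", "I", "R"))
  for (k in 1:5) {
    st <- contagion_step(st, g, sir_params(5, 0.5), dt = 0.1, seed = k)
  }
  expect_true(all(st$sir == "R"))
})

test_that("new infections on a complete graph are Binomial(n_S, k beta dt)", {
  # 5 agents all within range, 1 infected, beta_b*dt = 0.2, gamma = 0:
  # each susceptible is infected independently with p = 0.2
  st <- particle_state(
    data.frame(x = 5 + 0.1 * (0:4), y = 5, theta = 0), L = 20)
  g <- build_contact_graph(st, r_int = 1)
  expect_equal(nrow(g), 10) # complete graph
  ep <- sir_params(beta_b = 2, gamma = 1e-12)
  counts <- integer(400)
  set.seed(42)
  for (r in seq_along(counts)) {
    st$sir <- factor(c("I", "S", "S", "S", "S"), levels = c("S", "I", "R"))
    out <- suppressWarnings(contagion_step(st, g, ep, dt = 0.1))
    counts[r] <- sum(out$sir == "I") - 1L
  }
  expected <- length(counts) * dbinom(0:4, 4, 0.2)
  # pool the sparse tail so the chi-square approximation holds
  obs <- c(tabulate(counts + 1L, 5)[1:3], sum(counts >= 3))
  exp_p <- c(expected[1:3], sum(expected[4:5]))
  pval <- stats::chisq.test(obs, p = exp_p / sum(exp_p))$p.value
  expect_gt(pval, 1e-3)
})

test_that("outbreak with beta_b = 0: seeds recover, nobody else", {
  p <- abp_params(N = 500, pe = 32, g = 1)
  st <- seed_infections(init_particles(p, seed = 1), n_seed = 5, seed = 2)
  ob <- run_outbreak(st, p, sir_params(0, 0.05), seed = 3)
  expect_true(ob$final$finished)
  expect_equal(ob$final$rho_r_final, 5 / 500) # exactly the seeded fraction
  expect_equal(ob$final$rho_i_peak, 5 / 500)
})

test_that("overwhelming transmissibility on a static connected cluster infects everyone", {
  # static variant (v0 = 0, vanishing noise), all agents mutually in range
  p <- abp_params(N = 12, v0 = 0, r_int = 1, sigma = 1e-300, tau = 1,
                  L = 10, dt = 0.002)
  ang <- 2 * pi * (0:11) / 12
  st <- particle_state(
    data.frame(x = 5 + 0.3 * cos(ang), y = 5 + 0.3 * sin(ang), theta = 0),
    L = 10)
  st <- seed_infections(st, n_seed = 1, seed = 1)
  ep <- sir_params_from_theta(1000, 20) # beta_b = 50, gamma = 0.05
  # many simultaneously infected contacts intentionally strain linearization
  ob <- suppressWarnings(run_outbreak(st, p, ep, seed = 2))
  expect_true(ob$final$finished)
  expect_equal(ob$final$rho_r_final, 1)
})

test_that("epidemic duration with beta_b = 0 matches the order-statistic oracle", {
  # duration = max of n_seed iid geometric(gamma*dt) lifetimes
  p <- abp_params(N = 100, pe = 32, g = 1, phi_pack = 0.1)
  gamma <- 0.2
  dt <- 0.1
  n_seed <- 10
  ep <- sir_params(0, gamma)
  durs <- numeric(200)
  for (r in seq_along(durs)) {
    st <- seed_infections(init_particles(p, seed = r), n_seed = n_seed,
                          seed = 1000 + r)
    ob <- run_outbreak(st, p, ep, dt = dt, seed = 2000 + r)
    durs[r] <- ob$final$duration
  }
  expected_steps <- expected_max_geometric(n_seed, gamma * dt)
  se <- sd(durs / dt) / sqrt(length(durs))
  expect_lt(abs(mean(durs / dt) - expected_steps), 3 * se)
})

test_that("compartment counts are conserved and rho_R is monotone", {
  # 100 random short runs across parameter settings
  set.seed(99)
  for (r in 1:100) {
    n <- sample(30:80, 1)
    p <- abp_params(N = n, pe = sample(c(8, 32, 128), 1),
                    g = sample(c(1, 4, 32), 1), phi_pack = 0.3)
    st <- seed_infections(init_particles(p, seed = r),
                          n_seed = sample(1:3, 1), seed = r + 1)
    ep <- sir_params_from_theta(runif(1, 0, 20), runif(1, 0.5, 10))
    # multi-neighbor contacts can push k*beta_b*dt past the advisory 0.1
    ob <- suppressWarnings(
      run_outbreak(st, p, ep, t_max = 15, record_every = p$dt, seed = r + 2))
    s <- ob$series
    expect_true(all(s$n_s + s$n_i + s$n_r == n))
    expect_true(all(diff(s$n_r) >= 0))
    expect_true(all(diff(s$n_s) <= 0))
    if (ob$final$finished) {
      last <- s[nrow(s), ]
      expect_equal(last$n_i, 0)
      expect_equal(ob$final$rho_r_final, last$n_r / n)
      expect_gte(ob$final$rho_r_final, sum(st$sir == "I") / n)
    }
  }
})

test_that("coupled outbreak matches an independent graph-SIR on a frozen configuration", {
  # static lattice at spacing exactly r_int: repulsion vanishes, v0 = 0,
  # so run_outbreak evolves the SIR process on a fixed grid graph.
  # Compare final-size distributions with an independent R implementation.
  n_side <- 7
  st0 <- lattice_state(n_side, spacing = 1)
  n <- n_side^2
  p <- abp_params(N = n, v0 = 0, r_int = 1, sigma = 1e-300, tau = 1,
                  L = n_side, dt = 0.1)
  g <- build_contact_graph(st0, r_int = 1)
  nbr <- nbr_from_graph(g, n)
  ep <- sir_params(beta_b = 1, gamma = 0.25) # theta = 4 on the grid
  n_rep <- 300
  seed_agent <- 25 # center of the lattice
  pkg_final <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    st <- st0
    st$sir <- factor(ifelse(seq_len(n) == seed_agent, "I", "S"),
                     levels = c("S", "I", "R"))
    # grid agents have up to 4 infected contacts: k*beta_b*dt reaches 0.4,
    # intentionally matching the oracle's identical linear rule
    ob <- suppressWarnings(run_outbreak(st, p, ep, dt = 0.1, seed = 5000 + r))
    pkg_final[r] <- ob$final$rho_r_final * n
  }
  set.seed(77)
  ora_final <- replicate(n_rep,
    graph_sir_oracle(nbr, seed_agent, beta_b = 1, gamma = 0.25, dt = 0.1))
  pv <- suppressWarnings(stats::ks.test(pkg_final, ora_final))$p.value
  expect_gt(pv, 1e-3)
  # means agree within 3 pooled standard errors as well
  se <- sqrt(var(pkg_final) / n_rep + var(ora_final) / n_rep)
  expect_lt(abs(mean(pkg_final) - mean(ora_final)), 3 * se)
})
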