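# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own compiled kernels.

# all-pairs O(N^2) contact search with explicit minimum image
brute_force_pairs <- function(x, y, L, r_int) {
  n <- length(x)
  out <- list(i = integer(0), j = integer(0))
  if (n < 2) return(tibble::tibble(i = integer(0), j = integer(0)))
  mi <- function(d) ((d + L / 2) %% L) - L / 2
  pairs <- utils::combn(n, 2)
  dx <- mi(x[pairs[1, ]] - x[pairs[2, ]])
  dy <- mi(y[pairs[1, ]] - y[pairs[2, ]])
  keep <- sqrt(dx^2 + dy^2) <= r_int
  tibble::tibble(i = pairs[1, keep], j = pairs[2, keep])
}

edge_key <- function(i, j, n) pmin(i, j) * (n + 1) + pmax(i, j)

# square lattice of n x n agents with given spacing, common heading
lattice_state <- function(n_side, spacing, L = n_side * spacing, theta = 0) {
  g <- expand.grid(ix = seq_len(n_side) - 1, iy = seq_len(n_side) - 1)
  particle_state(
    data.frame(x = g$ix * spacing, y = g$iy * spacing,
               theta = theta),
    L = L
  )
}

# independent discrete-time synchronous SIR on a fixed neighbor-list graph;
# returns the final recovered count
graph_sir_oracle <- function(nbr, init_infected, beta_b, gamma, dt,
                             max_steps = 100000) {
  n <- length(nbr)
  state <- integer(n) # 0 S, 1 I, 2 R
  state[init_infected] <- 1L
  for (s in seq_len(max_steps)) {
    inf <- which(state == 1L)
    if (length(inf) == 0) break
    k <- tabulate(unlist(nbr[inf]), nbins = n)
    sus <- state == 0L
    p <- pmin(1, k * beta_b * dt)
    new_i <- sus & runif(n) < p
    new_r <- state == 1L & runif(n) < gamma * dt
    state[new_i] <- 1L
    state[new_r] <- 2L
  }
  sum(state == 2L)
}

# neighbor lists from a contact_graph tibble
nbr_from_graph <- function(graph, n) {
  nb <- replicate(n, integer(0), simplify = FALSE)
  for (k in seq_len(nrow(graph))) {
    i <- graph$i[k]; j <- graph$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# expected maximum of n iid geometric(p) step counts (support 1, 2, ...)
expected_max_geometric <- function(n, p, tol = 1e-12) {
  total <- 0
  k <- 0
  repeat {
    term <- 1 - (1 - (1 - p)^k)^n
    total <- total + term
    k <- k + 1
    if (term < tol) break
  }
  total
}
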