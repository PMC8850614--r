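# Shared cache of burned-in stationary states at the reference (Pe, g)
# points (N = 2500, packing 0.3). Burn-ins are expensive; every acceptance
# block that needs a given collective state reuses the same replicates.

.state_cache <- new.env(parent = emptyenv())

reference_params <- function(pe, g) {
  abp_params(N = 2500, pe = pe, g = g, phi_pack = 0.3)
}

reference_states <- function(pe, g, n_states = 5) {
  key <- sprintf("pe%s-g%s", pe, g)
  cur <- get0(key, envir = .state_cache)
  if (is.null(cur) || length(cur) < n_states) {
    p <- reference_params(pe, g)
    cur <- burn_in_states(p, n_states = n_states, seed = 20 + pe + g)
    assign(key, cur, envir = .state_cache)
  }
  cur[seq_len(n_states)]
}
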