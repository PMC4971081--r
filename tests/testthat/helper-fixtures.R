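# small deterministic fixtures used across test files

toy_connectome <- function(n = 3) {
  w <- matrix(0, n, n)
  if (n >= 2) {
    w[1, 2] <- 0.5
    w[2, 1] <- 0.5
  }
  if (n >= 3) {
    w[2, 3] <- 0.3
    w[3, 2] <- 0.3
  }
  coords <- cbind(seq_len(n) * 10, 0, 0)
  connectome(w, coords, tract_lengths = (w > 0) * 15)
}

star_connectome <- function(leaves = 4, weight = 0.2) {
  n <- leaves + 1
  w <- matrix(0, n, n)
  w[2:n, 1] <- weight
  w[1, 2:n] <- weight
  ang <- 2 * pi * seq_len(leaves) / leaves
  coords <- rbind(c(0, 0, 0), cbind(cos(ang), sin(ang), 0) * 30)
  connectome(w, coords, tract_lengths = (w > 0) * 30)
}

# small synthetic substrate + embedded network shared by light-weight tests
small_hybrid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      con <- synthesize_connectome(n_nodes = 96, density = 0.12, seed = 401)
      cache <<- suppressWarnings(
        build_embedding(con, G = 0.15, host_collision = "next", seed = 402))
    }
    cache
  }
})

scalar_tvb_derivative <- function(E, I, p, Gam) {
  # independent scalar transcription of the node equations
  sig <- function(f, a, b, c) c / (1 + exp(-a * (f - b)))
  SE <- sig(p$alpha_E * (p$c_EE * E - p$c_IE * I - p$theta_E + Gam),
            p$a_E, p$b_E, p$c_sigE)
  SI <- sig(p$alpha_I * (p$c_EI * E - p$c_II * I - p$theta_I + Gam),
            p$a_I, p$b_I, p$c_sigI)
  c((-E + (p$k_E - p$r_E * E) * SE) / p$tau_E,
    (-I + (p$k_I - p$r_I * I) * SI) / p$tau_I)
}
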