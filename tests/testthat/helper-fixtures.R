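# Shared fixture builders.  Everything is generated in code; expensive
# end-to-end runs are memoized for the lifetime of the test process so
# several test files can share them.

two_state_scheme <- function(k12 = 1, k21 = 1) {
  # collapse the chain to an effective two-state system: only the
  # rotation rates are nonzero, so the dynamics live on cnr <-> cr
  kinetic_scheme(k_cle = 0, k_lig_nr = 0, k_rec = k12, k_non_rec = k21,
                 k_lig_r = 0, k_cle_r = 0)
}

# Square-wave FRET trace (exact two-level signal, optionally noisy).
square_wave_fret <- function(levels = c(0.2, 0.8), period = 10,
                             n_frames = 200, noise = 0, seed = 1) {
  set.seed(seed)
  st <- rep(rep(c(1L, 2L), each = period), length.out = n_frames)
  E <- levels[st] + if (noise > 0) rnorm(n_frames, 0, noise) else 0
  structure(data.frame(frame = seq_len(n_frames),
                       time_s = (seq_len(n_frames) - 1) * 0.05,
                       E = E, valid = TRUE),
            trace_id = "sq", exposure = 0.05,
            valid_range = c(1L, n_frames), true_state = st,
            class = c("fret_trace", "data.frame"))
}

# Brute-force HMM likelihood: sum over all K^T state paths.
brute_force_loglik <- function(obs, mu, sd, trans, pi) {
  K <- length(mu); n <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    st <- as.integer(paths[r, ])
    p <- pi[st[1]] * prod(dnorm(obs, mu[st], sd[st]))
    if (n > 1)
      p <- p * prod(trans[cbind(st[-n], st[-1])])
    tot <- tot + p
  }
  log(tot)
}

# Memoized heavy pipeline runs shared across acceptance tests.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, maker) {
  if (!exists(key, envir = .run_cache))
    assign(key, maker(), envir = .run_cache)
  get(key, envir = .run_cache)
}

sin_replicates <- function(n_rep = 10) {
  cached_run("sin_reps", function() {
    lapply(seq_len(n_rep), function(r) {
      cfg <- run_config("sin37", n_traces = 200, seed = 1000 + r,
                        do_kinetics = (r == 1))
      run_pipeline(cfg, quiet = TRUE)
    })
  })
}

tn3_run <- function() {
  cached_run("tn3", function() {
    run_pipeline(run_config("tn3", n_traces = 200, seed = 2001),
                 quiet = TRUE)
  })
}
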