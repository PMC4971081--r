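# Shared full-experiment bundle for the behavioural / imaging test suites.
# One synthetic substrate, one 36-trial design, several retained simulated
# subjects with ISA and BOLD, plus the connectome-only stimulation control.
# Built once per test session (a few minutes) and reused by every test that
# needs whole-experiment data.

experiment_bundle <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- default_config()
    con <- synthesize_connectome(n_nodes = 128, density = 0.1, seed = 501)
    hy <- suppressWarnings(
      build_embedding(con, G = cfg$embedding$G, host_collision = "next",
                      seed = 502))
    des <- build_dms_design(seed = 503)
    subjects <- suppressWarnings(
      generate_subjects(hy, des, n_subjects = 6, config = cfg,
                        max_attempts = 12, seed = 504))
    bold <- lapply(subjects, function(s)
      balloon_bold(s$recordings$isa, bin_s = s$recordings$isa_window_ms / 1000,
                   TR = 2))
    v1_host <- hy$placements$V1h$host
    stim <- run_connectome_stimulation(con, v1_host, design = des,
                                       amplitude = 1, config = cfg,
                                       seed = 505)
    cache <<- list(cfg = cfg, con = con, hybrid = hy, design = des,
                   subjects = subjects, bold = bold, stim = stim)
    cache
  }
})

phase_steps <- function(design, k, phase, dt_ms = 5) {
  tr <- design$trials[k, ]
  lim <- switch(phase,
                s1 = c(tr$onset, tr$s1_off),
                delay = c(tr$s1_off, tr$s2_on),
                s2 = c(tr$s2_on, tr$s2_off),
                iti = c(tr$s2_off, tr$end))
  (round(lim[1] * 1000 / dt_ms) + 1):round(lim[2] * 1000 / dt_ms)
}

# mean module activity over the late part of the delay (memory expression,
# past the decay transient of the sample response)
delay_activity <- function(rec, design, rows, module) {
  mean(vapply(rows, function(k) {
    stp <- phase_steps(design, k, "delay")
    stp <- stp[stp > min(stp) + 100]          # skip first 0.5 s
    mean(rec$mod_mean[stp, module])
  }, 0))
}

# stimulus-period response amplitude: strongest-unit activity while a
# stimulus is on screen (insensitive to how many cells a pattern activates)
stim_amplitude <- function(rec, design, rows, module) {
  mean(vapply(rows, function(k) {
    stp <- c(phase_steps(design, k, "s1"), phase_steps(design, k, "s2"))
    stp <- stp[seq(60, length(stp))]          # past onset transient
    mean(rec$mod_max[stp, module])
  }, 0))
}
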