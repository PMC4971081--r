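#' Default connectome-node (Wilson-Cowan) parameters
#'
#' Classical Wilson-Cowan population constants as used for whole-brain
#' node dynamics: time constants in ms, a sigmoid per population, within-unit
#' weights, and the additive-noise standard deviation of the stochastic Euler
#' scheme.  `a_Gamma = NA` means "use the hybrid network's long-range coupling
#' constant G", so a single global coupling scale governs node-to-node,
#' node-to-module and module-to-node connections.
#'
#' @return named list of parameters.
#' @export
default_tvb_params <- function() {
  list(
    tau_E = 10, tau_I = 10,            # ms
    k_E = 1, k_I = 1, r_E = 1, r_I = 1,
    alpha_E = 1, alpha_I = 1,
    c_EE = 12, c_EI = 4, c_IE = 13, c_II = 11,
    theta_E = 0, theta_I = 0,
    a_E = 1.2, b_E = 2.8, c_sigE = 1,  # excitatory sigmoid (slope, centre, max)
    a_I = 1.0, b_I = 4.0, c_sigI = 1,
    a_Gamma = NA_real_,
    # additive-noise diffusion coefficient (units / sqrt(ms)): sized so the
    # connectome nodes are a vigorous noise source whose fluctuations
    # dominate ROI synaptic activity outside stimulus-driven episodes
    noise_sd = 0.10,
    conduction_speed = 3               # mm / ms
  )
}

#' Default task-unit (modified Wilson-Cowan) parameters
#'
#' The task units follow a rate-of-change / rate-of-decay form with a
#' unit-logistic response: `dE = Delta * sigma(K_E * (w_EE E + w_IE I + in_E -
#' phi_E + N)) - delta * E` and analogously for I (which has no
#' inhibitory-to-inhibitory self-connection).  `Delta = delta` keeps
#' activities in [0, 1].  Input thresholds `phi_E` differ per module; they set
#' which populations respond to feed-forward drive alone (sensory modules) and
#' which require attention or recurrent support (prefrontal modules).
#' Values were calibrated once against the task's behavioural repertoire
#' (delay-period activity under attention, match-specific response) and are
#' all overridable through the configuration file.
#'
#' @return named list of parameters; `phi_E_module` holds per-module
#'   excitatory thresholds overriding `phi_E`.
#' @export
default_lsnm_params <- function() {
  list(
    Delta = 0.05, delta = 0.05,        # ms^-1: rate of change / decay
    K_E = 12, K_I = 12,
    w_EE = 0.1, w_IE = -0.15, w_EI = 0.5,
    phi_E = 0.5, phi_I = 0.4,
    phi_E_module = c(V1h = 0.5, V1v = 0.5, V4h = 0.5, V4c = 0.62, V4v = 0.5,
                     IT = 0.5, FS = 0.45, D1 = 0.28, D2 = 0.45, FR = 0.75),
    # D2 units carry strong within-unit inhibition: their I elements, driven
    # by the stored trace, gate which units may ignite (memory protection)
    w_IE_module = c(D2 = -0.5),
    noise_sd = 0.025                   # s.d. of N(t), per unit per step
  )
}

#' Default Balloon-Windkessel parameters
#'
#' The standard published hemodynamic constants at 1.5 T: resting venous
#' volume fraction `V0`, resting oxygen extraction `E0`, echo time `TE` (s),
#' intra/extra-vascular signal ratio `epsilon_ratio`, intravascular relaxation
#' slope `r0` (1/s), frequency offset `theta0` (1/s), mean transit time `tau0`
#' (s), vessel stiffness `alpha`, neuronal efficacy `efficacy`, signal decay
#' `tau_s` (s) and flow autoregulation `tau_f` (s).
#'
#' @return named list.
#' @export
default_balloon_params <- function() {
  list(V0 = 0.02, E0 = 0.34, TE = 0.040,
       epsilon_ratio = 1.43, r0 = 25, theta0 = 40.3,
       tau0 = 2.0, alpha = 0.32,
       efficacy = 0.5, tau_s = 2.0, tau_f = 4.0)
}

#' Full default run configuration
#'
#' One nested list covering every stage: synthetic substrate, embedding,
#' node and unit dynamics, experiment design and forward models.  Any subset
#' can be overridden from a YAML file via [load_config()].
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    connectome = list(n_nodes = 998L, density = 0.03, decay_mm = 40,
                      weight_scale = 0.5, extent = c(70, 90, 60)),
    embedding = list(G = 0.15, coupling_sd_frac = 0.1, k_roi = 5L,
                     host_collision = "next"),
    tvb = default_tvb_params(),
    lsnm = default_lsnm_params(),
    weights = list(),                 # named "src->dst" overrides, w only
    experiment = list(n_blocks = 12L, attention_range = c(0.24, 0.34),
                      ctl_attention = 0.05, stim_amplitude = 0.7,
                      degraded_retention = 0.5,
                      match_pattern = c(TRUE, FALSE, TRUE),
                      dt_ms = 5, warmup_ms = 500),
    balloon = default_balloon_params(),
    analysis = list(TR = 2, isa_window_ms = 50, lag = 0L,
                    timepoints = c(4L, 5L, 6L))
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", here)
    bv <- base[[key]]
    ov <- override[[key]]
    if (is.list(bv) && !is.null(names(bv)) && path != "weights") {
      if (!is.list(ov))
        stop("configuration key ", here, " must be a mapping")
      base[[key]] <- merge_config(bv, ov, here)
    } else {
      # YAML maps of numbers come back as named lists; named numeric
      # parameter vectors (per-module overrides) need re-flattening
      if (is.numeric(bv) && is.list(ov) &&
          length(ov) && all(vapply(ov, is.numeric, TRUE)))
        ov <- unlist(ov)
      if (is.numeric(bv) && !is.numeric(ov))
        stop("type mismatch for configuration key ", here,
             ": expected numeric")
      if (is.character(bv) && !is.character(ov))
        stop("type mismatch for configuration key ", here,
             ": expected character")
      if (is.logical(bv) && !is.logical(ov))
        stop("type mismatch for configuration key ", here,
             ": expected logical")
      base[[key]] <- ov
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, applies it over [default_config()], rejects unknown
#' keys, and checks types against the defaults.  The `weights` section is a
#' free mapping from `"src->dst"` template names to weight overrides.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("configuration file not found: ", path)
  over <- yaml::read_yaml(path)
  if (is.null(over)) return(cfg)
  if (!is.null(over$weights)) {
    w <- over$weights
    over$weights <- NULL
    cfg$weights <- utils::modifyList(cfg$weights, w)
  }
  merge_config(cfg, over)
}

#' Write a configuration to YAML
#' @param cfg configuration list.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  # named parameter vectors must serialize as YAML maps to keep their names
  mapify <- function(x) {
    if (is.list(x)) lapply(x, mapify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(mapify(cfg), path)
  invisible(path)
}
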