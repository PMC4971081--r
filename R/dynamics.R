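#' Sigmoid population response
#'
#' `c / (1 + exp(-a * (f - b)))`: strictly increasing in the input `f`,
#' saturating at `c`.
#'
#' @param f input (any numeric vector).
#' @param a slope, `b` centre, `c` maximum (> 0).
#' @param b,c see above.
#' @return response in (0, c).
#' @export
sigmoid_response <- function(f, a, b, c) {
  if (any(c <= 0)) stop("sigmoid maximum c must be positive")
  c / (1 + exp(-a * (f - b)))
}

#' Long-range coupling sum
#'
#' `a_Gamma * sum_k u_k E_k` over the incoming connections of one target:
#' linear in the coupling scale and in each source activity.  Source
#' activities are the delayed values for connectome sources.
#'
#' @param E_sources source activities.
#' @param incoming_weights weights aligned with `E_sources`.
#' @param a_Gamma coupling scale.
#' @return scalar coupling term.
#' @export
long_range_coupling <- function(E_sources, incoming_weights, a_Gamma) {
  if (length(E_sources) != length(incoming_weights))
    stop("source activities and weights differ in length")
  a_Gamma * sum(incoming_weights * E_sources)
}

#' Connectome-node Wilson-Cowan derivative
#'
#' `dE = (1/tau_E) * (-E + (k_E - r_E E) * S_E[alpha_E (c_EE E - c_IE I -
#' theta_E + Gamma)])` and the analogous inhibitory form with
#' `(c_EI E - c_II I - theta_I + Gamma)`.  The local-neighbourhood coupling
#' of surface-based simulations is not part of this model.
#'
#' @param E,I node state (vectors ok).
#' @param p parameter list, see [default_tvb_params()].
#' @param Gamma_in long-range coupling input (same length as `E`).
#' @return list with `dE`, `dI` (per ms).
#' @export
connectome_node_derivative <- function(E, I, p, Gamma_in = 0) {
  SE <- sigmoid_response(p$alpha_E * (p$c_EE * E - p$c_IE * I - p$theta_E +
                                        Gamma_in),
                         p$a_E, p$b_E, p$c_sigE)
  SI <- sigmoid_response(p$alpha_I * (p$c_EI * E - p$c_II * I - p$theta_I +
                                        Gamma_in),
                         p$a_I, p$b_I, p$c_sigI)
  list(dE = (-E + (p$k_E - p$r_E * E) * SE) / p$tau_E,
       dI = (-I + (p$k_I - p$r_I * I) * SI) / p$tau_I)
}

#' Task-unit (modified Wilson-Cowan) derivative
#'
#' `dE = Delta * logistic(K_E * (w_EE E + w_IE I + in_E - phi_E + N)) -
#' delta * E`; `dI = Delta * logistic(K_I * (w_EI E + in_I - phi_I + N)) -
#' delta * I`.  There is no inhibitory self-connection.
#'
#' @param E,I unit state.
#' @param p parameter list, see [default_lsnm_params()]; `phi_E`/`phi_I` may
#'   be vectors aligned with the state.
#' @param in_E,in_I afferent input to the excitatory / inhibitory element.
#' @param noise noise sample N(t) (shared by both elements of a unit).
#' @return list with `dE`, `dI` (per ms).
#' @export
lsnm_unit_derivative <- function(E, I, p, in_E = 0, in_I = 0, noise = 0) {
  xE <- p$K_E * (p$w_EE * E + p$w_IE * I + in_E - p$phi_E + noise)
  xI <- p$K_I * (p$w_EI * E + in_I - p$phi_I + noise)
  list(dE = p$Delta * stats::plogis(xE) - p$delta * E,
       dI = p$Delta * stats::plogis(xI) - p$delta * I)
}

#' Afferent input sums of one task unit
#'
#' `in_E = sum_j wE_j E_j + sum_j wI_j I_j + sum_j c_j z_j C_j + drive` —
#' task-unit excitatory afferents, inhibitory afferents, connectome afferents
#' (coupling sample times structural weight times delayed node activity) and
#' external stimulus/attention drive; `in_I = sum_k wE_k E_k + sum_k wI_k
#' I_k` only, as connectome nodes never project to inhibitory elements.
#'
#' @param E_weights,E_sources weights and activities of excitatory task-unit
#'   afferents (split per target via `target`).
#' @param I_weights,I_sources weights and activities of inhibitory task-unit
#'   afferents.
#' @param coupling,structural,connectome_E per-afferent coupling samples,
#'   structural weights, and delayed connectome activities.
#' @param drive external drive onto the excitatory element.
#' @param target which element the unit-sourced terms feed (`"E"` or `"I"`).
#' @return list with `in_E` and `in_I`.
#' @export
lsnm_inputs <- function(E_weights = numeric(0), E_sources = numeric(0),
                        I_weights = numeric(0), I_sources = numeric(0),
                        coupling = numeric(0), structural = numeric(0),
                        connectome_E = numeric(0), drive = 0,
                        target = c("E", "I")) {
  target <- match.arg(target)
  unit_term <- sum(E_weights * E_sources) + sum(I_weights * I_sources)
  conn_term <- sum(coupling * structural * connectome_E)
  if (target == "E")
    list(in_E = unit_term + conn_term + drive, in_I = 0)
  else
    list(in_E = conn_term + drive, in_I = unit_term)
}

per_unit_param <- function(lsnm, modules, name) {
  base <- lsnm[[name]]
  ov <- lsnm[[paste0(name, "_module")]]
  val <- rep(base, length(modules) * LSNM_UNITS)
  if (!is.null(ov)) {
    for (m in seq_along(modules)) {
      nm <- modules[m]
      if (nm %in% names(ov))
        val[((m - 1) * LSNM_UNITS + 1):(m * LSNM_UNITS)] <- ov[[nm]]
    }
  }
  val
}

per_unit_phi <- function(lsnm, modules, which = c("E", "I")) {
  which <- match.arg(which)
  per_unit_param(lsnm, modules, if (which == "E") "phi_E" else "phi_I")
}

#' Prepare a hybrid network for integration
#'
#' Precompiles everything the stepper needs: by-lag sparse coupling matrices
#' of the connectome (conduction delays from tract length over conduction
#' speed, rounded to the nearest step, at least one step when the speed is
#' finite), the module feedback matrix, per-module connectome-to-unit
#' coupling matrices (Gaussian samples times structural weight), the compiled
#' inter-module weight matrices, and per-unit thresholds.
#'
#' @param hybrid a `hybrid_network` (or `NULL` for a connectome-only model).
#' @param con connectome; defaults to the hybrid's substrate.
#' @param tvb,lsnm parameter lists.
#' @param wset weight set.
#' @param multipliers per-template subject multipliers.
#' @param dt integration step, ms.
#' @return object of class `hybrid_model`.
#' @export
prepare_model <- function(hybrid = NULL, con = hybrid$connectome,
                          tvb = default_tvb_params(),
                          lsnm = default_lsnm_params(),
                          wset = default_weight_set(),
                          multipliers = NULL, dt = 5) {
  if (dt <= 0) stop("dt must be positive")
  stopifnot(inherits(con, "connectome"))
  n <- con$n_nodes
  aG <- if (is.na(tvb$a_Gamma))
    (if (!is.null(hybrid)) hybrid$long_range_G else 1) else tvb$a_Gamma
  speed <- tvb$conduction_speed
  # conduction lags in integer steps, per directed edge
  W <- con$weights
  has_edge <- W > 0
  if (is.infinite(speed)) {
    lag <- matrix(0L, n, n)
  } else {
    tl <- if (!is.null(con$tract_lengths)) con$tract_lengths else
      matrix(0, n, n)
    lag <- matrix(pmax(1L, as.integer(round(tl / (speed * dt)))), n, n)
  }
  lag[!has_edge] <- 0L
  # delayed coupling as flat edge arrays: contribution of edge (src -> dst)
  # is gathered from the ring buffer at the edge's lag and summed per target
  eidx <- which(has_edge, arr.ind = TRUE)
  ord <- order(eidx[, 2])                       # group by target node
  e_src <- eidx[ord, 1]
  e_dst <- eidx[ord, 2]
  e_w <- W[eidx][ord]
  e_lag <- lag[eidx][ord]
  e_udst <- unique(e_dst)
  buf_len <- max(1L, max(c(0L, e_lag)) + 1L)

  model <- list(con = con, hybrid = hybrid, tvb = tvb, lsnm = lsnm,
                dt = dt, n = n, aG = aG,
                e_src = e_src, e_dst = e_dst, e_w = e_w, e_lag = e_lag,
                e_udst = e_udst, buf_len = buf_len)
  if (!is.null(hybrid)) {
    modules <- names(hybrid$placements)
    L <- length(modules) * LSNM_UNITS
    cw <- compile_weights(wset, modules, multipliers)
    # stacked unit matrix: rows 1..L give E-element inputs, L+1..2L the
    # I-element inputs, so one sparse product serves both per step
    MEI <- rbind(cw$ME, cw$MI)
    cmods <- list()
    for (m in seq_along(modules)) {
      p <- hybrid$placements[[m]]
      un <- ((m - 1L) * LSNM_UNITS + 1L):(m * LSNM_UNITS)
      if (length(p$afferents)) {
        cmods[[m]] <- list(
          units = un, aff = p$afferents,
          lag = lag[cbind(p$afferents, rep(p$host, length(p$afferents)))],
          # feedback weight z/81 per unit: the module aggregate equals
          # z * mean(E_units), applied to each afferent node
          fbw = p$feedback_weights * LSNM_UNITS,
          # 81 x n_aff: coupling sample times structural weight
          CM = t(p$coupling_samples * p$structural_weights),
          receives = p$receives_connectome_input)
      } else {
        cmods[[m]] <- list(units = un, aff = integer(0), lag = integer(0),
                           fbw = numeric(0),
                           CM = matrix(0, LSNM_UNITS, 0), receives = FALSE)
      }
    }
    model <- c(model, list(
      modules = modules, L = L, ME = cw$ME, MI = cw$MI, MEI = MEI,
      absME = cw$absME, absMI = cw$absMI,
      nonneg_ME = all(cw$ME@x >= 0), nonneg_MI = all(cw$MI@x >= 0),
      cmods = cmods,
      phiE = per_unit_phi(lsnm, modules, "E"),
      phiI = per_unit_phi(lsnm, modules, "I"),
      wIE = per_unit_param(lsnm, modules, "w_IE"),
      att_units = module_units(hybrid, wset$attention_target),
      stim_units = list(h = module_units(hybrid, wset$stim_targets[["h"]]),
                        v = module_units(hybrid, wset$stim_targets[["v"]]))))
  } else {
    model <- c(model, list(modules = character(0), L = 0L))
  }
  class(model) <- "hybrid_model"
  model
}

#' Initial state of a hybrid model
#' @param model a `hybrid_model`.
#' @return state list: `E_T`, `I_T`, `E_L`, `I_L`, delay buffer and step
#'   counter.
#' @export
init_state <- function(model) {
  n <- model$n
  list(E_T = rep(0.1, n), I_T = rep(0.1, n),
       E_L = rep(0.01, model$L), I_L = rep(0.01, model$L),
       buf = matrix(0.1, n, model$buf_len), step = 0L)
}

#' Drive vector from a stimulus pattern and attention level
#' @param model a `hybrid_model` with task modules.
#' @param pattern a `stimulus_pattern` or `NULL`.
#' @param attention attention level added to the attention-target module.
#' @param amplitude stimulus drive amplitude per active cell.
#' @return numeric vector of per-unit excitatory drive.
#' @export
drive_vector <- function(model, pattern = NULL, attention = 0,
                         amplitude = 0.7) {
  drv <- numeric(model$L)
  if (!is.null(pattern)) {
    drv[model$stim_units$h] <- amplitude * as.vector(t(pattern$h))
    drv[model$stim_units$v] <- amplitude * as.vector(t(pattern$v))
  }
  drv[model$att_units] <- drv[model$att_units] + attention
  drv
}

# One stochastic Euler step of the full hybrid network.  `drive` is the
# per-unit excitatory drive; `node_drive` an optional additive input to the
# connectome coupling term (used by pulse stimulation).  Returns the updated
# state; when `need_IN` is TRUE, attaches the per-unit and per-node summed
# absolute synaptic inputs used by the imaging forward model.
step_core <- function(model, st, drive = NULL, node_drive = NULL,
                      need_IN = FALSE) {
  tvb <- model$tvb
  lsnm <- model$lsnm
  dt <- model$dt
  n <- model$n
  L <- model$L
  step <- st$step + 1L
  B <- model$buf_len
  pos <- (step - 1L) %% B + 1L
  st$buf[, pos] <- st$E_T
  # delayed long-range coupling among connectome nodes (edge gather)
  Gam <- numeric(n)
  if (length(model$e_src)) {
    cols <- (step - 1L - model$e_lag) %% B
    contrib <- model$e_w * st$buf[cols * n + model$e_src]
    Gam[model$e_udst] <- rowsum(contrib, model$e_dst, reorder = FALSE)
  }
  if (L > 0) {
    for (cm in model$cmods) {
      if (length(cm$aff))
        Gam[cm$aff] <- Gam[cm$aff] +
          cm$fbw * (sum(st$E_L[cm$units]) / LSNM_UNITS)
    }
  }
  if (!is.null(node_drive)) Gam <- Gam + node_drive
  Gam <- model$aG * Gam
  d <- connectome_node_derivative(st$E_T, st$I_T, tvb, Gam)
  sdt <- sqrt(dt) * tvb$noise_sd
  E_T <- st$E_T + dt * d$dE + if (sdt > 0) sdt * stats::rnorm(n) else 0
  I_T <- st$I_T + dt * d$dI + if (sdt > 0) sdt * stats::rnorm(n) else 0

  IN_nodes <- NULL
  IN_units <- NULL
  if (need_IN)
    IN_nodes <- (tvb$c_EE + tvb$c_EI) * abs(st$E_T) +
      (abs(tvb$c_IE) + abs(tvb$c_II)) * abs(st$I_T) + 2 * abs(Gam)

  if (L > 0) {
    if (is.null(drive)) drive <- numeric(L)
    both <- as.numeric(model$MEI %*% st$E_L)
    mev <- both[seq_len(L)]
    miv <- both[L + seq_len(L)]
    inE <- mev + drive
    conn_in <- numeric(L)
    for (cm in model$cmods) {
      if (cm$receives && length(cm$aff)) {
        cols <- (step - 1L - cm$lag) %% B
        Cdel <- st$buf[cols * n + cm$aff]
        conn_in[cm$units] <- as.numeric(cm$CM %*% Cdel)
      }
    }
    inE <- inE + conn_in
    inI <- miv
    noise <- if (lsnm$noise_sd > 0) stats::rnorm(L, 0, lsnm$noise_sd) else
      numeric(L)
    xE <- lsnm$K_E * (lsnm$w_EE * st$E_L + model$wIE * st$I_L + inE -
                        model$phiE + noise)
    xI <- lsnm$K_I * (lsnm$w_EI * st$E_L + inI - model$phiI + noise)
    if (need_IN)
      IN_units <- (lsnm$w_EE + lsnm$w_EI) * st$E_L +
        abs(model$wIE) * st$I_L +
        (if (model$nonneg_ME) mev else
           as.numeric(model$absME %*% st$E_L)) +
        (if (model$nonneg_MI) miv else
           as.numeric(model$absMI %*% st$E_L)) + conn_in + drive
    E_L <- st$E_L + dt * (lsnm$Delta * stats::plogis(xE) -
                            lsnm$delta * st$E_L)
    I_L <- st$I_L + dt * (lsnm$Delta * stats::plogis(xI) -
                            lsnm$delta * st$I_L)
    st$E_L <- pmin(1, pmax(0, E_L))
    st$I_L <- pmin(1, pmax(0, I_L))
  }
  st$E_T <- E_T
  st$I_T <- I_T
  st$step <- step
  if (need_IN) {
    st$IN_units <- IN_units
    st$IN_nodes <- IN_nodes
  }
  st
}

#' Advance the hybrid network by one stochastic Euler step
#'
#' Explicit Euler with additive Gaussian noise for the connectome populations
#' and threshold noise for the task units; connectome-sourced signals are
#' read from the delay buffer, task-internal connections are undelayed, and
#' task-unit activities are clamped to [0, 1].
#'
#' @param model a `hybrid_model`.
#' @param state state from [init_state()] or a previous step.
#' @param drive optional per-unit excitatory drive (see [drive_vector()]).
#' @param node_drive optional additive input to the connectome coupling sum.
#' @return updated state.
#' @export
step_network <- function(model, state, drive = NULL, node_drive = NULL) {
  stopifnot(inherits(model, "hybrid_model"))
  step_core(model, state, drive, node_drive)
}
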