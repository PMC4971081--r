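#' Generate a simulated subject
#'
#' A subject is a set of per-template multipliers in [0.95, 1] applied to the
#' feed-forward inter-module connections only; recurrent and feedback
#' templates are untouched.  Reproducible under a fixed seed.
#'
#' @param wset an `lsnm_weight_set`.
#' @param seed optional integer seed.
#' @return object of class `subject_weights`.
#' @export
generate_subject <- function(wset = default_weight_set(), seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  ff <- feedforward_templates(wset)
  mult <- stats::setNames(stats::runif(length(ff), 0.95, 1), ff)
  structure(list(multipliers = mult, seed = seed), class = "subject_weights")
}

segment_plan <- function(design, model, stim_amplitude) {
  seg <- design_segments(design)
  dt <- model$dt
  plans <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    pattern <- if (s$phase %in% c("s1", "s2"))
      design$stimuli[[s$trial]][[s$phase]] else NULL
    plans[[i]] <- list(
      from = as.integer(round(s$t0 * 1000 / dt)) + 1L,
      to = as.integer(round(s$t1 * 1000 / dt)),
      drive = drive_vector(model, pattern, s$attention, stim_amplitude))
  }
  plans
}

make_roi_matrix <- function(rois, L, n) {
  idx <- lapply(rois, function(r)
    c(r$units, L + r$nodes))
  i <- rep(seq_along(rois), lengths(idx))
  Matrix::sparseMatrix(i = i, j = unlist(idx), x = 1,
                       dims = c(length(rois), L + n))
}

simulate_schedule <- function(model, plans, n_steps, warmup_steps = 0,
                              seed = NULL, record = c("summary", "full"),
                              rois = NULL, node_plans = NULL) {
  record <- match.arg(record)
  if (!is.null(seed)) set.seed(seed)
  L <- model$L
  n <- model$n
  M <- length(model$modules)
  dt <- model$dt
  need_IN <- !is.null(rois)
  hosts <- if (!is.null(model$hybrid))
    vapply(model$hybrid$placements, function(p) p$host, 0L) else integer(0)
  fr_idx <- if ("FR" %in% model$modules)
    module_units(model$hybrid, "FR") else NULL

  # per-step plan lookup tables (0 = no drive)
  plan_of <- integer(n_steps)
  for (i in seq_along(plans)) {
    p <- plans[[i]]
    if (p$from <= n_steps)
      plan_of[p$from:min(p$to, n_steps)] <- i
  }
  node_plan_of <- integer(n_steps)
  for (i in seq_along(node_plans)) {
    p <- node_plans[[i]]
    if (p$from <= n_steps)
      node_plan_of[p$from:min(p$to, n_steps)] <- i
  }
  drive_at <- function(step) {
    i <- plan_of[step]
    if (i > 0) plans[[i]]$drive else NULL
  }
  node_drive_at <- function(step) {
    i <- node_plan_of[step]
    if (i > 0) node_plans[[i]]$drive else NULL
  }

  bin_steps <- as.integer(round(50 / dt))   # 50-ms synaptic-activity bins
  if (need_IN) {
    Risa <- make_roi_matrix(rois, L, n)
    n_bins <- n_steps %/% bin_steps
    isa <- matrix(0, n_bins, length(rois),
                  dimnames = list(NULL, names(rois)))
  }
  if (M > 0) {
    mod_mean <- matrix(NA_real_, n_steps, M,
                       dimnames = list(NULL, model$modules))
    mod_max <- mod_mean
    host_E <- mod_mean
  }
  if (!is.null(fr_idx)) fr_E <- matrix(NA_real_, n_steps, LSNM_UNITS)
  if (record == "full") {
    full <- list(E_L = matrix(NA_real_, n_steps, L),
                 I_L = matrix(NA_real_, n_steps, L),
                 E_T = matrix(NA_real_, n_steps, n),
                 I_T = matrix(NA_real_, n_steps, n))
  }
  target_E <- if (is.null(node_plans)) NULL else matrix(NA_real_, n_steps, n)

  st <- init_state(model)
  for (w in seq_len(warmup_steps))
    st <- step_core(model, st, drive = NULL, node_drive = NULL)
  st$step <- 0L                      # recorded clock starts at experiment t0
  for (s in seq_len(n_steps)) {
    st <- step_core(model, st, drive = drive_at(s),
                    node_drive = node_drive_at(s), need_IN = need_IN)
    if (M > 0) {
      em <- matrix(st$E_L, nrow = LSNM_UNITS)
      mod_mean[s, ] <- colMeans(em)
      for (m in seq_len(M)) mod_max[s, m] <- max(em[, m])
      host_E[s, ] <- st$E_T[hosts]
    }
    if (!is.null(fr_idx)) fr_E[s, ] <- st$E_L[fr_idx]
    if (need_IN) {
      b <- (s - 1L) %/% bin_steps + 1L
      if (b <= nrow(isa))
        isa[b, ] <- isa[b, ] +
          as.numeric(Risa %*% c(st$IN_units, st$IN_nodes))
    }
    if (record == "full") {
      if (L > 0) {
        full$E_L[s, ] <- st$E_L
        full$I_L[s, ] <- st$I_L
      }
      full$E_T[s, ] <- st$E_T
      full$I_T[s, ] <- st$I_T
    }
    if (!is.null(target_E)) target_E[s, ] <- st$E_T
  }
  out <- list(dt = dt, n_steps = n_steps, modules = model$modules,
              isa_window_ms = bin_steps * dt)
  if (M > 0) {
    out$mod_mean <- mod_mean
    out$mod_max <- mod_max
    out$host_E <- host_E
  }
  if (!is.null(fr_idx)) out$fr_E <- fr_E
  if (need_IN) {
    out$isa <- isa
    out$rois <- rois
  }
  if (record == "full") out$full <- full
  if (!is.null(target_E)) out$node_E <- target_E
  structure(out, class = "recordings")
}

#' @export
print.recordings <- function(x, ...) {
  cat(sprintf("recordings: %d steps at %g ms (%g s)%s%s\n",
              x$n_steps, x$dt, x$n_steps * x$dt / 1000,
              if (length(x$modules)) paste0(", ", length(x$modules),
                                            " modules") else "",
              if (!is.null(x$isa)) paste0(", ISA for ", ncol(x$isa),
                                          " ROIs") else ""))
  invisible(x)
}

#' Run a DMS experiment on a hybrid network
#'
#' Integrates the full hybrid network over the design, applying the stimulus
#' and attention drives of each trial phase, and records module summaries,
#' host-node activity, response-module unit traces, and ROI-level integrated
#' synaptic activity.
#'
#' @param hybrid a `hybrid_network`.
#' @param design an `experiment_design`.
#' @param subject optional `subject_weights`.
#' @param config run configuration (see [default_config()]).
#' @param rois ROI list for synaptic-activity integration; by default the
#'   region-level ROIs plus the contralateral-IT control region.
#' @param seed integer seed for the run's noise.
#' @param record `"summary"` or `"full"` (per-step state of every unit and
#'   node; only sensible for short runs).
#' @return a `recordings` object with the design attached.
#' @export
run_experiment <- function(hybrid, design, subject = NULL,
                           config = default_config(), rois = NULL,
                           seed = NULL, record = "summary") {
  stopifnot(inherits(hybrid, "hybrid_network"),
            inherits(design, "experiment_design"))
  if (design$n_blocks == 0) stop("design has no trials")
  wset <- override_weights(default_weight_set(), config$weights)
  model <- prepare_model(hybrid, tvb = config$tvb, lsnm = config$lsnm,
                         wset = wset,
                         multipliers = subject$multipliers,
                         dt = config$experiment$dt_ms)
  if (is.null(rois)) {
    rois <- region_rois(hybrid, k = config$embedding$k_roi)
    rois$cIT <- contralateral_roi(hybrid, "IT", k = config$embedding$k_roi,
                                  exclude = unlist(lapply(rois, `[[`,
                                                          "nodes")))
  }
  plans <- segment_plan(design, model, config$experiment$stim_amplitude)
  n_steps <- as.integer(round(design$duration * 1000 / model$dt))
  warmup_steps <- as.integer(round(config$experiment$warmup_ms / model$dt))
  rec <- simulate_schedule(model, plans, n_steps, warmup_steps,
                           seed = seed, record = record, rois = rois)
  rec$design <- design
  rec
}

#' Score one trial from response-module traces
#'
#' A response is registered when at least `min_units` units exceed the
#' `threshold` (strictly) at any step of the response window; a DMS trial is
#' correct when the model responds on a match and withholds on a mismatch.
#'
#' @param fr_trace steps x units activity matrix of the response module.
#' @param window integer step indices of the response window.
#' @param threshold response threshold.
#' @param min_units minimum number of supra-threshold units.
#' @param match logical match flag (NA for control trials).
#' @return list: `responded`, `correct`, `n_above`.
#' @export
score_trial <- function(fr_trace, window, threshold = 0.7, min_units = 2,
                        match = NA) {
  if (length(window) == 0) stop("empty response window")
  if (max(window) > nrow(fr_trace)) stop("window outside trace")
  peak <- apply(fr_trace[window, , drop = FALSE], 2, max)
  n_above <- sum(peak > threshold)
  responded <- n_above >= min_units
  list(responded = responded,
       correct = if (is.na(match)) NA else
         (responded && match) || (!responded && !match),
       n_above = n_above)
}

#' Score all trials of an experiment
#'
#' @param rec a `recordings` from [run_experiment()] (needs `fr_E` and the
#'   attached design).
#' @param design design override; defaults to the one attached to `rec`.
#' @inheritParams score_trial
#' @return data.frame with one row per trial.
#' @export
score_experiment <- function(rec, design = rec$design, threshold = 0.7,
                             min_units = 2) {
  if (is.null(rec$fr_E)) stop("recordings lack response-module traces")
  tr <- design$trials
  out <- lapply(seq_len(nrow(tr)), function(k) {
    t <- tr[k, ]
    win <- (as.integer(round(t$s2_on * 1000 / rec$dt)) + 1L):
      as.integer(round(t$s2_off * 1000 / rec$dt))
    sc <- score_trial(rec$fr_E, win, threshold, min_units,
                      match = if (t$condition == "DMS") t$match else NA)
    data.frame(trial = t$trial, condition = t$condition, match = t$match,
               responded = sc$responded, correct = sc$correct,
               n_above = sc$n_above)
  })
  do.call(rbind, out)
}

#' Task performance over the DMS trials
#'
#' @param outcomes data.frame from [score_experiment()].
#' @return percent correct over DMS trials.
#' @export
compute_performance <- function(outcomes) {
  dms <- outcomes[outcomes$condition == "DMS", ]
  if (!nrow(dms)) stop("no DMS trials to score")
  100 * sum(dms$correct) / nrow(dms)
}

#' Generate subjects until enough pass the inclusion bound
#'
#' Mirrors the subject-generation procedure: candidate weight sets are drawn
#' (feed-forward multipliers in [0.95, 1]), each candidate performs the full
#' experiment, and candidates are retained while their DMS accuracy exceeds
#' `min_accuracy` percent, until `n_subjects` are retained or `max_attempts`
#' candidates have been tried.
#'
#' @param hybrid a `hybrid_network`.
#' @param design an `experiment_design`.
#' @param n_subjects number of subjects to retain.
#' @param config run configuration.
#' @param min_accuracy inclusion bound, percent.
#' @param max_attempts cap on candidate draws.
#' @param seed master seed; subject and run seeds are derived from it.
#' @param rois ROI list passed to [run_experiment()].
#' @param verbose print per-candidate accuracy.
#' @return list of retained subjects: each `list(subject, recordings,
#'   outcomes, accuracy)`.
#' @export
generate_subjects <- function(hybrid, design, n_subjects = 10,
                              config = default_config(), min_accuracy = 60,
                              max_attempts = 4 * n_subjects, seed = 1,
                              rois = NULL, verbose = FALSE) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1, 2 * max_attempts),
                  ncol = 2)
  wset <- override_weights(default_weight_set(), config$weights)
  retained <- list()
  attempt <- 0
  while (length(retained) < n_subjects && attempt < max_attempts) {
    attempt <- attempt + 1
    subj <- generate_subject(wset, seed = seeds[attempt, 1])
    rec <- run_experiment(hybrid, design, subject = subj, config = config,
                          rois = rois, seed = seeds[attempt, 2])
    outc <- score_experiment(rec)
    acc <- compute_performance(outc)
    if (verbose)
      message(sprintf("candidate %d: %.1f%% %s", attempt, acc,
                      if (acc > min_accuracy) "(retained)" else "(rejected)"))
    if (acc > min_accuracy)
      retained[[length(retained) + 1]] <-
        list(subject = subj, recordings = rec, outcomes = outc,
             accuracy = acc)
  }
  if (length(retained) < n_subjects)
    warning("only ", length(retained), " of ", n_subjects,
            " subjects retained after ", attempt, " attempts")
  retained
}

#' Would-be ROIs on a bare connectome
#'
#' For the connectome-only control: the node nearest each module target plus
#' its `k` nearest neighbours, with no task units.
#'
#' @param con a [connectome()].
#' @param specs module specs.
#' @param k neighbours per ROI.
#' @param regions group into anatomical regions as in [region_rois()].
#' @return named ROI list (unit sets empty).
#' @export
connectome_rois <- function(con, specs = default_module_specs(), k = 5,
                            regions = TRUE) {
  specs <- validate_module_specs(specs)
  hosts <- vapply(seq_len(nrow(specs)), function(m)
    nearest_node(con, as.numeric(specs[m, c("x", "y", "z")]))$node, 0L)
  claimed <- hosts
  per_mod <- vector("list", nrow(specs))
  for (m in seq_len(nrow(specs))) {
    d2 <- colSums((t(con$coords) - con$coords[hosts[m], ])^2)
    cand <- setdiff(order(d2), claimed)
    take <- cand[seq_len(min(k, length(cand)))]
    claimed <- c(claimed, take)
    per_mod[[m]] <- list(module = specs$name[m], region = specs$region[m],
                         units = integer(0), nodes = c(hosts[m], take))
  }
  names(per_mod) <- specs$name
  if (!regions) return(per_mod)
  regs <- unique(specs$region)
  out <- lapply(regs, function(rg) {
    mem <- per_mod[vapply(per_mod, function(r) r$region == rg, TRUE)]
    list(region = rg, units = integer(0),
         nodes = unique(unlist(lapply(mem, `[[`, "nodes"))))
  })
  names(out) <- regs
  # contralateral-IT control: mirror of the would-be IT host
  it_host <- per_mod$IT$nodes[1]
  mirror <- con$coords[it_host, ] * c(-1, 1, 1)
  d2 <- colSums((t(con$coords) - mirror)^2)
  cand <- setdiff(order(d2), claimed)
  out$cIT <- list(region = "cIT", units = integer(0),
                  nodes = cand[seq_len(min(k + 1, length(cand)))])
  out
}

#' Pulse-stimulation control on the bare connectome
#'
#' Stimulates one connectome node (the would-be V1 host) with a train of 1-s
#' pulses following the stimulus timing of the DMS design — no task modules,
#' no attention — and records ROI-level integrated synaptic activity.
#'
#' @param con a [connectome()] (un-embedded).
#' @param target node index receiving the pulses.
#' @param design an `experiment_design` supplying the pulse timing (pulses
#'   during the S1 and S2 phases of every trial).
#' @param amplitude additive pulse drive to the node's coupling input.
#' @param config run configuration.
#' @param rois ROI list, e.g. from [connectome_rois()].
#' @param seed integer seed.
#' @return a `recordings` object with ISA (and per-node traces).
#' @export
run_connectome_stimulation <- function(con, target,
                                       design = build_dms_design(seed = 0),
                                       amplitude = 1,
                                       config = default_config(),
                                       rois = NULL, seed = NULL) {
  stopifnot(inherits(con, "connectome"))
  if (target < 1 || target > con$n_nodes)
    stop("target node out of range")
  model <- prepare_model(NULL, con = con, tvb = config$tvb,
                         dt = config$experiment$dt_ms)
  if (is.null(rois)) rois <- connectome_rois(con, k = config$embedding$k_roi)
  seg <- design_segments(design)
  seg <- seg[seg$phase %in% c("s1", "s2"), ]
  nd <- numeric(con$n_nodes)
  node_plans <- lapply(seq_len(nrow(seg)), function(i) {
    v <- nd
    v[target] <- amplitude
    list(from = as.integer(round(seg$t0[i] * 1000 / model$dt)) + 1L,
         to = as.integer(round(seg$t1[i] * 1000 / model$dt)),
         drive = v)
  })
  n_steps <- as.integer(round(design$duration * 1000 / model$dt))
  warmup_steps <- as.integer(round(config$experiment$warmup_ms / model$dt))
  rec <- simulate_schedule(model, plans = list(), n_steps = n_steps,
                           warmup_steps = warmup_steps, seed = seed,
                           rois = rois, node_plans = node_plans)
  rec$design <- design
  rec$target <- target
  rec
}
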