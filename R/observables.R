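#' Summed absolute synaptic input of one task unit
#'
#' `IN_i = w_EE E_i + w_EI E_i + |w_IE I_i| + sum_k |w_ki| E_k`: the
#' within-unit synaptic drives onto both elements plus the absolute
#' long-range inputs (other task units, connectome afferents, and external
#' drives).  This is the neural quantity the hemodynamic forward model sees.
#'
#' @param E,I the unit's activities.
#' @param p task-unit parameters.
#' @param afferent_inputs vector of afferent contributions (weight times
#'   source activity, including connectome and drive terms); absolute values
#'   are taken here.
#' @return nonnegative scalar.
#' @export
unit_input_magnitude <- function(E, I, p, afferent_inputs = numeric(0)) {
  p$w_EE * E + p$w_EI * E + abs(p$w_IE * I) + sum(abs(afferent_inputs))
}

#' Integrate synaptic activity over ROIs and 50-ms windows
#'
#' Sums per-member input magnitudes over all members of an ROI and over the
#' integration window (10 steps at the default 5-ms step).
#'
#' @param IN steps x channels matrix of per-step input magnitudes.
#' @param members list of integer channel sets, one per ROI.
#' @param window_ms integration window, must be a multiple of `dt_ms`.
#' @param dt_ms step size of `IN`.
#' @return bins x ROI matrix (class `isa_series` with attributes
#'   `window_ms`).
#' @export
integrated_synaptic_activity <- function(IN, members, window_ms = 50,
                                         dt_ms = 5) {
  steps_per_bin <- window_ms / dt_ms
  if (abs(steps_per_bin - round(steps_per_bin)) > 1e-9)
    stop("window_ms must be a multiple of dt_ms")
  steps_per_bin <- as.integer(round(steps_per_bin))
  n_bins <- nrow(IN) %/% steps_per_bin
  out <- matrix(0, n_bins, length(members),
                dimnames = list(NULL, names(members)))
  bin_of <- rep(seq_len(n_bins), each = steps_per_bin)
  use <- seq_len(n_bins * steps_per_bin)
  for (r in seq_along(members)) {
    tot <- rowSums(IN[use, members[[r]], drop = FALSE])
    out[, r] <- as.numeric(rowsum(tot, bin_of))
  }
  structure(out, window_ms = window_ms, class = c("isa_series", "matrix"))
}

balloon_k <- function(p) {
  list(k1 = 4.3 * p$theta0 * p$E0 * p$TE,
       k2 = p$epsilon_ratio * p$r0 * p$E0 * p$TE,
       k3 = 1 - p$epsilon_ratio)
}

#' Balloon-Windkessel BOLD forward model
#'
#' Integrates the hemodynamic state equations from rest `(s, f, v, q) =
#' (0, 1, 1, 1)` under the neuronal drive `x(t)`:
#' `ds/dt = efficacy * x - s/tau_s - (f - 1)/tau_f`, `df/dt = s`,
#' `tau0 dv/dt = f - v^(1/alpha)`,
#' `tau0 dq/dt = f (1 - (1 - E0)^(1/f))/E0 - v^(1/alpha) q/v`,
#' and reads out `y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))` with
#' `k1 = 4.3 theta0 E0 TE`, `k2 = epsilon_ratio r0 E0 TE`,
#' `k3 = 1 - epsilon_ratio`.  The drive is the ROI's integrated synaptic
#' activity scaled to zero mean and unit range (a constant series maps to
#' zero drive); integration is explicit Euler at the ISA bin width with
#' optional sub-stepping; the result is downsampled to the scanner TR by
#' decimation.
#'
#' @param isa bins x ROI matrix of integrated synaptic activity.
#' @param params balloon parameters, see [default_balloon_params()].
#' @param bin_s ISA bin width in seconds.
#' @param TR repetition time in seconds.
#' @param substeps Euler sub-steps per ISA bin (default 10, i.e. 5 ms).
#' @param normalize scale each ROI's drive to zero mean / unit range
#'   (default); set `FALSE` to pass `isa` through as-is.
#' @return TR-sampled BOLD matrix (class `bold_series`).
#' @export
balloon_bold <- function(isa, params = default_balloon_params(),
                         bin_s = 0.05, TR = 2, substeps = 10,
                         normalize = TRUE) {
  isa <- as.matrix(isa)
  if (any(!is.finite(isa))) stop("non-finite ISA input")
  k <- balloon_k(params)
  nb <- nrow(isa)
  nr <- ncol(isa)
  y <- matrix(0, nb, nr, dimnames = dimnames(isa))
  h <- bin_s / substeps
  for (r in seq_len(nr)) {
    x <- isa[, r]
    if (normalize) {
      rng <- diff(range(x))
      x <- if (rng > 0) (x - mean(x)) / rng else rep(0, nb)
    }
    s <- 0; f <- 1; v <- 1; q <- 1
    for (b in seq_len(nb)) {
      for (ss in seq_len(substeps)) {
        ds <- params$efficacy * x[b] - s / params$tau_s -
          (f - 1) / params$tau_f
        df <- s
        dv <- (f - v^(1 / params$alpha)) / params$tau0
        dq <- (f * (1 - (1 - params$E0)^(1 / f)) / params$E0 -
                 v^(1 / params$alpha) * q / v) / params$tau0
        s <- s + h * ds; f <- f + h * df
        v <- max(v + h * dv, 1e-6); q <- max(q + h * dq, 1e-6)
      }
      y[b, r] <- params$V0 *
        (k$k1 * (1 - q) + k$k2 * (1 - q / v) + k$k3 * (1 - v))
    }
  }
  decim <- as.integer(round(TR / bin_s))
  idx <- seq(decim, nb, by = decim)
  structure(y[idx, , drop = FALSE], TR = TR, class = c("bold_series",
                                                       "matrix"))
}

#' Per-condition block signal change and DMS-CTL differences
#'
#' For each block, takes the mean signal at the given timepoints (TR indices
#' counted from the block onset, timepoint 1 being the first TR at or after
#' onset), expresses it as percent change about the series mean (signal
#' baseline 1 + y), and averages within condition; the per-ROI within-subject
#' difference is DMS minus CTL.
#'
#' @param bold TR-sampled BOLD matrix.
#' @param design an `experiment_design`.
#' @param TR repetition time, s.
#' @param timepoints TR offsets after block onset (default 4:6).
#' @return list with `per_condition` (condition x ROI means) and `difference`
#'   (named vector, DMS - CTL).
#' @export
block_signal_change <- function(bold, design, TR = 2, timepoints = 4:6) {
  bold <- as.matrix(bold)
  ons <- block_onsets(design)
  if (!nrow(ons)) stop("design has no blocks")
  if (design$block_len / TR < max(timepoints))
    stop("block shorter than the requested timepoints")
  conds <- unique(ons$condition)
  pct <- matrix(NA_real_, length(conds), ncol(bold),
                dimnames = list(conds, colnames(bold)))
  base <- 1 + colMeans(bold)
  for (ci in seq_along(conds)) {
    rows <- which(ons$condition == conds[ci])
    vals <- matrix(NA_real_, length(rows), ncol(bold))
    for (bi in seq_along(rows)) {
      onset_tr <- floor(ons$onset[rows[bi]] / TR) + 1L
      idx <- onset_tr + timepoints - 1L
      idx <- idx[idx <= nrow(bold)]
      if (!length(idx)) next
      vals[bi, ] <- colMeans(1 + bold[idx, , drop = FALSE])
    }
    pct[ci, ] <- 100 * (colMeans(vals, na.rm = TRUE) - base) / base
  }
  diff <- if (all(c("DMS", "CTL") %in% conds))
    pct["DMS", ] - pct["CTL", ] else NULL
  list(per_condition = pct, difference = diff)
}
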