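trial_timing <- function() {
  list(s1 = 1.0, delay = 1.5, s2 = 1.0, iti = 2.0)   # seconds
}

#' Build a delayed match-to-sample experiment design
#'
#' Alternating blocks of three DMS trials and three passive-viewing control
#' (CTL) trials.  Each trial presents a sample S1 for 1 s, holds a 1.5-s
#' delay, presents a probe S2 for 1 s, and ends with a 2-s inter-trial
#' interval (5.5 s per trial, 16.5 s per block).  The default 12 blocks give
#' 36 trials and 198 s.  The attention/task-control level is constant within
#' a block: evenly spaced over `attention_range` across the DMS blocks, and a
#' constant low `ctl_attention` for CTL blocks, whose stimuli are degraded
#' versions of the shapes.  Match/mismatch follows `match_pattern` within
#' each block.  Realized stimulus patterns (including the degraded-cell draws)
#' are fixed at design time, so a design is a fully reproducible object.
#'
#' @param n_blocks total number of blocks (DMS and CTL alternating, DMS
#'   first).
#' @param attention_range range of the attention parameter over DMS blocks.
#' @param ctl_attention attention level of CTL blocks.
#' @param match_pattern logical vector of length 3: match flags per block.
#' @param degraded_retention cell-retention probability of CTL stimuli.
#' @param shapes shape library.
#' @param seed optional seed for shape selection and degradation draws.
#' @return object of class `experiment_design`.
#' @export
build_dms_design <- function(n_blocks = 12, attention_range = c(0.24, 0.34),
                             ctl_attention = 0.05,
                             match_pattern = c(TRUE, FALSE, TRUE),
                             degraded_retention = 0.5,
                             shapes = shape_library(), seed = NULL) {
  stopifnot(length(attention_range) == 2,
            all(attention_range > 0 & attention_range < 1))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  tm <- trial_timing()
  trial_len <- tm$s1 + tm$delay + tm$s2 + tm$iti
  block_len <- 3 * trial_len
  shape_ids <- setdiff(names(shapes), "blank")
  # mismatch probes are drawn from shapes whose object-level footprints
  # barely overlap the sample's, as in discriminability-controlled stimulus
  # sets; fall back to any other shape when a sample has no such partner
  ovl <- shape_overlap_matrix(shapes)
  partners <- lapply(shape_ids, function(s) {
    ok <- shape_ids[ovl[s, shape_ids] <= 1 & shape_ids != s]
    if (length(ok)) ok else setdiff(shape_ids, s)
  })
  names(partners) <- shape_ids
  trials <- list()
  stimuli <- list()
  if (n_blocks > 0) {
    conds <- rep(c("DMS", "CTL"), length.out = n_blocks)
    n_dms <- sum(conds == "DMS")
    att_dms <- if (n_dms > 1)
      seq(attention_range[1], attention_range[2], length.out = n_dms)
    else mean(attention_range)
    k <- 0
    dms_i <- 0
    for (b in seq_len(n_blocks)) {
      cond <- conds[b]
      if (cond == "DMS") dms_i <- dms_i + 1
      att <- if (cond == "DMS") att_dms[dms_i] else ctl_attention
      for (j in 1:3) {
        k <- k + 1
        onset <- (b - 1) * block_len + (j - 1) * trial_len
        s1 <- sample(shape_ids, 1)
        match <- match_pattern[j]
        s2 <- if (match) s1 else sample(partners[[s1]], 1)
        degraded <- cond == "CTL"
        stimuli[[k]] <- list(
          s1 = make_stimulus(s1, degraded, degraded_retention, shapes),
          s2 = make_stimulus(s2, degraded, degraded_retention, shapes))
        trials[[k]] <- data.frame(
          trial = k, block = b, condition = cond, attention = att,
          s1 = s1, s2 = s2, match = match, degraded = degraded,
          onset = onset,
          s1_off = onset + tm$s1,
          s2_on = onset + tm$s1 + tm$delay,
          s2_off = onset + tm$s1 + tm$delay + tm$s2,
          end = onset + trial_len)
      }
    }
  }
  trials <- if (length(trials)) do.call(rbind, trials) else
    data.frame(trial = integer(0), block = integer(0),
               condition = character(0), attention = numeric(0),
               s1 = character(0), s2 = character(0), match = logical(0),
               degraded = logical(0), onset = numeric(0), s1_off = numeric(0),
               s2_on = numeric(0), s2_off = numeric(0), end = numeric(0))
  structure(
    list(trials = trials, stimuli = stimuli, timing = tm,
         block_len = block_len, n_blocks = n_blocks,
         ctl_attention = ctl_attention,
         duration = n_blocks * block_len),
    class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("DMS design: %d blocks, %d trials, %.1f s total\n",
              x$n_blocks, nrow(x$trials), x$duration))
  invisible(x)
}

#' Block onsets of a design, per condition
#' @param design an `experiment_design`.
#' @return data.frame with `block`, `condition`, `onset` (s).
#' @export
block_onsets <- function(design) {
  tr <- design$trials
  if (!nrow(tr)) return(data.frame(block = integer(0),
                                   condition = character(0),
                                   onset = numeric(0)))
  agg <- tr[!duplicated(tr$block), c("block", "condition", "onset")]
  rownames(agg) <- NULL
  agg
}

#' Piecewise-constant drive schedule of a design
#'
#' Expands a design into time segments with the stimulus pattern on display
#' (or none) and the active attention level; the integrator holds drives
#' constant within a segment.  The task-control (attention) input is applied
#' from sample onset through probe offset; during the inter-trial interval it
#' falls back to the passive-viewing level, which lets the delay-period
#' attractor collapse and clears the memory trace before the next trial.
#'
#' @param design an `experiment_design`.
#' @return data.frame of segments with `t0`, `t1` (s), `attention`, `trial`,
#'   `phase`; the pattern of stimulus segments is looked up in
#'   `design$stimuli`.
#' @export
design_segments <- function(design) {
  tr <- design$trials
  if (!nrow(tr))
    return(data.frame(t0 = numeric(0), t1 = numeric(0),
                      attention = numeric(0), trial = integer(0),
                      phase = character(0)))
  seg <- list()
  for (k in seq_len(nrow(tr))) {
    t <- tr[k, ]
    seg[[length(seg) + 1]] <- data.frame(t0 = t$onset, t1 = t$s1_off,
                                         attention = t$attention,
                                         trial = t$trial, phase = "s1")
    seg[[length(seg) + 1]] <- data.frame(t0 = t$s1_off, t1 = t$s2_on,
                                         attention = t$attention,
                                         trial = t$trial, phase = "delay")
    seg[[length(seg) + 1]] <- data.frame(t0 = t$s2_on, t1 = t$s2_off,
                                         attention = t$attention,
                                         trial = t$trial, phase = "s2")
    seg[[length(seg) + 1]] <- data.frame(t0 = t$s2_off, t1 = t$end,
                                         attention = design$ctl_attention,
                                         trial = t$trial, phase = "iti")
  }
  out <- do.call(rbind, seg)
  rownames(out) <- NULL
  out
}
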