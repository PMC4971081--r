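#' Per-condition sample indices of a series
#'
#' Assigns each sample of a series (ISA bins or BOLD TRs) to the condition of
#' the block containing its acquisition time, optionally shifted by `lag`
#' samples (truncated at the series end).  The two sets are disjoint.
#'
#' @param design an `experiment_design`.
#' @param sampling_interval seconds between samples.
#' @param n_samples series length; defaults to the design duration over the
#'   sampling interval.
#' @param lag shift applied to the index sets, in samples.
#' @return list of integer index vectors, one per condition.
#' @export
condition_timepoints <- function(design, sampling_interval,
                                 n_samples = NULL, lag = 0L) {
  ons <- block_onsets(design)
  if (is.null(n_samples))
    n_samples <- as.integer(floor(design$duration / sampling_interval))
  if (!nrow(ons))
    return(list(DMS = integer(0), CTL = integer(0)))
  times <- (seq_len(n_samples) - 1) * sampling_interval
  blk <- findInterval(times, ons$onset)
  cond <- ifelse(blk >= 1, ons$condition[pmax(blk, 1)], NA)
  out <- lapply(c(DMS = "DMS", CTL = "CTL"), function(cc) {
    idx <- which(cond == cc) + lag
    idx[idx >= 1 & idx <= n_samples]
  })
  out
}

#' Within-condition functional connectivity
#'
#' Pearson correlation of two regional time series over the given sample
#' indices.
#'
#' @param x,y numeric series.
#' @param indices sample indices (>= 3).
#' @return correlation coefficient.
#' @export
functional_connectivity <- function(x, y, indices = seq_along(x)) {
  if (length(indices) < 3) stop("need at least 3 indices")
  xs <- x[indices]; ys <- y[indices]
  if (any(!is.finite(xs)) || any(!is.finite(ys)))
    stop("non-finite series values")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("zero variance in the indexed samples")
  stats::cor(xs, ys)
}

#' Fisher-Z group average of correlations
#'
#' `tanh(mean(atanh(r)))`: correlations are averaged on the z scale so the
#' group value is unbiased by the bounded r scale.
#'
#' @param r_values correlations, all strictly inside (-1, 1).
#' @return group-average correlation.
#' @export
group_average_fc <- function(r_values) {
  if (any(abs(r_values) >= 1))
    stop("|r| = 1 cannot be Fisher-averaged")
  tanh(mean(atanh(r_values)))
}

#' Paired t test from closed form
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d = a - b`,
#' with `n - 1` degrees of freedom and a two-sided p value.
#'
#' @param a,b paired samples of equal length (n >= 2).
#' @return list with `t`, `df`, `p`, `mean_difference`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples differ in length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero variance of the paired differences")
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1,
       p = 2 * stats::pt(-abs(t), df = n - 1),
       mean_difference = mean(d))
}

#' Seed-based task difference in functional connectivity across subjects
#'
#' For each subject's regional series, computes the within-condition
#' correlation between the seed region and every other region, then reports
#' per-condition Fisher-Z group averages, the mean within-subject DMS-CTL
#' difference, and its paired t statistic.
#'
#' @param series_list one matrix (samples x regions) per subject.
#' @param design the shared `experiment_design`.
#' @param sampling_interval seconds between samples.
#' @param seed_region column name of the seed (default `"IT"`).
#' @param lag optional hemodynamic lag, in samples.
#' @return data.frame with one row per non-seed region.
#' @export
fc_task_table <- function(series_list, design, sampling_interval,
                          seed_region = "IT", lag = 0L) {
  stopifnot(length(series_list) >= 2)
  regions <- setdiff(colnames(series_list[[1]]), seed_region)
  idx <- condition_timepoints(design, sampling_interval,
                              n_samples = nrow(series_list[[1]]), lag = lag)
  r_dms <- sapply(series_list, function(m)
    vapply(regions, function(rg)
      functional_connectivity(m[, seed_region], m[, rg], idx$DMS), 0.0))
  r_ctl <- sapply(series_list, function(m)
    vapply(regions, function(rg)
      functional_connectivity(m[, seed_region], m[, rg], idx$CTL), 0.0))
  r_dms <- matrix(r_dms, nrow = length(regions),
                  dimnames = list(regions, NULL))
  r_ctl <- matrix(r_ctl, nrow = length(regions),
                  dimnames = list(regions, NULL))
  out <- lapply(regions, function(rg) {
    tt <- paired_ttest(r_dms[rg, ], r_ctl[rg, ])
    data.frame(region = rg,
               dms_mean = group_average_fc(r_dms[rg, ]),
               dms_sd = stats::sd(r_dms[rg, ]),
               ctl_mean = group_average_fc(r_ctl[rg, ]),
               ctl_sd = stats::sd(r_ctl[rg, ]),
               mean_difference = tt$mean_difference,
               t = tt$t, df = tt$df, p = tt$p)
  })
  do.call(rbind, out)
}
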