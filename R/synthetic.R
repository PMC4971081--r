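#' Synthesize a cortical-shell connectome
#'
#' Generates a stand-in structural substrate with the statistical shape of a
#' DSI-derived human connectome: ~1000 nodes on a two-hemisphere ellipsoidal
#' shell, sparse symmetric nonnegative weights whose probability and magnitude
#' decay with Euclidean distance, and tract lengths equal to the straight-line
#' distance.  Nodes come in mirror pairs (node `i` and node `i + n/2` are
#' reflections through the midsagittal plane), which gives every region a
#' well-defined contralateral homologue.
#'
#' @param n_nodes number of nodes (>= 8; default emulates the 998-ROI human
#'   substrate).
#' @param density target edge density in (0, 1] (default 0.03, the sparsity
#'   regime of DSI region networks).
#' @param decay_mm distance-decay length of connection probability and weight,
#'   in mm.
#' @param weight_scale multiplicative scale of the connection weights.
#' @param extent semi-axes (x, y, z) of the cortical shell in mm.
#' @param seed optional integer seed; the generator is deterministic given it.
#' @return a [connectome()] with tract lengths.
#' @export
synthesize_connectome <- function(n_nodes = 998, density = 0.03,
                                  decay_mm = 40, weight_scale = 0.5,
                                  extent = c(70, 90, 60), seed = NULL) {
  if (n_nodes < 8) stop("n_nodes must be >= 8")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  half <- n_nodes %/% 2
  # right-hemisphere points on a jittered ellipsoid shell, then mirror in x
  u <- matrix(stats::rnorm(3 * half), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u[, 1] <- abs(u[, 1])                      # x > 0 hemisphere
  r <- stats::runif(half, 0.88, 1.0)         # shell thickness
  right <- sweep(u * r, 2, extent, `*`)
  left <- right
  left[, 1] <- -left[, 1]
  coords <- rbind(right, left)
  if (n_nodes %% 2 == 1) {                   # odd count: one midline node
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2)); v[1] <- 0
    coords <- rbind(coords, v * extent * stats::runif(1, 0.88, 1))
  }
  d <- as.matrix(stats::dist(coords))
  praw <- exp(-d / decay_mm)
  diag(praw) <- 0
  up <- upper.tri(d)
  target_edges <- density * sum(up)
  p <- pmin(1, praw * target_edges / sum(praw[up]))
  adj <- matrix(0, n_nodes, n_nodes)
  adj[up] <- stats::runif(sum(up)) < p[up]
  adj <- adj + t(adj)
  mag <- weight_scale * exp(-d / decay_mm) *
    matrix(stats::rlnorm(n_nodes^2, 0, 0.5), n_nodes)
  mag[up] <- t(mag)[up]                      # symmetrize magnitudes
  w <- adj * mag
  diag(w) <- 0
  tl <- d * (adj > 0)
  connectome(w, coords, tract_lengths = tl,
             labels = sprintf("syn_%04d", seq_len(n_nodes)))
}
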