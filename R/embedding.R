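#' Default task-module specifications
#'
#' The visual short-term-memory network comprises ten 81-unit neuronal
#' populations: orientation channels in early visual cortex (V1h, V1v),
#' extrastriate populations (V4h, V4c, V4v), inferotemporal cortex (IT) and
#' four prefrontal populations following the Funahashi response typology —
#' stimulus-sensitive (FS), delay-active (D1), stimulus-and-delay (D2) and
#' response (FR).  Each population carries a hypothesized Talairach coordinate
#' used to select its host connectome node; V1/V4 sub-populations and the
#' prefrontal populations other than D1 sit at illustrative adjacent
#' locations.
#'
#' @return data.frame with columns `name`, `x`, `y`, `z`, `region`,
#'   `receives_connectome_input`, `sends_feedback`.
#' @export
default_module_specs <- function() {
  specs <- data.frame(
    name = c("V1h", "V1v", "V4h", "V4c", "V4v", "IT", "FS", "D1", "D2", "FR"),
    x = c(18, 10, 30, 38, 24, 28, 47, 42, 42, 29),
    y = c(-88, -94, -72, -66, -78, -36, 19, 26, 39, 25),
    z = c(8, 12, -12, -8, -16, -8, 9, 20, 2, 40),
    region = c("V1", "V1", "V4", "V4", "V4", "IT", "FS", "D1", "D2", "FR"),
    stringsAsFactors = FALSE)
  specs$receives_connectome_input <- TRUE
  specs$sends_feedback <- TRUE
  specs
}

#' Number of units per task module
#' @export
LSNM_UNITS <- 81L

validate_module_specs <- function(specs) {
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(specs)))
    stop("module specs need columns name, x, y, z")
  if (anyDuplicated(specs$name)) stop("module names must be unique")
  if (is.null(specs$region)) specs$region <- specs$name
  if (is.null(specs$receives_connectome_input))
    specs$receives_connectome_input <- TRUE
  if (is.null(specs$sends_feedback)) specs$sends_feedback <- TRUE
  specs
}

#' Embed task modules into a connectome
#'
#' Four-step embedding: (1) each module carries a hypothesized stereotaxic
#' coordinate; (2) the nearest connectome node becomes its designated host;
#' (3) every connectome node with a connection *into* the host is wired to all
#' 81 units of the module, with a per-(afferent, unit) coupling drawn from a
#' Gaussian whose mean is the long-range coupling constant `G` divided by the
#' 81 units, multiplied by the structural weight into the host; (4) reciprocal
#' feedback connections are created from the module's excitatory units back to
#' exactly those afferent nodes, carrying `G * structural weight / 81` each so
#' the module aggregate matches one node of equivalent mean activity.
#' All original connectome edges are left untouched: embedding only adds
#' connections, and the host remains an active connectome node.
#'
#' @param con a [connectome()].
#' @param specs module specification data.frame (see
#'   [default_module_specs()]).
#' @param G long-range coupling constant (> 0).
#' @param coupling_sd_frac s.d. of the Gaussian coupling samples as a fraction
#'   of their mean; samples are clipped at zero.
#' @param host_collision `"error"` (two modules resolving to the same node is
#'   an error) or `"next"` (assign the next-nearest unclaimed node, with a
#'   warning) for coarse substrates.
#' @param seed optional integer seed for the coupling draws.
#' @return object of class `hybrid_network`.
#' @export
build_embedding <- function(con, specs = default_module_specs(), G = 0.15,
                            coupling_sd_frac = 0.1,
                            host_collision = c("error", "next"),
                            seed = NULL) {
  stopifnot(inherits(con, "connectome"))
  host_collision <- match.arg(host_collision)
  specs <- validate_module_specs(specs)
  if (!is.finite(G) || G <= 0) stop("G must be positive")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n_mod <- nrow(specs)
  taken <- integer(0)
  placements <- vector("list", n_mod)
  mean_c <- G / LSNM_UNITS
  for (m in seq_len(n_mod)) {
    target <- as.numeric(specs[m, c("x", "y", "z")])
    d2 <- colSums((t(con$coords) - target)^2)
    ord <- order(d2)
    host <- ord[1]
    if (host %in% taken) {
      if (host_collision == "error")
        stop("modules ", specs$name[m], " and ",
             specs$name[match(host, vapply(placements[seq_len(m - 1)],
                                           function(p) p$host, 0L))],
             " resolve to the same host node ", host,
             "; hosts must be distinct")
      host <- ord[!(ord %in% taken)][1]
      warning("module ", specs$name[m],
              ": nearest node already hosts another module; using ",
              "next-nearest node ", host)
    }
    taken <- c(taken, host)
    aff <- which(con$weights[, host] > 0)
    if (length(aff) == 0)
      warning("module ", specs$name[m], ": host node ", host,
              " has no afferent connections; empty afferent set")
    z <- con$weights[aff, host]
    csamp <- matrix(pmax(0, stats::rnorm(length(aff) * LSNM_UNITS,
                                         mean = mean_c,
                                         sd = coupling_sd_frac * mean_c)),
                    nrow = length(aff), ncol = LSNM_UNITS)
    placements[[m]] <- list(
      module = specs$name[m], region = specs$region[m],
      target = target, host = host,
      host_coords = con$coords[host, ], distance_mm = sqrt(d2[host]),
      afferents = aff, structural_weights = unname(z),
      coupling_samples = csamp,
      # per-unit feedback weight before scaling by a_Gamma (= G by default)
      feedback_weights = if (isTRUE(specs$sends_feedback[m]))
        unname(z) / LSNM_UNITS else numeric(length(aff)),
      receives_connectome_input = isTRUE(specs$receives_connectome_input[m]))
  }
  names(placements) <- specs$name
  structure(
    list(connectome = con, placements = placements, specs = specs,
         long_range_G = G, n_units = n_mod * LSNM_UNITS,
         n_modules = n_mod),
    class = "hybrid_network")
}

#' @export
print.hybrid_network <- function(x, ...) {
  cat(sprintf(
    "hybrid network: %d connectome nodes + %d modules x %d units, G = %g\n",
    x$connectome$n_nodes, x$n_modules, LSNM_UNITS, x$long_range_G))
  invisible(x)
}

#' Unit index range of a module within the stacked unit vector
#' @param hybrid a `hybrid_network`.
#' @param module module name.
#' @return integer vector of unit indices.
#' @export
module_units <- function(hybrid, module) {
  m <- match(module, names(hybrid$placements))
  if (is.na(m)) stop("unknown module: ", module)
  ((m - 1L) * LSNM_UNITS + 1L):(m * LSNM_UNITS)
}

#' Tabular embedding report
#'
#' One row per module: target coordinate, designated host, distance from the
#' target to the host, and afferent count.
#'
#' @param hybrid a `hybrid_network`.
#' @return data.frame.
#' @export
embedding_report <- function(hybrid) {
  stopifnot(inherits(hybrid, "hybrid_network"))
  do.call(rbind, lapply(hybrid$placements, function(p) {
    data.frame(module = p$module,
               target_x = p$target[1], target_y = p$target[2],
               target_z = p$target[3],
               host = p$host,
               host_x = p$host_coords[1], host_y = p$host_coords[2],
               host_z = p$host_coords[3],
               distance_mm = p$distance_mm,
               n_afferents = length(p$afferents),
               row.names = NULL)
  }))
}

#' Regions of interest around each embedded module
#'
#' Each ROI holds one module's 81 units, its host connectome node, and the
#' `k` connectome nodes closest to the host (non-task neighbours contributing
#' only noise to the imaging signal).  Neighbour assignment is disjoint: a
#' node belongs to at most one ROI (modules claim neighbours in order), so
#' imaging regions never share signal by construction — on coarse substrates
#' overlapping membership would correlate nearby ROIs artificially.
#'
#' @param hybrid a `hybrid_network`.
#' @param k number of adjacent non-host connectome nodes per ROI (default 5).
#' @return named list of ROIs, each `list(module, units, nodes)` with the host
#'   first in `nodes`.
#' @export
define_rois <- function(hybrid, k = 5) {
  stopifnot(inherits(hybrid, "hybrid_network"))
  if (k < 0) stop("k must be >= 0")
  con <- hybrid$connectome
  hosts <- vapply(hybrid$placements, function(p) p$host, 0L)
  claimed <- hosts
  rois <- vector("list", length(hybrid$placements))
  for (m in seq_along(hybrid$placements)) {
    p <- hybrid$placements[[m]]
    d2 <- colSums((t(con$coords) - p$host_coords)^2)
    cand <- setdiff(order(d2), claimed)
    kk <- min(k, length(cand))
    if (kk < k)
      warning("ROI ", p$module, ": only ", kk, " candidate neighbour nodes")
    take <- cand[seq_len(kk)]
    claimed <- c(claimed, take)
    rois[[m]] <- list(module = p$module, region = p$region,
                      units = module_units(hybrid, p$module),
                      nodes = c(p$host, take))
  }
  names(rois) <- names(hybrid$placements)
  rois
}

#' Region-level ROIs (populations grouped into anatomical regions)
#'
#' Merges the per-module ROIs of [define_rois()] by the `region` column of the
#' module specs, so V1h/V1v form one V1 region and V4h/V4c/V4v one V4 region,
#' mirroring how a scanner voxel pools co-located populations.
#'
#' @inheritParams define_rois
#' @return named list of ROIs `list(region, units, nodes)`.
#' @export
region_rois <- function(hybrid, k = 5) {
  per_mod <- define_rois(hybrid, k = k)
  regions <- unique(vapply(per_mod, function(r) r$region, ""))
  out <- lapply(regions, function(reg) {
    members <- per_mod[vapply(per_mod, function(r) r$region == reg, TRUE)]
    list(region = reg,
         units = sort(unique(unlist(lapply(members, `[[`, "units")))),
         nodes = unique(unlist(lapply(members, `[[`, "nodes"))))
  })
  names(out) <- regions
  out
}

#' Contralateral control ROI
#'
#' Noise-only control region: the connectome node nearest the mirror image
#' (x negated) of a module's host, plus its `k` nearest neighbours.  Used as
#' the contralateral-IT region in functional-connectivity analyses.
#'
#' @param hybrid a `hybrid_network`.
#' @param module module whose mirror is taken (default `"IT"`).
#' @param k neighbour count.
#' @param exclude additional node indices barred from membership (e.g. nodes
#'   already claimed by task ROIs).
#' @return `list(region, units, nodes)` with an empty unit set.
#' @export
contralateral_roi <- function(hybrid, module = "IT", k = 5,
                              exclude = integer(0)) {
  p <- hybrid$placements[[module]]
  if (is.null(p)) stop("unknown module: ", module)
  mirror <- p$host_coords * c(-1, 1, 1)
  con <- hybrid$connectome
  d2 <- colSums((t(con$coords) - mirror)^2)
  hosts <- vapply(hybrid$placements, function(q) q$host, 0L)
  cand <- setdiff(order(d2), c(hosts, exclude))
  centre <- cand[1]
  rest <- setdiff(cand, centre)
  list(region = paste0("c", module), units = integer(0),
       nodes = c(centre, rest[seq_len(min(k, length(rest)))]))
}
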