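#' Default inter-module weight set of the visual DMS network
#'
#' Declarative wiring templates between the 9x9 unit grids of the task
#' modules.  Topology: orientation-selective V1 channels converge onto V4
#' through 3x3 receptive fields (V4c pools both channels, responding to
#' corners); V4 projects divergently onto IT, giving shapes a distributed
#' inferotemporal representation; IT drives the stimulus-sensitive prefrontal
#' population FS and, gated by attention, the stimulus-and-delay population
#' D2; D1 and D2 form a recurrent loop that holds the sample across the delay;
#' D2 sends feedback to IT and recruits module-wide lateral inhibition that
#' protects the stored pattern from being overwritten; FR detects the
#' coincidence of the held trace (D1) with the current stimulus (FS) and
#' crosses its response threshold only on a match.
#'
#' Template types: `one2one` (grid-aligned), `conv3` (3x3 convergence, each
#' source cell carrying `w/3`), `divergent` (each target unit samples `fan`
#' source units at `w` per edge, drawn once from `template_seed`), `spread`
#' (uniform all-to-all at `w/81`).  `target` selects the postsynaptic element
#' (E or I).  Feed-forward templates (`tag == "ff"`) are the ones scaled per
#' simulated subject; recurrent and feedback templates are left untouched.
#'
#' @param template_seed integer seed fixing the divergent V4-to-IT sampling;
#'   part of the model definition, not of subject generation.
#' @return object of class `lsnm_weight_set`.
#' @export
default_weight_set <- function(template_seed = 42L) {
  tpl <- function(src, dst, w, type = "one2one", target = "E",
                  tag = "ff", fan = NA_integer_, name = NULL) {
    list(src = src, dst = dst, w = w, type = type, target = target,
         tag = tag, fan = fan, name = name)
  }
  templates <- list(
    tpl("V1h", "V4h", 0.80, "conv3"),
    tpl("V1v", "V4v", 0.80, "conv3"),
    tpl("V1h", "V4c", 0.45, "conv3"),
    tpl("V1v", "V4c", 0.45, "conv3"),
    # distributed IT code: the three V4 channels are pooled cell-wise and
    # scattered over the IT grid by a seed-fixed permutation, so the
    # inferotemporal representation carries no retinotopy but preserves
    # pattern identity exactly
    tpl("V4h", "IT", 0.70, "permuted"),
    tpl("V4c", "IT", 0.70, "permuted"),
    tpl("V4v", "IT", 0.70, "permuted"),
    tpl("IT", "FS", 0.90),
    tpl("IT", "D2", 0.35),
    tpl("D1", "D2", 0.80, tag = "lat"),
    # stored-trace protection: the held pattern drives all D2 inhibitory
    # elements (high gain, so protection saturates for any stored trace);
    # only units with grid-aligned D1 support can overcome it, hence a
    # mismatching probe cannot overwrite the memory
    tpl("D1", "D2", 6.0, "spread", target = "I", tag = "lat",
        name = "D1->D2:spread"),
    tpl("D2", "D1", 0.60, tag = "lat"),
    tpl("D2", "IT", 0.10, tag = "fb"),
    tpl("FS", "FR", 0.50),
    tpl("D1", "FR", 0.50))
  names(templates) <- vapply(templates, function(t)
    if (!is.null(t$name)) t$name else
      paste0(t$src, "->", t$dst, if (t$target == "I") ":I" else ""), "")
  structure(list(templates = templates,
                 attention_target = "D2",
                 stim_targets = c(h = "V1h", v = "V1v"),
                 template_seed = as.integer(template_seed)),
            class = "lsnm_weight_set")
}

#' Names of the feed-forward templates of a weight set
#' @param wset an `lsnm_weight_set`.
#' @return character vector.
#' @export
feedforward_templates <- function(wset) {
  names(wset$templates)[vapply(wset$templates,
                               function(t) t$tag == "ff", TRUE)]
}

#' Apply "src->dst" weight overrides from a configuration
#' @param wset an `lsnm_weight_set`.
#' @param overrides named list/vector of weights keyed by template name.
#' @return modified weight set.
#' @export
override_weights <- function(wset, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(wset$templates))
      stop("unknown weight template: ", nm)
    ov <- overrides[[nm]]
    w <- if (is.list(ov)) ov$w else ov
    wset$templates[[nm]]$w <- as.numeric(w)
  }
  wset
}

grid_neighbors3 <- function(i) {
  r <- (i - 1L) %/% 9L + 1L
  c <- (i - 1L) %% 9L + 1L
  rr <- max(1L, r - 1L):min(9L, r + 1L)
  cc <- max(1L, c - 1L):min(9L, c + 1L)
  as.vector(outer(rr, cc, function(a, b) (a - 1L) * 9L + b))
}

template_edges <- function(t, seed_stream, perm = NULL) {
  u <- LSNM_UNITS
  switch(t$type,
    one2one = list(src = seq_len(u), dst = seq_len(u), w = rep(t$w, u)),
    permuted = list(src = seq_len(u), dst = perm, w = rep(t$w, u)),
    conv3 = {
      src <- integer(0); dst <- integer(0)
      for (i in seq_len(u)) {
        nb <- grid_neighbors3(i)
        src <- c(src, nb); dst <- c(dst, rep(i, length(nb)))
      }
      list(src = src, dst = dst, w = rep(t$w / 3, length(src)))
    },
    divergent = {
      smp <- matrix(0L, u, t$fan)
      for (i in seq_len(u)) smp[i, ] <- seed_stream(u, t$fan)
      list(src = as.vector(smp),
           dst = rep(seq_len(u), times = t$fan),
           w = rep(t$w, u * t$fan))
    },
    spread = list(src = rep(seq_len(u), each = u),
                  dst = rep(seq_len(u), times = u),
                  w = rep(t$w / u, u * u)),
    stop("unknown template type: ", t$type))
}

#' Compile a weight set into sparse unit-to-unit matrices
#'
#' Produces the matrices used by the integrator: `ME` maps the stacked
#' excitatory activity vector onto excitatory-element inputs, `MI` onto
#' inhibitory-element inputs, with absolute-value twins for the synaptic-input
#' magnitude used by the imaging forward model.  Optional per-template
#' multipliers (a simulated subject) scale feed-forward templates only.
#'
#' @param wset an `lsnm_weight_set`.
#' @param modules character vector of module names in stacking order.
#' @param multipliers optional named numeric vector of per-template
#'   multipliers (see [generate_subject()]).
#' @return list with sparse matrices `ME`, `MI`, `absME`, `absMI` and the
#'   effective templates.
#' @export
compile_weights <- function(wset, modules, multipliers = NULL) {
  stopifnot(inherits(wset, "lsnm_weight_set"))
  L <- length(modules) * LSNM_UNITS
  offs <- stats::setNames((seq_along(modules) - 1L) * LSNM_UNITS, modules)
  iE <- jE <- iI <- jI <- integer(0)
  xE <- xI <- numeric(0)
  # deterministic divergent sampling, isolated from the caller's RNG
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  # one scatter permutation per target module, shared by all its permuted
  # afferent templates so co-located channels stay pooled
  perm_dsts <- unique(vapply(
    Filter(function(t) t$type == "permuted", wset$templates),
    function(t) t$dst, ""))
  perms <- lapply(perm_dsts, function(d) {
    set.seed(wset$template_seed + 1000L * match(d, modules))
    sample.int(LSNM_UNITS)
  })
  names(perms) <- perm_dsts
  set.seed(wset$template_seed)
  seed_stream <- function(n, k) sample.int(n, k)
  for (nm in names(wset$templates)) {
    t <- wset$templates[[nm]]
    if (!t$src %in% modules || !t$dst %in% modules)
      stop("template ", nm, " references unknown module")
    mult <- 1
    if (!is.null(multipliers) && nm %in% names(multipliers) &&
        t$tag == "ff")
      mult <- multipliers[[nm]]
    e <- template_edges(t, seed_stream, perm = perms[[t$dst]])
    src <- e$src + offs[[t$src]]
    dst <- e$dst + offs[[t$dst]]
    w <- e$w * mult
    if (t$target == "E") {
      iE <- c(iE, dst); jE <- c(jE, src); xE <- c(xE, w)
    } else {
      iI <- c(iI, dst); jI <- c(jI, src); xI <- c(xI, w)
    }
  }
  ME <- Matrix::sparseMatrix(i = iE, j = jE, x = xE, dims = c(L, L))
  MI <- Matrix::sparseMatrix(i = iI, j = jI, x = xI, dims = c(L, L))
  list(ME = ME, MI = MI, absME = abs(ME), absMI = abs(MI),
       templates = wset$templates)
}
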