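#' Shape library for the visual task
#'
#' Ten axis-aligned stroke shapes on the 9x9 input grid, each a set of
#' horizontal and vertical segments (the two orientation channels the early
#' visual populations are selective for), plus a `blank`.  Shapes are stored
#' as stroke lists `c(orientation, row, col, length)`.
#'
#' @return named list of stroke lists.
#' @export
shape_library <- function() {
  H <- function(r, c, l) c(orient = 0, row = r, col = c, len = l)
  V <- function(r, c, l) c(orient = 1, row = r, col = c, len = l)
  # shapes occupy distinct grid regions so their orientation-channel codes
  # (and hence the distributed IT representations) overlap little
  list(
    blank  = list(),
    square = list(H(2, 2, 4), H(5, 2, 4), V(2, 2, 4), V(2, 5, 4)),
    tee    = list(H(2, 5, 5), V(2, 7, 5)),
    ell    = list(V(4, 2, 5), H(8, 2, 4)),
    aitch  = list(V(5, 3, 4), V(5, 6, 4), H(6, 3, 4)),
    yu     = list(V(2, 6, 4), V(2, 9, 4), H(5, 6, 4)),
    ee     = list(V(2, 2, 5), H(2, 2, 4), H(4, 2, 3), H(6, 2, 4)),
    ef     = list(V(5, 8, 5), H(5, 6, 3), H(7, 6, 3)),
    cross  = list(H(7, 5, 5), V(5, 7, 5)),
    jay    = list(V(2, 4, 4), H(5, 2, 3)),
    stairs = list(H(3, 2, 3), V(3, 4, 3), H(5, 4, 3), V(5, 6, 3), H(7, 6, 3))
  )
}

stroke_channels <- function(strokes) {
  h <- matrix(0, 9, 9)
  v <- matrix(0, 9, 9)
  for (s in strokes) {
    if (s[["orient"]] == 0) {
      h[s[["row"]], s[["col"]]:(s[["col"]] + s[["len"]] - 1)] <- 1
    } else {
      v[s[["row"]]:(s[["row"]] + s[["len"]] - 1), s[["col"]]] <- 1
    }
  }
  list(h = h, v = v)
}

#' Build a stimulus pattern
#'
#' An intact stimulus activates the grid cells of its strokes, split into a
#' horizontal and a vertical orientation channel (corner cells belong to
#' both).  A degraded stimulus — used for the passive-viewing control
#' condition — randomly retains each active cell with probability
#' `retention`, applied cell-wise to both channels.
#'
#' @param shape_id name from [shape_library()].
#' @param degraded logical.
#' @param retention retention probability of each active cell when degraded.
#' @param shapes shape library (override for custom shapes).
#' @return object of class `stimulus_pattern`: list with 9x9 channel matrices
#'   `h`, `v`, combined `grid`, `shape`, `degraded`.
#' @export
make_stimulus <- function(shape_id, degraded = FALSE, retention = 0.5,
                          shapes = shape_library()) {
  if (!shape_id %in% names(shapes))
    stop("unknown shape_id: ", shape_id)
  ch <- stroke_channels(shapes[[shape_id]])
  if (degraded) {
    active <- which(ch$h > 0 | ch$v > 0)
    keep <- active[stats::runif(length(active)) < retention]
    mask <- matrix(0, 9, 9)
    mask[keep] <- 1
    ch$h <- ch$h * mask
    ch$v <- ch$v * mask
  }
  structure(list(shape = shape_id, h = ch$h, v = ch$v,
                 grid = pmax(ch$h, ch$v), degraded = degraded),
            class = "stimulus_pattern")
}

#' Predicted extrastriate footprint of a shape
#'
#' The set of grid cells whose 3x3 neighbourhood contains at least three
#' active cells of one orientation channel — the cells the V4 band of the
#' shape will occupy.  Used to quantify how discriminable two shapes are at
#' the level of the distributed object representation.
#'
#' @param shape_id shape name.
#' @param shapes shape library.
#' @return logical 9x9 matrix.
#' @export
shape_footprint <- function(shape_id, shapes = shape_library()) {
  ch <- stroke_channels(shapes[[shape_id]])
  band <- function(g) {
    cnt <- matrix(0, 9, 9)
    for (r in 1:9) for (c in 1:9) {
      rr <- max(1, r - 1):min(9, r + 1)
      cc <- max(1, c - 1):min(9, c + 1)
      cnt[r, c] <- sum(g[rr, cc])
    }
    cnt >= 3
  }
  band(ch$h) | band(ch$v)
}

#' Pairwise footprint overlaps of a shape library
#'
#' @param shapes shape library.
#' @return symmetric integer matrix of shared footprint cells (blank
#'   excluded).
#' @export
shape_overlap_matrix <- function(shapes = shape_library()) {
  ids <- setdiff(names(shapes), "blank")
  fp <- lapply(ids, shape_footprint, shapes = shapes)
  ov <- outer(seq_along(ids), seq_along(ids),
              Vectorize(function(a, b) sum(fp[[a]] & fp[[b]])))
  dimnames(ov) <- list(ids, ids)
  ov
}

#' @export
print.stimulus_pattern <- function(x, ...) {
  cat(sprintf("stimulus '%s'%s, %d active cells\n", x$shape,
              if (x$degraded) " (degraded)" else "", sum(x$grid > 0)))
  chr <- matrix(".", 9, 9)
  chr[x$h > 0] <- "-"
  chr[x$v > 0] <- "|"
  chr[x$h > 0 & x$v > 0] <- "+"
  cat(apply(chr, 1, paste, collapse = ""), sep = "\n")
  invisible(x)
}
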