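#' Construct a structural connectome object
#'
#' A connectome is a weighted directed graph of cortical regions of interest:
#' a nonnegative weight matrix (row = source, column = target), one stereotaxic
#' coordinate (Talairach mm) per node, and optionally a matrix of white-matter
#' tract lengths in mm used to derive conduction delays.
#'
#' @param weights square numeric matrix of nonnegative connection weights with
#'   zero diagonal.
#' @param coords n x 3 numeric matrix of node centres in mm.
#' @param tract_lengths optional symmetric nonnegative n x n matrix of fibre
#'   lengths in mm.
#' @param labels optional character vector of node identifiers.
#' @param region_of optional vector mapping each node to an anatomical region.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, coords, tract_lengths = NULL, labels = NULL,
                       region_of = NULL) {
  weights <- as.matrix(weights)
  coords <- as.matrix(coords)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("weights must be a square matrix")
  if (nrow(coords) != n || ncol(coords) != 3)
    stop("coords must be an n x 3 matrix matching the weight matrix")
  if (any(!is.finite(coords)))
    stop("coords must be finite")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative")
  if (any(diag(weights) != 0))
    stop("weights must have a zero diagonal")
  if (!is.null(tract_lengths)) {
    tract_lengths <- as.matrix(tract_lengths)
    if (!all(dim(tract_lengths) == c(n, n)))
      stop("tract_lengths must be n x n")
    if (any(!is.finite(tract_lengths)) || any(tract_lengths < 0))
      stop("tract_lengths must be finite and nonnegative")
    if (max(abs(tract_lengths - t(tract_lengths))) > 1e-8)
      stop("tract_lengths must be symmetric")
  }
  if (is.null(labels)) labels <- sprintf("node_%04d", seq_len(n))
  if (length(labels) != n) stop("labels length must equal node count")
  structure(
    list(n_nodes = n, weights = weights, coords = coords,
         tract_lengths = tract_lengths, labels = as.character(labels),
         region_of = region_of),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  dens <- mean(x$weights[upper.tri(x$weights)] > 0 |
                 t(x$weights)[upper.tri(x$weights)] > 0)
  cat(sprintf("connectome: %d nodes, edge density %.3f, tract lengths %s\n",
              x$n_nodes, dens,
              if (is.null(x$tract_lengths)) "absent" else "present"))
  invisible(x)
}

#' Load a connectivity bundle
#'
#' Reads the de-facto whole-brain connectivity dialect: a directory (or zip
#' archive) holding `weights.txt` (whitespace-delimited square matrix),
#' `centres.txt` (`label x y z` per line) and optionally `tract_lengths.txt`.
#' `.csv` variants of the three files are also accepted.
#'
#' @param path directory or `.zip` file.
#' @return a [connectome()].
#' @export
load_connectome <- function(path) {
  if (length(path) != 1 || !file.exists(path))
    stop("connectivity bundle not found: ", path)
  dir <- path
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    dir <- tempfile("bundle")
    utils::unzip(path, exdir = dir)
    inner <- list.dirs(dir, recursive = FALSE)
    if (length(inner) == 1 &&
        !length(list.files(dir, pattern = "^(weights|centres)")))
      dir <- inner
  }
  find1 <- function(stem) {
    hits <- list.files(dir, pattern = paste0("^", stem, "\\.(txt|csv)$"),
                       full.names = TRUE)
    if (length(hits)) hits[[1]] else NULL
  }
  wf <- find1("weights")
  cf <- find1("centres")
  if (is.null(wf)) stop("bundle format error: missing weights file in ", path)
  if (is.null(cf)) stop("bundle format error: missing centres file in ", path)
  read_mat <- function(f) {
    sep <- if (grepl("\\.csv$", f)) "," else ""
    as.matrix(utils::read.table(f, sep = sep, header = FALSE))
  }
  weights <- unname(read_mat(wf))
  cen <- utils::read.table(cf, sep = if (grepl("\\.csv$", cf)) "," else "",
                           header = FALSE, stringsAsFactors = FALSE)
  if (ncol(cen) < 4)
    stop("bundle format error: centres file needs 'label x y z' per line")
  labels <- as.character(cen[[1]])
  coords <- as.matrix(cen[, 2:4])
  storage.mode(coords) <- "double"
  if (nrow(weights) != nrow(coords))
    stop("bundle format error: weight matrix size (", nrow(weights),
         ") does not match number of centres (", nrow(coords), ")")
  tf <- find1("tract_lengths")
  tl <- if (!is.null(tf)) unname(read_mat(tf)) else NULL
  connectome(weights, coords, tract_lengths = tl, labels = labels)
}

#' Write a connectome as a connectivity bundle directory
#'
#' @param con a [connectome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_connectome <- function(con, dir) {
  stopifnot(inherits(con, "connectome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(con$weights, file.path(dir, "weights.txt"),
                     row.names = FALSE, col.names = FALSE)
  cen <- data.frame(label = con$labels, con$coords)
  utils::write.table(cen, file.path(dir, "centres.txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(con$tract_lengths))
    utils::write.table(con$tract_lengths, file.path(dir, "tract_lengths.txt"),
                       row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Nearest connectome node to a stereotaxic point
#'
#' Euclidean distance in the coordinate frame of the connectome; ties are
#' broken by the lowest node index.
#'
#' @param con a [connectome()].
#' @param point_mm numeric 3-vector in mm.
#' @return list with `node` (index) and `distance_mm`.
#' @export
nearest_node <- function(con, point_mm) {
  stopifnot(inherits(con, "connectome"))
  if (con$n_nodes < 1) stop("empty connectome")
  point_mm <- as.numeric(point_mm)
  if (length(point_mm) != 3 || any(!is.finite(point_mm)))
    stop("point_mm must be a finite 3-vector")
  d2 <- colSums((t(con$coords) - point_mm)^2)
  i <- which.min(d2)   # which.min returns the first (lowest-index) minimum
  list(node = unname(i), distance_mm = sqrt(d2[[i]]))
}
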