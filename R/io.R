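## Readers and writers. On-disk vertex indices are 0-based in every format
## (edge-list TSV, coordinate CSV, community CSV); in-memory indices are
## 1-based.

#' Read a graph from edge-list TSV or MatrixMarket file
#'
#' Edge lists are tab-separated with header \code{source target weight}
#' and 0-based vertex indices. MatrixMarket files use the coordinate
#' format; a \code{symmetric} header is expanded to both edge directions.
#' Self-loop entries are dropped with a warning.
#'
#' @param path file to read.
#' @param format \code{"auto"} (by extension), \code{"tsv"} or
#'   \code{"mtx"}.
#' @param n vertex count override (edge lists only; defaults to the
#'   largest index + 1).
#' @param coords optional path of a \code{vertex,x,y,z} CSV of 0-based
#'   vertex coordinates to attach.
#' @return a \code{\linkS4class{DirectedGraph}}.
#' @export
readGraph <- function(path, format = c("auto", "tsv", "mtx"), n = NULL,
                      coords = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "tsv") {
    raw <- readLines(path)
    if (!length(raw)) stop("empty edge-list file: ", path)
    header <- strsplit(raw[1], "\t", fixed = TRUE)[[1]]
    if (!all(c("source", "target") %in% header))
      stop("edge list must have a 'source<TAB>target[<TAB>weight]' header")
    si <- match("source", header); ti <- match("target", header)
    wi <- match("weight", header)
    src <- integer(0); tgt <- integer(0); w <- numeric(0)
    for (ln in seq_along(raw)[-1]) {
      if (!nzchar(raw[ln])) next
      parts <- strsplit(raw[ln], "\t", fixed = TRUE)[[1]]
      s <- suppressWarnings(as.integer(parts[si]))
      t <- suppressWarnings(as.integer(parts[ti]))
      ww <- if (!is.na(wi) && length(parts) >= wi)
        suppressWarnings(as.numeric(parts[wi])) else 1
      if (is.na(s) || is.na(t) || is.na(ww))
        stop("malformed edge-list line ", ln, " in ", path)
      src <- c(src, s); tgt <- c(tgt, t); w <- c(w, ww)
    }
    if (is.null(n)) n <- if (length(src)) max(src, tgt) + 1L else 0L
    A <- Matrix::sparseMatrix(i = src + 1L, j = tgt + 1L, x = w,
                              dims = c(n, n))
  } else {
    A <- Matrix::readMM(path)
    A <- as(as(as(A, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  }
  if (any(Matrix::diag(A) != 0)) {
    warning("dropping self-loop entries in ", path)
    Matrix::diag(A) <- 0
    A <- Matrix::drop0(A)
  }
  cc <- if (!is.null(coords)) readCoordinates(coords, nrow(A)) else NULL
  DirectedGraph(adjacency = A, coords = cc)
}

#' @describeIn readGraph write a graph (TSV or MTX, 0-based indices).
#' @param g a \code{DirectedGraph}.
#' @export
writeGraph <- function(g, path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "tsv") {
    e <- edgeTable(g)
    lines <- c("source\ttarget\tweight",
               sprintf("%d\t%d\t%s", e$source - 1L, e$target - 1L,
                       format(e$weight, digits = 17)))
    writeLines(lines, path)
  } else {
    Matrix::writeMM(adjacencyMatrix(g), path)
  }
  invisible(path)
}

#' Read 0-based vertex coordinates from CSV
#'
#' @param path CSV with header \code{vertex,x,y[,z]}.
#' @param n expected vertex count.
#' @return coordinate matrix ordered by vertex.
#' @export
readCoordinates <- function(path, n = NULL) {
  d <- utils::read.csv(path)
  if (!"vertex" %in% names(d)) stop("coordinate CSV needs a vertex column")
  cols <- intersect(c("x", "y", "z"), names(d))
  if (is.null(n)) n <- max(d$vertex) + 1L
  cc <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  cc[d$vertex + 1L, ] <- as.matrix(d[, cols])
  if (anyNA(cc)) stop("coordinate CSV does not cover every vertex")
  cc
}

#' @describeIn readCoordinates write coordinates (0-based vertex ids).
#' @param coords coordinate matrix.
#' @export
writeCoordinates <- function(coords, path) {
  d <- data.frame(vertex = seq_len(nrow(coords)) - 1L, coords)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write community assignments and leader summary
#'
#' \code{writeCommunities} emits \code{vertex,community_id,leader_vertex,
#' radius} rows (0-based vertices); \code{writeLeaderSummary} emits
#' \code{community_id,leader_vertex,vL1,rank}.
#'
#' @param cs a \code{\linkS4class{CommunitySet}}.
#' @param path output CSV path.
#' @export
writeCommunities <- function(cs, path) {
  d <- data.frame(vertex = seq_along(cs@membership) - 1L,
                  community_id = cs@membership,
                  leader_vertex = cs@leaders[cs@membership] - 1L,
                  radius = cs@radii)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCommunities
#' @export
writeLeaderSummary <- function(cs, path) {
  d <- data.frame(community_id = seq_along(cs@leaders),
                  leader_vertex = cs@leaders - 1L,
                  vL1 = cs@leaderScore,
                  rank = seq_along(cs@leaders))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write voxel community CSVs
#'
#' Format: \code{community_id,x,y,z} with integer mm-grid coordinates.
#'
#' @param path CSV path.
#' @return \code{readVoxelCommunities}: list of
#'   \code{\linkS4class{VoxelCommunity}}.
#' @export
readVoxelCommunities <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$community_id), function(part)
    new("VoxelCommunity", id = as.integer(part$community_id[1]),
        voxels = as.matrix(part[, c("x", "y", "z")])))
}

#' @rdname readVoxelCommunities
#' @param communities list of \code{VoxelCommunity}.
#' @export
writeVoxelCommunities <- function(communities, path) {
  d <- do.call(rbind, lapply(communities, function(v)
    data.frame(community_id = v@id, x = v@voxels[, 1],
               y = v@voxels[, 2], z = v@voxels[, 3])))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a plain-text run manifest
#'
#' Records the package version, seed and configuration of a run as
#' \code{key = value} lines next to its outputs.
#'
#' @param path manifest path.
#' @param config named list of settings (must include any seed used).
#' @export
writeManifest <- function(path, config) {
  lines <- c(paste0("cdinet_version = ",
                    as.character(utils::packageVersion("cdinet"))),
             vapply(names(config), function(k)
               paste0(k, " = ", paste(format(config[[k]]), collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
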