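#' Regular-lattice voxel geometry
#'
#' Builds the voxel geometry for a rectangular grid: voxel centers in
#' millimetres, a deterministic voxel ordering (ascending linear index,
#' first axis fastest -- R's native array order), and the grid metadata
#' needed for distance and adjacency computations.
#'
#' @param grid_shape Integer vector of length 3, voxels per axis.
#' @param spacing_mm Voxel spacing in mm; a scalar or a length-3 vector.
#' @param hemisphere Free-form tag carried through to outputs
#'   (`"left"`, `"right"` or `"synthetic"`).
#'
#' @return A `voxel_geometry` object: list with `voxel_ids`, `coords`
#'   (V x 3 matrix, mm), `grid_shape`, `spacing`, `hemisphere`.
#' @examples
#' g <- generate_geometry(c(3, 3, 3), spacing_mm = 3)
#' max(dist(g$coords))  # 3 * sqrt(12)
#' @export
generate_geometry <- function(grid_shape, spacing_mm = 1, hemisphere = "synthetic") {
  if (length(grid_shape) != 3 || any(!is.finite(grid_shape)) ||
      any(grid_shape < 1) || any(grid_shape != round(grid_shape))) {
    stop("`grid_shape` must be three positive integers", call. = FALSE)
  }
  if (!(length(spacing_mm) %in% c(1L, 3L)) || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be positive (scalar or length 3)", call. = FALSE)
  }
  grid_shape <- as.integer(grid_shape)
  spacing <- rep(as.numeric(spacing_mm), length.out = 3)
  V <- prod(grid_shape)
  idx <- arrayInd(seq_len(V), grid_shape)
  coords <- sweep(idx - 1L, 2, spacing, `*`)
  colnames(coords) <- c("x", "y", "z")
  structure(
    list(voxel_ids = seq_len(V), coords = coords, grid_shape = grid_shape,
         spacing = spacing, hemisphere = hemisphere),
    class = "voxel_geometry"
  )
}

#' Number of voxels in a geometry
#' @param geometry A `voxel_geometry`.
#' @return Integer voxel count.
#' @export
n_voxels <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  length(geometry$voxel_ids)
}

#' Pairwise Euclidean voxel distances (mm)
#' @param geometry A `voxel_geometry`.
#' @return A V x V symmetric matrix of distances.
#' @export
voxel_distances <- function(geometry) {
  as.matrix(stats::dist(geometry$coords))
}

#' Face-adjacent voxel pairs (6-connectivity)
#'
#' @param geometry A `voxel_geometry`.
#' @return Two-column integer matrix of voxel index pairs (i < j), one row
#'   per pair of voxels sharing a face on the lattice.
#' @export
lattice_adjacency <- function(geometry) {
  g <- geometry$grid_shape
  lin <- array(seq_len(prod(g)), dim = g)
  pairs <- list()
  if (g[1] > 1) {
    pairs[[1]] <- cbind(as.vector(lin[-g[1], , , drop = FALSE]),
                        as.vector(lin[-1, , , drop = FALSE]))
  }
  if (g[2] > 1) {
    pairs[[2]] <- cbind(as.vector(lin[, -g[2], , drop = FALSE]),
                        as.vector(lin[, -1, , drop = FALSE]))
  }
  if (g[3] > 1) {
    pairs[[3]] <- cbind(as.vector(lin[, , -g[3], drop = FALSE]),
                        as.vector(lin[, , -1, drop = FALSE]))
  }
  out <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  colnames(out) <- c("i", "j")
  out
}

# neighbour list keyed by voxel index
.neighbour_list <- function(geometry) {
  adj <- lattice_adjacency(geometry)
  V <- n_voxels(geometry)
  nb <- vector("list", V)
  both <- rbind(adj, adj[, 2:1, drop = FALSE])
  sp <- split(both[, 2], both[, 1])
  nb[as.integer(names(sp))] <- sp
  nb[vapply(nb, is.null, logical(1))] <- list(integer(0))
  nb
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("<voxel_geometry> %d voxels, grid %s, spacing %s mm, hemisphere '%s'\n",
              n_voxels(x), paste(x$grid_shape, collapse = "x"),
              paste(format(x$spacing), collapse = "/"), x$hemisphere))
  invisible(x)
}
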