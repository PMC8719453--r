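#' Write a BOLD series as delimited text plus a geometry sidecar
#'
#' Writes `<prefix>_data.tsv` (T rows x V columns, header `v<id>`) and
#' `<prefix>_geometry.tsv` (voxel_id, x, y, z in mm, with grid shape,
#' spacing and hemisphere in `#`-comment header lines). Voxel order is the
#' ascending linear index of the lattice.
#'
#' @param b A `bold_series`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_bold <- function(b, prefix) {
  stopifnot(inherits(b, "bold_series"))
  data_path <- paste0(prefix, "_data.tsv")
  geom_path <- paste0(prefix, "_geometry.tsv")
  df <- as.data.frame(b$data)
  names(df) <- paste0("v", b$geometry$voxel_ids)
  utils::write.table(df, data_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_geometry(b$geometry, geom_path)
  invisible(c(data = data_path, geometry = geom_path))
}

#' Write a voxel geometry sidecar table
#' @param geometry A `voxel_geometry`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_geometry <- function(geometry, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# grid_shape: %s", paste(geometry$grid_shape, collapse = " ")),
    sprintf("# spacing: %s", paste(format(geometry$spacing, digits = 15), collapse = " ")),
    sprintf("# hemisphere: %s", geometry$hemisphere),
    "# coordinates: voxel centers, mm, 0-based lattice, first axis fastest"
  ), con)
  df <- data.frame(voxel_id = geometry$voxel_ids, geometry$coords)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a voxel geometry sidecar table
#' @param path Sidecar path written by [write_geometry()].
#' @return A `voxel_geometry`.
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "", grep(sprintf("^# %s:", key), hdr, value = TRUE)[1])
  grid_shape <- as.integer(strsplit(get("grid_shape"), " ")[[1]])
  spacing <- as.numeric(strsplit(get("spacing"), " ")[[1]])
  hemisphere <- get("hemisphere")
  geom <- generate_geometry(grid_shape, spacing, hemisphere)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (nrow(tab) != n_voxels(geom)) {
    stop(sprintf("geometry sidecar '%s' lists %d voxels but grid %s implies %d",
                 path, nrow(tab), paste(grid_shape, collapse = "x"), n_voxels(geom)),
         call. = FALSE)
  }
  geom$coords[] <- as.matrix(tab[, c("x", "y", "z")])
  geom
}

#' Read a BOLD series from delimited text plus a geometry sidecar
#'
#' @param data_path TSV written by [write_bold()].
#' @param geometry_path Geometry sidecar path.
#' @param subject_id,condition Metadata tags.
#' @return A `bold_series`.
#' @export
read_bold <- function(data_path, geometry_path, subject_id = "s1",
                      condition = "synthetic") {
  geom <- read_geometry(geometry_path)
  dat <- utils::read.table(data_path, header = TRUE, sep = "\t")
  if (ncol(dat) != n_voxels(geom)) {
    stop(sprintf("data file '%s' has %d columns but geometry '%s' has %d voxels",
                 data_path, ncol(dat), geometry_path, n_voxels(geom)), call. = FALSE)
  }
  bold_series(as.matrix(dat), geom, subject_id, condition)
}

#' Write a BOLD series as a 4D NIfTI volume
#'
#' The voxel columns are scattered back onto the full lattice (ascending
#' linear index) and written as a 4D volume with the grid spacing in the
#' pixel dimensions.
#'
#' @param b A `bold_series`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_bold_nifti <- function(b, path) {
  stopifnot(inherits(b, "bold_series"))
  g <- b$geometry
  arr <- array(0, dim = c(g$grid_shape, nrow(b$data)))
  flat <- matrix(0, prod(g$grid_shape), nrow(b$data))
  flat[g$voxel_ids, ] <- t(b$data)
  arr[] <- flat
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- c(g$spacing, 1)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a masked BOLD series from a 4D NIfTI volume
#'
#' @param path 4D NIfTI path.
#' @param mask 3D logical/numeric array (nonzero = in-mask), or a path to
#'   a 3D NIfTI mask; `NULL` keeps every voxel. Voxels are ordered by
#'   ascending linear index.
#' @param hemisphere,subject_id,condition Metadata tags.
#' @return A `bold_series`.
#' @export
read_bold_nifti <- function(path, mask = NULL, hemisphere = "synthetic",
                            subject_id = "s1", condition = "synthetic") {
  nii <- RNifti::readNifti(path)
  dims <- dim(nii)
  if (length(dims) != 4) stop(sprintf("'%s' is not 4D (dims %s)", path,
                                      paste(dims, collapse = "x")), call. = FALSE)
  spacing <- RNifti::pixdim(nii)[1:3]
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
  if (!is.null(mask) && !identical(dim(mask), dims[1:3])) {
    stop(sprintf("mask grid %s does not match volume grid %s",
                 paste(dim(mask), collapse = "x"),
                 paste(dims[1:3], collapse = "x")), call. = FALSE)
  }
  keep <- if (is.null(mask)) seq_len(prod(dims[1:3])) else which(as.numeric(mask) != 0)
  geom <- generate_geometry(dims[1:3], spacing, hemisphere)
  geom$voxel_ids <- keep
  geom$coords <- geom$coords[keep, , drop = FALSE]
  flat <- matrix(as.numeric(nii), prod(dims[1:3]), dims[4])
  bold_series(t(flat[keep, , drop = FALSE]), geom, subject_id, condition)
}

#' Write a parcellation with a voxel-count legend
#'
#' Text format: `<prefix>_labels.tsv` (voxel_id, label) and
#' `<prefix>_legend.tsv` (label, voxel_count). NIfTI format: 3D integer
#' label volume (0 = unassigned) plus the same legend.
#'
#' @param parc A `parcellation` with at least one assigned voxel.
#' @param prefix Output path prefix.
#' @param format `"tsv"` (default) or `"nifti"`.
#' @return Invisibly, the written paths.
#' @export
write_parcellation <- function(parc, prefix, format = c("tsv", "nifti")) {
  format <- match.arg(format)
  stopifnot(inherits(parc, "parcellation"))
  if (all(parc$labels == 0)) stop("refusing to write an empty parcellation", call. = FALSE)
  g <- parc$geometry
  legend_path <- paste0(prefix, "_legend.tsv")
  counts <- table(factor(parc$labels[parc$labels > 0], levels = seq_len(parc$K)))
  utils::write.table(
    data.frame(label = seq_len(parc$K), voxel_count = as.integer(counts)),
    legend_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (format == "tsv") {
    lab_path <- paste0(prefix, "_labels.tsv")
    utils::write.table(
      data.frame(voxel_id = if (!is.null(g)) g$voxel_ids else seq_along(parc$labels),
                 label = parc$labels),
      lab_path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    if (is.null(g)) stop("NIfTI output needs a geometry attached to the parcellation", call. = FALSE)
    lab_path <- paste0(prefix, "_labels.nii.gz")
    arr <- array(0L, dim = g$grid_shape)
    arr[g$voxel_ids] <- parc$labels
    nii <- RNifti::asNifti(arr)
    RNifti::pixdim(nii) <- g$spacing
    RNifti::writeNifti(nii, lab_path, datatype = "int16")
  }
  invisible(c(labels = lab_path, legend = legend_path))
}

#' Read a parcellation written by [write_parcellation()]
#'
#' @param path `_labels.tsv` or label NIfTI path.
#' @param geometry Optional `voxel_geometry` to attach (required to match
#'   voxel order for the TSV format when subsetted).
#' @param K Number of components; defaults to the maximum label found.
#' @param threshold Threshold metadata to attach.
#' @return A `parcellation`.
#' @export
read_parcellation <- function(path, geometry = NULL, K = NULL, threshold = NA_real_) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    nii <- RNifti::readNifti(path)
    labels <- as.integer(round(as.numeric(nii)))
    if (!is.null(geometry)) labels <- labels[geometry$voxel_ids]
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t")
    labels <- as.integer(tab$label)
  }
  if (is.null(K)) K <- max(labels, 1L)
  structure(
    list(labels = labels, K = K, threshold = threshold, geometry = geometry,
         provenance = list(source = path)),
    class = "parcellation"
  )
}
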