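#' Write the core solid mask of a domain as a TIFF stack
#'
#' One 8-bit page per layer along the third array axis; solid voxels are
#' written as 1, pore as 0.  Only the core is written (the margin shell is
#' reconstructed on load).
#'
#' @param domain a [voxel_domain()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_voxel_mask <- function(domain, path) {
  core <- core_labels(domain)
  pages <- lapply(seq_len(dim(core)[3]),
                  function(k) (core[, , k] == 1L) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Load a segmented voxel mask as a simulation domain
#'
#' Reads a binary TIFF stack (one page per slice), embeds it in an outer
#' fluid margin shell, and applies connectivity cleanup.  Intended for
#' user-supplied segmented micro-CT masks; the result is ready for the
#' solvers.
#'
#' @param path TIFF stack of a binary mask (nonzero = solid).
#' @param pitch_um voxel pitch in micrometres.
#' @param margin_vox margin shell thickness in voxels.
#' @param loading_axis loading axis of the resulting domain.
#' @return a cleaned [voxel_domain()].
#' @export
load_voxel_mask <- function(path, pitch_um = 18, margin_vox = 2L,
                            loading_axis = 3L) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("unreadable TIFF mask: ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(t(vapply(pages, dim, integer(2))))
  if (nrow(dims) != 1L)
    stop("mask stack is not cuboidal: slice dimensions differ")
  mask <- array(0L, dim = c(dims[1, 1], dims[1, 2], length(pages)))
  for (k in seq_along(pages)) mask[, , k] <- as.integer(pages[[k]] != 0)
  vals <- unique(as.vector(vapply(pages, as.numeric, numeric(prod(dims[1, ])))))
  if (!all(vals %in% c(0, 1) | vals %in% c(0, 255)))
    stop("mask is not binary (values other than 0/1 or 0/255 found)")
  m <- as.integer(margin_vox)
  d <- dim(mask) + 2L * m
  labels <- array(2L, dim = d)
  labels[(m + 1L):(d[1] - m), (m + 1L):(d[2] - m), (m + 1L):(d[3] - m)] <- mask
  dom <- voxel_domain(labels, pitch_um = pitch_um,
                      loading_axis = loading_axis, margin_vox = m)
  dom <- cleanup_connectivity(dom)
  bv <- compute_bvtv(dom)
  if (bv <= 0 || bv >= 1)
    stop(infeasible_geometry(
      sprintf("loaded mask yields a degenerate domain (BV/TV %.3f)", bv)))
  dom
}

#' Export a domain or scalar field as legacy VTK image data
#'
#' Writes an ASCII VTK structured-points file (cell data) that ParaView and
#' similar tools read directly, for visual inspection of geometries and
#' fields.
#'
#' @param x either a [voxel_domain()] (labels are written) or a 3-D numeric
#'   array.
#' @param path output `.vtk` path.
#' @param name data array name in the file.
#' @param pitch_um voxel pitch; taken from the domain when `x` is one.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(x, path, name = "labels", pitch_um = 18) {
  if (inherits(x, "voxel_domain")) {
    arr <- x$labels
    pitch_um <- x$pitch_um
  } else arr <- x
  d <- dim(arr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "marrowflow field export",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1L, d[2] + 1L, d[3] + 1L),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", pitch_um, pitch_um, pitch_um),
               sprintf("CELL_DATA %d", prod(d)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(formatC(as.vector(arr), format = "g"), con)
  invisible(path)
}
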