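#' Physical voxel spacing of a 3D stack
#'
#' Acquisition geometry of the simulated and analysed z-stacks. The default
#' matches the axial sampling used for 3D Q-FISH on an AxioImager-class
#' microscope: 102 nm laterally and 200 nm between z-slices.
#'
#' @param dx,dy Lateral sampling distance in nm.
#' @param dz Axial sampling distance (z-step) in nm.
#' @return A `voxel_spacing` object (named list with `dx`, `dy`, `dz`).
#' @examples
#' voxel_spacing()
#' @export
voxel_spacing <- function(dx = 102, dy = 102, dz = 200) {
  if (any(c(dx, dy, dz) <= 0) || any(!is.finite(c(dx, dy, dz)))) {
    abort("voxel spacing components must be strictly positive and finite")
  }
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 dz = as.numeric(dz)), class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("<voxel_spacing> dx=%g dy=%g dz=%g nm\n", x$dx, x$dy, x$dz))
  invisible(x)
}

# spacing as c(z, y, x), the array axis order
spacing_zyx <- function(spacing) c(spacing$dz, spacing$dy, spacing$dx)

#' Single-channel 3D image stack
#'
#' A voxel grid with physical spacing and a channel label. The array axis
#' order is `(z, y, x)`: the first array index walks down the z-stack.
#'
#' @param voxels Numeric 3D array, non-negative intensities, dim `(nz, ny, nx)`.
#' @param spacing A [voxel_spacing()].
#' @param channel Channel label, one of `"DAPI"`, `"Cy3"`, `"FITC"`.
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, spacing = voxel_spacing(),
                        channel = c("DAPI", "Cy3", "FITC")) {
  channel <- match.arg(channel)
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    abort("`voxels` must be a 3D array with dim (nz, ny, nx)")
  }
  if (any(voxels < 0)) abort("stack intensities must be non-negative")
  stopifnot(inherits(spacing, "voxel_spacing"))
  structure(list(voxels = voxels, spacing = spacing, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s %d x %d x %d (z,y,x), %g/%g/%g nm\n",
              x$channel, d[1], d[2], d[3],
              x$spacing$dz, x$spacing$dy, x$spacing$dx))
  invisible(x)
}

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per z-slice. Intensities are rescaled to `[0, 1]` for
#' 32-bit float TIFF storage; the scale factor, spacing and channel label go
#' to `<path>.json` so [read_stack()] restores the original values.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  scale <- max(v, 1e-12)
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / scale)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                 reduce = FALSE),
                 error = function(e) abort(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e))))
  meta <- list(channel = stack$channel, scale = scale,
               spacing = list(dx = stack$spacing$dx, dy = stack$spacing$dy,
                              dz = stack$spacing$dz),
               dim = dim(v))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must sit next to it).
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side)) {
    abort(sprintf("stack '%s' or its sidecar JSON is missing", path))
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(pages)
  v <- array(0, dim = c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_len(nz)) v[z, , ] <- pages[[z]] * meta$scale
  image_stack(v, voxel_spacing(meta$spacing$dx, meta$spacing$dy,
                               meta$spacing$dz),
              channel = meta$channel)
}
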