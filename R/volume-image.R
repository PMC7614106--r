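#' 3D intensity volume with physical voxel size
#'
#' The basic container for a light-sheet stack: a 3D numeric array in
#' `(z, y, x)` order plus the physical voxel dimensions in micrometres.
#' Axis order is fixed internally as `(z, y, x)`; physical coordinates are
#' reported as `(x, y, z)` micrometres where files are exchanged (Amira
#' convention).
#'
#' @param data 3D numeric array, `(z, y, x)` order.
#' @param voxel_size numeric triple, micrometres per voxel along `(z, y, x)`.
#' @param channel_label free-text channel description (e.g. `"PNAd"`).
#' @return An object of class `volume_image`.
#' @examples
#' v <- volume_image(array(0, c(4, 8, 8)), voxel_size = c(5, 2, 2))
#' dim(v)
#' @export
volume_image <- function(data, voxel_size, channel_label = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume intensities must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values (z, y, x), in micrometres")
  structure(
    list(data = data, voxel_size = voxel_size,
         channel_label = as.character(channel_label)[1]),
    class = "volume_image"
  )
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d x %d x %d voxels (z,y,x), voxel %s um%s\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 4), collapse = " x "),
              if (nzchar(x$channel_label)) paste0(", channel '", x$channel_label, "'") else ""))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Binary 3D mask
#'
#' A boolean grid with the same geometry as its source volume.  `kind`
#' records whether the mask delineates the vessel (PNAd+) signal or the
#' tissue envelope used for volume normalisation.
#'
#' @param data 3D logical array, `(z, y, x)`.
#' @param voxel_size micrometres per voxel, `(z, y, x)`.
#' @param kind `"vessel"` or `"tissue"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, voxel_size, kind = c("vessel", "tissue")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.logical(data)) {
    data <- array(as.logical(data), dim(data))
    if (anyNA(data)) stop("mask values must be TRUE/FALSE")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values")
  structure(list(data = data, voxel_size = voxel_size, kind = kind),
            class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$data)

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask kind=%s> %d x %d x %d voxels, %d true (%.3g%%), volume %.6g um^3\n",
              x$kind, d[1], d[2], d[3], sum(x$data),
              100 * mean(x$data), mask_volume(x)))
  invisible(x)
}

#' Physical volume of a mask
#'
#' Number of true voxels times the voxel volume.
#'
#' @param mask a [binary_mask].
#' @return volume in cubic micrometres.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * prod(mask$voxel_size)
}
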