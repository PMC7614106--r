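#' Gaussian pre-smoothing of a volume
#'
#' Denoising ahead of thresholding.  Sigma is given in micrometres per axis
#' and converted to voxels internally, so the same setting applies across
#' anisotropic acquisitions; `sigma = 0` returns the input unchanged.
#'
#' @param vol a [volume_image].
#' @param smooth_sigma_um Gaussian sigma in micrometres, either one value or
#'   a `(z, y, x)` triple.
#' @return the smoothed [volume_image].
#' @export
preprocess <- function(vol, smooth_sigma_um = 0) {
  stopifnot(inherits(vol, "volume_image"))
  s <- as.numeric(smooth_sigma_um)
  if (length(s) == 1L) s <- rep(s, 3L)
  if (length(s) != 3L || any(!is.finite(s)) || any(s < 0))
    stop("`smooth_sigma_um` must be non-negative (one value or a z,y,x triple)")
  if (all(s == 0)) return(vol)
  sig_vox <- s / vol$voxel_size
  out <- cpp_gaussian3d(as.numeric(vol$data), dim(vol$data), sig_vox)
  volume_image(array(out, dim(vol$data)), vol$voxel_size, vol$channel_label)
}

#' Otsu threshold of an intensity sample
#'
#' Maximises the between-class variance on a 256-bin histogram; the returned
#' value is on the original intensity scale (threshold between the two bin
#' centres that split the classes).
#'
#' @param x numeric vector or array of intensities.
#' @param nbins histogram resolution.
#' @return the threshold; voxels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(pmin(nbins, pmax(1L, findInterval(x, br, rightmost.closed = TRUE))),
                nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(as.numeric(h))   # double: voxel counts overflow integer products
  m <- cumsum(h * mids)
  tot <- w[nbins]; mtot <- m[nbins]
  w0 <- w[-nbins]; m0 <- m[-nbins]
  w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, nbins - 1L)
  sb[valid] <- (mtot * w0[valid] - tot * m0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sb)
  (mids[k] + mids[k + 1]) / 2
}

#' Threshold a volume into a binary vessel mask
#'
#' @param vol a [volume_image] (usually after [preprocess()]).
#' @param method `"otsu"` (parameter-free default), `"percentile"` (param =
#'   percentile in (0,100); that quantile of all intensities becomes the
#'   threshold) or `"fixed"` (param = threshold).
#' @param param threshold or percentile for the non-Otsu methods.
#' @return a vessel [binary_mask]; the threshold actually applied is recorded
#'   in `attr(, "threshold")` so that auto-chosen values stay auditable.
#' @export
binarize <- function(vol, method = c("otsu", "percentile", "fixed"), param = NULL) {
  stopifnot(inherits(vol, "volume_image"))
  if (is.character(method) && length(method) == 1 &&
      !method %in% c("otsu", "percentile", "fixed"))
    stop("unknown binarization method: '", method, "'")
  method <- match.arg(method)
  thr <- switch(method,
    otsu = otsu_threshold(vol$data),
    percentile = {
      if (is.null(param)) stop("percentile method needs `param`")
      if (param <= 0 || param >= 100) stop("percentile must lie strictly in (0, 100)")
      as.numeric(stats::quantile(vol$data, param / 100))
    },
    fixed = {
      if (is.null(param)) stop("fixed method needs `param` (the threshold)")
      as.numeric(param)
    })
  m <- binary_mask(vol$data > thr, vol$voxel_size, "vessel")
  attr(m, "threshold") <- thr
  attr(m, "method") <- method
  m
}

#' Remove speckle and fill cavities in a binary mask
#'
#' Deletes 26-connected components smaller than a voxel-count floor (speckle
#' that would otherwise surface as spurious vessel networks) and optionally
#' fills internal cavities (background regions not 6-connected to the volume
#' border).  Idempotent at fixed parameters.
#'
#' @param mask a [binary_mask].
#' @param min_component_voxels components with fewer true voxels are removed.
#' @param fill_holes fill internal cavities?
#' @return the cleaned [binary_mask].
#' @export
clean_mask <- function(mask, min_component_voxels = 0L, fill_holes = FALSE) {
  stopifnot(inherits(mask, "binary_mask"))
  if (min_component_voxels < 0) stop("`min_component_voxels` must be >= 0")
  d <- dim(mask$data)
  a <- mask$data
  if (min_component_voxels > 0 && any(a)) {
    lab <- cpp_label26(as.logical(a), d)
    sz <- tabulate(lab)
    keep <- sz >= min_component_voxels
    a <- array(lab > 0L & keep[pmax(lab, 1L)], d)
  }
  if (fill_holes && any(a))
    a <- array(cpp_fill_holes(as.logical(a), d), d)
  out <- binary_mask(a, mask$voxel_size, mask$kind)
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

#' Tissue envelope mask and volume
#'
#' The 3D descriptors are normalised by the lymph-node volume.  With a
#' single PNAd channel the node outline is approximated by the convex hull
#' of the vessel mask (HEVs span the paracortex, so their hull tracks the
#' node); with a second autofluorescence channel the envelope is thresholded
#' directly, the largest component kept and cavities filled.
#'
#' @param x a vessel [binary_mask] (`method = "convex_hull"`) or a
#'   [volume_image] of the autofluorescence channel
#'   (`method = "autofluorescence"`).
#' @param method envelope construction rule.
#' @return a tissue [binary_mask]; its physical volume is
#'   `mask_volume(result)`.
#' @export
tissue_mask <- function(x, method = c("convex_hull", "autofluorescence")) {
  method <- match.arg(method)
  if (method == "convex_hull") {
    stopifnot(inherits(x, "binary_mask"))
    if (!any(x$data)) stop("cannot take the convex hull of an empty vessel mask")
    d <- dim(x$data)
    idx <- which(x$data)
    i1 <- (idx - 1L) %% d[1]
    i2 <- ((idx - 1L) %/% d[1]) %% d[2]
    i3 <- (idx - 1L) %/% (d[1] * d[2])
    pts <- cbind((i3 + 0.5) * x$voxel_size[3],
                 (i2 + 0.5) * x$voxel_size[2],
                 (i1 + 0.5) * x$voxel_size[1])
    hull <- cpp_convex_mask(pts, d, x$voxel_size)
    if (!length(hull)) {
      # degenerate point set (rank < 3): fall back to the mask itself
      warning("vessel mask is degenerate (coplanar/collinear); tissue envelope = mask")
      return(binary_mask(x$data, x$voxel_size, "tissue"))
    }
    binary_mask(array(hull, d), x$voxel_size, "tissue")
  } else {
    stopifnot(inherits(x, "volume_image"))
    thr <- otsu_threshold(x$data)
    a <- x$data > thr
    d <- dim(a)
    if (!any(a)) stop("autofluorescence channel thresholded to an empty mask")
    lab <- cpp_label26(as.logical(a), d)
    sz <- tabulate(lab)
    a <- array(lab == which.max(sz), d)
    a <- array(cpp_fill_holes(as.logical(a), d), d)
    binary_mask(a, x$voxel_size, "tissue")
  }
}
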