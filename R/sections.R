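#' 2D HEV metrics on a labelled section
#'
#' Section-based quantification of PNAd+ vessels: per-vessel areas from a
#' labelled mask, the total HEV area as a percentage of the LN section area,
#' HEV density (vessels per mm^2 of LN) and the mean vessel area.  Vessels
#' are taken as pre-delineated labels (manual or synthetic); automated 2D
#' detection is out of scope.
#'
#' @param vessel_labels integer matrix, 0 = background, k > 0 = vessel k.
#' @param tissue_outline logical matrix of the LN section, same shape.
#' @param pixel_size micrometres per pixel, `(y, x)` pair (or one value).
#' @return an object of class `section_metrics` with fields `ln_area` (um^2),
#'   `vessel_areas` (um^2 per label), `hev_area_pct`, `hev_density`
#'   (vessels/mm^2), `mean_vessel_area` (um^2; 0 with `no_vessels = TRUE`
#'   when the section is empty).
#' @export
measure_section <- function(vessel_labels, tissue_outline, pixel_size) {
  if (!is.matrix(vessel_labels)) stop("`vessel_labels` must be a matrix")
  if (!is.matrix(tissue_outline) || !identical(dim(vessel_labels), dim(tissue_outline)))
    stop("`tissue_outline` must be a logical matrix of the same shape")
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  if (length(pixel_size) != 2L || any(pixel_size <= 0))
    stop("`pixel_size` must be one or two positive values (um)")
  outline <- as.logical(tissue_outline)
  if (!any(outline)) stop("tissue outline is empty")
  if (any(vessel_labels > 0 & !tissue_outline))
    stop("vessel labels fall outside the tissue outline")
  px_area <- prod(pixel_size)
  ln_area <- sum(outline) * px_area
  labs <- vessel_labels[vessel_labels > 0]
  areas <- if (length(labs)) as.numeric(table(factor(labs))) * px_area else numeric(0)
  n <- length(areas)
  structure(list(
    ln_area = ln_area,
    vessel_areas = areas,
    n_vessels = n,
    hev_area_pct = 100 * sum(areas) / ln_area,
    hev_density = n / (ln_area * 1e-6),
    mean_vessel_area = if (n > 0) sum(areas) / n else 0,
    no_vessels = n == 0L
  ), class = "section_metrics")
}

#' @export
print.section_metrics <- function(x, ...) {
  cat("<section_metrics>\n")
  cat(sprintf("  LN area        %.6g um^2\n", x$ln_area))
  cat(sprintf("  HEV area       %.4g%% of LN\n", x$hev_area_pct))
  cat(sprintf("  HEV density    %.4g vessels/mm^2\n", x$hev_density))
  cat(sprintf("  mean HEV area  %.6g um^2 (n = %d)\n", x$mean_vessel_area, x$n_vessels))
  invisible(x)
}

#' HEVhi / HEVlo classification by median split
#'
#' Samples are split at the median of their HEV area fractions: values
#' strictly above the median are labelled `"hi"`, values at or below it
#' `"lo"` (the tie rule is a deterministic convention).  The threshold is
#' echoed so reported splits are auditable.
#'
#' @param per_sample_values HEV area fractions, one per sample (>= 2).
#' @return list with `threshold` (the median) and `status` (`"hi"`/`"lo"`
#'   per sample, names preserved).
#' @export
classify_hev_status <- function(per_sample_values) {
  v <- as.numeric(per_sample_values)
  if (length(v) < 2L) stop("need at least two samples for a median split")
  thr <- stats::median(v)
  status <- ifelse(v > thr, "hi", "lo")
  names(status) <- names(per_sample_values)
  list(threshold = thr, status = status)
}
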