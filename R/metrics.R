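#' Binned distribution with micrometre labels
#'
#' Values are divided into upper-inclusive bins `(w(k-1), wk]` labelled
#' `"1-10"`, `"11-20"`, ... for the default 10 um width, so a value of
#' exactly 20 falls in `"11-20"`, matching the printed bin convention of HEV
#' length/width distributions.  Values beyond `cap` collect in an open-ended
#' trailing bin.  Percentages are of the total count.
#'
#' @param values positive lengths or widths, micrometres.
#' @param bin_width bin width in micrometres.
#' @param cap upper edge of the last closed bin; values above it land in
#'   `"> cap"`.
#' @return data.frame with `bin` (label), `lower`, `upper`, `count`, `pct`;
#'   an empty input yields an empty histogram flagged with
#'   `attr(, "empty") = TRUE`.
#' @export
bin_distribution <- function(values, bin_width = 10, cap = 100) {
  if (bin_width <= 0) stop("`bin_width` must be positive")
  values <- as.numeric(values)
  if (!length(values)) {
    h <- data.frame(bin = character(0), lower = numeric(0), upper = numeric(0),
                    count = integer(0), pct = numeric(0))
    attr(h, "empty") <- TRUE
    return(h)
  }
  if (any(values <= 0) || any(!is.finite(values)))
    stop("values must be positive and finite")
  nbin <- ceiling(cap / bin_width)
  k <- pmin(ceiling(values / bin_width), nbin + 1L)
  counts <- tabulate(k, nbins = nbin + 1L)
  lab <- c(sprintf("%d-%d", round(bin_width * (seq_len(nbin) - 1)) + 1L,
                   round(bin_width * seq_len(nbin))),
           sprintf("> %d", round(bin_width * nbin)))
  h <- data.frame(bin = lab,
                  lower = bin_width * (seq_len(nbin + 1L) - 1L),
                  upper = c(bin_width * seq_len(nbin), Inf),
                  count = counts,
                  pct = 100 * counts / length(values))
  if (counts[nbin + 1L] == 0L) h <- h[seq_len(nbin), , drop = FALSE]
  attr(h, "empty") <- FALSE
  h
}

#' Extracted numerical parameters of a vessel network
#'
#' The summary table of a 3D HEV analysis: totals, counts, tissue volume,
#' densities and the binned length/width distributions.  Because the exact
#' meaning of a 3D "HEV density" is ambiguous, both variants are emitted:
#' `density_length` (um of vessel per mm^3 of tissue) and `density_count`
#' (segments per mm^3).
#'
#' @param graph a pruned, measured [vessel_graph].
#' @param tissue the tissue [binary_mask] of the same sample (its physical
#'   volume normalises the densities).
#' @param bin_width,bin_cap histogram parameters, micrometres.
#' @return an object of class `network_metrics`.
#' @export
summarize_network <- function(graph, tissue, bin_width = 10, bin_cap = 100) {
  stopifnot(inherits(graph, "vessel_graph"), inherits(tissue, "binary_mask"))
  ln_volume <- mask_volume(tissue)
  if (ln_volume <= 0) stop("tissue mask volume is zero")
  if (is.null(graph$networks)) graph <- identify_networks(graph)
  segs <- graph$segments
  len <- vapply(segs, function(s) s$length_um %||% NA_real_, 0)
  wid <- vapply(segs, function(s) s$width_um %||% NA_real_, 0)
  if (length(segs) && anyNA(len)) stop("graph lengths not measured")
  total <- sum(len)
  mm3 <- ln_volume * 1e-9
  m <- list(
    total_length = total,
    n_segments = length(segs),
    n_branch_points = sum(graph$nodes$degree >= 3L),
    n_endpoints = sum(graph$nodes$degree == 1L),
    n_networks = nrow(graph$networks),
    ln_volume = ln_volume,
    density_length = total / mm3,
    density_count = length(segs) / mm3,
    mean_segment_length = if (length(segs)) mean(len) else 0,
    mean_segment_width = if (length(segs) && !anyNA(wid)) mean(wid) else 0,
    length_histogram = bin_distribution(len, bin_width, bin_cap),
    width_histogram = if (length(segs) && !anyNA(wid))
      bin_distribution(wid, bin_width, bin_cap) else bin_distribution(numeric(0), bin_width, bin_cap)
  )
  structure(m, class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("<network_metrics>\n")
  cat(sprintf("  total HEV length   %.6g um\n", x$total_length))
  cat(sprintf("  segments           %d\n", x$n_segments))
  cat(sprintf("  branch points      %d\n", x$n_branch_points))
  cat(sprintf("  networks           %d\n", x$n_networks))
  cat(sprintf("  LN volume          %.6g um^3\n", x$ln_volume))
  cat(sprintf("  density            %.6g um/mm^3, %.6g segments/mm^3\n",
              x$density_length, x$density_count))
  cat(sprintf("  mean segment       %.4g um long, %.4g um wide\n",
              x$mean_segment_length, x$mean_segment_width))
  invisible(x)
}

#' Histogram bar plot of a binned distribution
#'
#' @param x a `network_metrics` object.
#' @param which `"length"` or `"width"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.network_metrics <- function(x, which = c("width", "length"), ...) {
  which <- match.arg(which)
  h <- if (which == "width") x$width_histogram else x$length_histogram
  if (!nrow(h)) { warning("empty histogram"); return(invisible(NULL)) }
  graphics::barplot(h$pct, names.arg = h$bin, las = 2,
                    ylab = "% of segments", xlab = paste(which, "(µm)"), ...)
  invisible(x)
}

#' Pairwise fold changes between labelled samples
#'
#' Ratios of LN volume, total HEV length, segment and branch-point counts
#' between every pair of samples (second over first, in list order).  No
#' hypothesis testing is performed.
#'
#' @param metrics_list named list of `network_metrics` (>= 2 samples).
#' @return data.frame with one row per unordered pair.
#' @export
compare_conditions <- function(metrics_list) {
  if (!is.list(metrics_list) || length(metrics_list) < 2L)
    stop("need at least two labelled samples")
  if (is.null(names(metrics_list)))
    names(metrics_list) <- paste0("sample", seq_along(metrics_list))
  if (any(vapply(metrics_list, function(m) m$ln_volume, 0) == 0))
    stop("zero LN volume in input")
  pairs <- utils::combn(length(metrics_list), 2)
  rows <- apply(pairs, 2, function(p) {
    a <- metrics_list[[p[1]]]; b <- metrics_list[[p[2]]]
    data.frame(sample_a = names(metrics_list)[p[1]],
               sample_b = names(metrics_list)[p[2]],
               fold_ln_volume = b$ln_volume / a$ln_volume,
               fold_total_length = b$total_length / a$total_length,
               fold_n_segments = b$n_segments / a$n_segments,
               fold_n_branch_points = b$n_branch_points / a$n_branch_points)
  })
  do.call(rbind, rows)
}
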