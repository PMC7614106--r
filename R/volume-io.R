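#' Read a multi-page grayscale TIFF stack
#'
#' Pages become the z axis of a [volume_image].  The voxel size is supplied
#' by the caller (or by a YAML sidecar written by [write_stack()]) rather
#' than decoded from TIFF tags: resolution-tag dialects vary between
#' acquisition software, and an explicit value keeps analyses bit-exactly
#' reproducible.
#'
#' @param path TIFF file (uncompressed baseline grayscale, 8/16-bit).
#' @param voxel_size micrometres per voxel `(z, y, x)`; if `NULL`, taken from
#'   the sidecar `<path>.yaml` when present, else `c(1, 1, 1)` with a message.
#' @param channel_label optional channel annotation.
#' @return a [volume_image].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, voxel_size = NULL, channel_label = NULL) {
  td <- .tiff_read(path)
  sidecar <- paste0(path, ".yaml")
  if (is.null(voxel_size) || is.null(channel_label)) {
    meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
    if (is.null(voxel_size)) {
      if (!is.null(meta$voxel_size_um)) voxel_size <- as.numeric(meta$voxel_size_um)
      else {
        message("read_stack: no voxel size given or found; assuming 1x1x1 um")
        voxel_size <- c(1, 1, 1)
      }
    }
    if (is.null(channel_label))
      channel_label <- if (!is.null(meta$channel_label)) meta$channel_label else ""
  }
  volume_image(td$data, voxel_size, channel_label)
}

#' Write a volume as a multi-page grayscale TIFF
#'
#' Integer-valued volumes round-trip bit-exactly through [read_stack()].
#' Voxel size and channel label travel in a YAML sidecar (`<path>.yaml`).
#'
#' @param vol a [volume_image] with integer-valued intensities in
#'   `[0, 65535]`.  Values in `[0, 255]` are stored as 8-bit, otherwise
#'   16-bit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  a <- vol$data
  if (max(abs(a - round(a))) > 0) {
    warning("non-integer intensities rounded for TIFF storage")
    a <- round(a)
  }
  if (min(a) < 0 || max(a) > 65535)
    stop("intensities outside [0, 65535] cannot be stored as baseline TIFF")
  bits <- if (max(a) <= 255) 8L else 16L
  .tiff_write(a, path, bits)
  yaml::write_yaml(list(voxel_size_um = as.numeric(vol$voxel_size),
                        channel_label = vol$channel_label),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Export a vessel graph as an Amira-compatible SpatialGraph file
#'
#' ASCII "AmiraMesh 3D ASCII 2.0" dialect with VertexCoordinates,
#' EdgeConnectivity, NumEdgePoints, EdgePointCoordinates and thickness
#' blocks, the format consumed by Amira for 3D rendering of vessel
#' networks.  Coordinates are physical `(x, y, z)` micrometres; thickness is
#' the local vessel radius in micrometres.
#'
#' @param graph a measured [vessel_graph] (node positions and segment point
#'   polylines populated, see [measure_lengths()]).
#' @param path output `.am` file.
#' @return `path`, invisibly.
#' @export
write_spatial_graph <- function(graph, path) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (nrow(graph$nodes) == 0L || length(graph$segments) == 0L)
    stop("nothing to write: the vessel graph has no segments")
  if (is.null(graph$segments[[1]]$points))
    stop("graph has no measured point polylines; run measure_lengths() first")

  nodes <- graph$nodes
  nseg <- length(graph$segments)
  pts <- lapply(graph$segments, function(s) s$points)
  npts <- vapply(pts, nrow, 0L)
  idx_of <- match(vapply(graph$segments, function(s) s$from, 0L), nodes$id)
  idx_to <- match(vapply(graph$segments, function(s) s$to, 0L), nodes$id)

  thick <- lapply(graph$segments, function(s) {
    k <- nrow(s$points)
    if (!is.null(s$radius_profile) && length(s$radius_profile) == k) s$radius_profile
    else if (!is.null(s$width_um) && is.finite(s$width_um)) rep(s$width_um / 2, k)
    else rep(1, k)
  })

  num <- function(x) formatC(x, format = "f", digits = 6)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "# AmiraMesh 3D ASCII 2.0",
    "",
    sprintf("define VERTEX %d", nrow(nodes)),
    sprintf("define EDGE %d", nseg),
    sprintf("define POINT %d", sum(npts)),
    "",
    "Parameters {",
    "    ContentType \"HxSpatialGraph\"",
    "}",
    "",
    "VERTEX { float[3] VertexCoordinates } @1",
    "EDGE { int[2] EdgeConnectivity } @2",
    "EDGE { int NumEdgePoints } @3",
    "POINT { float[3] EdgePointCoordinates } @4",
    "POINT { float thickness } @5",
    ""), con)
  writeLines("@1", con)
  writeLines(paste(num(nodes$x), num(nodes$y), num(nodes$z)), con)
  writeLines(c("", "@2"), con)
  writeLines(paste(idx_of - 1L, idx_to - 1L), con)
  writeLines(c("", "@3"), con)
  writeLines(as.character(npts), con)
  writeLines(c("", "@4"), con)
  for (p in pts) writeLines(paste(num(p[, 1]), num(p[, 2]), num(p[, 3])), con)
  writeLines(c("", "@5"), con)
  for (tt in thick) writeLines(num(tt), con)
  invisible(path)
}

#' Parse a SpatialGraph file back into a vessel graph
#'
#' Inverse of [write_spatial_graph()]; the reconstructed graph carries node
#' positions, segment polylines, per-point radii, recomputed degrees/kinds
#' and polyline arc lengths, and passes the vessel-graph invariants.
#'
#' @param path `.am` file in the dialect emitted by [write_spatial_graph()].
#' @return a [vessel_graph].
#' @export
parse_spatial_graph <- function(path) {
  if (!file.exists(path)) stop("SpatialGraph file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  if (!length(ln) || !grepl("AmiraMesh 3D ASCII", ln[1]))
    stop("not an AmiraMesh ASCII file: ", path)
  getdef <- function(what) {
    m <- grep(sprintf("^define %s ", what), ln, value = TRUE)
    if (!length(m)) stop("malformed SpatialGraph: missing 'define ", what, "' header")
    as.integer(sub(sprintf("^define %s ", what), "", m[1]))
  }
  nv <- getdef("VERTEX"); ne <- getdef("EDGE"); np <- getdef("POINT")
  block <- function(tag, n) {
    i <- which(trimws(ln) == tag)
    if (!length(i)) stop("malformed SpatialGraph: missing data section ", tag)
    rows <- ln[(i[1] + 1):length(ln)]
    rows <- rows[nzchar(trimws(rows))]
    stop_at <- grep("^@", rows)
    if (length(stop_at)) rows <- rows[seq_len(stop_at[1] - 1)]
    if (length(rows) < n) stop("malformed SpatialGraph: truncated section ", tag)
    vals <- strsplit(trimws(rows[seq_len(n)]), "[[:space:]]+")
    do.call(rbind, lapply(vals, as.numeric))
  }
  vc <- block("@1", nv)
  ec <- block("@2", ne)
  npts <- as.integer(block("@3", ne)[, 1])
  if (any(npts < 2L)) stop("malformed SpatialGraph: per-edge point count < 2")
  epc <- block("@4", sum(npts))
  th <- block("@5", sum(npts))[, 1]
  if (any(ec < 0) || any(ec >= nv)) stop("malformed SpatialGraph: edge index out of range")

  segments <- vector("list", ne)
  off <- 0L
  for (e in seq_len(ne)) {
    k <- npts[e]
    p <- epc[(off + 1):(off + k), , drop = FALSE]
    rp <- th[(off + 1):(off + k)]
    segments[[e]] <- list(id = e, from = as.integer(ec[e, 1]) + 1L,
                          to = as.integer(ec[e, 2]) + 1L,
                          points = p, radius_profile = rp,
                          length_um = sum(sqrt(rowSums(diff(p)^2))),
                          width_um = 2 * mean(rp))
    off <- off + k
  }
  nodes <- data.frame(id = seq_len(nv), x = vc[, 1], y = vc[, 2], z = vc[, 3])
  g <- new_vessel_graph(nodes, segments, voxel_size = NULL)
  g
}

#' Write network or section metrics to CSV or JSON
#'
#' Lossless tabular export: every scalar field becomes a column, histogram
#' bins become one column per bin labelled with the micrometre bin label.
#' A list of metrics objects yields one row per sample.
#'
#' @param metrics a `network_metrics` or `section_metrics` object, or a
#'   (optionally named) list of them.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, format = c("csv", "json")) {
  if (is.character(format) && length(format) == 1 && !format %in% c("csv", "json"))
    stop("unknown format: '", format, "' (use \"csv\" or \"json\")")
  format <- match.arg(format)
  single <- inherits(metrics, "network_metrics") || inherits(metrics, "section_metrics")
  batch <- if (single) list(metrics) else metrics
  if (!length(batch) || !all(vapply(batch, function(m)
    inherits(m, "network_metrics") || inherits(m, "section_metrics"), TRUE)))
    stop("`metrics` must be (a list of) network_metrics or section_metrics")
  if (is.null(names(batch)))
    names(batch) <- paste0("sample", seq_along(batch))

  if (format == "json") {
    out <- lapply(batch, function(m) {
      l <- unclass(m)
      l$length_histogram <- if (!is.null(l$length_histogram)) as.list(l$length_histogram)
      l$width_histogram <- if (!is.null(l$width_histogram)) as.list(l$width_histogram)
      l
    })
    if (single) out <- out[[1]]
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    rows <- lapply(batch, .metrics_row)
    cols <- unique(unlist(lapply(rows, names)))
    tab <- do.call(rbind, lapply(rows, function(r) {
      r[setdiff(cols, names(r))] <- NA
      as.data.frame(r[cols], check.names = FALSE)
    }))
    tab <- cbind(sample = names(batch), tab)
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

.metrics_row <- function(m) {
  l <- unclass(m)
  hl <- l$length_histogram; hw <- l$width_histogram
  l$length_histogram <- NULL; l$width_histogram <- NULL
  l$vessel_areas <- NULL  # per-vessel list stays in JSON form only
  row <- lapply(l, function(v) if (length(v) == 1) v else paste(v, collapse = ";"))
  addh <- function(row, h, prefix) {
    if (is.null(h) || !nrow(h)) return(row)
    for (i in seq_len(nrow(h)))
      row[[sprintf("%s_pct[%s um]", prefix, h$bin[i])]] <- h$pct[i]
    row
  }
  row <- addh(row, hl, "length")
  row <- addh(row, hw, "width")
  row
}
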