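# Synthetic vessel phantoms with exact ground-truth topology.  Tubes are
# unions of capsules (spheres swept along polylines), which gives an exact
# inside/outside test and closed-form length/radius oracles.

#' Specification of a synthetic vessel phantom
#'
#' Describes everything needed to generate a stack with known ground truth:
#' the grid, an ellipsoidal tissue domain, either an explicit node/edge
#' topology or parameters for a procedural branching tree, and the intensity
#' model.  Defaults emulate the imaging targets of a cleared lymph node:
#' a 128^3 grid of isotropic 2 um voxels holding branched tubes in the
#' 4-20 um diameter range (the dominant reported vessel classes) with
#' bright-tube/dark-background contrast.
#'
#' @param shape grid dimensions `(z, y, x)`.
#' @param voxel_size micrometres per voxel `(z, y, x)`.
#' @param domain_semiaxes_um ellipsoid semi-axes `(x, y, z)` um; default 45%
#'   of the grid extent.
#' @param topology `NULL` for a procedural tree, or a list with `nodes`
#'   (n x 3 matrix of `(x, y, z)` um) and `edges` (data.frame `from`, `to`,
#'   `radius_um`) for an explicit network.  `list()` gives a background-only
#'   phantom.
#' @param n_roots,branch_prob,step_len_um,branch_angle_deg,radius_um,taper,max_segments
#'   procedural-tree parameters: number of surface roots, per-step branching
#'   probability, segment length range (um; the default `NULL` scales segment
#'   length with vessel calibre, 6-12 radii, which also guarantees the
#'   junction separation >= 6r of the benchmark world), branch angle range
#'   (degrees), root radius range (um), radius taper per generation, total
#'   segment cap.
#' @param vessel_level,background_level,noise_sd,psf_sigma_um intensity
#'   model: tube and background levels, additive Gaussian noise sd, optional
#'   PSF blur sigma (um).
#' @param seed RNG seed fixing every stochastic draw.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 128), voxel_size = c(2, 2, 2),
                         domain_semiaxes_um = NULL, topology = NULL,
                         n_roots = 3L, branch_prob = 0.35,
                         step_len_um = NULL, branch_angle_deg = c(40, 80),
                         radius_um = c(4, 10), taper = 0.85, max_segments = 25L,
                         vessel_level = 200, background_level = 50,
                         noise_sd = 0, psf_sigma_um = 0, seed = NULL) {
  shape <- as.integer(shape); voxel_size <- as.numeric(voxel_size)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0))
  extent <- shape * voxel_size                      # (z,y,x) um
  if (is.null(domain_semiaxes_um))
    domain_semiaxes_um <- 0.45 * extent[c(3, 2, 1)] # (x,y,z)
  if (min(radius_um) < max(voxel_size))
    stop("tube radii must be at least one voxel after rasterization")
  if (noise_sd < 0 || psf_sigma_um < 0) stop("noise/PSF parameters must be >= 0")
  structure(list(
    shape = shape, voxel_size = voxel_size,
    domain_centre = extent[c(3, 2, 1)] / 2,         # (x,y,z) um
    domain_semiaxes_um = as.numeric(domain_semiaxes_um),
    topology = topology,
    n_roots = as.integer(n_roots), branch_prob = branch_prob,
    step_len_um = step_len_um, branch_angle_deg = branch_angle_deg,
    radius_um = radius_um, taper = taper, max_segments = as.integer(max_segments),
    vessel_level = vessel_level, background_level = background_level,
    noise_sd = noise_sd, psf_sigma_um = psf_sigma_um, seed = seed
  ), class = "phantom_spec")
}

# minimum distance between segments p1-p2 and q1-q2 (Ericson, Real-Time
# Collision Detection, closest-point-of-two-segments)
.segseg_dist <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  tiny <- 1e-12
  if (a <= tiny && e <= tiny) return(sqrt(sum(r * r)))
  if (a <= tiny) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    cc <- sum(d1 * r)
    if (e <= tiny) { t <- 0; s <- min(max(-cc / a, 0), 1) }
    else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > tiny) min(max((b * f - cc * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (q1 + t * d2)
  sqrt(sum(v * v))
}

.unit <- function(v) v / sqrt(sum(v^2))

.rand_unit <- function() .unit(stats::rnorm(3))

# rotate v by angle_deg around a uniformly random axis perpendicular to v
.tilt <- function(v, angle_deg) {
  v <- .unit(v)
  w <- .rand_unit()
  while (abs(sum(w * v)) > 0.99) w <- .rand_unit()
  axis <- .unit(c(v[2] * w[3] - v[3] * w[2],
                  v[3] * w[1] - v[1] * w[3],
                  v[1] * w[2] - v[2] * w[1]))
  th <- angle_deg * pi / 180
  v * cos(th) + c(axis[2] * v[3] - axis[3] * v[2],
                  axis[3] * v[1] - axis[1] * v[3],
                  axis[1] * v[2] - axis[2] * v[1]) * sin(th) +
    axis * sum(axis * v) * (1 - cos(th))
}

# grow a self-avoiding branching tree of straight capsule segments inside
# the ellipsoidal domain; returns nodes (x,y,z um) and edges (from, to,
# radius_um)
.grow_tree <- function(spec, clearance_um = 4) {
  ctr <- spec$domain_centre; semi <- spec$domain_semiaxes_um
  inside <- function(p, r) {
    s <- pmax(semi - r, 1e-6)
    sum(((p - ctr) / s)^2) <= 1
  }
  nodes <- list(); edges <- list()
  new_node <- function(p) { nodes[[length(nodes) + 1L]] <<- p; length(nodes) }
  seg_clear <- function(p1, p2, r, exclude_nodes) {
    if (!length(edges)) return(TRUE)
    for (e in edges) {
      if (e$from %in% exclude_nodes || e$to %in% exclude_nodes) next
      d <- .segseg_dist(p1, p2, nodes[[e$from]], nodes[[e$to]])
      if (d < r + e$radius_um + clearance_um) return(FALSE)
    }
    TRUE
  }
  new_root <- function() {
    for (try in 1:20) {
      u <- .rand_unit()
      p <- ctr + u * semi * 0.95
      dir <- .unit(.unit(ctr - p) + 0.3 * .rand_unit())
      r <- stats::runif(1, spec$radius_um[1], spec$radius_um[2])
      if (inside(p, r)) break
    }
    list(node = new_node(p), dir = dir, radius = r)
  }
  tips <- lapply(seq_len(spec$n_roots), function(i) new_root())
  n_seg <- 0L
  respawns <- 0L
  while (n_seg < spec$max_segments) {
    if (!length(tips)) {
      # all tips exhausted before the target density was reached: seed a
      # fresh surface root so the family keeps its stated segment count
      if (respawns >= 5L * spec$max_segments) break
      respawns <- respawns + 1L
      tips <- list(new_root())
    }
    tip <- tips[[1]]; tips <- tips[-1]
    placed <- FALSE
    for (try in 1:15) {
      dir <- if (try == 1) tip$dir else .tilt(tip$dir, stats::runif(1, 5, 30))
      L <- if (is.null(spec$step_len_um))
        stats::runif(1, 6, 12) * tip$radius      # calibre-scaled segments
      else max(stats::runif(1, spec$step_len_um[1], spec$step_len_um[2]),
               6 * tip$radius)
      q <- nodes[[tip$node]] + dir * L
      if (!inside(q, tip$radius)) next
      if (!seg_clear(nodes[[tip$node]], q, tip$radius, exclude_nodes = tip$node)) next
      qid <- new_node(q)
      edges[[length(edges) + 1L]] <- list(from = tip$node, to = qid,
                                          radius_um = tip$radius)
      n_seg <- n_seg + 1L
      placed <- TRUE
      if (n_seg < spec$max_segments &&
          stats::runif(1) < spec$branch_prob) {
        a1 <- stats::runif(1, spec$branch_angle_deg[1], spec$branch_angle_deg[2])
        a2 <- stats::runif(1, spec$branch_angle_deg[1], spec$branch_angle_deg[2])
        rc <- max(spec$radius_um[1], tip$radius * spec$taper)
        d1 <- .tilt(dir, a1); d2 <- .tilt(dir, a2)
        for (try2 in 1:10) {   # children must head apart
          if (sum(d1 * d2) < cos(spec$branch_angle_deg[1] * pi / 180)) break
          d2 <- .tilt(dir, a2)
        }
        tips <- c(tips, list(list(node = qid, dir = d1, radius = rc),
                             list(node = qid, dir = d2, radius = rc)))
      } else {
        tips <- c(tips, list(list(node = qid, dir = dir, radius = tip$radius)))
      }
      break
    }
    # a tip that found no room simply terminates (its node stays an endpoint)
    if (!placed) next
  }
  list(nodes = do.call(rbind, nodes),
       edges = if (length(edges)) do.call(rbind, lapply(edges, function(e)
         data.frame(from = e$from, to = e$to, radius_um = e$radius_um)))
       else data.frame(from = integer(0), to = integer(0), radius_um = numeric(0)))
}

# explicit/derived topology -> ground-truth vessel graph
.truth_graph <- function(nodes_xyz, edges, voxel_size) {
  if (is.null(nodes_xyz) || !nrow(edges)) {
    nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0))
    return(new_vessel_graph(nodes, list(), voxel_size))
  }
  nodes <- data.frame(id = seq_len(nrow(nodes_xyz)), x = nodes_xyz[, 1],
                      y = nodes_xyz[, 2], z = nodes_xyz[, 3])
  segments <- lapply(seq_len(nrow(edges)), function(i) {
    p <- rbind(nodes_xyz[edges$from[i], ], nodes_xyz[edges$to[i], ])
    r <- edges$radius_um[i]
    list(id = i, from = as.integer(edges$from[i]), to = as.integer(edges$to[i]),
         points = unname(p),
         length_um = sqrt(sum((p[2, ] - p[1, ])^2)),
         width_um = 2 * r, radius_um = r,
         radius_profile = rep(r, 2))
  })
  # ground truth is the topological graph: growth-step chain nodes of degree 2
  # are dissolved into polyline segments (radius is constant along a chain)
  dis <- .dissolve_degree2(nodes, segments)
  segments <- dis$segs
  used <- unique(c(vapply(segments, function(s) s$from, 0L),
                   vapply(segments, function(s) s$to, 0L)))
  nodes <- nodes[nodes$id %in% used, , drop = FALSE]
  new_vessel_graph(nodes, segments, voxel_size)
}

#' Generate a synthetic vessel phantom with ground truth
#'
#' Rasterises the phantom's tube network as a union of capsules at the
#' vessel intensity over background, optionally blurs with a Gaussian PSF
#' and adds seeded Gaussian noise, and returns the exact ground truth
#' alongside: the true vessel graph (analytic lengths, radii), the tissue
#' domain and its analytic volume, and the intensity levels.  Identical
#' spec + seed give bit-identical output.
#'
#' @param spec a [phantom_spec].
#' @return list with `volume` (a [volume_image]) and `truth` (list: `graph`
#'   a ground-truth [vessel_graph]; `tissue_volume_um3` analytic ellipsoid
#'   volume; `domain` centre/semi-axes; `vessel_level`, `background_level`;
#'   `tissue_mask` the rasterised domain as a [binary_mask]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  topo <- if (is.null(spec$topology)) .grow_tree(spec)
          else if (length(spec$topology) == 0L) list(nodes = NULL,
            edges = data.frame(from = integer(0), to = integer(0), radius_um = numeric(0)))
          else spec$topology
  if (nrow(topo$edges) && min(topo$edges$radius_um) < max(spec$voxel_size))
    stop("tube radius below one voxel")
  truth_graph <- .truth_graph(topo$nodes, topo$edges, spec$voxel_size)

  d <- spec$shape
  caps <- NULL
  if (nrow(topo$edges)) {
    caps <- do.call(rbind, lapply(truth_graph$segments, function(s) {
      p <- s$points
      cbind(p[-nrow(p), 1], p[-nrow(p), 2], p[-nrow(p), 3],
            p[-1, 1], p[-1, 2], p[-1, 3], s$radius_um)
    }))
    mask <- array(cpp_rasterize_capsules(d, spec$voxel_size, caps), d)
  } else mask <- array(FALSE, d)

  vol <- array(spec$background_level, d)
  vol[mask] <- spec$vessel_level
  if (spec$psf_sigma_um > 0)
    vol <- array(cpp_gaussian3d(as.numeric(vol), d,
                                spec$psf_sigma_um / spec$voxel_size), d)
  if (spec$noise_sd > 0)
    vol <- vol + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)

  tissue <- binary_mask(array(cpp_ellipsoid_mask(d, spec$voxel_size,
                                                 spec$domain_centre,
                                                 spec$domain_semiaxes_um), d),
                        spec$voxel_size, "tissue")
  list(
    volume = volume_image(vol, spec$voxel_size, "phantom"),
    truth = list(
      graph = truth_graph,
      vessel_mask = binary_mask(mask, spec$voxel_size, "vessel"),
      tissue_mask = tissue,
      tissue_volume_um3 = 4 / 3 * pi * prod(spec$domain_semiaxes_um),
      domain = list(centre = spec$domain_centre,
                    semiaxes_um = spec$domain_semiaxes_um),
      vessel_level = spec$vessel_level,
      background_level = spec$background_level
    )
  )
}

#' Section a 3D phantom into a labelled 2D mask
#'
#' Emulates a thin histological section through the volume: a slab of
#' `thickness_um` starting at `z_index` is maximum-projected, binarised at
#' the midpoint between background and vessel intensity, and its 2D
#' connected components labelled.  The per-slice truth lists which tubes
#' intersect the slab.  Sectioning is the 2D counterpart against which the
#' 3D analysis is contrasted: slices through networks of very different
#' total extent can carry identical cross-section statistics.
#'
#' @param vol the phantom [volume_image].
#' @param truth the phantom's ground-truth list.
#' @param z_index first slice (1-based).
#' @param thickness_um slab thickness; must be at least one z-step.
#' @return list with `labels` (integer matrix, 8-connected components),
#'   `outline` (logical matrix, the section field), `pixel_size` um `(y, x)`,
#'   and `truth` (`n_vessels`, `segment_ids`, `radii_um` of tubes crossing
#'   the slab).
#' @export
section_phantom <- function(vol, truth, z_index, thickness_um) {
  stopifnot(inherits(vol, "volume_image"))
  d <- dim(vol$data)
  hz <- vol$voxel_size[1]
  if (thickness_um < hz) stop("slab thickness is below one z-step")
  if (z_index < 1 || z_index > d[1]) stop("z_index outside the volume")
  nsl <- min(max(1L, as.integer(round(thickness_um / hz))), d[1] - z_index + 1L)
  slab <- vol$data[z_index:(z_index + nsl - 1L), , , drop = FALSE]
  mip <- apply(slab, c(2, 3), max)
  thr <- (truth$vessel_level + truth$background_level) / 2
  bin <- mip > thr
  lab <- array(cpp_label26(as.logical(array(bin, c(1, d[2], d[3]))),
                           c(1L, d[2], d[3])), c(d[2], d[3]))
  z0 <- (z_index - 1) * hz; z1 <- (z_index + nsl - 1) * hz
  hit <- vapply(truth$graph$segments, function(s) {
    zr <- range(s$points[, 3])
    (zr[1] - s$radius_um) <= z1 && (zr[2] + s$radius_um) >= z0
  }, TRUE)
  list(labels = lab,
       outline = matrix(TRUE, d[2], d[3]),
       pixel_size = vol$voxel_size[2:3],
       truth = list(n_vessels = sum(hit),
                    segment_ids = which(hit),
                    radii_um = vapply(truth$graph$segments[hit],
                                      function(s) s$radius_um %||% NA_real_, 0)))
}
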