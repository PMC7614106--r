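# Attributed vessel graph: junction/endpoint nodes, traced segments with
# voxel paths and physical polylines, grouped into discrete networks.

# Internal constructor: recomputes degrees and kinds from the segment list
# and validates the node/segment invariants.
new_vessel_graph <- function(nodes, segments, voxel_size = NULL, networks = NULL) {
  nodes$id <- as.integer(nodes$id)
  for (i in seq_along(segments)) {
    segments[[i]]$from <- as.integer(segments[[i]]$from)
    segments[[i]]$to <- as.integer(segments[[i]]$to)
  }
  if (length(segments)) {
    ends <- c(vapply(segments, function(s) s$from, 0L),
              vapply(segments, function(s) s$to, 0L))
    if (!all(ends %in% nodes$id))
      stop("vessel graph invariant violated: segment endpoint is not a node id")
    deg <- tabulate(match(ends, nodes$id), nbins = nrow(nodes))
  } else deg <- integer(nrow(nodes))
  nodes$degree <- deg
  nodes$kind <- ifelse(deg >= 3L, "junction", "endpoint")
  for (i in seq_along(segments)) segments[[i]]$id <- i
  structure(list(nodes = nodes, segments = segments,
                 networks = networks, voxel_size = voxel_size),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes (%d branch points), %d segments%s\n",
              nrow(x$nodes), sum(x$nodes$degree >= 3), length(x$segments),
              if (!is.null(x$networks)) sprintf(", %d networks", nrow(x$networks)) else ""))
  len <- vapply(x$segments, function(s) s$length_um %||% NA_real_, 0)
  if (length(len) && any(is.finite(len)))
    cat(sprintf("  total length %.6g um\n", sum(len, na.rm = TRUE)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_igraph <- function(graph) {
  el <- if (length(graph$segments))
    cbind(vapply(graph$segments, function(s) s$from, 0L),
          vapply(graph$segments, function(s) s$to, 0L))
  else matrix(0L, 0, 2)
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(graph$nodes$id))
  if (nrow(el))
    g <- igraph::add_edges(g, as.character(t(el)))
  g
}

#' Independent cycle count of a vessel graph
#'
#' First Betti number of the network: number of segments minus nodes plus
#' connected components (self-loops and isolated nodes handled through the
#' underlying multigraph).
#'
#' @param graph a [vessel_graph].
#' @return integer cycle count.
#' @export
cycle_count <- function(graph) {
  g <- as_igraph(graph)
  as.integer(igraph::ecount(g) - igraph::vcount(g) + igraph::count_components(g))
}

#' Convert a skeleton into a vessel graph
#'
#' Skeleton voxels are classified by their 26-neighbour count: 1 neighbour is
#' an endpoint, 2 a slab (segment interior), 3 or more a junction.
#' 26-adjacent junction voxels are merged into a single node at their
#' centroid, so one anatomical branch point does not splinter into several
#' nodes; slab runs are traced into segments between nodes; an isolated
#' closed loop becomes one self-loop segment anchored at its
#' lexicographically smallest voxel.  Every skeleton voxel belongs to exactly
#' one segment path or node.
#'
#' @param skel a [skeleton].
#' @return an unmeasured [vessel_graph] (voxel paths populated; run
#'   [measure_lengths()] / [measure_widths()] next).
#' @export
build_graph <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  V <- skel$voxels
  n <- nrow(V)
  empty_nodes <- data.frame(id = integer(0), vox_z = numeric(0), vox_y = numeric(0),
                            vox_x = numeric(0), degree = integer(0),
                            kind = character(0), stringsAsFactors = FALSE)
  if (n == 0L)
    return(new_vessel_graph(empty_nodes, list(), skel$voxel_size))

  nz <- skel$source_shape[1]; ny <- skel$source_shape[2]; nx <- skel$source_shape[3]
  lin <- (V[, 3] - 1) * (nz * ny) + (V[, 2] - 1) * nz + V[, 1]  # increasing

  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nbmat <- matrix(NA_integer_, n, 26)
  for (o in seq_len(26)) {
    zz <- V[, 1] + offs[o, 1]; yy <- V[, 2] + offs[o, 2]; xx <- V[, 3] + offs[o, 3]
    ok <- zz >= 1 & zz <= nz & yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    cand <- rep(NA_real_, n)
    cand[ok] <- (xx[ok] - 1) * (nz * ny) + (yy[ok] - 1) * nz + zz[ok]
    nbmat[, o] <- match(cand, lin)
  }
  deg_vox <- rowSums(!is.na(nbmat))
  nbrs <- function(i) sort(nbmat[i, !is.na(nbmat[i, ])])

  kind_vox <- ifelse(deg_vox >= 3L, "junction",
                     ifelse(deg_vox == 2L, "slab",
                            ifelse(deg_vox == 1L, "endpoint", "isolated")))

  # --- nodes: junction clusters (26-connected), endpoints, isolated voxels
  node_of <- integer(n)          # 0 = slab / unassigned
  node_rows <- list()            # member rows per node
  node_kind <- character(0)
  nid <- 0L
  for (i in seq_len(n)) {
    if (node_of[i] != 0L || kind_vox[i] == "slab") next
    nid <- nid + 1L
    if (kind_vox[i] == "junction") {
      members <- i; node_of[i] <- nid
      queue <- i
      while (length(queue)) {
        c0 <- queue[[1]]; queue <- queue[-1]
        for (w in nbrs(c0)) {
          if (kind_vox[w] == "junction" && node_of[w] == 0L) {
            node_of[w] <- nid; members <- c(members, w); queue <- c(queue, w)
          }
        }
      }
      node_rows[[nid]] <- sort(members)
      node_kind[nid] <- "junction"
    } else {
      node_of[i] <- nid
      node_rows[[nid]] <- i
      node_kind[nid] <- kind_vox[i]
    }
  }

  # --- trace slab runs between nodes
  assigned <- logical(n)
  segments <- list()
  direct_seen <- character(0)
  add_seg <- function(from, to, rows) {
    segments[[length(segments) + 1L]] <<-
      list(id = length(segments) + 1L, from = from, to = to,
           path_vox = V[rows, , drop = FALSE])
  }
  node_voxels <- which(node_of != 0L)
  for (v in node_voxels) {
    for (w in nbrs(v)) {
      if (node_of[w] != 0L) {
        if (node_of[w] == node_of[v]) next          # intra-cluster
        key <- paste(min(v, w), max(v, w))
        if (key %in% direct_seen) next
        direct_seen <- c(direct_seen, key)
        add_seg(node_of[v], node_of[w], c(v, w))
      } else if (!assigned[w]) {
        rows <- c(v, w); assigned[w] <- TRUE
        prev <- v; cur <- w
        repeat {
          nxt <- setdiff(nbrs(cur), prev)[1]
          rows <- c(rows, nxt)
          if (node_of[nxt] != 0L) break
          assigned[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
        add_seg(node_of[v], node_of[rows[length(rows)]], rows)
      }
    }
  }

  # --- leftover slab voxels form node-free closed loops
  repeat {
    left <- which(!assigned & node_of == 0L & kind_vox == "slab")
    if (!length(left)) break
    a <- left[1]
    nid <- nid + 1L
    node_of[a] <- nid; node_rows[[nid]] <- a; node_kind[nid] <- "endpoint"
    assigned[a] <- TRUE
    first <- nbrs(a)[1]
    rows <- c(a, first); assigned[first] <- TRUE
    prev <- a; cur <- first
    repeat {
      nxt <- setdiff(nbrs(cur), prev)[1]
      rows <- c(rows, nxt)
      if (nxt == a) break
      assigned[nxt] <- TRUE
      prev <- cur; cur <- nxt
    }
    add_seg(nid, nid, rows)
  }

  cents <- t(vapply(node_rows, function(r) colMeans(V[r, , drop = FALSE]),
                    numeric(3)))
  nodes <- data.frame(id = seq_len(nid), vox_z = cents[, 1], vox_y = cents[, 2],
                      vox_x = cents[, 3], stringsAsFactors = FALSE)
  g <- new_vessel_graph(nodes, segments, skel$voxel_size)
  # isolated single voxels keep their 'endpoint' standing at degree 0
  g
}

# moving-average smoothing of a polyline (odd window, symmetric, shrinking
# at the ends); collinear equally spaced paths are exactly invariant
.smooth_path <- function(p, window) {
  k <- nrow(p)
  if (k < 3L || window < 3L) return(p)
  half <- (min(window, if (k %% 2L) k else k - 1L) - 1L) %/% 2L
  out <- p
  for (i in seq_len(k)) {
    h <- min(half, i - 1L, k - i)
    if (h > 0L) out[i, ] <- colMeans(p[(i - h):(i + h), , drop = FALSE])
  }
  out
}

#' Measure physical segment lengths
#'
#' Node positions become physical centroids; each segment's voxel path is
#' mapped to micrometres, lightly smoothed (moving average, default window 5)
#' to remove the staircase bias of the digitised centerline, and extended to
#' the centroids of its terminal nodes.  The segment length is the sum of the
#' anisotropically scaled Euclidean steps along the resulting polyline, so
#' that summed segment lengths tile the skeleton without double counting.
#' Axis-aligned and perfectly diagonal paths are invariant under the
#' smoothing, so their lengths stay the exact step sums.
#'
#' @param graph a [vessel_graph] from [build_graph()] (or a parsed graph with
#'   point polylines, in which case lengths are recomputed from the points).
#' @param voxel_size micrometres per voxel `(z, y, x)`; defaults to the value
#'   recorded in the graph.
#' @param smooth_window odd moving-average window in voxels; 1 disables
#'   smoothing.
#' @return the graph with `nodes$x/y/z` (um) and per-segment `points` and
#'   `length_um` populated.
#' @export
measure_lengths <- function(graph, voxel_size = NULL, smooth_window = 5L) {
  stopifnot(inherits(graph, "vessel_graph"))
  voxel_size <- voxel_size %||% graph$voxel_size
  to_phys <- function(vox) {
    # vox: (z,y,x) voxel coords (possibly fractional) -> (x,y,z) um
    cbind((vox[, 3] - 0.5) * voxel_size[3],
          (vox[, 2] - 0.5) * voxel_size[2],
          (vox[, 1] - 0.5) * voxel_size[1])
  }
  have_vox <- !is.null(graph$nodes$vox_z)
  if (have_vox) {
    if (is.null(voxel_size)) stop("no voxel size available")
    pc <- to_phys(as.matrix(graph$nodes[, c("vox_z", "vox_y", "vox_x")]))
    graph$nodes$x <- pc[, 1]; graph$nodes$y <- pc[, 2]; graph$nodes$z <- pc[, 3]
  }
  cent <- as.matrix(graph$nodes[, c("x", "y", "z")])
  rownames(cent) <- as.character(graph$nodes$id)
  for (i in seq_along(graph$segments)) {
    s <- graph$segments[[i]]
    if (!is.null(s$path_vox)) {
      k <- nrow(s$path_vox)
      if (k < 1L) stop("segment ", s$id, " has an empty voxel path")
      interior <- if (k > 2L) to_phys(s$path_vox[2:(k - 1L), , drop = FALSE])
                  else matrix(0, 0, 3)
      interior <- .smooth_path(interior, smooth_window)
      pts <- rbind(cent[as.character(s$from), , drop = FALSE],
                   interior,
                   cent[as.character(s$to), , drop = FALSE])
    } else if (!is.null(s$points)) {
      pts <- s$points
    } else stop("segment ", s$id, " has neither a voxel path nor points")
    graph$segments[[i]]$points <- unname(pts)
    graph$segments[[i]]$length_um <- sum(sqrt(rowSums(diff(pts)^2)))
  }
  graph$voxel_size <- voxel_size
  graph
}

#' Measure segment widths from the distance transform
#'
#' The Euclidean distance transform of the vessel mask is computed with
#' physical voxel weighting; the local vessel width at a path voxel is twice
#' its distance to the background.  The segment width is the mean over its
#' interior path voxels after discarding the `junction_exclude` voxels
#' nearest each incident junction, where the distance transform inflates at
#' confluences.
#'
#' @param graph a measured [vessel_graph] whose voxel paths derive from
#'   `mask`.
#' @param mask the source vessel [binary_mask].
#' @param junction_exclude path voxels discarded next to each junction node.
#' @return the graph with per-segment `width_um` and a per-polyline-point
#'   `radius_profile` (um) populated.
#' @export
measure_widths <- function(graph, mask, junction_exclude = 2L) {
  stopifnot(inherits(graph, "vessel_graph"), inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  edt <- cpp_edt(as.logical(mask$data), d, mask$voxel_size)
  kind <- graph$nodes$kind
  names(kind) <- as.character(graph$nodes$id)
  for (i in seq_along(graph$segments)) {
    s <- graph$segments[[i]]
    if (is.null(s$path_vox)) stop("segment ", s$id, " has no voxel path; widths need the source mask geometry")
    pv <- s$path_vox
    lin <- (pv[, 3] - 1) * (d[1] * d[2]) + (pv[, 2] - 1) * d[1] + pv[, 1]
    w_all <- 2 * edt[lin]
    if (any(w_all <= 0)) stop("segment ", s$id, " path exits the vessel mask")
    k <- nrow(pv)
    use <- if (k > 2L) w_all[2:(k - 1L)] else w_all
    vals <- use
    if (k > 2L) {
      j <- junction_exclude
      drop <- integer(0)
      if (kind[as.character(s$from)] == "junction") drop <- c(drop, seq_len(min(j, length(vals))))
      if (kind[as.character(s$to)] == "junction")
        drop <- c(drop, seq(length(vals), by = -1L, length.out = min(j, length(vals))))
      if (length(drop) && length(drop) < length(vals)) vals <- vals[-unique(drop)]
    }
    graph$segments[[i]]$width_um <- mean(vals)
    prof <- if (k > 2L) c(use[1], use, use[length(use)]) / 2 else w_all / 2
    graph$segments[[i]]$radius_profile <- prof
  }
  graph
}

# Dissolve degree-2 nodes by merging their two incident segments: paths are
# concatenated, lengths summed, widths length-weighted.  Self-loop anchors
# (a single segment incident twice) are left alone.
.dissolve_degree2 <- function(nodes, segs) {
  changed <- FALSE
  repeat {
    if (!length(segs)) break
    ends <- cbind(vapply(segs, function(s) s$from, 0L),
                  vapply(segs, function(s) s$to, 0L))
    deg <- tabulate(match(c(ends[, 1], ends[, 2]), nodes$id), nbins = nrow(nodes))
    cand <- nodes$id[deg == 2L]
    done <- TRUE
    for (m in cand) {
      inc <- which(ends[, 1] == m | ends[, 2] == m)
      if (length(inc) != 2L) next  # self-loop at m: keep its anchor
      s1 <- segs[[inc[1]]]; s2 <- segs[[inc[2]]]
      orient <- function(s, at_end) {
        # reverse so that segment runs ...->m (at_end) or m->... (!at_end)
        hit_to <- s$to == m
        if (hit_to != at_end) {
          if (!is.null(s$points))
            s$points <- s$points[rev(seq_len(nrow(s$points))), , drop = FALSE]
          if (!is.null(s$path_vox))
            s$path_vox <- s$path_vox[rev(seq_len(nrow(s$path_vox))), , drop = FALSE]
          if (!is.null(s$radius_profile)) s$radius_profile <- rev(s$radius_profile)
          tmp <- s$from; s$from <- s$to; s$to <- tmp
        }
        s
      }
      s1 <- orient(s1, TRUE); s2 <- orient(s2, FALSE)
      merged <- list(id = s1$id, from = s1$from, to = s2$to,
                     length_um = s1$length_um + s2$length_um)
      if (!is.null(s1$points) && !is.null(s2$points))
        merged$points <- rbind(s1$points, s2$points[-1, , drop = FALSE])
      if (!is.null(s1$path_vox) && !is.null(s2$path_vox))
        merged$path_vox <- rbind(s1$path_vox, s2$path_vox)
      if (!is.null(s1$width_um) && !is.null(s2$width_um))
        merged$width_um <- (s1$width_um * s1$length_um + s2$width_um * s2$length_um) /
          (s1$length_um + s2$length_um)
      if (!is.null(s1$radius_um)) merged$radius_um <- s1$radius_um
      if (!is.null(s1$radius_profile) && !is.null(s2$radius_profile))
        merged$radius_profile <- c(s1$radius_profile, s2$radius_profile[-1])
      segs <- c(segs[-inc], list(merged))
      changed <- TRUE; done <- FALSE
      break
    }
    if (done) break
  }
  list(segs = segs, changed = changed)
}

#' Prune short terminal spurs
#'
#' Thinning leaves short terminal twigs at tube ends and junctions that
#' would inflate the segment and branch-point counts.  Terminal segments
#' (exactly one end of degree 1) shorter than `min_spur_um` are removed
#' iteratively; after each sweep, degree-2 nodes created by the removal are
#' dissolved and their two segments merged (lengths summed, widths
#' length-weighted).  The operation terminates and is idempotent; a
#' threshold of 0 is the identity.
#'
#' @param graph a measured [vessel_graph].
#' @param min_spur_um spur length threshold, micrometres (default 10, one
#'   histogram bin width: anything below the smallest reported vessel class
#'   is treated as a thinning artifact).
#' @return the pruned [vessel_graph].
#' @export
prune_spurs <- function(graph, min_spur_um = 10) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (min_spur_um < 0) stop("`min_spur_um` must be non-negative")
  segs <- graph$segments
  nodes <- graph$nodes
  keep_isolated <- nodes$id[nodes$degree == 0L]
  if (min_spur_um > 0 && length(segs)) {
    repeat {
      ends <- cbind(vapply(segs, function(s) s$from, 0L),
                    vapply(segs, function(s) s$to, 0L))
      deg <- tabulate(match(c(ends[, 1], ends[, 2]), nodes$id), nbins = nrow(nodes))
      names(deg) <- as.character(nodes$id)
      changed <- FALSE
      if (length(segs)) {
        len <- vapply(segs, function(s) s$length_um %||% stop("prune_spurs needs measured lengths"), 0)
        d1 <- deg[as.character(ends[, 1])] == 1L
        d2 <- deg[as.character(ends[, 2])] == 1L
        spur <- xor(d1, d2) & len < min_spur_um & ends[, 1] != ends[, 2]
        if (any(spur)) {
          segs <- segs[!spur]
          changed <- TRUE
          ends <- ends[!spur, , drop = FALSE]
          deg <- tabulate(match(c(ends[, 1], ends[, 2]), nodes$id), nbins = nrow(nodes))
          names(deg) <- as.character(nodes$id)
        }
      }
      dis <- .dissolve_degree2(nodes, segs)
      if (dis$changed) changed <- TRUE
      segs <- dis$segs
      if (!changed) break
    }
  }
  used <- unique(c(vapply(segs, function(s) s$from, 0L),
                   vapply(segs, function(s) s$to, 0L)))
  nodes <- nodes[nodes$id %in% c(used, keep_isolated), , drop = FALSE]
  g <- new_vessel_graph(nodes, segs, graph$voxel_size)
  if (!is.null(graph$networks)) g <- identify_networks(g)
  g
}

#' Merge branch points closer than one vessel diameter
#'
#' At a confluence the union of two tubes forms a webbed throat whose
#' skeleton can split one anatomical branch point into two nearby junction
#' nodes, occasionally joined by a small spurious ring.  Any segment whose
#' two endpoints are both junctions and whose length is below `scale` times
#' the local vessel calibre (the widest segment meeting either endpoint)
#' lies inside that throat: at branch angles of 40 degrees and up the web
#' extends at most about two diameters from the confluence, while real
#' junction separations in a vessel hierarchy sit beyond 2.5 diameters
#' (six radii under moderate taper).  Its end nodes are
#' contracted into one node at their midpoint, and self-loops shorter than
#' the same bound are dropped.  Iterates to a fixed point; degree-2 nodes
#' left behind are dissolved.
#'
#' @param graph a measured [vessel_graph] (lengths and widths populated).
#' @param scale multiple of the local segment width below which a
#'   junction-junction segment is contracted.
#' @return the cleaned [vessel_graph].
#' @export
merge_close_junctions <- function(graph, scale = 2) {
  stopifnot(inherits(graph, "vessel_graph"))
  segs <- graph$segments
  nodes <- graph$nodes
  if (!length(segs)) return(graph)
  if (any(vapply(segs, function(s) is.null(s$width_um) || is.null(s$length_um), TRUE)))
    stop("merge_close_junctions needs measured lengths and widths")
  repeat {
    ends <- cbind(vapply(segs, function(s) s$from, 0L),
                  vapply(segs, function(s) s$to, 0L))
    deg <- tabulate(match(c(ends[, 1], ends[, 2]), nodes$id), nbins = nrow(nodes))
    names(deg) <- as.character(nodes$id)
    len <- vapply(segs, function(s) s$length_um, 0)
    wid <- vapply(segs, function(s) s$width_um, 0)
    # local calibre = widest vessel meeting either endpoint (the throat
    # itself is a thin web, so its own width understates the confluence)
    local_w <- vapply(seq_along(segs), function(k) {
      inc <- ends[, 1] %in% ends[k, ] | ends[, 2] %in% ends[k, ]
      max(wid[inc])
    }, 0)
    short <- len < scale * local_w
    loops <- ends[, 1] == ends[, 2]
    # spurious webbing rings first
    drop <- which(short & loops)
    if (length(drop)) { segs <- segs[-drop]; next }
    jj <- which(short & !loops &
                deg[as.character(ends[, 1])] >= 3L &
                deg[as.character(ends[, 2])] >= 3L)
    if (!length(jj)) break
    k <- jj[1]
    a <- segs[[k]]$from; b <- segs[[k]]$to
    ra <- which(nodes$id == a); rb <- which(nodes$id == b)
    mid <- (as.numeric(nodes[ra, c("x", "y", "z")]) +
            as.numeric(nodes[rb, c("x", "y", "z")])) / 2
    nodes[ra, c("x", "y", "z")] <- as.list(mid)
    if (!is.null(nodes$vox_z))
      nodes[ra, c("vox_z", "vox_y", "vox_x")] <-
        as.list((as.numeric(nodes[rb, c("vox_z", "vox_y", "vox_x")]) +
                 as.numeric(nodes[ra, c("vox_z", "vox_y", "vox_x")])) / 2)
    nodes <- nodes[-rb, , drop = FALSE]
    segs <- segs[-k]
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      touched <- FALSE
      if (s$from %in% c(a, b)) { s$from <- a; s$points[1, ] <- mid; touched <- TRUE }
      if (s$to %in% c(a, b)) { s$to <- a; s$points[nrow(s$points), ] <- mid; touched <- TRUE }
      if (touched) {
        s$length_um <- sum(sqrt(rowSums(diff(s$points)^2)))
        segs[[i]] <- s
      }
    }
  }
  dis <- .dissolve_degree2(nodes, segs)
  segs <- dis$segs
  used <- unique(c(vapply(segs, function(s) s$from, 0L),
                   vapply(segs, function(s) s$to, 0L)))
  keep0 <- graph$nodes$id[graph$nodes$degree == 0L]
  nodes <- nodes[nodes$id %in% c(used, keep0), , drop = FALSE]
  g <- new_vessel_graph(nodes, segs, graph$voxel_size)
  if (!is.null(graph$networks)) g <- identify_networks(g)
  g
}

#' Partition a vessel graph into discrete networks
#'
#' Connected components of the graph, ranked by descending total segment
#' length: rank 1 is the dominant network, mirroring the hierarchy of
#' branching structures within a node's HEV system.  Each segment is
#' labelled with its network rank and per-network totals are tabulated.
#'
#' @param graph a measured (typically pruned) [vessel_graph].
#' @return the graph with `networks` (one row per component with segments:
#'   rank, totals) and per-segment `network` labels.
#' @export
identify_networks <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (!length(graph$segments)) {
    graph$networks <- data.frame(network = integer(0), n_segments = integer(0),
                                 n_branch_points = integer(0), n_endpoints = integer(0),
                                 total_length_um = numeric(0))
    return(graph)
  }
  g <- as_igraph(graph)
  comp <- igraph::components(g)$membership
  segc <- vapply(graph$segments, function(s) comp[[as.character(s$from)]], 0)
  len <- vapply(graph$segments, function(s) s$length_um %||% NA_real_, 0)
  if (anyNA(len)) stop("identify_networks needs measured lengths")
  comps <- sort(unique(segc))
  tot <- vapply(comps, function(cc) sum(len[segc == cc]), 0)
  minid <- vapply(comps, function(cc) min(graph$nodes$id[comp == cc]), 0)
  rank <- order(-tot, minid)
  nets <- data.frame(
    network = seq_along(comps),
    n_segments = vapply(comps[rank], function(cc) sum(segc == cc), 0L),
    n_branch_points = vapply(comps[rank], function(cc)
      sum(graph$nodes$degree >= 3 & comp[as.character(graph$nodes$id)] == cc), 0L),
    n_endpoints = vapply(comps[rank], function(cc)
      sum(graph$nodes$degree == 1 & comp[as.character(graph$nodes$id)] == cc), 0L),
    total_length_um = tot[rank]
  )
  rank_of <- integer(length(comps)); rank_of[rank] <- seq_along(comps)
  names(rank_of) <- as.character(comps)
  for (i in seq_along(graph$segments))
    graph$segments[[i]]$network <- rank_of[[as.character(segc[i])]]
  graph$networks <- nets
  graph
}

#' Per-segment table
#'
#' @param graph a measured [vessel_graph].
#' @return data.frame with one row per segment: id, end nodes, network rank,
#'   length and width (um), polyline point count.
#' @export
segment_table <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (!length(graph$segments))
    return(data.frame(id = integer(0), from = integer(0), to = integer(0),
                      network = integer(0), length_um = numeric(0),
                      width_um = numeric(0), n_points = integer(0)))
  data.frame(
    id = vapply(graph$segments, function(s) s$id, 0L),
    from = vapply(graph$segments, function(s) s$from, 0L),
    to = vapply(graph$segments, function(s) s$to, 0L),
    network = vapply(graph$segments, function(s) s$network %||% NA_integer_, 0L),
    length_um = vapply(graph$segments, function(s) s$length_um %||% NA_real_, 0),
    width_um = vapply(graph$segments, function(s) s$width_um %||% NA_real_, 0),
    n_points = vapply(graph$segments, function(s)
      if (!is.null(s$points)) nrow(s$points) else nrow(s$path_vox), 0L)
  )
}
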