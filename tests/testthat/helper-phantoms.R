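# Shared fixtures: hand-built skeletons, phantom pipelines, and the seeded
# recovery benchmark (computed once, reused by several acceptance checks).

skeleton_from_voxels <- function(vox, shape, voxel_size = c(1, 1, 1)) {
  vox <- matrix(as.integer(vox), ncol = 3, dimnames = list(NULL, c("z", "y", "x")))
  structure(list(voxels = vox, voxel_size = as.numeric(voxel_size),
                 source_shape = as.integer(shape)),
            class = "skeleton")
}

# straight run of n voxels along +x from (z0, y0, x0)
line_voxels <- function(n, z0 = 5, y0 = 5, x0 = 1) {
  cbind(rep(z0, n), rep(y0, n), x0 + seq_len(n) - 1)
}

# three arms (+x, -x, +y) of `arm` voxels meeting at one centre voxel
y_skeleton <- function(arm = 30, c0 = c(5, 40, 40), shape = c(10, 80, 80)) {
  vox <- rbind(
    c0,
    t(vapply(seq_len(arm), function(i) c0 + c(0, 0, i), numeric(3))),
    t(vapply(seq_len(arm), function(i) c0 + c(0, 0, -i), numeric(3))),
    t(vapply(seq_len(arm), function(i) c0 + c(0, i, 0), numeric(3))))
  skeleton_from_voxels(vox, shape)
}

# diamond ring (Manhattan circle) of 4r voxels, every voxel of degree 2
ring_voxels <- function(r = 10, z0 = 3, c0 = c(20, 20)) {
  ks <- 0:(r - 1)
  pts <- rbind(
    cbind(r - ks, ks),          # (r,0) -> (1,r-1)
    cbind(-ks, r - ks),         # (0,r) -> (-(r-1),1)
    cbind(ks - r, -ks),         # (-r,0) -> (-1,-(r-1))
    cbind(ks, ks - r))          # (0,-r) -> (r-1,-1)
  cbind(z0, c0[1] + pts[, 1], c0[2] + pts[, 2])
}

# standard pipeline on a noiseless phantom (threshold at the midpoint)
phantom_pipeline <- function(ph, spur = 10, min_component = 27) {
  thr <- (ph$truth$vessel_level + ph$truth$background_level) / 2
  mask <- clean_mask(binarize(ph$volume, "fixed", thr), min_component)
  g <- build_graph(skeletonize(mask))
  g <- measure_lengths(g)
  g <- measure_widths(g, mask)
  g <- merge_close_junctions(prune_spurs(g, spur))
  list(graph = identify_networks(g), mask = mask)
}

total_truth_length <- function(truth)
  sum(vapply(truth$graph$segments, function(s) s$length_um, 0))

# consistency of the graph's own bookkeeping with an independent traversal:
# degrees sum to twice the segment count, endpoints are node ids, and the
# Euler relation #nodes - #segments = #components - #cycles holds with the
# component count recomputed by BFS over the segment list (self-loops and
# isolated nodes included)
expect_euler <- function(graph) {
  n <- nrow(graph$nodes); m <- length(graph$segments)
  ends <- if (m) cbind(vapply(graph$segments, function(s) s$from, 0L),
                       vapply(graph$segments, function(s) s$to, 0L))
          else matrix(0L, 0, 2)
  expect_true(all(ends %in% graph$nodes$id))
  expect_identical(sum(graph$nodes$degree), 2L * m)
  adj <- lapply(seq_len(n), function(i) integer(0))
  id2row <- match(seq_len(max(c(graph$nodes$id, 1L))), graph$nodes$id)
  for (k in seq_len(m)) {
    a <- id2row[ends[k, 1]]; b <- id2row[ends[k, 2]]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); comps <- 0L
  for (i in seq_len(n)) {
    if (seen[i]) next
    comps <- comps + 1L
    q <- i; seen[i] <- TRUE
    while (length(q)) {
      cur <- q[[1]]; q <- q[-1]
      for (w in adj[[cur]]) if (!seen[w]) { seen[w] <- TRUE; q <- c(q, w) }
    }
  }
  expect_identical(n - m, comps - cycle_count(graph))
  invisible(graph)
}

# seeded recovery benchmark: 50 procedural phantoms at 128^3, radii 2-5
# voxels, junction separation >= 6r, noiseless (the generator's stated
# world).  Heavier than the unit fixtures, so computed once and shared.
.acc_env <- new.env(parent = emptyenv())
acceptance_suite <- function() {
  if (!is.null(.acc_env$suite)) return(.acc_env$suite)
  t0 <- Sys.time()
  runs <- lapply(1:50, function(s) {
    ph <- generate_phantom(phantom_spec(seed = s, max_segments = 5 + (s %% 26)))
    res <- phantom_pipeline(ph)
    list(truth = ph$truth, graph = res$graph, seed = s)
  })
  .acc_env$suite <- list(runs = runs,
                         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  .acc_env$suite
}
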