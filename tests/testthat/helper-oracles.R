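# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately brute-force / plainly coded so it cannot
# share a defect with the implementation under test.

# rasterize an axis-rotated ellipse on a pixel grid by centre-of-pixel
# inclusion; returns integer (i, j) index matrix
raster_ellipse <- function(a, b, theta_deg = 0, spacing = c(1, 1),
                           jitter = 0, pad = 3) {
  r <- max(a, b)
  n1 <- ceiling((2 * r) / spacing[1]) + 2 * pad
  n2 <- ceiling((2 * r) / spacing[2]) + 2 * pad
  center <- c(n1 / 2 * spacing[1], n2 / 2 * spacing[2]) +
    runif(2, -jitter, jitter)
  th <- theta_deg * pi / 180
  g <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  x <- (g$i - 0.5) * spacing[1] - center[1]
  y <- (g$j - 0.5) * spacing[2] - center[2]
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  as.matrix(g[inside, c("i", "j")])
}

# brute-force Feret diameter: max pairwise distance over ALL pixel corner
# points (no convex hull involved)
brute_force_long_axis <- function(pixels, spacing) {
  i <- pixels[, 1]; j <- pixels[, 2]
  pts <- unique(rbind(cbind(i - 1L, j - 1L), cbind(i, j - 1L),
                      cbind(i - 1L, j), cbind(i, j)))
  pts <- cbind(pts[, 1] * spacing[1], pts[, 2] * spacing[2])
  max(dist(pts))
}

# exhaustive optimal one-to-one assignment by total distance, small n only
brute_force_assignment <- function(da, db, max_dist) {
  na <- nrow(da); nb <- nrow(db)
  dmat <- as.matrix(dist(rbind(da, db)))[seq_len(na), na + seq_len(nb),
                                         drop = FALSE]
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  k <- min(na, nb)
  best <- NULL; best_cost <- Inf
  for (rows in utils::combn(na, k, simplify = FALSE))
    for (cols in perms(seq_len(nb))) {
      cols <- cols[seq_len(k)]
      d <- dmat[cbind(rows, cols)]
      if (any(d > max_dist)) next
      cost <- sum(d)
      if (cost < best_cost) {
        best_cost <- cost
        best <- data.frame(a = rows, b = cols)
      }
    }
  best
}

# independently coded CR/PR/SD/PD truth table for target lesions
oracle_target_call <- function(node_shorts_now, baseline_sum, nadir_sum,
                               path_mm = 10, pr_pct = 30, pd_pct = 20,
                               pd_abs = 5) {
  current <- sum(node_shorts_now)
  if (max(node_shorts_now) < path_mm) return("CR")
  growth <- current - nadir_sum
  if (growth >= pd_pct / 100 * nadir_sum && growth >= pd_abs) return("PD")
  if (baseline_sum - current >= pr_pct / 100 * baseline_sum) return("PR")
  "SD"
}

# build a 3-timepoint single-patient series directly from short diameters;
# shorts_by_tp: list of numeric vectors named by node id (names shared
# across timepoints mean "same node"; a node absent from a follow-up
# vector has disappeared; extra names at follow-up are new nodes)
series_from_shorts <- function(shorts_by_tp, patient_id = "p1") {
  tps <- lapply(seq_along(shorts_by_tp), function(t) {
    s <- shorts_by_tp[[t]]
    ids <- as.integer(names(s))
    data.frame(source_id = rep(patient_id, length(ids)), node_id = ids,
               short_mm = as.numeric(s), long_mm = as.numeric(s) + 2,
               slice = rep(1L, length(ids)), volume_mm3 = rep(100, length(ids)),
               centroid_x = ids * 50, centroid_y = rep(0, length(ids)),
               centroid_z = rep(0, length(ids)), stringsAsFactors = FALSE)
  })
  base_ids <- as.integer(names(shorts_by_tp[[1]]))
  links <- do.call(rbind, lapply(seq_along(tps)[-1], function(t) {
    shared <- intersect(base_ids, as.integer(names(shorts_by_tp[[t]])))
    if (!length(shared)) return(NULL)
    data.frame(timepoint_a = 1L, node_a = shared,
               timepoint_b = t, node_b = shared)
  }))
  if (is.null(links))
    links <- data.frame(timepoint_a = integer(), node_a = integer(),
                        timepoint_b = integer(), node_b = integer())
  matched_series(patient_id, tps, links)
}

# small two-node phantom reused by several files
two_node_phantom <- function(shape = c(96, 96, 24), spacing = c(1.75, 1.75, 4)) {
  phantom_spec(list(
    list(center_mm = c(50, 50, 48), semi_axes_mm = c(10, 8, 8)),
    list(center_mm = c(120, 120, 48), semi_axes_mm = c(7, 6, 7))),
    shape = shape, spacing = spacing)
}

random_mask_pair <- function(dim3 = c(12, 12, 6), p = 0.3) {
  list(array(runif(prod(dim3)) < p, dim3),
       array(runif(prod(dim3)) < p, dim3))
}
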