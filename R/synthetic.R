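#' Phantom specification for a label volume of ellipsoidal nodes
#'
#' Describes a grid with DWI-like geometry and a set of ellipsoidal
#' nodes with known axes. Defaults emulate an axial diffusion-weighted
#' pelvic acquisition: anisotropic voxels with ~1.75 mm in-plane
#' resolution and 4 mm slice thickness on a 256 x 256 x 24 grid — large
#' enough for realistic node counts, small enough for seconds-scale
#' tests.
#'
#' @param nodes list of nodes, each a list with `center_mm` (physical
#'   coordinates, length 3), `semi_axes_mm` (a, b, c: in-plane long,
#'   in-plane short, through-plane semi-axes) and optional
#'   `rotation_deg` (in-plane rotation).
#' @param shape grid dimension, default `c(256, 256, 24)`.
#' @param spacing voxel size mm, default `c(1.75, 1.75, 4)`.
#' @param source_id provenance tag for the rasterized volume.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(nodes = list(), shape = c(256, 256, 24),
                         spacing = c(1.75, 1.75, 4), source_id = "phantom") {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape > 0),
            length(spacing) == 3L, all(spacing > 0))
  extent <- shape * spacing
  for (k in seq_along(nodes)) {
    nd <- nodes[[k]]
    stopifnot(length(nd$center_mm) == 3L, length(nd$semi_axes_mm) == 3L)
    if (any(nd$semi_axes_mm <= 0))
      stop(sprintf("node %d: semi-axes must be positive", k), call. = FALSE)
    r <- c(max(nd$semi_axes_mm[1:2]), max(nd$semi_axes_mm[1:2]),
           nd$semi_axes_mm[3])
    if (any(nd$center_mm - r < 0) || any(nd$center_mm + r > extent))
      stop(sprintf("node %d does not fit inside the grid", k), call. = FALSE)
    if (is.null(nd$rotation_deg)) nodes[[k]]$rotation_deg <- 0
  }
  structure(list(nodes = nodes, shape = shape, spacing = spacing,
                 source_id = source_id),
            class = "phantom_spec")
}

#' Rasterize a phantom into a label volume
#'
#' Each ellipsoid is rasterized by a centre-of-voxel inclusion test in
#' physical coordinates (no partial-volume modelling, so the ground
#' truth is unambiguous); node k receives label k in spec order.
#' Overlapping ellipsoids are an error because overlapping instances
#' would make the ground truth ill-defined.
#'
#' @param spec a [phantom_spec()].
#' @return A [label_volume()].
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vox <- array(0L, spec$shape)
  sp <- spec$spacing
  for (k in seq_along(spec$nodes)) {
    nd <- spec$nodes[[k]]
    ctr <- nd$center_mm; ax <- nd$semi_axes_mm
    th <- nd$rotation_deg * pi / 180
    r_ip <- max(ax[1:2])
    ## bounding index box (voxel centres at (i - 0.5) * spacing)
    lo <- pmax(1L, ceiling((ctr - c(r_ip, r_ip, ax[3])) / sp + 0.5) - 1L)
    hi <- pmin(spec$shape, floor((ctr + c(r_ip, r_ip, ax[3])) / sp + 0.5) + 1L)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    x <- (ii - 0.5) * sp[1] - ctr[1]
    y <- (jj - 0.5) * sp[2] - ctr[2]
    z <- (kk - 0.5) * sp[3] - ctr[3]
    g <- expand.grid(x = x, y = y, z = z)
    xr <- g$x * cos(th) + g$y * sin(th)
    yr <- -g$x * sin(th) + g$y * cos(th)
    inside <- (xr / ax[1])^2 + (yr / ax[2])^2 + (g$z / ax[3])^2 <= 1
    if (any(inside)) {
      sub <- vox[ii, jj, kk]
      if (any(sub[inside] != 0L))
        stop(sprintf("node %d overlaps an earlier node", k), call. = FALSE)
      sub[inside] <- k
      vox[ii, jj, kk] <- sub
    }
  }
  label_volume(vox, spacing = sp, source_id = spec$source_id)
}

#' Trajectory specification for a longitudinal phantom series
#'
#' Describes how each baseline node evolves over the follow-up
#' timepoints, plus node appearance/disappearance events. Size factors
#' are absolute multipliers of the baseline semi-axes (factor 0.6 at t2
#' means 60 % of baseline size at t2, regardless of t1).
#'
#' @param factors numeric matrix, baseline nodes in rows, follow-up
#'   timepoints in columns; a factor of exactly 0 marks the node as
#'   absent (not visible) at that timepoint.
#' @param new_nodes optional list of events, each a list with
#'   `timepoint` (follow-up column index at which the node first
#'   appears; it persists afterwards) and `node` (a phantom node spec as
#'   in [phantom_spec()]).
#' @return List of class `trajectory_spec`.
#' @export
trajectory_spec <- function(factors, new_nodes = list()) {
  factors <- as.matrix(factors)
  if (any(factors < 0))
    stop("size factors must be >= 0 (0 = disappeared)", call. = FALSE)
  for (ev in new_nodes)
    stopifnot(ev$timepoint >= 1L, !is.null(ev$node))
  structure(list(factors = factors, new_nodes = new_nodes),
            class = "trajectory_spec")
}

## Independent truth arithmetic: intended response calls from intended
## short diameters. Deliberately plain re-statements of the thresholds,
## kept separate from the rules engine so end-to-end tests have an
## oracle that shares only the response_rules() numbers with it.
truth_calls <- function(base_short, short_by_tp, new_short_by_tp, rules) {
  categ <- classify_short(base_short, rules)
  tgt <- which(categ == "target")
  nt <- which(categ == "nontarget")
  np <- which(categ == "nonpathological")
  n_tp <- ncol(short_by_tp)
  out <- list()
  sums <- if (length(tgt)) sum(base_short[tgt]) else NA_real_
  for (t in seq_len(n_tp)) {
    cur <- short_by_tp[, t]
    new_path <- sum(new_short_by_tp[[t]] >= rules$pathological_mm)
    tgt_call <- if (!length(tgt)) "not-evaluable" else {
      s_t <- sum(cur[tgt]); nadir <- min(sums); b <- sum(base_short[tgt])
      if (max(cur[tgt]) < rules$pathological_mm) "CR"
      else if (s_t - nadir >= rules$pd_percent / 100 * nadir &&
               s_t - nadir >= rules$pd_absolute_mm) "PD"
      else if (b - s_t >= rules$pr_percent / 100 * b) "PR"
      else "SD"
    }
    if (length(tgt)) sums <- c(sums, sum(cur[tgt]))
    nt_call <- if (!length(nt)) "not-evaluable" else {
      grow <- cur[nt] - base_short[nt]
      if (new_path > 0 ||
          any(cur[nt] >= rules$target_mm &
              grow >= rules$pd_percent / 100 * base_short[nt] &
              grow >= rules$pd_absolute_mm)) "PD"
      else if (max(cur[nt]) < rules$pathological_mm) "CR"
      else "SD"
    }
    np_call <- if (!length(np)) "not-evaluable"
      else if (max(cur[np]) >= rules$pathological_mm) "PD" else "SD"
    out[[t]] <- data.frame(
      timepoint = paste0("followup", t),
      category = c("target", "nontarget", "nonpathological"),
      call = c(tgt_call, nt_call, np_call), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a longitudinal label-volume series with known truth
#'
#' Emits one rasterized volume per timepoint (baseline plus one per
#' trajectory column) and the intended per-category response calls,
#' computed by plain threshold arithmetic on the intended diameters —
#' independent of the rules engine, so the truth table can serve as an
#' end-to-end oracle.
#'
#' @param spec baseline [phantom_spec()].
#' @param traj a [trajectory_spec()] with one row per baseline node.
#' @return List with `volumes` (list of [label_volume()], baseline
#'   first), `truth` (data frame `timepoint`, `category`, `call`) and
#'   `intended` (matrix of intended short diameters, nodes x timepoints,
#'   baseline in column 1).
#' @export
simulate_series <- function(spec, traj) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(traj, "trajectory_spec"))
  n_nodes <- length(spec$nodes)
  if (nrow(traj$factors) != n_nodes)
    stop("trajectory has ", nrow(traj$factors), " rows for ",
         n_nodes, " baseline nodes", call. = FALSE)
  n_tp <- ncol(traj$factors)
  min_ax <- min(spec$spacing)
  base_short <- vapply(spec$nodes, function(nd)
    2 * min(nd$semi_axes_mm[1:2]), numeric(1))
  volumes <- vector("list", n_tp + 1L)
  volumes[[1]] <- rasterize_phantom(spec)
  volumes[[1]]$source_id <- paste0(spec$source_id, "_baseline")
  short_by_tp <- matrix(0, n_nodes, n_tp)
  new_short_by_tp <- vector("list", n_tp)
  for (t in seq_len(n_tp)) {
    nodes_t <- list()
    for (i in seq_len(n_nodes)) {
      f <- traj$factors[i, t]
      if (f == 0) next
      nd <- spec$nodes[[i]]
      if (min(nd$semi_axes_mm) * f < min_ax / 2)
        stop(sprintf(
          "node %d shrinks below one voxel at timepoint %d without a declared disappearance",
          i, t), call. = FALSE)
      nd$semi_axes_mm <- nd$semi_axes_mm * f
      nodes_t[[length(nodes_t) + 1L]] <- nd
      short_by_tp[i, t] <- base_short[i] * f
    }
    new_short <- numeric(0)
    for (ev in traj$new_nodes) if (ev$timepoint <= t) {
      nodes_t[[length(nodes_t) + 1L]] <- ev$node
      ## still "new" relative to baseline at every later timepoint
      new_short <- c(new_short, 2 * min(ev$node$semi_axes_mm[1:2]))
    }
    new_short_by_tp[[t]] <- new_short
    sp_t <- phantom_spec(nodes_t, shape = spec$shape, spacing = spec$spacing,
                         source_id = paste0(spec$source_id, "_followup", t))
    volumes[[t + 1L]] <- rasterize_phantom(sp_t)
  }
  truth <- truth_calls(base_short, short_by_tp, new_short_by_tp,
                       response_rules())
  list(volumes = volumes, truth = truth,
       intended = cbind(baseline = base_short, short_by_tp))
}

## restore the caller's RNG state on exit; seed scoped to this call
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

## shift a 3D logical array by one voxel along an axis, zero-filled
shift3 <- function(mask, axis, dir) {
  d <- dim(mask)
  out <- array(FALSE, d)
  idx_src <- lapply(d, seq_len); idx_dst <- idx_src
  if (dir > 0) { idx_dst[[axis]] <- 2:d[axis]; idx_src[[axis]] <- 1:(d[axis] - 1L) }
  else { idx_dst[[axis]] <- 1:(d[axis] - 1L); idx_src[[axis]] <- 2:d[axis] }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

dilate1 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (dr in c(-1, 1)) out <- out | shift3(mask, ax, dr)
  out
}

erode1 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (dr in c(-1, 1)) out <- out & shift3(mask, ax, dr)
  out
}

#' Random boundary perturbation of a label volume
#'
#' Stand-in for the disagreement between two segmentation sources: each
#' node is independently eroded or dilated by a random number of
#' one-voxel morphological steps (6-connectivity cross), drawn as
#' `round(rnorm(1, 0, boundary_sd_voxels))`. Label identities are
#' preserved; dilation never overwrites other nodes; a node annihilated
#' by erosion is dropped with a warning. Expected Dice overlap with the
#' original decreases as `boundary_sd_voxels` grows; output is
#' deterministic per seed and the caller's RNG state is left untouched.
#'
#' @param volume a [label_volume()].
#' @param boundary_sd_voxels SD of the per-node boundary shift in voxel
#'   steps; 0 returns the volume unchanged.
#' @param seed integer seed.
#' @return A perturbed [label_volume()].
#' @export
perturb_mask <- function(volume, boundary_sd_voxels, seed) {
  stopifnot(inherits(volume, "label_volume"), boundary_sd_voxels >= 0)
  if (boundary_sd_voxels == 0) return(volume)
  labs <- sort(unique(volume$voxels[volume$voxels > 0L]))
  with_local_seed(seed, {
    shifts <- round(rnorm(length(labs), 0, boundary_sd_voxels))
    out <- array(0L, dim(volume$voxels))
    occupied <- volume$voxels > 0L
    for (idx in seq_along(labs)) {
      l <- labs[idx]
      mask <- volume$voxels == l
      k <- shifts[idx]
      if (k > 0) {
        free <- !(occupied & !mask)   # may grow into background only
        for (s in seq_len(k)) mask <- dilate1(mask) & free
      } else if (k < 0) {
        for (s in seq_len(-k)) mask <- erode1(mask)
      }
      if (!any(mask)) {
        warning(sprintf("perturbation annihilated node %d; node dropped", l),
                call. = FALSE)
        next
      }
      out[mask] <- l
    }
    label_volume(out, spacing = volume$spacing,
                 axial_axis = volume$axial_axis,
                 source_id = paste0(volume$source_id, "_perturbed"))
  })
}

#' Simulate a multi-patient cohort with known response trajectories
#'
#' Generates a cohort of longitudinal phantom series for pipeline
#' validation. Each patient receives 1-2 target nodes (baseline short
#' diameter 26 or 30 mm), 1-2 nontarget nodes (12.5 mm, the centre of
#' the nontarget band) and 1-2 nonpathological nodes (6 mm), placed at
#' mutually distant centres, and a random trajectory per follow-up drawn
#' from size factors chosen so that every intended diameter and sum
#' change stays clear of the classification and response thresholds by
#' at least the measurement-error budget of the corner-hull convention
#' (about one in-plane pixel diagonal per node): targets 0 = nodes
#' vanish (the complete-response regime), 0.5 = partial response,
#' 1.0 = stable, 1.5 = progression; nontargets 0.55, 1.0, 1.9;
#' nonpathological 1.0 or 2.2. Through-plane semi-axes are kept at
#' >= 2.4 slice thicknesses so equatorial slice sampling shaves well
#' under half a millimetre off the in-plane section. Some patients
#' additionally sprout a new 12.5 mm pathological node (nontarget
#' progression).
#'
#' @param n_patients number of patients.
#' @param seed integer seed; the cohort is reproducible given the seed.
#' @param n_timepoints_range min/max number of follow-up timepoints per
#'   patient, default 1 to 3 (i.e. 2-4 scans per patient).
#' @param shape,spacing grid geometry, defaults as in [phantom_spec()].
#' @return List of patients, each with `patient_id`, `spec`, `traj`, and
#'   the [simulate_series()] output (`volumes`, `truth`, `intended`).
#' @export
simulate_cohort <- function(n_patients, seed,
                            n_timepoints_range = c(1, 3),
                            shape = c(256, 256, 24),
                            spacing = c(1.75, 1.75, 4)) {
  with_local_seed(seed, {
    lapply(seq_len(n_patients), function(p) {
      n_tgt <- sample(1:2, 1); n_nt <- sample(1:2, 1); n_np <- sample(1:2, 1)
      shorts <- c(sample(c(26, 30), n_tgt, replace = TRUE),
                  rep(12.5, n_nt), rep(6, n_np))
      n_nodes <- length(shorts)
      extent <- shape * spacing
      ## well-separated centres on a jittered grid, away from the border
      slots <- as.matrix(expand.grid(
        x = seq(60, extent[1] - 60, length.out = 3),
        y = seq(60, extent[2] - 60, length.out = 3)))
      slots <- slots[sample(nrow(slots), n_nodes + 1L), , drop = FALSE]
      zc <- extent[3] / 2
      nodes <- lapply(seq_len(n_nodes), function(i) {
        b <- shorts[i] / 2
        ## pathological nodes get the full through-plane extent (their
        ## trajectories skirt thresholds); small nodes stay ovoid
        cz <- max(b, if (shorts[i] >= 10) 2.4 * spacing[3] else 6.5)
        list(center_mm = c(slots[i, 1] + runif(1, -3, 3),
                           slots[i, 2] + runif(1, -3, 3),
                           zc + runif(1, -2, 2)),
             semi_axes_mm = c(b * runif(1, 1.15, 1.4), b, cz),
             rotation_deg = runif(1, 0, 180))
      })
      spec <- phantom_spec(nodes, shape = shape, spacing = spacing,
                           source_id = sprintf("patient%02d", p))
      n_tp <- sample(seq(n_timepoints_range[1], n_timepoints_range[2]), 1)
      f_tgt <- sample(c(0, 0.5, 1.0, 1.5), n_tp, replace = TRUE)
      f_nt <- sample(c(0.55, 1.0, 1.9), n_tp, replace = TRUE)
      f_np <- sample(c(1.0, 2.2), n_tp, replace = TRUE,
                     prob = c(0.8, 0.2))
      factors <- rbind(
        matrix(rep(f_tgt, each = n_tgt), n_tgt),
        matrix(rep(f_nt, each = n_nt), n_nt),
        matrix(rep(f_np, each = n_np), n_np))
      new_nodes <- list()
      if (runif(1) < 0.25) {
        b <- 12.5 / 2
        new_nodes <- list(list(
          timepoint = sample(n_tp, 1),
          node = list(center_mm = c(slots[n_nodes + 1L, 1],
                                    slots[n_nodes + 1L, 2], zc),
                      semi_axes_mm = c(b * 1.25, b, max(b, 2.4 * spacing[3])),
                      rotation_deg = runif(1, 0, 180))))
      }
      traj <- trajectory_spec(factors, new_nodes)
      sim <- simulate_series(spec, traj)
      c(list(patient_id = spec$source_id, spec = spec, traj = traj), sim)
    })
  })
}
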