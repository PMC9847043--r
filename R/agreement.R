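#' Dice similarity coefficient and volumetric similarity of two masks
#'
#' DSC = 2|A&B| / (|A|+|B|) measures voxelwise overlap; VS =
#' 1 - ||A|-|B|| / (|A|+|B|) compares volumes only. DSC <= VS always,
#' since 2 min(|A|,|B|) >= 2|A&B|. Two empty masks are defined as
#' perfectly agreeing (DSC = VS = 1) with a degenerate flag, so loops
#' over true-negative cases do not crash.
#'
#' @param a,b [label_volume()]s (foreground = any positive label),
#'   logical/integer arrays of identical shape, or vectors of voxel
#'   linear indices (then `n_total` is not needed; any numeric vectors
#'   are treated as index sets).
#' @param spacing optional voxel spacing (mm) used to report physical
#'   volumes; taken from the inputs when they are label volumes.
#' @param subgroup optional label carried through to reports.
#' @return List of class `overlap_result`: `dsc`, `vs`,
#'   `volumes` (named `a`, `b`; mm3 when spacing known, else voxels),
#'   `degenerate`, `subgroup`.
#' @examples
#' m1 <- array(FALSE, c(4, 4, 2)); m1[1:2, 1:2, 1] <- TRUE
#' dice_vs(m1, m1)$dsc  # 1
#' @export
dice_vs <- function(a, b, spacing = NULL, subgroup = NA_character_) {
  if (inherits(a, "label_volume")) { spacing <- a$spacing; a <- a$voxels > 0L }
  if (inherits(b, "label_volume")) {
    if (is.null(spacing)) spacing <- b$spacing
    b <- b$voxels > 0L
  }
  if (is.array(a) && is.array(b)) {
    if (!identical(dim(a), dim(b)))
      stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
           paste(dim(b), collapse = "x"), call. = FALSE)
    na <- sum(a > 0); nb <- sum(b > 0); ni <- sum(a > 0 & b > 0)
  } else {
    a <- unique(as.integer(a)); b <- unique(as.integer(b))
    na <- length(a); nb <- length(b); ni <- length(intersect(a, b))
  }
  degenerate <- (na + nb) == 0L
  dsc <- if (degenerate) 1 else 2 * ni / (na + nb)
  vs <- if (degenerate) 1 else 1 - abs(na - nb) / (na + nb)
  vol_unit <- if (is.null(spacing)) 1 else prod(spacing)
  structure(list(dsc = dsc, vs = vs,
                 volumes = c(a = na * vol_unit, b = nb * vol_unit),
                 degenerate = degenerate, subgroup = subgroup),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: DSC %.4f, VS %.4f%s\n", x$dsc, x$vs,
              if (x$degenerate) " (both masks empty)" else ""))
  invisible(x)
}

#' Per-node overlap between two segmentations of the same grid
#'
#' Pairs nodes from two sources (e.g. automated vs manually corrected
#' segmentation) greedily by descending voxel overlap, then scores each
#' pair with [dice_vs()]. Unpaired nodes on either side are reported
#' against an empty counterpart (DSC 0), so misses and false positives
#' count in subgroup means. Each row is tagged with the reference node's
#' size category when `ref_measurements` is supplied, enabling
#' per-category mean +/- SD summaries.
#'
#' @param auto,ref lists of `node_object`s from [extract_nodes()], both
#'   from the same grid.
#' @param grid_dim dimension of the common grid (needed to form linear
#'   indices).
#' @param spacing optional voxel spacing for physical volumes.
#' @param ref_measurements optional measurement table for the reference
#'   nodes (from [measure_nodes()]) supplying `node_id` and `category`.
#' @return Data frame with one row per pair or unpaired node:
#'   `auto_id`, `ref_id`, `overlap_voxels`, `dsc`, `vs`, `category`.
#' @export
per_node_overlap <- function(auto, ref, grid_dim, spacing = NULL,
                             ref_measurements = NULL) {
  lin <- function(n) as.integer(
    n$voxel_idx[, 1] +
    (n$voxel_idx[, 2] - 1L) * grid_dim[1] +
    (n$voxel_idx[, 3] - 1L) * grid_dim[1] * grid_dim[2])
  ia <- lapply(auto, lin); ib <- lapply(ref, lin)
  na <- length(auto); nb <- length(ref)
  ov <- matrix(0L, nrow = max(na, 1L), ncol = max(nb, 1L))
  if (na && nb)
    for (i in seq_len(na)) for (j in seq_len(nb))
      ov[i, j] <- length(intersect(ia[[i]], ib[[j]]))
  rows <- list()
  used_a <- logical(na); used_b <- logical(nb)
  if (na && nb) {
    ord <- order(-ov)
    for (pos in ord) {
      if (ov[pos] == 0L) break
      i <- (pos - 1L) %% nrow(ov) + 1L
      j <- (pos - 1L) %/% nrow(ov) + 1L
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      res <- dice_vs(ia[[i]], ib[[j]], spacing = spacing)
      rows[[length(rows) + 1L]] <- data.frame(
        auto_id = auto[[i]]$node_id, ref_id = ref[[j]]$node_id,
        overlap_voxels = ov[i, j], dsc = res$dsc, vs = res$vs)
    }
  }
  for (j in seq_len(nb)[!used_b]) rows[[length(rows) + 1L]] <- data.frame(
    auto_id = NA_integer_, ref_id = ref[[j]]$node_id,
    overlap_voxels = 0L, dsc = 0, vs = 0)
  for (i in seq_len(na)[!used_a]) rows[[length(rows) + 1L]] <- data.frame(
    auto_id = auto[[i]]$node_id, ref_id = NA_integer_,
    overlap_voxels = 0L, dsc = 0, vs = 0)
  if (!length(rows))
    return(data.frame(auto_id = integer(), ref_id = integer(),
                      overlap_voxels = integer(), dsc = numeric(),
                      vs = numeric(), category = character()))
  out <- do.call(rbind, rows)
  out$category <- if (!is.null(ref_measurements))
    ref_measurements$category[match(out$ref_id, ref_measurements$node_id)]
  else NA_character_
  out[order(is.na(out$ref_id), out$ref_id, out$auto_id), , drop = FALSE]
}

#' Bland-Altman analysis of paired diameter measurements
#'
#' Works on the percent measurement difference, which is robust to the
#' size composition of the sample: for a pair (a, b) the difference is
#' 100 (a - b) / ((a + b) / 2), i.e. automated minus reference relative
#' to the pair mean. Reports the mean difference (bias), its sample SD,
#' the 95 % limits of agreement (mean +/- 1.96 SD) and the fraction of
#' pairs falling inside them.
#'
#' @param a,b numeric vectors of paired positive measurements (mm), e.g.
#'   short diameters from two segmentation sources.
#' @return List of class `bland_altman_result`: `mean_percent_diff`,
#'   `sd_percent_diff`, `loa_low`, `loa_high`, `fraction_within_loa`,
#'   `n`, and `pairs` (data frame `mean_mm`, `percent_diff`).
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L)
    stop("Bland-Altman analysis needs at least 2 pairs", call. = FALSE)
  if (any(a <= 0) || any(b <= 0))
    stop("Bland-Altman percent differences need positive values",
         call. = FALSE)
  m <- (a + b) / 2
  pd <- 100 * (a - b) / m
  mu <- mean(pd); s <- sd(pd)
  loa <- c(mu - 1.96 * s, mu + 1.96 * s)
  structure(list(mean_percent_diff = mu, sd_percent_diff = s,
                 loa_low = loa[1], loa_high = loa[2],
                 fraction_within_loa = mean(pd >= loa[1] & pd <= loa[2]),
                 n = length(a),
                 pairs = data.frame(mean_mm = m, percent_diff = pd)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (%% diff, n = %d): bias %.2f, SD %.2f, LOA [%.2f, %.2f], %.0f%% within\n",
    x$n, x$mean_percent_diff, x$sd_percent_diff, x$loa_low, x$loa_high,
    100 * x$fraction_within_loa))
  invisible(x)
}

#' Cohen's kappa and accuracy for paired response calls
#'
#' Unweighted Cohen's kappa over the fixed category order CR, PR, SD, PD
#' (categories absent from the data are kept in the confusion matrix with
#' zero counts; categories observed outside the alphabet are appended).
#' The 95 % CI uses the standard large-sample standard error
#' (Fleiss, Cohen & Everitt), clipped to [-1, 1]. Accuracy is the
#' diagonal fraction of the confusion matrix with a Clopper-Pearson
#' exact 95 % CI. When both raters use one single category throughout,
#' chance agreement is 1 and kappa is undefined; it is reported as 1
#' for perfect observed agreement (and NA otherwise) with a degenerate
#' flag.
#'
#' @param calls_a,calls_b equal-length character vectors of response
#'   calls from two sources.
#' @param levels category alphabet and display order.
#' @return List of class `consistency_result`: `kappa`, `se`, `ci95`,
#'   `confusion` (calls_a in rows, calls_b in columns), `accuracy`,
#'   `accuracy_ci95`, `n`, `degenerate`.
#' @examples
#' cohen_kappa(rep(c("CR", "PD"), c(20, 5)), rep(c("CR", "PD"), c(18, 7)))
#' @export
cohen_kappa <- function(calls_a, calls_b,
                        levels = c("CR", "PR", "SD", "PD")) {
  if (length(calls_a) != length(calls_b))
    stop("call lists differ in length", call. = FALSE)
  n <- length(calls_a)
  if (!n) stop("empty call lists", call. = FALSE)
  levels <- union(levels, unique(c(calls_a, calls_b)))
  fa <- factor(calls_a, levels = levels)
  fb <- factor(calls_b, levels = levels)
  conf <- table(a = fa, b = fb)
  p <- conf / n
  po <- sum(diag(p))
  row_m <- rowSums(p); col_m <- colSums(p)
  pe <- sum(row_m * col_m)
  degenerate <- pe >= 1 - 1e-12
  if (degenerate) {
    kap <- if (po >= 1 - 1e-12) 1 else NA_real_
    se <- 0
  } else {
    kap <- (po - pe) / (1 - pe)
    ## Fleiss-Cohen-Everitt asymptotic variance of kappa-hat
    k <- length(levels)
    A <- sum(diag(p) * (1 - (row_m + col_m) * (1 - kap))^2)
    off <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
      off[i, j] <- p[i, j] * (col_m[i] + row_m[j])^2
    B <- (1 - kap)^2 * sum(off)
    C <- (kap - pe * (1 - kap))^2
    se <- sqrt(max(A + B - C, 0) / (n * (1 - pe)^2))
  }
  ci <- pmin(1, pmax(-1, kap + c(-1.96, 1.96) * se))
  acc <- sum(diag(conf)) / n
  acc_ci <- as.numeric(binom.test(sum(diag(conf)), n)$conf.int)
  structure(list(kappa = kap, se = se, ci95 = ci, confusion = conf,
                 accuracy = acc, accuracy_ci95 = acc_ci, n = n,
                 degenerate = degenerate),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("kappa %.3f (95%% CI %.3f-%.3f), accuracy %.3f (%.3f-%.3f), n = %d\n",
              x$kappa, x$ci95[1], x$ci95[2], x$accuracy,
              x$accuracy_ci95[1], x$accuracy_ci95[2], x$n))
  print(x$confusion)
  invisible(x)
}

#' Mean +/- SD overlap summary by subgroup
#'
#' Aggregates a [per_node_overlap()] table into per-category counts and
#' mean +/- SD of DSC and VS, with a pooled `all` row, the shape of a
#' segmentation-performance summary table.
#'
#' @param pairs data frame from [per_node_overlap()] (needs `dsc`, `vs`,
#'   `category`).
#' @return Data frame with columns `subgroup`, `n`, `dsc_mean`, `dsc_sd`,
#'   `vs_mean`, `vs_sd`.
#' @export
overlap_summary <- function(pairs) {
  groups <- c(list(all = pairs),
              split(pairs, pairs$category))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(subgroup = g, n = nrow(x),
               dsc_mean = mean(x$dsc), dsc_sd = sd(x$dsc),
               vs_mean = mean(x$vs), vs_sd = sd(x$vs),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
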