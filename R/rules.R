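#' Response-rule configuration
#'
#' All numeric thresholds of the nodal response rules live in this one
#' object so a deviating reading of the criteria is a one-line change.
#' Defaults follow the MET-RADS-P / RECIST 1.1 nodal logic: a node is
#' pathological at short axis >= 10 mm and a target lesion at >= 15 mm;
#' partial response requires a >= 30 % drop of the target short-axis sum
#' from baseline; progression requires a >= 20 % and >= 5 mm rise of the
#' sum above the nadir; complete response requires every target node to
#' fall below the pathological size. All boundary comparisons are
#' inclusive.
#'
#' @param pathological_mm short-axis size (mm) at and above which a node
#'   is pathological; default 10.
#' @param target_mm short-axis size (mm) at and above which a node is a
#'   target lesion; default 15.
#' @param pr_percent percent decrease of the target sum from baseline
#'   required for PR; default 30.
#' @param pd_percent percent increase of the target sum from nadir
#'   required for PD; default 20.
#' @param pd_absolute_mm absolute increase (mm) from nadir also required
#'   for PD; default 5.
#' @param max_targets optional cap on the number of baseline target
#'   lesions (largest first); default `Inf` (no cap).
#' @param rule_version free-text tag echoed into report headers.
#' @return Named list of class `response_rules`.
#' @export
response_rules <- function(pathological_mm = 10, target_mm = 15,
                           pr_percent = 30, pd_percent = 20,
                           pd_absolute_mm = 5, max_targets = Inf,
                           rule_version = "metradsp-nodal-rules-1.0") {
  stopifnot(pathological_mm > 0, target_mm > pathological_mm,
            pr_percent > 0, pr_percent < 100,
            pd_percent > 0, pd_percent < 100, pd_absolute_mm > 0)
  structure(list(pathological_mm = as.numeric(pathological_mm),
                 target_mm = as.numeric(target_mm),
                 pr_percent = as.numeric(pr_percent),
                 pd_percent = as.numeric(pd_percent),
                 pd_absolute_mm = as.numeric(pd_absolute_mm),
                 max_targets = as.numeric(max_targets),
                 rule_version = rule_version),
            class = "response_rules")
}

#' MET-RADS-P size category from short-axis diameter
#'
#' `target` at short >= 15 mm, `nontarget` at 10 mm <= short < 15 mm,
#' `nonpathological` below 10 mm (closed lower bounds: exactly 10.0 is
#' nontarget, exactly 15.0 is target).
#'
#' @param short_mm numeric vector of short-axis diameters (mm).
#' @param rules a [response_rules()].
#' @return Character vector over
#'   `c("target", "nontarget", "nonpathological")`.
#' @examples
#' classify_short(c(9.9, 10, 14.999, 15))
#' @export
classify_short <- function(short_mm, rules = response_rules()) {
  ifelse(short_mm >= rules$target_mm, "target",
         ifelse(short_mm >= rules$pathological_mm, "nontarget",
                "nonpathological"))
}

#' Assemble a matched longitudinal series by hand
#'
#' Constructor used when measurement tables and node correspondences are
#' already known (tests, manual overrides). `timepoints` is an ordered
#' list of measurement data frames as produced by [measure_nodes()]
#' (minimally `node_id` and `short_mm`); the first entry is baseline.
#' `links` holds baseline-to-follow-up node correspondences.
#'
#' @param patient_id patient identifier.
#' @param timepoints named or unnamed ordered list of measurement data
#'   frames; first = baseline.
#' @param links data frame with columns `timepoint_a` (baseline index,
#'   always 1), `node_a`, `timepoint_b` (follow-up index into
#'   `timepoints`), `node_b`.
#' @return A `matched_series`: `patient_id`, `timepoints`, `links`,
#'   `unmatched_new` (follow-up nodes with no baseline correspondent) and
#'   `disappeared` (baseline nodes with no correspondent at a follow-up).
#' @export
matched_series <- function(patient_id, timepoints, links = NULL) {
  stopifnot(is.list(timepoints), length(timepoints) >= 2L)
  if (is.null(names(timepoints)))
    names(timepoints) <- c("baseline", paste0("followup", seq_len(length(timepoints) - 1L)))
  if (is.null(links))
    links <- data.frame(timepoint_a = integer(), node_a = integer(),
                        timepoint_b = integer(), node_b = integer())
  validate_links(links, timepoints)
  unmatched <- do.call(rbind, lapply(seq_along(timepoints)[-1], function(t) {
    ids <- timepoints[[t]]$node_id
    new <- setdiff(ids, links$node_b[links$timepoint_b == t])
    if (!length(new)) return(NULL)
    data.frame(timepoint = t, node_id = new)
  }))
  gone <- do.call(rbind, lapply(seq_along(timepoints)[-1], function(t) {
    ids <- timepoints[[1]]$node_id
    lost <- setdiff(ids, links$node_a[links$timepoint_b == t])
    if (!length(lost)) return(NULL)
    data.frame(timepoint = t, node_id = lost)
  }))
  empty <- data.frame(timepoint = integer(), node_id = integer())
  structure(list(patient_id = as.character(patient_id),
                 timepoints = timepoints, links = links,
                 unmatched_new = if (is.null(unmatched)) empty else unmatched,
                 disappeared = if (is.null(gone)) empty else gone),
            class = "matched_series")
}

validate_links <- function(links, timepoints) {
  need <- c("timepoint_a", "node_a", "timepoint_b", "node_b")
  if (!all(need %in% names(links)))
    stop("links must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (r in seq_len(nrow(links))) {
    ta <- links$timepoint_a[r]; tb <- links$timepoint_b[r]
    if (!links$node_a[r] %in% timepoints[[ta]]$node_id ||
        !links$node_b[r] %in% timepoints[[tb]]$node_id)
      stop(sprintf("link row %d references unknown node ids", r),
           call. = FALSE)
  }
  for (t in unique(links$timepoint_b)) {
    sub <- links[links$timepoint_b == t, ]
    if (anyDuplicated(sub$node_a) || anyDuplicated(sub$node_b))
      stop(sprintf("duplicated correspondence at follow-up timepoint %d", t),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.matched_series <- function(x, ...) {
  cat(sprintf("matched_series [%s]: %d timepoints, %d links, %d new, %d disappeared\n",
              x$patient_id, length(x$timepoints), nrow(x$links),
              nrow(x$unmatched_new), nrow(x$disappeared)))
  invisible(x)
}

#' Match nodes across timepoints by centroid proximity
#'
#' Node registration between baseline and post-treatment scans is done
#' without image registration: baseline and follow-up nodes are paired
#' greedily by ascending physical centroid distance, accepting pairs
#' closer than `max_centroid_distance_mm`. A manual correspondence table
#' (the human-in-the-loop override that makes the pipeline
#' "semiautomated") is taken verbatim first, validated for
#' one-to-one-ness; only the remaining nodes enter the greedy stage.
#' Follow-up nodes left unmatched are recorded as new; baseline nodes
#' left unmatched are recorded as disappeared and contribute 0 mm
#' downstream.
#'
#' @param patient_id patient identifier.
#' @param timepoints ordered list of measurement data frames from
#'   [measure_nodes()] (first = baseline); need `node_id`, `short_mm`,
#'   `centroid_x/y/z`.
#' @param max_centroid_distance_mm acceptance radius in mm (default 15).
#' @param manual_links optional data frame of verbatim correspondences
#'   (`timepoint_a`, `node_a`, `timepoint_b`, `node_b`).
#' @return A [matched_series()].
#' @export
match_nodes <- function(patient_id, timepoints,
                        max_centroid_distance_mm = 15,
                        manual_links = NULL) {
  stopifnot(is.list(timepoints), length(timepoints) >= 2L)
  base <- timepoints[[1]]
  links <- if (is.null(manual_links))
    data.frame(timepoint_a = integer(), node_a = integer(),
               timepoint_b = integer(), node_b = integer())
  else {
    validate_links(manual_links, timepoints)
    manual_links[, c("timepoint_a", "node_a", "timepoint_b", "node_b")]
  }
  for (t in seq_along(timepoints)[-1]) {
    cur <- timepoints[[t]]
    used_a <- links$node_a[links$timepoint_b == t]
    used_b <- links$node_b[links$timepoint_b == t]
    cand_a <- base[!base$node_id %in% used_a, , drop = FALSE]
    cand_b <- cur[!cur$node_id %in% used_b, , drop = FALSE]
    if (!nrow(cand_a) || !nrow(cand_b)) next
    ca <- as.matrix(cand_a[, c("centroid_x", "centroid_y", "centroid_z")])
    cb <- as.matrix(cand_b[, c("centroid_x", "centroid_y", "centroid_z")])
    dmat <- sqrt(pmax(outer(rowSums(ca^2), rep(1, nrow(cb))) +
                      outer(rep(1, nrow(ca)), rowSums(cb^2)) -
                      2 * ca %*% t(cb), 0))
    ord <- order(dmat)
    taken_a <- logical(nrow(cand_a)); taken_b <- logical(nrow(cand_b))
    for (pos in ord) {
      if (dmat[pos] > max_centroid_distance_mm) break
      a <- (pos - 1L) %% nrow(cand_a) + 1L
      b <- (pos - 1L) %/% nrow(cand_a) + 1L
      if (taken_a[a] || taken_b[b]) next
      taken_a[a] <- TRUE; taken_b[b] <- TRUE
      links <- rbind(links, data.frame(
        timepoint_a = 1L, node_a = cand_a$node_id[a],
        timepoint_b = t, node_b = cand_b$node_id[b]))
    }
  }
  matched_series(patient_id, timepoints, links)
}

## short diameter of baseline node `id` at follow-up timepoint t;
## disappeared nodes read 0 mm (RECIST handling of lesions too small to see)
short_at <- function(series, id, t) {
  hit <- series$links$node_b[series$links$timepoint_a == 1L &
                             series$links$timepoint_b == t &
                             series$links$node_a == id]
  if (!length(hit)) return(0)
  tp <- series$timepoints[[t]]
  tp$short_mm[match(hit[1], tp$node_id)]
}

new_pathological_count <- function(series, t, rules) {
  new <- series$unmatched_new[series$unmatched_new$timepoint == t, ]
  if (!nrow(new)) return(0L)
  tp <- series$timepoints[[t]]
  sum(tp$short_mm[match(new$node_id, tp$node_id)] >= rules$pathological_mm)
}

assessment_row <- function(series, t, category, call, baseline_sum,
                           current_sum, nadir_sum, rules) {
  data.frame(
    patient_id = series$patient_id,
    timepoint = names(series$timepoints)[t],
    category = category, call = call,
    baseline_sum_mm = baseline_sum, current_sum_mm = current_sum,
    nadir_sum_mm = nadir_sum,
    percent_change_from_baseline =
      if (!is.na(baseline_sum) && baseline_sum > 0)
        100 * (current_sum - baseline_sum) / baseline_sum else NA_real_,
    percent_change_from_nadir =
      if (!is.na(nadir_sum) && nadir_sum > 0)
        100 * (current_sum - nadir_sum) / nadir_sum else NA_real_,
    absolute_change_from_nadir_mm = current_sum - nadir_sum,
    new_pathological_nodes = new_pathological_count(series, t, rules),
    stringsAsFactors = FALSE)
}

#' Target-lesion response per follow-up timepoint
#'
#' Target lesions are designated at baseline (short axis >= the target
#' threshold; optionally capped at the `max_targets` largest) and carried
#' forward — a target that shrinks below 15 mm stays a target for sum
#' bookkeeping. Let S_t be the sum of target short diameters at
#' timepoint t (disappeared nodes contribute 0) and the nadir the
#' smallest sum over baseline and all earlier follow-ups. The call at t
#' is CR if every target node is below the pathological size
#' (CR takes precedence over PD); else PD if S_t exceeds the nadir by
#' both >= 20 % and >= 5 mm; else PR if S_t is >= 30 % below baseline;
#' else SD. Thresholds are inclusive and configurable via
#' [response_rules()].
#'
#' @param series a [matched_series()].
#' @param rules a [response_rules()].
#' @return Data frame, one row per follow-up timepoint, with the call and
#'   the evidence sums/changes that justify it; call `"not-evaluable"`
#'   when baseline has no target lesion.
#' @export
assess_target <- function(series, rules = response_rules()) {
  stopifnot(inherits(series, "matched_series"))
  base <- series$timepoints[[1]]
  targets <- base[base$short_mm >= rules$target_mm, , drop = FALSE]
  if (is.finite(rules$max_targets) && nrow(targets) > rules$max_targets)
    targets <- targets[order(-targets$short_mm), , drop = FALSE][
      seq_len(rules$max_targets), , drop = FALSE]
  fups <- seq_along(series$timepoints)[-1]
  if (!nrow(targets)) {
    return(do.call(rbind, lapply(fups, function(t)
      assessment_row(series, t, "target", "not-evaluable",
                     NA_real_, NA_real_, NA_real_, rules))))
  }
  baseline_sum <- sum(targets$short_mm)
  sums <- baseline_sum   # running record: baseline + assessed follow-ups
  out <- vector("list", length(fups))
  for (k in seq_along(fups)) {
    t <- fups[k]
    shorts <- vapply(targets$node_id, short_at, numeric(1),
                     series = series, t = t)
    s_t <- sum(shorts)
    nadir <- min(sums)
    call <-
      if (all(shorts < rules$pathological_mm)) "CR"
      else if (s_t - nadir >= rules$pd_percent / 100 * nadir &&
               s_t - nadir >= rules$pd_absolute_mm) "PD"
      else if (baseline_sum - s_t >= rules$pr_percent / 100 * baseline_sum) "PR"
      else "SD"
    out[[k]] <- assessment_row(series, t, "target", call,
                               baseline_sum, s_t, nadir, rules)
    sums <- c(sums, s_t)
  }
  do.call(rbind, out)
}

#' Nontarget-lesion response per follow-up timepoint
#'
#' Baseline nontarget nodes (10 mm <= short < 15 mm) are followed
#' qualitatively: CR when every one of them falls below the pathological
#' size and no new pathological node has appeared; PD on any new
#' pathological node (an unmatched follow-up node at short >= 10 mm) or
#' on unequivocal progression, operationalised as any baseline nontarget
#' node reaching target size (>= 15 mm) with both a >= 20 % and >= 5 mm
#' short-axis increase from baseline; otherwise SD.
#'
#' @inheritParams assess_target
#' @return Data frame as in [assess_target()]; `"not-evaluable"` when
#'   baseline has no nontarget lesion.
#' @export
assess_nontarget <- function(series, rules = response_rules()) {
  stopifnot(inherits(series, "matched_series"))
  base <- series$timepoints[[1]]
  nts <- base[base$short_mm >= rules$pathological_mm &
              base$short_mm < rules$target_mm, , drop = FALSE]
  fups <- seq_along(series$timepoints)[-1]
  if (!nrow(nts)) {
    return(do.call(rbind, lapply(fups, function(t)
      assessment_row(series, t, "nontarget", "not-evaluable",
                     NA_real_, NA_real_, NA_real_, rules))))
  }
  baseline_sum <- sum(nts$short_mm)
  do.call(rbind, lapply(fups, function(t) {
    shorts <- vapply(nts$node_id, short_at, numeric(1),
                     series = series, t = t)
    growth <- shorts - nts$short_mm
    new_path <- new_pathological_count(series, t, rules)
    unequivocal <- any(shorts >= rules$target_mm &
                       growth >= rules$pd_percent / 100 * nts$short_mm &
                       growth >= rules$pd_absolute_mm)
    call <-
      if (new_path > 0 || unequivocal) "PD"
      else if (all(shorts < rules$pathological_mm)) "CR"
      else "SD"
    assessment_row(series, t, "nontarget", call,
                   baseline_sum, sum(shorts), NA_real_, rules)
  }))
}

#' Nonpathological-node response per follow-up timepoint
#'
#' Nodes below 10 mm at baseline can only progress: PD when any of them
#' reaches pathological size (short >= 10 mm) at the follow-up, SD
#' otherwise (shrinkage or disappearance cannot progress). CR and PR do
#' not apply to this category.
#'
#' @inheritParams assess_target
#' @return Data frame as in [assess_target()]; `"not-evaluable"` when
#'   baseline has no nonpathological node.
#' @export
assess_nonpathological <- function(series, rules = response_rules()) {
  stopifnot(inherits(series, "matched_series"))
  base <- series$timepoints[[1]]
  nps <- base[base$short_mm < rules$pathological_mm, , drop = FALSE]
  fups <- seq_along(series$timepoints)[-1]
  if (!nrow(nps)) {
    return(do.call(rbind, lapply(fups, function(t)
      assessment_row(series, t, "nonpathological", "not-evaluable",
                     NA_real_, NA_real_, NA_real_, rules))))
  }
  baseline_sum <- sum(nps$short_mm)
  do.call(rbind, lapply(fups, function(t) {
    shorts <- vapply(nps$node_id, short_at, numeric(1),
                     series = series, t = t)
    call <- if (any(shorts >= rules$pathological_mm)) "PD" else "SD"
    assessment_row(series, t, "nonpathological", call,
                   baseline_sum, sum(shorts), NA_real_, rules)
  }))
}

#' Full per-category assessment of one matched series
#'
#' Runs [assess_target()], [assess_nontarget()] and
#' [assess_nonpathological()] and stacks the results.
#'
#' @inheritParams assess_target
#' @return Data frame with one row per (follow-up timepoint, category).
#' @export
assess_series <- function(series, rules = response_rules()) {
  rbind(assess_target(series, rules),
        assess_nontarget(series, rules),
        assess_nonpathological(series, rules))
}
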