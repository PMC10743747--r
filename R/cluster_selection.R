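#' @name cluster_selection
#' @title Inter-slice cluster selection
#'
#' @description
#' Given candidate clusters on every slice of a patient's short-axis stack,
#' selection picks the one sequence of clusters (one per slice) most
#' consistent with a single left ventricle: the sequence minimising the sum
#' of centroid distances between consecutive slices, validated by pairwise
#' pixel overlap. Slices whose best candidate cannot be reconciled with the
#' rest of the stack are placed on a skip list and emitted as blank
#' (background) — the ventricle is declared undetected there. The procedure
#' runs in at most two passes: after the first consistent sequence is
#' found, surviving slices are pinned ("fixed") and previously skipped
#' slices get a second chance against the pinned track.
NULL

#' Selection configuration
#'
#' @param overlap_threshold adjacent-pair overlap percentage below which a
#'   sequence is considered inconsistent (default 20).
#' @param max_passes number of passes over the stack (fixed at 2).
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(overlap_threshold = 20, max_passes = 2L) {
  if (overlap_threshold < 0 || overlap_threshold > 100)
    stop("overlap_threshold must lie in [0, 100]", call. = FALSE)
  if (max_passes != 2L)
    stop("max_passes is fixed at 2", call. = FALSE)
  structure(list(overlap_threshold = overlap_threshold, max_passes = 2L),
            class = "selection_config")
}

#' Read a selection configuration from YAML or JSON
#' @param path file with an `overlap_threshold` (or
#'   `overlap_threshold_percent`) field.
#' @export
read_selection_config <- function(path) {
  vals <- read_config_file(path)
  thr <- vals$overlap_threshold_percent
  if (is.null(thr)) thr <- vals$overlap_threshold
  if (is.null(thr)) thr <- 20
  selection_config(overlap_threshold = thr)
}

#' Overlap percentage between two clusters
#'
#' 100 x |A intersect B| / min(|A|, |B|), computed on 2D pixel coordinates
#' regardless of which slices the clusters come from. The minimum-size
#' denominator makes the measure symmetric and robust to the apex/base
#' size taper of the ventricle.
#'
#' @param a,b clusters from [new_cluster()].
#' @return a real in \[0, 100\].
#' @export
overlap_percent <- function(a, b) {
  inter <- length(intersect(a$pixels, b$pixels))
  100 * inter / min(a$size, b$size)
}

#' Minimum-distance cluster sequence across slices
#'
#' Over the non-skipped slices in stack order (skipped slices are removed
#' so their neighbours become consecutive), chooses one cluster per slice
#' minimising the total Euclidean distance between consecutive centroids,
#' by dynamic programming over the per-slice candidates. Slices with no
#' candidates are treated as skipped. Fixed choices pin a slice to one
#' specific candidate. Path-cost ties prefer the larger total cluster
#' size, then the lexicographically smallest choice indices.
#'
#' @param candidates list of [cluster_set()], one per slice, in order.
#' @param skip integer vector of 1-based slice positions to leave out.
#' @param fixed named integer vector: names are slice positions, values the
#'   pinned candidate index within that slice's cluster list.
#' @return integer vector of length `length(candidates)`: the chosen
#'   candidate index per slice, `NA` for skipped or empty slices.
#' @export
min_distance_sequence <- function(candidates, skip = integer(0),
                                  fixed = integer(0)) {
  n <- length(candidates)
  n_cand <- vapply(candidates, function(cs) length(cs$clusters), integer(1))
  active <- setdiff(which(n_cand > 0L), skip)
  choice <- rep(NA_integer_, n)
  if (length(active) == 0L) return(choice)
  eps <- 1e-9
  # dynamic programme: states are (active slice, candidate index)
  states <- lapply(active, function(i) {
    allowed <- seq_len(n_cand[i])
    if (as.character(i) %in% names(fixed))
      allowed <- fixed[[as.character(i)]]
    allowed
  })
  # each entry: list(cost, totsize, path) per allowed candidate
  first <- candidates[[active[1]]]$clusters
  dp <- lapply(states[[1]], function(j)
    list(cost = 0, totsize = first[[j]]$size, path = j))
  for (s in seq_along(active)[-1]) {
    cur <- candidates[[active[s]]]$clusters
    prev_cl <- candidates[[active[s - 1]]]$clusters
    dp <- lapply(states[[s]], function(j) {
      best <- NULL
      for (p in seq_along(dp)) {
        st <- dp[[p]]
        k <- st$path[length(st$path)]
        d <- sqrt(sum((cur[[j]]$centroid - prev_cl[[k]]$centroid)^2))
        cand <- list(cost = st$cost + d,
                     totsize = st$totsize + cur[[j]]$size,
                     path = c(st$path, j))
        if (is.null(best) || dp_better(cand, best, eps)) best <- cand
      }
      best
    })
  }
  final <- dp[[1]]
  for (p in seq_along(dp)[-1])
    if (dp_better(dp[[p]], final, eps)) final <- dp[[p]]
  choice[active] <- final$path
  choice
}

dp_better <- function(a, b, eps) {
  if (a$cost < b$cost - eps) return(TRUE)
  if (a$cost > b$cost + eps) return(FALSE)
  if (a$totsize != b$totsize) return(a$totsize > b$totsize)
  cmp <- a$path - b$path
  nz <- which(cmp != 0)
  length(nz) > 0 && cmp[nz[1]] < 0
}

#' Select the left-ventricle cluster on every slice
#'
#' Iterates: (1) find the minimum-centroid-distance sequence; (2) check the
#' overlap of each adjacent pair; (3) if all pairs meet the threshold,
#' proceed to the fixing step, else (4) count, for each currently chosen
#' cluster, how many of the other chosen clusters overlap it above the
#' threshold ("valid overlaps"); (5) skip the earliest slice with the
#' fewest valid overlaps and restart. On first arrival at the fixing step,
#' surviving slices are pinned, the skip list is cleared and the loop
#' restarts so previously skipped slices can rejoin; on second arrival (or
#' when no slice remains skippable) the procedure stops. Skipped slices
#' are emitted blank.
#'
#' @param candidates list of [cluster_set()], one per slice, in order.
#' @param config a [selection_config()].
#' @return an object of class `selection_result`: `chosen` (per-slice
#'   cluster or `NULL`), `skipped` (0-based indices of blank slices),
#'   `iterations` (loop count).
#' @export
select_ventricle <- function(candidates, config = selection_config()) {
  n <- length(candidates)
  n_cand <- vapply(candidates, function(cs) length(cs$clusters), integer(1))
  thr <- config$overlap_threshold
  skip <- integer(0)
  fixed <- integer(0)
  reached_fix <- FALSE
  max_iter <- 2L * n + 4L
  iter <- 0L
  choice <- rep(NA_integer_, n)
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("cluster selection failed to terminate within the two-pass bound",
           call. = FALSE)
    choice <- min_distance_sequence(candidates, skip = skip, fixed = fixed)
    active <- which(!is.na(choice))
    chosen <- lapply(active, function(i)
      candidates[[i]]$clusters[[choice[i]]])
    consistent <- TRUE
    if (length(chosen) >= 2L) {
      adj <- vapply(seq_len(length(chosen) - 1L), function(p)
        overlap_percent(chosen[[p]], chosen[[p + 1L]]), numeric(1))
      consistent <- all(adj >= thr)
    }
    if (consistent) {
      if (reached_fix || length(active) == 0L) break
      fixed <- structure(choice[active], names = as.character(active))
      skip <- integer(0)
      reached_fix <- TRUE
      next
    }
    # census of valid overlaps among the currently chosen clusters
    m <- length(chosen)
    valid <- integer(m)
    for (p in seq_len(m - 1L)) for (q in seq(p + 1L, m)) {
      if (overlap_percent(chosen[[p]], chosen[[q]]) > thr) {
        valid[p] <- valid[p] + 1L
        valid[q] <- valid[q] + 1L
      }
    }
    skippable <- which(!(as.character(active) %in% names(fixed)))
    if (length(skippable) == 0L) break
    target <- skippable[valid[skippable] == min(valid[skippable])][1]
    skip <- c(skip, active[target])
  }
  chosen_out <- vector("list", n)
  for (i in which(!is.na(choice)))
    chosen_out[[i]] <- candidates[[i]]$clusters[[choice[i]]]
  blank <- which(is.na(choice))
  structure(list(chosen = chosen_out,
                 skipped = as.integer(sort(blank)) - 1L,
                 iterations = iter),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  n <- length(x$chosen)
  cat(sprintf("selection_result: %d slices, %d blank (%s), %d iteration(s)\n",
              n, length(x$skipped),
              if (length(x$skipped)) paste(x$skipped, collapse = ", ")
              else "none", x$iterations))
  invisible(x)
}

#' Apply a selection result to a stack
#'
#' Per slice, every pixel outside the chosen cluster is set to background;
#' skipped slices become entirely background; labels inside the chosen
#' cluster are unchanged.
#'
#' @param stack the [segmentation_stack()] the candidates came from.
#' @param result a [selection_result()][select_ventricle()].
#' @return a new `segmentation_stack`.
#' @export
apply_selection <- function(stack, result) {
  if (!inherits(stack, "segmentation_stack"))
    stop("stack must be a segmentation_stack", call. = FALSE)
  n <- n_slices(stack)
  if (length(result$chosen) != n)
    stop("selection result does not match the stack's slice count",
         call. = FALSE)
  d <- dim(stack$slices[[1]])
  slices <- lapply(seq_len(n), function(i) {
    cl <- result$chosen[[i]]
    if (is.null(cl)) return(matrix(0L, d[1], d[2]))
    if (!all(cl$dim == d))
      stop("cluster dimensions do not match the stack", call. = FALSE)
    clusters_to_map(list(cl), d)
  })
  segmentation_stack(slices, patient_id = stack$patient_id,
                     geometry = stack$geometry)
}

#' Full post-processing chain for one stack
#'
#' Generates candidate clusters on every slice, selects the
#' left-ventricle track, and rasterises the result.
#'
#' @param stack a [segmentation_stack()].
#' @param cluster_cfg a [cluster_config()].
#' @param selection_cfg a [selection_config()].
#' @return list with `stack` (cleaned segmentation_stack), `result`
#'   (selection_result) and `candidates` (per-slice cluster sets).
#' @export
postprocess_stack <- function(stack, cluster_cfg = cluster_config(),
                              selection_cfg = selection_config()) {
  candidates <- lapply(seq_len(n_slices(stack)), function(i)
    generate_clusters(stack$slices[[i]], cluster_cfg, slice_index = i - 1L))
  result <- select_ventricle(candidates, selection_cfg)
  list(stack = apply_selection(stack, result), result = result,
       candidates = candidates)
}
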