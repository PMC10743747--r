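# Independent oracles used to cross-check the implementation. These are
# deliberately naive (recursive flood fill, exhaustive enumeration,
# brute-force distance scans) and kept free of any package internals.

# Flood-fill connected-component labeling over non-zero pixels.
oracle_components <- function(map, connectivity = 8) {
  h <- nrow(map); w <- ncol(map)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  next_id <- 0L
  for (start in which(map != 0L & lab == 0L)) {
    if (lab[start] != 0L) next
    next_id <- next_id + 1L
    frontier <- start
    lab[start] <- next_id
    while (length(frontier) > 0L) {
      p <- frontier[1]; frontier <- frontier[-1]
      r <- ((p - 1L) %% h) + 1L; c <- ((p - 1L) %/% h) + 1L
      for (k in seq_len(nrow(nb))) {
        r2 <- r + nb$dr[k]; c2 <- c + nb$dc[k]
        if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
        q <- (c2 - 1L) * h + r2
        if (map[q] != 0L && lab[q] == 0L) {
          lab[q] <- next_id
          frontier <- c(frontier, q)
        }
      }
    }
  }
  lab
}

# Pixel sets of oracle components, as sorted linear-index vectors ordered
# by decreasing size.
oracle_component_sets <- function(map, connectivity = 8) {
  lab <- oracle_components(map, connectivity)
  sets <- split(which(lab > 0L), lab[lab > 0L])
  sets[order(-lengths(sets))]
}

# Exhaustive minimum-total-centroid-distance sequence cost over per-slice
# candidate lists (list of lists of centroids).
oracle_min_path_cost <- function(centroids_per_slice) {
  n <- length(centroids_per_slice)
  combos <- expand.grid(lapply(centroids_per_slice, seq_along))
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    cost <- 0
    for (s in seq_len(n - 1)) {
      a <- centroids_per_slice[[s]][[combos[i, s]]]
      b <- centroids_per_slice[[s + 1]][[combos[i, s + 1]]]
      cost <- cost + sqrt(sum((a - b)^2))
    }
    if (cost < best) best <- cost
  }
  best
}

# Brute-force nearest-component assignment of points to pixel sets.
oracle_nearest_set <- function(pt, sets_rc) {
  d <- vapply(sets_rc, function(s)
    min(sqrt((s[, 1] - pt[1])^2 + (s[, 2] - pt[2])^2)), numeric(1))
  which(d <= min(d) + 1e-9)
}

# Canonical form for comparing collections of pixel sets irrespective of
# order: each set sorted, sets ordered by their smallest element.
canon_sets <- function(sets) {
  sets <- unname(lapply(sets, function(s) as.integer(sort(unname(s)))))
  sets[order(vapply(sets, function(s) s[1], integer(1)))]
}

# A random valid label map with a few blobs, for property tests.
random_label_map <- function(h = 32, w = 32, n_blobs = 3) {
  m <- matrix(0L, h, w)
  for (b in seq_len(n_blobs)) {
    ctr <- c(sample.int(h, 1), sample.int(w, 1))
    r <- sample(2:6, 1)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    d <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
    m[d <= r] <- sample(1:3, 1)
  }
  m
}

# A random stack of valid label maps (shared dimensions).
random_stack <- function(n = 4, h = 24, w = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slices <- lapply(seq_len(n), function(i)
    matrix(sample(0:3, h * w, replace = TRUE,
                  prob = c(0.7, 0.1, 0.1, 0.1)), h, w))
  segmentation_stack(slices, patient_id = "rand",
                     geometry = voxel_geometry(1.2, 1.4, 7, 1.5))
}

# Candidate cluster at a given centre: a filled square of the given
# half-width, labelled with a mix of classes.
square_cluster <- function(center, half = 5, dim = c(100, 100),
                           label = 2L) {
  rows <- pmax(1, center[1] - half):pmin(dim[1], center[1] + half)
  cols <- pmax(1, center[2] - half):pmin(dim[2], center[2] + half)
  g <- expand.grid(row = rows, col = cols)
  idx <- (g$col - 1L) * dim[1] + g$row
  new_cluster(idx, rep(label, length(idx)), dim)
}

# Random per-slice candidate sets for selection tests.
random_candidates <- function(n_slices, max_cands = 3, dim = c(100, 100)) {
  lapply(seq_len(n_slices), function(s) {
    k <- sample.int(max_cands, 1)
    centers <- replicate(k, c(sample(10:90, 1), sample(10:90, 1)),
                         simplify = FALSE)
    cls <- lapply(centers, square_cluster, half = sample(2:5, 1), dim = dim)
    # enforce disjointness by dropping overlapping candidates
    keep <- list()
    used <- integer(0)
    for (cl in cls) {
      if (!any(cl$pixels %in% used)) {
        keep <- c(keep, list(cl))
        used <- c(used, cl$pixels)
      }
    }
    cluster_set(s - 1L, keep)
  })
}

# Default far-distractor phantom used across selection tests: the mimic
# track sits in a corner, well clear of the tapered ventricle.
far_distractor_phantom <- function(seed, kind = "rv_mimic") {
  generate_phantom(phantom_config(
    seed = seed,
    distractors = list(distractor_spec(kind, center = c(45, 160),
                                       radius = 15, jitter = 3))))
}

# Do the stack's foreground pixels exactly match the ground-truth track?
stack_equals_truth <- function(stack, ground_truth) {
  d <- dim(stack$slices[[1]])
  all(vapply(seq_len(n_slices(stack)), function(i) {
    cl <- ground_truth$chosen[[i]]
    target <- if (is.null(cl)) matrix(0L, d[1], d[2])
              else clusters_to_map(list(cl), d)
    identical(stack$slices[[i]], target)
  }, logical(1)))
}

# Count hallucination pixels still labelled foreground after cleaning.
remaining_hallucination_pixels <- function(stack, hallucinations) {
  sum(vapply(seq_len(n_slices(stack)), function(i)
    sum(stack$slices[[i]][hallucinations[[i]]] != 0L), integer(1)))
}
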