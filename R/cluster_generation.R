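#' @name cluster_generation
#' @title Per-slice candidate-cluster generation
#'
#' @description
#' A slice of network output may contain several connected blobs of
#' ventricle-like labels, only one of which is the left ventricle; the rest
#' are hallucinations (most commonly the right ventricle). Candidate
#' generation keeps the largest connected components, splits components
#' whose cavity-plus-trabeculae core is fragmented (reassigning
#' external-layer pixels to the nearest fragment), and merges sub-clusters
#' smaller than a fraction of the largest back into their nearest
#' neighbour.
NULL

idx_to_rc <- function(idx, h) {
  cbind(row = ((idx - 1L) %% h) + 1L, col = ((idx - 1L) %/% h) + 1L)
}

#' Construct a cluster from pixel indices
#'
#' A cluster is one connected candidate-ventricle region within a slice:
#' its pixels (stored as 1-based column-major linear indices into the
#' slice), their class labels, centroid in (row, col) coordinates, and the
#' count of cavity/trabecular (IC or TZ) pixels.
#'
#' @param pixels integer vector of linear pixel indices.
#' @param labels integer vector of class labels (1, 2 or 3), same length.
#' @param dim slice dimensions `c(height, width)`.
#' @return an object of class `lv_cluster`.
#' @export
new_cluster <- function(pixels, labels, dim) {
  if (length(pixels) == 0L)
    stop("a cluster must contain at least one pixel", call. = FALSE)
  if (length(pixels) != length(labels))
    stop("pixels and labels must have equal length", call. = FALSE)
  ord <- order(pixels)
  pixels <- as.integer(pixels[ord]); labels <- as.integer(labels[ord])
  rc <- idx_to_rc(pixels, dim[1])
  structure(list(pixels = pixels, labels = labels,
                 size = length(pixels),
                 centroid = c(mean(rc[, 1]), mean(rc[, 2])),
                 ictz_size = sum(labels == LABEL_IC | labels == LABEL_TZ),
                 dim = as.integer(dim)),
            class = "lv_cluster")
}

cluster_coords <- function(cl) {
  matrix(as.numeric(idx_to_rc(cl$pixels, cl$dim[1])), ncol = 2)
}

#' @export
print.lv_cluster <- function(x, ...) {
  cat(sprintf("lv_cluster: %d px (%d IC/TZ), centroid (%.1f, %.1f)\n",
              x$size, x$ictz_size, x$centroid[1], x$centroid[2]))
  invisible(x)
}

# Canonical cluster order: size descending, ties by lexicographically
# smaller (row, col) centroid.
sort_clusters <- function(clusters) {
  if (length(clusters) <= 1L) return(clusters)
  sizes <- vapply(clusters, `[[`, integer(1), "size")
  rows <- vapply(clusters, function(c) c$centroid[1], numeric(1))
  cols <- vapply(clusters, function(c) c$centroid[2], numeric(1))
  clusters[order(-sizes, rows, cols)]
}

#' Construct a per-slice cluster set
#'
#' @param slice_index 0-based slice index.
#' @param clusters list of [new_cluster()] objects, pairwise disjoint.
#' @return an object of class `cluster_set` with clusters in canonical
#'   order (size descending, centroid tie-break).
#' @export
cluster_set <- function(slice_index, clusters) {
  clusters <- sort_clusters(clusters)
  px <- unlist(lapply(clusters, `[[`, "pixels"))
  if (anyDuplicated(px))
    stop("clusters in a cluster_set must be pairwise disjoint", call. = FALSE)
  structure(list(slice_index = as.integer(slice_index), clusters = clusters),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set (slice %d): %d cluster(s) of size %s\n",
              x$slice_index, length(x$clusters),
              paste(vapply(x$clusters, `[[`, integer(1), "size"),
                    collapse = ", ")))
  invisible(x)
}

#' Cluster-generation configuration
#'
#' @param top_k number of largest components retained per slice.
#' @param connectivity pixel connectivity, 4 or 8.
#' @param merge_fraction sub-clusters smaller than this fraction of the
#'   largest cluster are merged into their nearest neighbour.
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(top_k = 3L, connectivity = 8L,
                           merge_fraction = 0.05) {
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  if (merge_fraction <= 0 || merge_fraction >= 1)
    stop("merge_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(top_k = as.integer(top_k),
                 connectivity = as.integer(connectivity),
                 merge_fraction = merge_fraction),
            class = "cluster_config")
}

#' Read a cluster configuration from YAML or JSON
#' @param path file with any subset of the [cluster_config()] fields.
#' @export
read_cluster_config <- function(path) {
  vals <- read_config_file(path)
  do.call(cluster_config, utils::modifyList(
    list(top_k = 3L, connectivity = 8L, merge_fraction = 0.05),
    vals[intersect(names(vals), c("top_k", "connectivity", "merge_fraction"))]))
}

read_config_file <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file: %s", path), call. = FALSE)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Find the k largest connected components of a slice
#'
#' Any set of connected non-background pixels (EL, IC or TZ in any mix)
#' counts as one cluster; the `k` largest are kept, largest first.
#'
#' @param map a label-map matrix.
#' @param k number of components to keep (default 3).
#' @param connectivity 4 or 8 (default 8).
#' @return a [cluster_set()]; empty for an all-background slice.
#' @export
find_top_clusters <- function(map, k = 3L, connectivity = 8L,
                              slice_index = 0L) {
  map <- label_map(map, slice = slice_index)
  lab <- cc_label_cpp(map, as.integer(connectivity))
  fg <- which(lab > 0L)
  if (length(fg) == 0L) return(cluster_set(slice_index, list()))
  groups <- unname(split(fg, lab[fg]))
  clusters <- lapply(groups, function(px)
    new_cluster(px, map[px], dim(map)))
  clusters <- sort_clusters(clusters)
  cluster_set(slice_index, clusters[seq_len(min(k, length(clusters)))])
}

#' Split a cluster along its cavity/trabecular components
#'
#' If the IC+TZ pixels of the cluster fall apart into several connected
#' components, the cluster is split into one sub-cluster per component and
#' every EL pixel is reassigned to the sub-cluster containing its nearest
#' pixel (Euclidean distance; ties go to the larger sub-cluster). Pixels
#' and labels are conserved exactly.
#'
#' @param cl an [new_cluster()] object.
#' @param connectivity 4 or 8.
#' @return list of clusters (length 1 when no split applies).
#' @export
split_cluster <- function(cl, connectivity = 8L) {
  core <- cl$pixels[cl$labels %in% c(LABEL_IC, LABEL_TZ)]
  if (length(core) == 0L) return(list(cl))
  mask <- matrix(0L, cl$dim[1], cl$dim[2])
  mask[core] <- 1L
  lab <- cc_label_cpp(mask, as.integer(connectivity))
  ncomp <- max(lab)
  if (ncomp <= 1L) return(list(cl))
  comp_px <- unname(split(core, lab[core]))
  comp_cl <- sort_clusters(lapply(comp_px, function(px)
    new_cluster(px, rep(LABEL_IC, length(px)), cl$dim)))
  comp_px <- lapply(comp_cl, `[[`, "pixels")
  el <- cl$pixels[cl$labels == LABEL_EL]
  assign <- integer(length(el))
  if (length(el) > 0L) {
    d <- cross_min_dists_cpp(
      matrix(as.numeric(idx_to_rc(el, cl$dim[1])), ncol = 2),
      lapply(comp_px, function(px)
        matrix(as.numeric(idx_to_rc(px, cl$dim[1])), ncol = 2)))
    # components are ordered largest-first, so the first minimum wins ties
    assign <- apply(d, 1, function(row) which(row <= min(row) + 1e-9)[1])
  }
  lab_of <- structure(cl$labels, names = cl$pixels)
  out <- lapply(seq_along(comp_px), function(j) {
    px <- c(comp_px[[j]], el[assign == j])
    new_cluster(px, unname(lab_of[as.character(px)]), cl$dim)
  })
  out[vapply(out, `[[`, integer(1), "size") > 0L]
}

#' Merge sub-threshold clusters into their nearest neighbour
#'
#' Any cluster smaller than `min_fraction` of the largest input cluster is
#' merged, smallest first, into the cluster nearest by minimum pairwise
#' pixel distance; sizes are re-evaluated after each merge. Pixels and
#' labels are conserved.
#'
#' @param clusters list of disjoint clusters.
#' @param min_fraction threshold fraction (default 0.05).
#' @return list of clusters, each above threshold (or a single survivor).
#' @export
merge_small_clusters <- function(clusters, min_fraction = 0.05) {
  if (length(clusters) == 0L) return(list())
  thr <- min_fraction * max(vapply(clusters, `[[`, integer(1), "size"))
  repeat {
    if (length(clusters) == 1L) break
    sizes <- vapply(clusters, `[[`, integer(1), "size")
    small <- which(sizes < thr)
    if (length(small) == 0L) break
    i <- small[which.min(sizes[small])]
    others <- setdiff(seq_along(clusters), i)
    ci <- cluster_coords(clusters[[i]])
    dists <- vapply(others, function(j)
      min_set_dist_cpp(ci, cluster_coords(clusters[[j]])), numeric(1))
    near <- others[dists <= min(dists) + 1e-9]
    j <- near[order(-sizes[near], near)][1]
    merged <- new_cluster(c(clusters[[i]]$pixels, clusters[[j]]$pixels),
                          c(clusters[[i]]$labels, clusters[[j]]$labels),
                          clusters[[i]]$dim)
    clusters <- c(clusters[-c(i, j)], list(merged))
  }
  sort_clusters(clusters)
}

#' Generate candidate clusters for one slice
#'
#' Composition of the three generation steps: keep the `top_k` largest
#' connected components, split along fragmented IC+TZ cores, and merge
#' sub-threshold fragments. Deterministic for a fixed configuration.
#'
#' @param map a label-map matrix.
#' @param config a [cluster_config()].
#' @param slice_index 0-based index recorded in the output.
#' @return a [cluster_set()].
#' @export
generate_clusters <- function(map, config = cluster_config(),
                              slice_index = 0L) {
  top <- find_top_clusters(map, k = config$top_k,
                           connectivity = config$connectivity,
                           slice_index = slice_index)
  if (length(top$clusters) == 0L) return(top)
  parts <- unlist(lapply(top$clusters, split_cluster,
                         connectivity = config$connectivity),
                  recursive = FALSE)
  cluster_set(slice_index, merge_small_clusters(parts, config$merge_fraction))
}

#' Rasterise clusters back into a label map
#'
#' @param clusters a [cluster_set()] or list of clusters.
#' @param dim slice dimensions `c(height, width)`; inferred when omitted.
#' @return a label-map matrix with the clusters' pixels at their labels and
#'   background elsewhere.
#' @export
clusters_to_map <- function(clusters, dim = NULL) {
  if (inherits(clusters, "cluster_set")) clusters <- clusters$clusters
  if (length(clusters) == 0L) {
    if (is.null(dim)) stop("dim required for an empty cluster list",
                           call. = FALSE)
    return(matrix(0L, dim[1], dim[2]))
  }
  if (is.null(dim)) dim <- clusters[[1]]$dim
  out <- matrix(0L, dim[1], dim[2])
  for (cl in clusters) out[cl$pixels] <- cl$labels
  out
}
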