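test_that("component labeling matches a flood-fill oracle on random maps", {
  set.seed(11)
  for (i in 1:20) {
    conn <- sample(c(4L, 8L), 1)
    m <- random_label_map()
    cs <- find_top_clusters(m, k = 99L, connectivity = conn)
    got <- lapply(cs$clusters, `[[`, "pixels")
    want <- oracle_component_sets(m, conn)
    expect_equal(length(got), length(want))
    # same collection of pixel sets (order may differ among equal sizes)
    expect_equal(canon_sets(got), canon_sets(want))
  }
})

test_that("component labeling agrees with EBImage's 4-connectivity labeller", {
  skip_if_not_installed("EBImage")
  set.seed(12)
  for (i in 1:5) {
    m <- random_label_map()
    got <- lapply(find_top_clusters(m, 99L, connectivity = 4L)$clusters,
                  `[[`, "pixels")
    lab <- EBImage::bwlabel(matrix(as.numeric(m > 0), nrow(m)))
    want <- split(which(lab > 0), lab[lab > 0])
    expect_equal(canon_sets(got), canon_sets(want))
  }
})

test_that("only the k largest components are kept, largest first", {
  m <- matrix(0L, 40, 120)
  blobs <- list(c(10, 10, 100), c(10, 45, 50), c(10, 75, 30), c(30, 100, 10))
  for (b in blobs) {
    cols <- b[2]:(b[2] + b[3] / 10 - 1)
    m[b[1]:(b[1] + 9), cols] <- 1L
  }
  cs <- find_top_clusters(m, k = 3L)
  expect_equal(vapply(cs$clusters, `[[`, integer(1), "size"),
               c(100L, 50L, 30L))
  expect_equal(length(find_top_clusters(m, k = 2L)$clusters), 2L)
})

test_that("a single blob's cluster covers exactly the foreground", {
  set.seed(5)
  m <- matrix(0L, 20, 20); m[5:12, 6:15] <- 3L
  cs <- find_top_clusters(m)
  expect_equal(length(cs$clusters), 1L)
  expect_equal(cs$clusters[[1]]$size, sum(m > 0))
  expect_setequal(cs$clusters[[1]]$pixels, which(m > 0))
})

test_that("all-background maps give an empty cluster set", {
  cs <- find_top_clusters(matrix(0L, 8, 8))
  expect_length(cs$clusters, 0)
  expect_length(generate_clusters(matrix(0L, 8, 8))$clusters, 0)
})

test_that("clusters with a single connected IC+TZ core are not split", {
  # EL rectangle with one central IC disc: core is one component
  m <- matrix(0L, 20, 20)
  m[4:16, 4:16] <- 1L; m[8:12, 8:12] <- 2L
  cl <- find_top_clusters(m)$clusters[[1]]
  expect_length(split_cluster(cl), 1)
  # pure-EL cluster: nothing to split on
  m2 <- matrix(0L, 10, 10); m2[2:5, 2:5] <- 1L
  cl2 <- find_top_clusters(m2)$clusters[[1]]
  expect_identical(split_cluster(cl2), list(cl2))
})

test_that("splitting assigns EL pixels to the nearest IC+TZ component", {
  # one EL slab containing two IC discs, centred at (10,10) and (10,40)
  m <- matrix(0L, 20, 50)
  m[6:14, 4:46] <- 1L
  rows <- matrix(seq_len(20), 20, 50)
  cols <- matrix(seq_len(50), 20, 50, byrow = TRUE)
  m[sqrt((rows - 10)^2 + (cols - 10)^2) <= 3] <- 2L
  m[sqrt((rows - 10)^2 + (cols - 40)^2) <= 3] <- 2L
  cl <- find_top_clusters(m)$clusters[[1]]
  parts <- split_cluster(cl)
  expect_length(parts, 2)
  # conservation of the pixel multiset and labels
  expect_setequal(c(parts[[1]]$pixels, parts[[2]]$pixels), cl$pixels)
  expect_equal(sum(vapply(parts, `[[`, integer(1), "size")), cl$size)
  # the named probes land with their nearest disc
  left <- if (parts[[1]]$centroid[2] < parts[[2]]$centroid[2]) 1 else 2
  px_at <- function(r, c) (c - 1L) * 20L + r
  expect_true(px_at(10, 20) %in% parts[[left]]$pixels)
  expect_true(px_at(10, 35) %in% parts[[3 - left]]$pixels)
  # every EL pixel agrees with the brute-force nearest-set oracle
  sets_rc <- lapply(parts, function(p)
    cbind(((p$pixels[p$labels != 1L] - 1L) %% 20L) + 1L,
          ((p$pixels[p$labels != 1L] - 1L) %/% 20L) + 1L))
  for (p in 1:2) {
    el <- parts[[p]]$pixels[parts[[p]]$labels == 1L]
    for (px in el) {
      pt <- c(((px - 1L) %% 20L) + 1L, ((px - 1L) %/% 20L) + 1L)
      expect_true(p %in% oracle_nearest_set(pt, sets_rc))
    }
  }
})

test_that("splitting conserves pixels and labels on random clusters", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_label_map(n_blobs = 4)
    for (cl in find_top_clusters(m)$clusters) {
      parts <- split_cluster(cl)
      got_px <- unlist(lapply(parts, `[[`, "pixels"))
      got_lab <- unlist(lapply(parts, `[[`, "labels"))
      expect_setequal(got_px, cl$pixels)
      expect_equal(as.vector(table(factor(got_lab, 1:3))),
                   as.vector(table(factor(cl$labels, 1:3))))
    }
  }
})

test_that("sub-threshold clusters are merged into their nearest neighbour", {
  big <- square_cluster(c(20, 20), half = 15, dim = c(100, 100), label = 2L)
  mid <- square_cluster(c(20, 70), half = 14, dim = c(100, 100), label = 1L)
  expect_length(merge_small_clusters(list(big, mid)), 2)

  tiny <- square_cluster(c(22, 45), half = 2, dim = c(100, 100), label = 3L)
  merged <- merge_small_clusters(list(big, tiny))
  expect_length(merged, 1)
  expect_equal(merged[[1]]$size, big$size + tiny$size)
  # per-label pixel counts conserved
  labs <- table(merged[[1]]$labels)
  expect_equal(unname(labs[["2"]]), big$size)
  expect_equal(unname(labs[["3"]]), tiny$size)
  expect_identical(merge_small_clusters(list()), list())
})

test_that("merging is re-evaluated smallest-first", {
  big <- square_cluster(c(50, 20), half = 20, dim = c(100, 100))   # 1681 px
  a <- square_cluster(c(50, 60), half = 4, dim = c(100, 100))      # 81 px
  b <- square_cluster(c(50, 70), half = 3, dim = c(100, 100))      # 49 px
  # threshold 5% of 1681 = 84.05: both a and b are small, but merging b
  # into its nearest (a) lifts the pair above threshold
  out <- merge_small_clusters(list(big, a, b))
  expect_length(out, 2)
  expect_setequal(vapply(out, `[[`, integer(1), "size"),
                  c(big$size, a$size + b$size))
})

test_that("generate_clusters is deterministic and idempotent", {
  set.seed(31)
  for (i in 1:8) {
    m <- random_label_map(n_blobs = 4)
    cs1 <- generate_clusters(m)
    cs2 <- generate_clusters(m)
    expect_identical(cs1, cs2)
    # reconstruct-and-rerun: rasterising the output and regenerating
    # reproduces the same pixel partition
    m2 <- clusters_to_map(cs1, dim(m))
    cs3 <- generate_clusters(m2)
    expect_equal(canon_sets(lapply(cs1$clusters, `[[`, "pixels")),
                 canon_sets(lapply(cs3$clusters, `[[`, "pixels")))
  }
})

test_that("generated clusters are pairwise disjoint and sorted by size", {
  set.seed(41)
  for (i in 1:10) {
    cs <- generate_clusters(random_label_map(n_blobs = 5))
    px <- unlist(lapply(cs$clusters, `[[`, "pixels"))
    expect_false(anyDuplicated(px) > 0)
    sizes <- vapply(cs$clusters, `[[`, integer(1), "size")
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("a slice with a ventricle plus a mimic yields both candidates", {
  ph <- far_distractor_phantom(seed = 3)
  cs <- generate_clusters(ph$stack$slices[[5]])
  expect_gte(length(cs$clusters), 2)
  truth_px <- ph$ground_truth$chosen[[5]]$pixels
  match_truth <- vapply(cs$clusters, function(cl)
    setequal(cl$pixels, truth_px), logical(1))
  expect_true(any(match_truth))
})

test_that("cluster configuration validates and loads from YAML and JSON", {
  expect_error(cluster_config(top_k = 0), "top_k")
  expect_error(cluster_config(connectivity = 6), "connectivity")
  expect_error(cluster_config(merge_fraction = 1), "merge_fraction")
  f <- tempfile(fileext = ".yaml")
  writeLines("top_k: 5\nconnectivity: 4", f)
  cfg <- read_cluster_config(f)
  expect_equal(cfg$top_k, 5L)
  expect_equal(cfg$connectivity, 4L)
  expect_equal(cfg$merge_fraction, 0.05)
  g <- tempfile(fileext = ".json")
  writeLines('{"merge_fraction": 0.1}', g)
  expect_equal(read_cluster_config(g)$merge_fraction, 0.1)
})
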