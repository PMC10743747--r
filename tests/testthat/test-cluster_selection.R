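test_that("overlap percentage follows the min-size convention", {
  dim <- c(100, 100)
  a <- new_cluster(1:100, rep(2L, 100), dim)
  b <- new_cluster(1:100, rep(3L, 100), dim)
  expect_equal(overlap_percent(a, b), 100)
  c <- new_cluster(201:300, rep(1L, 100), dim)
  expect_equal(overlap_percent(a, c), 0)
  # |a| = 100, |b| = 50, intersection 25 -> 100 * 25 / 50 = 50
  d <- new_cluster(76:125, rep(2L, 50), dim)
  expect_equal(overlap_percent(a, d), 50)
  expect_equal(overlap_percent(d, a), 50)
})

test_that("a forced choice (one candidate per slice) is returned as-is", {
  cands <- lapply(1:4, function(s)
    cluster_set(s - 1L, list(square_cluster(c(50, 50 + s), half = 4))))
  expect_equal(min_distance_sequence(cands), rep(1L, 4))
})

test_that("the DP sequence cost equals the exhaustive-enumeration minimum", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    cands <- random_candidates(n, max_cands = 3)
    choice <- min_distance_sequence(cands)
    active <- which(!is.na(choice))
    cents <- lapply(active, function(i)
      lapply(cands[[i]]$clusters, `[[`, "centroid"))
    dp_cost <- 0
    for (p in seq_len(length(active) - 1)) {
      a <- cands[[active[p]]]$clusters[[choice[active[p]]]]$centroid
      b <- cands[[active[p + 1]]]$clusters[[choice[active[p + 1]]]]$centroid
      dp_cost <- dp_cost + sqrt(sum((a - b)^2))
    }
    expect_equal(dp_cost, oracle_min_path_cost(cents), tolerance = 1e-10)
  }
})

test_that("a stationary track beats a jittering distractor track", {
  set.seed(8)
  cands <- lapply(1:6, function(s) {
    jit <- sample(-10:10, 2)
    cluster_set(s - 1L, list(
      square_cluster(c(40, 40), half = 6),
      square_cluster(c(40, 80) + jit, half = 5)))
  })
  choice <- min_distance_sequence(cands)
  chosen_cols <- vapply(seq_along(cands), function(i)
    cands[[i]]$clusters[[choice[i]]]$centroid[2], numeric(1))
  expect_true(all(abs(chosen_cols - 40) < 1))
})

test_that("fixed choices pin the DP and skipped slices drop out", {
  cands <- lapply(1:3, function(s)
    cluster_set(s - 1L, list(square_cluster(c(40, 40), half = 5),
                             square_cluster(c(40, 80), half = 5))))
  pin <- structure(2L, names = "2")
  choice <- min_distance_sequence(cands, fixed = pin)
  expect_equal(choice, rep(2L, 3))  # pinning slice 2 drags the whole path
  choice2 <- min_distance_sequence(cands, skip = 2L)
  expect_true(is.na(choice2[2]))
  expect_equal(choice2[c(1, 3)], c(1L, 1L))
})

test_that("a clean phantom passes selection without skips", {
  ph <- generate_phantom(phantom_config(seed = 2))
  out <- postprocess_stack(ph$stack)
  expect_length(out$result$skipped, 0)
  expect_true(stack_equals_truth(out$stack, ph$ground_truth))
})

test_that("a slice whose only candidate is a far blob is emitted blank", {
  # five overlapping stationary candidates; slice 3 only offers a far blob
  cands <- lapply(1:5, function(s) {
    if (s == 3)
      cluster_set(s - 1L, list(square_cluster(c(20, 90), half = 4)))
    else
      cluster_set(s - 1L, list(square_cluster(c(50, 40), half = 8)))
  })
  res <- select_ventricle(cands)
  expect_equal(res$skipped, 2L)  # 0-based index of slice 3
  expect_null(res$chosen[[3]])
  expect_false(is.null(res$chosen[[1]]))
})

test_that("selection terminates within the two-pass iteration bound", {
  set.seed(15)
  for (rep in 1:15) {
    n <- sample(3:8, 1)
    cands <- random_candidates(n)
    res <- select_ventricle(cands)
    expect_lte(res$iterations, 2L * n)
    # blank slices are exactly those without a chosen cluster
    blank <- which(vapply(res$chosen, is.null, logical(1))) - 1L
    expect_equal(res$skipped, as.integer(blank))
  }
})

test_that("far distractors are never selected over the true ventricle", {
  for (seed in 1:30) {
    ph <- far_distractor_phantom(seed)
    out <- postprocess_stack(ph$stack)
    expect_equal(remaining_hallucination_pixels(out$stack,
                                                ph$hallucinations), 0L)
    expect_true(stack_equals_truth(out$stack, ph$ground_truth))
  }
})

test_that("apply_selection blanks non-chosen pixels and conserves labels", {
  ph <- far_distractor_phantom(seed = 4)
  out <- postprocess_stack(ph$stack)
  for (i in seq_len(n_slices(ph$stack))) {
    cl <- out$result$chosen[[i]]
    sl <- out$stack$slices[[i]]
    expect_equal(sum(sl != 0L), cl$size)
    expect_equal(sl[cl$pixels], cl$labels)
    # at most one connected foreground component remains
    expect_lte(length(find_top_clusters(sl, k = 99L)$clusters), 1L)
  }
})

test_that("an all-skip result yields an all-background stack", {
  stack <- segmentation_stack(list(matrix(0L, 8, 8), matrix(0L, 8, 8)))
  out <- postprocess_stack(stack)
  expect_equal(out$result$skipped, c(0L, 1L))
  expect_true(all(vapply(out$stack$slices, function(m) all(m == 0L),
                         logical(1))))
})

test_that("post-processing is idempotent on its own output", {
  ph <- far_distractor_phantom(seed = 9)
  once <- postprocess_stack(ph$stack)
  twice <- postprocess_stack(once$stack)
  expect_identical(twice$stack$slices, once$stack$slices)
})

test_that("apply_selection validates shape agreement", {
  ph <- generate_phantom(phantom_config(seed = 1, n_slices = 3))
  other <- segmentation_stack(list(matrix(0L, 8, 8), matrix(0L, 8, 8)))
  res <- postprocess_stack(ph$stack)$result
  expect_error(apply_selection(other, res), "slice count")
})

test_that("selection configuration validates and loads from file", {
  expect_error(selection_config(overlap_threshold = 120), "0, 100")
  expect_error(selection_config(max_passes = 3), "fixed at 2")
  f <- tempfile(fileext = ".yaml")
  writeLines("overlap_threshold_percent: 35", f)
  expect_equal(read_selection_config(f)$overlap_threshold, 35)
})
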