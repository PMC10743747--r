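#' @name synthetic_phantom
#' @title Synthetic short-axis phantom stacks
#'
#' @description
#' Schematic left-ventricle segmentation stacks with known ground truth:
#' the ventricle is drawn as concentric regions (compacted external-layer
#' annulus, trabecular crown of radial spokes, internal-cavity disc) whose
#' radius tapers toward the stack ends, and hallucinations (a
#' right-ventricle mimic, stray external-layer fragments, tiny
#' trabecular blobs) can be stamped at known positions. Every drawn
#' hallucination pixel is recorded, so removal can be verified exactly,
#' and the analytic trabecular volume percentage of the true ventricle is
#' returned alongside the stack.
NULL

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a hallucination to stamp into a phantom
#'
#' Kinds: `rv_mimic` draws a small ventricle-like object (EL ring around an
#' IC core) — the most common real hallucination, a mislabelled right
#' ventricle; `el_fragment` draws a disc of pure external-layer label;
#' `mini_cluster` a tiny trabecular blob. The centre can jitter slice to
#' slice.
#'
#' @param kind one of `"rv_mimic"`, `"el_fragment"`, `"mini_cluster"`.
#' @param center `(row, col)` nominal centre.
#' @param radius radius in pixels.
#' @param jitter maximal per-slice uniform centre displacement, pixels.
#' @param slices 0-based slice indices to stamp (`NULL` = all slices).
#' @return an object of class `distractor_spec`.
#' @export
distractor_spec <- function(kind = c("rv_mimic", "el_fragment",
                                     "mini_cluster"),
                            center, radius, jitter = 0, slices = NULL) {
  kind <- match.arg(kind)
  if (radius <= 0) stop("distractor radius must be positive", call. = FALSE)
  structure(list(kind = kind, center = center, radius = radius,
                 jitter = jitter, slices = slices),
            class = "distractor_spec")
}

#' Phantom configuration
#'
#' Defaults draw a 200 x 200 px, 10-slice stack (matching the working
#' resolution of the segmentation network) with a ventricle of 50 px outer
#' radius, a 12 px compacted wall, a trabecular crown occupying the outer
#' 45 percent of the inner disc, and a 35 percent radius taper toward the
#' stack ends (end slices of real stacks show limited trabeculation).
#'
#' @param image_size side length in pixels.
#' @param n_slices number of slices.
#' @param lv_center `(row, col)` ventricle centre.
#' @param lv_outer_radius outer radius of the compacted wall, pixels.
#' @param el_thickness compacted-wall thickness, pixels.
#' @param tz_crown_fraction fraction of the inner-disc radius occupied by
#'   the trabecular crown, in (0, 1).
#' @param n_spokes number of trabecular spokes around the crown.
#' @param taper fractional radius shrink at the stack ends, in \[0, 1).
#' @param distractors list of [distractor_spec()]s.
#' @param seed integer seed controlling all phantom randomness (jitter).
#' @param geometry a [voxel_geometry()].
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 200L, n_slices = 10L,
                           lv_center = NULL, lv_outer_radius = 50,
                           el_thickness = 12, tz_crown_fraction = 0.45,
                           n_spokes = 12L, taper = 0.35,
                           distractors = list(), seed = 1L,
                           geometry = voxel_geometry()) {
  if (is.null(lv_center)) lv_center <- c(image_size / 2, image_size / 2)
  if (lv_outer_radius <= el_thickness)
    stop("lv_outer_radius must exceed el_thickness", call. = FALSE)
  if (tz_crown_fraction <= 0 || tz_crown_fraction >= 1)
    stop("tz_crown_fraction must lie in (0, 1)", call. = FALSE)
  if (taper < 0 || taper >= 1)
    stop("taper must lie in [0, 1)", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 n_slices = as.integer(n_slices), lv_center = lv_center,
                 lv_outer_radius = lv_outer_radius,
                 el_thickness = el_thickness,
                 tz_crown_fraction = tz_crown_fraction,
                 n_spokes = as.integer(n_spokes), taper = taper,
                 distractors = distractors, seed = as.integer(seed),
                 geometry = geometry),
            class = "phantom_config")
}

# Draw one schematic ventricle into `canvas`; returns the modified canvas.
draw_lv <- function(canvas, center, outer_r, el_thick, crown_frac,
                    n_spokes) {
  h <- nrow(canvas); w <- ncol(canvas)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  inner_r <- max(outer_r - el_thick, 2)
  canvas[d <= outer_r & d > inner_r] <- LABEL_EL
  inside <- d <= inner_r
  canvas[inside] <- LABEL_IC
  crown <- inside & d >= inner_r * (1 - crown_frac)
  theta <- atan2(cols - center[2], rows - center[1])  # (-pi, pi]
  wedge <- floor((theta + pi) / (2 * pi / (2 * n_spokes)))
  canvas[crown & wedge %% 2 == 0] <- LABEL_TZ
  canvas
}

draw_disc <- function(canvas, center, radius, label) {
  h <- nrow(canvas); w <- ncol(canvas)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  canvas[d <= radius] <- label
  canvas
}

#' Generate a phantom stack with known ground truth
#'
#' @param config a [phantom_config()].
#' @return list with `stack` (the [segmentation_stack()] including
#'   hallucinations), `ground_truth` (a selection result carrying the true
#'   ventricle cluster per slice), `hallucinations` (per-slice integer
#'   pixel indices of all stamped distractor pixels), `true_vt_percent`
#'   (analytic VT% of the true ventricle) and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  n <- config$n_slices
  sz <- config$image_size
  slices <- vector("list", n)
  truth <- vector("list", n)
  halluc <- vector("list", n)
  tz_total <- 0L; el_total <- 0L
  with_seed(config$seed, {
    for (s in seq_len(n)) {
      end_dist <- if (n > 1) abs(2 * (s - 1) / (n - 1) - 1) else 0
      scale <- 1 - config$taper * end_dist
      canvas <- matrix(0L, sz, sz)
      canvas <- draw_lv(canvas, config$lv_center,
                        config$lv_outer_radius * scale,
                        config$el_thickness, config$tz_crown_fraction,
                        config$n_spokes)
      true_px <- which(canvas > 0L)
      truth[[s]] <- new_cluster(true_px, canvas[true_px], c(sz, sz))
      tz_total <- tz_total + sum(canvas == LABEL_TZ)
      el_total <- el_total + sum(canvas == LABEL_EL)
      hal <- integer(0)
      for (spec in config$distractors) {
        on_slice <- is.null(spec$slices) || (s - 1L) %in% spec$slices
        jit <- if (spec$jitter > 0)
          round(runif(2, -spec$jitter, spec$jitter)) else c(0, 0)
        if (!on_slice) next
        ctr <- spec$center + jit
        stamp <- matrix(0L, sz, sz)
        stamp <- switch(spec$kind,
          rv_mimic = {
            ring <- max(2, round(spec$radius / 3))
            st <- draw_disc(stamp, ctr, spec$radius, LABEL_EL)
            draw_disc(st, ctr, spec$radius - ring, LABEL_IC)
          },
          el_fragment = draw_disc(stamp, ctr, spec$radius, LABEL_EL),
          mini_cluster = draw_disc(stamp, ctr, spec$radius, LABEL_TZ))
        px <- which(stamp > 0L)
        if (any(canvas[px] > 0L))
          stop(sprintf(
            "distractor '%s' overlaps existing foreground on slice %d",
            spec$kind, s - 1L), call. = FALSE)
        canvas[px] <- stamp[px]
        hal <- c(hal, px)
      }
      halluc[[s]] <- sort(hal)
      slices[[s]] <- canvas
    }
  })
  stack <- segmentation_stack(slices,
                              patient_id = sprintf("phantom%04d", config$seed),
                              geometry = config$geometry)
  gt <- structure(list(chosen = truth, skipped = integer(0),
                       iterations = 0L),
                  class = "selection_result")
  true_vt <- if (tz_total + el_total > 0)
    100 * tz_total / (tz_total + el_total) else 0
  list(stack = stack, ground_truth = gt, hallucinations = halluc,
       true_vt_percent = true_vt, config = config)
}

#' Degrade a stack with boundary label noise
#'
#' Emulates the raggedness of raw network output: a given fraction of the
#' pixels lying on region boundaries (pixels with a 4-neighbour of a
#' different label) are flipped to the label of a randomly chosen
#' 4-neighbour. Reproducible for a fixed seed; rate 0 is the identity.
#'
#' @param stack a [segmentation_stack()].
#' @param rate fraction of boundary pixels to flip, in \[0, 0.2\].
#' @param seed integer seed.
#' @return a degraded `segmentation_stack`.
#' @export
degrade_phantom <- function(stack, rate, seed = 1L) {
  if (rate < 0 || rate > 0.2)
    stop("rate must lie in [0, 0.2]", call. = FALSE)
  if (rate == 0) return(stack)
  with_seed(seed, {
    slices <- lapply(stack$slices, function(m) {
      h <- nrow(m); w <- ncol(m)
      shift <- function(dr, dc) {
        out <- m
        rs <- pmin(pmax(seq_len(h) + dr, 1L), h)
        cs <- pmin(pmax(seq_len(w) + dc, 1L), w)
        out[] <- m[rs, cs]
        out
      }
      nb <- list(shift(-1, 0), shift(1, 0), shift(0, -1), shift(0, 1))
      boundary <- which(nb[[1]] != m | nb[[2]] != m |
                        nb[[3]] != m | nb[[4]] != m)
      n_flip <- floor(rate * length(boundary))
      if (n_flip == 0L) return(m)
      targets <- sample(boundary, n_flip)
      pick <- sample.int(4L, n_flip, replace = TRUE)
      for (i in seq_len(n_flip))
        m[targets[i]] <- nb[[pick[i]]][targets[i]]
      m
    })
    segmentation_stack(slices, patient_id = stack$patient_id,
                       geometry = stack$geometry)
  })
}
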