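#' @name network_contracts
#' @title Architecture-level contracts of the segmentation network
#'
#' @description
#' The trainable networks themselves are out of scope here; this module
#' pins down the parts of the architecture that are checkable without
#' training: the shape contract of the 800-to-200-pixel
#' downsample/upsample wrapper, the deep-supervision loss combination used
#' to train the nested (U-Net++-style) decoder heads, and the
#' encoder-freeze partition used for transfer learning.
NULL

#' Deep-supervision loss weights
#'
#' The four intermediate decoder outputs carry weights 0.25, 0.25, 0.5 and
#' 0.75; the final output carries weight 1.
#' @export
deep_supervision_weights <- function() {
  c(w1 = 0.25, w2 = 0.25, w3 = 0.5, w4 = 0.75, w_output = 1.0)
}

#' Combined deep-supervision loss
#'
#' `L = 0.25 L1 + 0.25 L2 + 0.5 L3 + 0.75 L4 + L_output`, linear in every
#' component.
#'
#' @param l1,l2,l3,l4 intermediate-head losses, finite and non-negative.
#' @param l_output final-output loss, finite and non-negative.
#' @return the combined loss.
#' @export
deep_supervision_loss <- function(l1, l2, l3, l4, l_output) {
  v <- c(l1, l2, l3, l4, l_output)
  if (any(!is.finite(v)) || any(v < 0))
    stop("component losses must be finite and non-negative", call. = FALSE)
  w <- deep_supervision_weights()
  sum(w * v)
}

#' Wrapper specification for full-resolution segmentation
#'
#' The network segments at 200 x 200 but inputs arrive at 800 x 800: an
#' entry stage of two strided encoder blocks (each two 3x3 convolutions,
#' batch normalisation, leaky-ReLU with negative slope 0.01, stride 2)
#' downsamples 800 -> 400 -> 200, and an exit stage of two stride-2
#' transposed convolutions interspersed with two encoder-style blocks
#' upsamples 200 -> 400 -> 800, ending in 4 class maps.
#'
#' @return a list describing the wrapper stages.
#' @export
wrapper_spec <- function() {
  list(input_side = 800L, internal_side = 200L,
       downsample_blocks = 2L, upsample_blocks = 2L,
       block = list(convs = 2L, kernel = 3L, stride = 2L,
                    norm = "batch", activation = "leaky_relu",
                    negative_slope = 0.01),
       output_channels = 4L)
}

#' Shape contract of the resolution wrapper
#'
#' Two stride-2 stages on entry and exit mean the input side must be
#' divisible by 4; the internal working shape is a quarter of the input
#' side and the output restores the input shape.
#'
#' @param input_shape `(height, width)` in pixels.
#' @param spec wrapper description from [wrapper_spec()].
#' @return list with `internal` and `output` shapes.
#' @export
wrapper_shape_check <- function(input_shape, spec = wrapper_spec()) {
  h <- input_shape[1]; w <- input_shape[2]
  factor <- 2L^spec$downsample_blocks
  if (h %% factor != 0L || w %% factor != 0L)
    stop(sprintf("input shape (%d, %d) must be divisible by %d",
                 h, w, factor), call. = FALSE)
  list(internal = c(h %/% factor, w %/% factor), output = c(h, w))
}

#' Freeze the encoder path of a parameter inventory
#'
#' For transfer learning the encoder (the contracting path; for the nested
#' variant, the backbone column of the grid) is frozen and only decoder
#' parameters remain trainable. The inventory is a named list/vector
#' tagging each parameter group as `"encoder"` or `"decoder"`.
#'
#' @param inventory named character vector or list of `"encoder"` /
#'   `"decoder"` tags per parameter group.
#' @return data.frame with columns `group`, `path`, `trainable`; all
#'   encoder groups frozen, decoder groups untouched. Idempotent.
#' @export
freeze_encoder <- function(inventory) {
  tags <- unlist(inventory)
  if (is.null(names(tags)) || any(!nzchar(names(tags))))
    stop("every parameter group must be named", call. = FALSE)
  bad <- setdiff(unique(tags), c("encoder", "decoder"))
  if (length(bad) > 0L)
    stop(sprintf("untagged or unknown parameter group path(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  data.frame(group = names(tags), path = unname(tags),
             trainable = unname(tags) == "decoder",
             stringsAsFactors = FALSE)
}
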