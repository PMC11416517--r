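# Network architecture as data: four (or, when the input is too small for
# four, fewer) convolutional blocks -- Conv3D(3x3x3, stride 1, valid, ELU)
# -> channel-wise batch normalization -> 2x2x2 max pooling -- followed by
# flatten, dense(40, ELU), dropout(0.2), dense(10, ELU), dropout(0.2),
# dense(1, sigmoid). L2 coefficient 0.05 on every conv and dense weight,
# He initialization everywhere. The kernel/stride/padding combination is the
# unique one reproducing the published layer shapes and parameter counts.

conv_out_dim <- function(d, k = 3L, s = 1L) as.integer(floor((d - k) / s) + 1L)
pool_out_dim <- function(d, p = 2L) as.integer(d %/% p)

#' Construct the 3D CNN architecture specification
#'
#' Builds the layer-by-layer specification (shapes, parameter counts,
#' hyperparameters) for the binary cSVD classifier. `profile = "paper"` is
#' the full `(120, 128, 128, 1)` input with four conv blocks;
#' `profile = "reduced"` is a `(24, 32, 32, 1)` desk-scale input with the
#' same block structure (blocks that no longer fit a valid 3x3x3
#' convolution are dropped, leaving three).
#'
#' @param profile `"paper"` or `"reduced"`; ignored when `input_shape` is
#'   given explicitly.
#' @param input_shape Optional custom `(depth, height, width, channels)`.
#' @param filters Conv-block filter counts, truncated automatically when the
#'   spatial extent runs out.
#' @param dense_units Widths of the hidden fully connected layers.
#' @param dropout_rate Dropout after each hidden dense layer.
#' @param l2 L2 regularization coefficient on conv and dense weights.
#' @return A `voxcnn_architecture` object: `$layers` (block-level tibble, as
#'   in the published model summary) and `$ops` (expanded op list for the
#'   network engine).
#' @examples
#' arch <- architecture("paper")
#' count_parameters(arch)$total  # 534653
#' @export
architecture <- function(profile = c("paper", "reduced"), input_shape = NULL,
                         filters = c(8L, 16L, 32L, 64L),
                         dense_units = c(40L, 10L), dropout_rate = 0.2,
                         l2 = 0.05) {
  if (is.null(input_shape)) {
    profile <- match.arg(profile)
    input_shape <- if (profile == "paper") c(120L, 128L, 128L, 1L)
                   else c(24L, 32L, 32L, 1L)
  } else {
    profile <- "custom"
    stopifnot(length(input_shape) == 4)
  }
  ops <- list()
  layers <- list()
  shape <- as.integer(input_shape)
  layers[[1]] <- list(layer = "Input", kind = "input",
                      input_shape = shape, output_shape = shape,
                      params = 0L, trainable = 0L, non_trainable = 0L)
  blk <- 0L
  for (f in filters) {
    sp <- shape[1:3]
    if (any(sp - 2L < 2L)) break  # conv then pool must both fit
    blk <- blk + 1L
    cin <- shape[4]
    conv_shape <- c(vapply(sp, conv_out_dim, integer(1)), f)
    pool_shape <- c(vapply(conv_shape[1:3], pool_out_dim, integer(1)), f)
    p_conv <- f * (27L * cin + 1L)
    p_bn_tr <- 2L * f
    p_bn_nt <- 2L * f
    ops <- c(ops, list(
      list(kind = "conv3d", name = sprintf("conv%d", blk), filters = f,
           kernel = c(3L, 3L, 3L), in_channels = cin, activation = "elu",
           l2 = l2, input_shape = shape, output_shape = conv_shape),
      list(kind = "batchnorm", name = sprintf("bn%d", blk), channels = f,
           input_shape = conv_shape, output_shape = conv_shape),
      list(kind = "maxpool3d", name = sprintf("pool%d", blk), pool = 2L,
           input_shape = conv_shape, output_shape = pool_shape,
           block = sprintf("conv_block%d", blk))
    ))
    layers[[length(layers) + 1]] <- list(
      layer = sprintf("Conv Block%d", blk), kind = "conv_block",
      input_shape = shape, output_shape = pool_shape,
      params = p_conv + p_bn_tr + p_bn_nt,
      trainable = p_conv + p_bn_tr, non_trainable = p_bn_nt)
    shape <- pool_shape
  }
  flat <- as.integer(prod(shape))
  ops <- c(ops, list(list(kind = "flatten", name = "flatten",
                          input_shape = shape, output_shape = flat)))
  layers[[length(layers) + 1]] <- list(layer = "Flatten", kind = "flatten",
                                       input_shape = shape,
                                       output_shape = flat,
                                       params = 0L, trainable = 0L,
                                       non_trainable = 0L)
  width <- flat
  for (i in seq_along(dense_units)) {
    u <- dense_units[i]
    p <- width * u + u
    ops <- c(ops, list(
      list(kind = "dense", name = sprintf("fc%d", i), units = u,
           in_units = width, activation = "elu", l2 = l2,
           input_shape = width, output_shape = u),
      list(kind = "dropout", name = sprintf("drop%d", i), rate = dropout_rate,
           input_shape = u, output_shape = u)
    ))
    layers[[length(layers) + 1]] <- list(layer = "Fully Connected",
                                         kind = "dense", input_shape = width,
                                         output_shape = u, params = p,
                                         trainable = p, non_trainable = 0L)
    layers[[length(layers) + 1]] <- list(layer = "Dropout", kind = "dropout",
                                         input_shape = u, output_shape = u,
                                         params = 0L, trainable = 0L,
                                         non_trainable = 0L)
    width <- u
  }
  p <- width + 1L
  ops <- c(ops, list(list(kind = "dense", name = "output", units = 1L,
                          in_units = width, activation = "sigmoid", l2 = l2,
                          input_shape = width, output_shape = 1L)))
  layers[[length(layers) + 1]] <- list(layer = "Fully Connected",
                                       kind = "dense", input_shape = width,
                                       output_shape = 1L, params = p,
                                       trainable = p, non_trainable = 0L)
  layer_tbl <- tibble(
    layer = map_chr(layers, "layer"),
    kind = map_chr(layers, "kind"),
    input_shape = map(layers, "input_shape"),
    output_shape = map(layers, "output_shape"),
    params = map_int(layers, function(l) as.integer(l$params)),
    trainable = map_int(layers, function(l) as.integer(l$trainable)),
    non_trainable = map_int(layers, function(l) as.integer(l$non_trainable))
  )
  structure(list(profile = profile, input_shape = as.integer(input_shape),
                 layers = layer_tbl, ops = ops, l2 = l2),
            class = "voxcnn_architecture")
}

#' Count model parameters
#'
#' Per-layer and total parameter counts, recomputed from the chained shapes
#' (conv: `filters * (k^3 * in_channels + 1)`; batch normalization: 4 per
#' channel, 2 of them the non-trainable running statistics; dense:
#' `in * units + units`).
#'
#' @param arch A `voxcnn_architecture`.
#' @return A list with `total`, `trainable`, `non_trainable` and the
#'   per-layer tibble `per_layer`.
#' @export
count_parameters <- function(arch) {
  stopifnot(inherits(arch, "voxcnn_architecture"))
  # verify the shape chain before trusting the counts
  for (i in seq_len(nrow(arch$layers) - 1)) {
    a <- arch$layers$output_shape[[i]]
    b <- arch$layers$input_shape[[i + 1]]
    if (!identical(as.integer(a), as.integer(b))) {
      abort(sprintf("shape chain broken entering layer %d (%s)",
                    i + 1, arch$layers$layer[i + 1]))
    }
  }
  list(
    total = sum(arch$layers$params),
    trainable = sum(arch$layers$trainable),
    non_trainable = sum(arch$layers$non_trainable),
    per_layer = arch$layers
  )
}

.fmt_shape <- function(s) {
  if (length(s) == 1) sprintf("(None, %d)", s)
  else sprintf("(None, %s)", paste(s, collapse = ", "))
}

#' Model summary table
#'
#' The layer table in the published format: layer name, input shape, output
#' shape, parameter count, plus total/trainable/non-trainable rows.
#'
#' @param arch A `voxcnn_architecture` (default: the full paper profile).
#' @return A tibble with columns `layer`, `input_shape`, `output_shape`,
#'   `parameters` (character, to accommodate the total rows).
#' @export
model_table <- function(arch = architecture("paper")) {
  pc <- count_parameters(arch)
  rows <- tibble(
    layer = arch$layers$layer,
    input_shape = map_chr(arch$layers$input_shape, .fmt_shape),
    output_shape = map_chr(arch$layers$output_shape, .fmt_shape),
    parameters = format(arch$layers$params, big.mark = ",", trim = TRUE)
  )
  totals <- tibble(
    layer = c("Total Parameters", "Trainable Parameters",
              "Non-Trainable Parameters"),
    input_shape = "", output_shape = "",
    parameters = format(c(pc$total, pc$trainable, pc$non_trainable),
                        big.mark = ",", trim = TRUE)
  )
  bind_rows(rows, totals)
}

#' Print the model summary table
#'
#' @param arch A `voxcnn_architecture`.
#' @return The summary tibble, invisibly.
#' @export
print_model_table <- function(arch = architecture("paper")) {
  tbl <- model_table(arch)
  print(as.data.frame(tbl), right = FALSE, row.names = FALSE)
  invisible(tbl)
}

#' @export
print.voxcnn_architecture <- function(x, ...) {
  cat(sprintf("<voxcnn_architecture profile=%s input=(%s)>\n", x$profile,
              paste(x$input_shape, collapse = ", ")))
  print_model_table(x)
  invisible(x)
}

#' @rdname tidy.voxcnn_cv
#' @export
tidy.voxcnn_architecture <- function(x, ...) {
  mutate(x$layers,
         input_shape = map_chr(.data$input_shape, .fmt_shape),
         output_shape = map_chr(.data$output_shape, .fmt_shape))
}
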