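# Volumetric Grad-CAM: channel weights are the spatial means of the
# pre-sigmoid logit gradient at a convolutional block's output; the CAM is
# the rectified weighted sum of the feature maps, upsampled trilinearly to
# the input grid and max-normalized to [0, 1].

.cam_layers <- function(model) {
  ops <- model$arch$ops
  idx <- which(map_chr(ops, function(o) o$block %||% "") != "")
  setNames(idx, map_chr(ops[idx], "block"))
}

# default CAM layer: the deepest block whose feature map still has at least
# two cells along every spatial axis (a 1-cell axis cannot localize at all);
# on the full-profile model this is block 4, output (5, 6, 6, 64)
.cam_default_layer <- function(model, layers) {
  ok <- vapply(layers, function(i) {
    min(model$arch$ops[[i]]$output_shape[1:3]) >= 2
  }, logical(1))
  if (any(ok)) names(layers)[max(which(ok))] else names(layers)[length(layers)]
}

# rectified, gradient-weighted feature-map combination (the Grad-CAM core)
cam_from_features <- function(features, grads) {
  stopifnot(identical(dim(features), dim(grads)))
  ch_w <- apply(grads, 4, mean)
  spatial <- dim(features)[1:3]
  cam <- matrix(features, prod(spatial)) %*% ch_w
  array(pmax(cam, 0), spatial)
}

# half-pixel-centre linear interpolation matrix (dst x src)
.lin_weights <- function(src, dst) {
  M <- matrix(0, dst, src)
  for (t in seq_len(dst)) {
    p <- (t - 0.5) * src / dst - 0.5
    i0 <- floor(p)
    w <- p - i0
    a <- min(max(i0, 0), src - 1) + 1
    b <- min(max(i0 + 1, 0), src - 1) + 1
    M[t, a] <- M[t, a] + (1 - w)
    M[t, b] <- M[t, b] + w
  }
  M
}

# separable trilinear upsampling of a 3D array
upsample3_linear <- function(a, out_dim) {
  d <- dim(a)
  for (ax in 1:3) {
    M <- .lin_weights(dim(a)[1], out_dim[ax])
    m <- M %*% matrix(a, dim(a)[1])
    a <- aperm(array(m, c(out_dim[ax], dim(a)[2], dim(a)[3])), c(2, 3, 1))
  }
  a
}

#' Grad-CAM relevance volume for one stack
#'
#' Computes the gradient of the pre-sigmoid class logit with respect to the
#' chosen convolutional block's output, averages it spatially per channel,
#' forms the rectified weighted sum of the feature maps, upsamples it
#' trilinearly to the input spatial grid, and max-normalizes to `[0, 1]`
#' (an identically zero map is left at zero).
#'
#' @param model A `voxcnn_model` (or `voxcnn_fit`).
#' @param stack A `volume_stack` matching the model input.
#' @param target_layer Block identifier (`"conv_block1"`, ...); default is
#'   the deepest block whose feature map retains at least two cells along
#'   every spatial axis (block 4, shape `(5, 6, 6, 64)`, on the full
#'   profile).
#' @return A `cam_map`: 3D array `(depth, height, width)` in `[0, 1]` with
#'   attributes `source_layer`, `predicted_class`, `raw_feature_shape`.
#' @export
grad_cam <- function(model, stack, target_layer = NULL) {
  if (inherits(model, "voxcnn_fit")) model <- model$model
  stopifnot(inherits(model, "voxcnn_model"), inherits(stack, "volume_stack"))
  layers <- .cam_layers(model)
  target_layer <- target_layer %||% .cam_default_layer(model, layers)
  if (!target_layer %in% names(layers)) {
    abort(sprintf("unknown layer '%s'; valid layers: %s", target_layer,
                  paste(names(layers), collapse = ", ")))
  }
  op_idx <- layers[[target_layer]]
  fw <- nn_forward(model, stack_batch(stack), training = FALSE,
                   capture = op_idx)
  bw <- nn_backward(model, fw$caches, dlogit = 1, stop_at = op_idx,
                    param_grads = FALSE)
  fdim <- dim(fw$acts[[as.character(op_idx)]])
  features <- array(fw$acts[[as.character(op_idx)]], fdim[1:4])
  grads <- array(bw$dx, fdim[1:4])
  cam <- cam_from_features(features, grads)
  cam <- upsample3_linear(cam, dim(stack)[1:3])
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  structure(cam, source_layer = target_layer,
            predicted_class = as.integer(sigmoid(fw$logit) >= 0.5),
            raw_feature_shape = fdim[1:4],
            class = "cam_map")
}

#' @export
print.cam_map <- function(x, ...) {
  cat(sprintf("<cam_map %s  layer=%s  predicted=%d  max=%.3f>\n",
              paste(dim(x), collapse = "x"), attr(x, "source_layer"),
              attr(x, "predicted_class"), max(x)))
  invisible(x)
}

.heat_rgb <- function(v) {
  # black -> red -> yellow ramp
  r <- pmin(1, 2 * v)
  g <- pmax(0, 2 * v - 1)
  list(r = r, g = g, b = v * 0)
}

#' Render per-slice Grad-CAM overlays as PNG files
#'
#' One raster per requested slice: grayscale anatomy with a red-yellow heat
#' overlay whose opacity follows the CAM value. Slices with an all-zero CAM
#' render as plain grayscale; zero-padded slices render black.
#'
#' @param cam A `cam_map`.
#' @param stack The aligned `volume_stack`.
#' @param out_dir Output directory (created if needed).
#' @param slice_indices 1-based depth indices; default: four slices evenly
#'   spread over the real (non-padded) depth range.
#' @param alpha Maximum overlay opacity.
#' @return Paths of the written files, invisibly.
#' @export
render_overlays <- function(cam, stack, out_dir, slice_indices = NULL,
                            alpha = 0.6) {
  stopifnot(inherits(cam, "cam_map"), inherits(stack, "volume_stack"))
  depth <- dim(stack)[1]
  n_real <- attr(stack, "n_real_slices")
  slice_indices <- slice_indices %||%
    unique(round(seq(1, n_real, length.out = 4)))
  if (any(slice_indices < 1 | slice_indices > depth)) {
    abort(sprintf("slice indices must lie in [1, %d]", depth))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  real <- stack[seq_len(n_real), , , 1, drop = FALSE]
  rng <- range(real)
  paths <- character(0)
  for (i in slice_indices) {
    n <- dim(stack)[2]
    if (i > n_real || diff(rng) == 0) {
      gray <- matrix(0, n, dim(stack)[3])
      camv <- matrix(0, n, dim(stack)[3])
    } else {
      gray <- (stack[i, , , 1] - rng[1]) / diff(rng)
      camv <- cam[i, , ]
    }
    heat <- .heat_rgb(camv)
    a <- alpha * camv
    img <- array(0, c(nrow(gray), ncol(gray), 3))
    img[, , 1] <- gray * (1 - a) + heat$r * a
    img[, , 2] <- gray * (1 - a) + heat$g * a
    img[, , 3] <- gray * (1 - a) + heat$b * a
    f <- file.path(out_dir, sprintf("slice_%03d.png", i))
    png::writePNG(img, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Plot one CAM slice
#'
#' @param object A `cam_map`.
#' @param slice 1-based depth index.
#' @param ... Unused.
#' @return A ggplot raster of the relevance slice.
#' @rdname autoplot.voxcnn_fit
#' @export
autoplot.cam_map <- function(object, slice = 1L, ...) {
  m <- object[slice, , ]
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$relevance <- as.numeric(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$relevance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "yellow",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}
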