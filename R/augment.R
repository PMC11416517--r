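# Training-pool augmentation: in-plane spatial transforms applied slice-wise
# to each real slice of a volume stack (zero-padded slices stay zero, and
# out-of-bounds regions are filled with the padding value 0).

.aug_ranges <- list(
  translation = list(shift_frac = 0.10),   # of the in-plane extent
  shear = list(max_deg = 10),
  rotation = list(max_deg = 15),
  affine = list(rot_deg = 10, scale_frac = 0.10)
)

# 2x2 linear map + centre-preserving offset in EBImage's forward convention
.aug_matrix <- function(op, params, n) {
  A <- diag(2)
  t_extra <- c(0, 0)
  if (op == "translation") {
    t_extra <- c(params$du, params$dv)
  } else if (op == "rotation") {
    th <- params$deg * pi / 180
    A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  } else if (op == "shear") {
    A <- matrix(c(1, tan(params$deg * pi / 180), 0, 1), 2, 2)
  } else if (op == "affine") {
    th <- params$deg * pi / 180
    A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) %*%
      diag(c(params$sx, params$sy))
  }
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  rbind(A, ctr - ctr %*% A + t_extra)
}

.draw_params <- function(op, n) {
  r <- .aug_ranges[[op]]
  switch(op,
    translation = list(du = runif(1, -r$shift_frac, r$shift_frac) * n,
                       dv = runif(1, -r$shift_frac, r$shift_frac) * n),
    shear = list(deg = runif(1, -r$max_deg, r$max_deg)),
    rotation = list(deg = runif(1, -r$max_deg, r$max_deg)),
    affine = list(deg = runif(1, -r$rot_deg, r$rot_deg),
                  sx = runif(1, 1 - r$scale_frac, 1 + r$scale_frac),
                  sy = runif(1, 1 - r$scale_frac, 1 + r$scale_frac))
  )
}

.check_params <- function(op, params, n) {
  r <- .aug_ranges[[op]]
  ok <- switch(op,
    translation = abs(params$du) <= r$shift_frac * n + 1e-9 &&
      abs(params$dv) <= r$shift_frac * n + 1e-9,
    shear = abs(params$deg) <= r$max_deg + 1e-9,
    rotation = abs(params$deg) <= r$max_deg + 1e-9,
    affine = abs(params$deg) <= r$rot_deg + 1e-9 &&
      abs(params$sx - 1) <= r$scale_frac + 1e-9 &&
      abs(params$sy - 1) <= r$scale_frac + 1e-9
  )
  if (!isTRUE(ok)) {
    abort(sprintf("augment_volume: %s parameters outside configured ranges", op))
  }
}

#' Apply one spatial augmentation to a volume stack
#'
#' Applies the transform in-plane to every real slice (bilinear
#' interpolation, zero fill); zero-padded tail slices are untouched, so the
#' output keeps the exact stack shape and padding contract. Deterministic
#' under `seed` when parameters are drawn.
#'
#' @param stack A `volume_stack`.
#' @param op One of `"translation"`, `"shear"`, `"rotation"`, `"affine"`.
#' @param params Optional explicit parameters (`du`/`dv` pixels for
#'   translation; `deg` for shear/rotation; `deg`, `sx`, `sy` for affine);
#'   must lie within the configured ranges. Drawn uniformly from those
#'   ranges when omitted.
#' @param seed Seed for drawn parameters.
#' @return The augmented `volume_stack` (attribute `augmented = op`).
#' @export
augment_volume <- function(stack, op = c("translation", "shear", "rotation",
                                         "affine"),
                           params = NULL, seed = NULL) {
  op <- match.arg(op)
  stopifnot(inherits(stack, "volume_stack"))
  d <- dim(stack)
  n <- d[2]
  if (is.null(params)) {
    params <- if (is.null(seed)) .draw_params(op, n)
              else with_local_seed(seed, .draw_params(op, n))
  }
  .check_params(op, params, n)
  m <- .aug_matrix(op, params, n)
  out <- unclass(stack)
  n_real <- attr(stack, "n_real_slices")
  for (i in seq_len(n_real)) {
    out[i, , , 1] <- EBImage::affine(stack[i, , , 1], m, filter = "bilinear",
                                     output.dim = c(n, n), bg.col = 0,
                                     antialias = FALSE)
  }
  res <- new_volume_stack(out, patient_id = attr(stack, "patient_id"),
                          label = attr(stack, "label"),
                          n_real_slices = n_real)
  attr(res, "augmented") <- op
  res
}

#' Per-class augmentation policy
#'
#' Which augmentation operations are applied to each class when balancing
#' the training pool. Two presets mirror the study's protocols:
#' `"rotation_affine"` (rotation on both classes, affine on the control
#' class -- the headline recipe) and `"shear_balance"` (shear on both
#' classes, translation and affine on the control class).
#'
#' @param preset Preset name, or `NULL` to pass explicit op lists.
#' @param diseased,control Character vectors of ops for each class.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(preset = c("rotation_affine", "shear_balance"),
                                diseased = NULL, control = NULL) {
  if (is.null(preset)) {
    pol <- list(diseased = diseased %||% character(0),
                control = control %||% character(0))
  } else {
    preset <- match.arg(preset)
    pol <- switch(preset,
      rotation_affine = list(diseased = "rotation",
                             control = c("rotation", "affine")),
      shear_balance = list(diseased = "shear",
                           control = c("translation", "affine", "shear")))
  }
  ok <- c("translation", "shear", "rotation", "affine")
  stopifnot(all(unlist(pol) %in% ok))
  structure(pol, class = "augmentation_policy")
}

#' Expand a training pool with class-balancing augmented copies
#'
#' Every original stack is retained; each gains one augmented copy per
#' operation listed for its class. With the study's 2:1 class imbalance and
#' the `"shear_balance"` policy (one extra op for the majority class, three
#' for the minority), the classes come out balanced. Augmented samples keep
#' their source's label and a provenance link (`source_id`).
#'
#' @param cohort A `stack_cohort`.
#' @param policy An [augmentation_policy()].
#' @param seed Integer seed.
#' @return The expanded `stack_cohort`.
#' @export
balance_with_augmentation <- function(cohort, policy, seed = 1L) {
  stopifnot(inherits(cohort, "stack_cohort"),
            inherits(policy, "augmentation_policy"))
  stacks <- cohort$stacks
  info_rows <- list(cohort$info)
  for (i in seq_len(nrow(cohort$info))) {
    lb <- cohort$info$label[i]
    ops <- policy[[lb]] %||% character(0)
    for (j in seq_along(ops)) {
      sid <- sprintf("%s_aug_%s", cohort$info$sample_id[i], ops[j])
      stacks[[sid]] <- augment_volume(cohort$stacks[[i]], ops[j],
                                      seed = seed + 1009L * i + j)
      info_rows[[length(info_rows) + 1L]] <- tibble(
        sample_id = sid, patient_id = cohort$info$patient_id[i],
        label = lb, augmented = TRUE,
        source_id = cohort$info$source_id[i])
    }
  }
  info <- bind_rows(info_rows)
  stack_cohort(stacks[info$sample_id], info)
}
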