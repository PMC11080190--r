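#' Letterbox an image to a square model input
#'
#' Scales the image so its longer dimension equals `side` while preserving
#' the aspect ratio, then pads the shorter dimension with black (zero)
#' pixels to produce a `side x side` output. Aspect ratio carries
#' anatomical information (e.g. crown/root proportions), so it is never
#' distorted. Padding is split symmetrically, with an odd leftover pixel
#' placed on the trailing edge.
#'
#' @param img Image array `h x w x 3`.
#' @param side Output side length in pixels (default 224).
#' @return A `side x side x 3` array.
#' @export
resize_pad <- function(img, side = 224L) {
  side <- as.integer(side)
  if (side < 1) stop("side must be >= 1")
  d <- dim(img)
  h <- d[1]
  w <- d[2]
  if (h < 1 || w < 1) stop("zero-area input image")
  s <- side / max(h, w)
  out_h <- max(1L, as.integer(round(h * s)))
  out_w <- max(1L, as.integer(round(w * s)))
  if (out_h == h && out_w == w) {
    content <- img
  } else {
    inv <- function(r, c) {
      list((r - 0.5) * (h / out_h) + 0.5, (c - 0.5) * (w / out_w) + 0.5)
    }
    content <- warp_image(img, inv, out_h, out_w, fill = 0)
  }
  canvas <- array(0, dim = c(side, side, d[3]))
  top <- (side - out_h) %/% 2
  left <- (side - out_w) %/% 2
  canvas[top + seq_len(out_h), left + seq_len(out_w), ] <- content
  canvas
}

#' Training-time augmentation policy
#'
#' Four spatial transforms are applied independently at train time, each
#' with its own probability: rotation, dropout (a coarse rectangular
#' occlusion of the image, i.e. cutout), perspective distortion, and a
#' random affine transform. Defaults follow the probabilities 0.5, 0.2,
#' 0.2, 0.2; the magnitudes are package defaults and fully configurable.
#'
#' @param p_rotation,p_dropout,p_perspective,p_affine Application
#'   probabilities in `[0, 1]`.
#' @param rotation_deg Maximum absolute rotation angle, degrees.
#' @param dropout_frac Maximum occluded area as a fraction of the image.
#' @param perspective_scale Corner displacement as a fraction of the image
#'   side.
#' @param affine_translate Maximum translation as a fraction of each
#'   dimension.
#' @param affine_scale Length-2 range of isotropic scale factors.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(p_rotation = 0.5, p_dropout = 0.2,
                                p_perspective = 0.2, p_affine = 0.2,
                                rotation_deg = 15, dropout_frac = 0.1,
                                perspective_scale = 0.2,
                                affine_translate = 0.1,
                                affine_scale = c(0.9, 1.1)) {
  probs <- c(p_rotation, p_dropout, p_perspective, p_affine)
  if (any(probs < 0 | probs > 1)) {
    stop("augmentation probabilities must lie in [0, 1]")
  }
  structure(
    list(
      p_rotation = p_rotation, p_dropout = p_dropout,
      p_perspective = p_perspective, p_affine = p_affine,
      rotation_deg = rotation_deg, dropout_frac = dropout_frac,
      perspective_scale = perspective_scale,
      affine_translate = affine_translate,
      affine_scale = affine_scale
    ),
    class = "augmentation_policy"
  )
}

#' A policy that never transforms (evaluation-path equivalent)
#' @export
no_augmentation <- function() {
  augmentation_policy(
    p_rotation = 0, p_dropout = 0,
    p_perspective = 0, p_affine = 0
  )
}

#' Apply the stochastic augmentations to one image
#'
#' Each transform is applied independently with its policy probability.
#' Fully deterministic given `seed`; output dimensions always equal input
#' dimensions. Degenerate magnitudes reduce to the identity.
#'
#' @param img Image array `h x w x 3`.
#' @param policy An [augmentation_policy()].
#' @param seed Integer seed for this image's draws.
#' @return Augmented image array of identical dimensions.
#' @export
augment <- function(img, policy = augmentation_policy(), seed = 0L) {
  stopifnot(inherits(policy, "augmentation_policy"))
  h <- dim(img)[1]
  w <- dim(img)[2]
  withr::with_seed(as.integer(seed), {
    apply_flags <- stats::runif(4) < c(
      policy$p_rotation, policy$p_dropout,
      policy$p_perspective, policy$p_affine
    )
    if (apply_flags[1] && policy$rotation_deg > 0) {
      angle <- stats::runif(1, -policy$rotation_deg, policy$rotation_deg)
      img <- rotate_image(img, angle)
    }
    if (apply_flags[2] && policy$dropout_frac > 0) {
      img <- cutout_image(img, policy$dropout_frac)
    }
    if (apply_flags[3] && policy$perspective_scale > 0) {
      img <- perspective_image(img, policy$perspective_scale)
    }
    if (apply_flags[4]) {
      img <- affine_image(img, policy$affine_translate, policy$affine_scale)
    }
  })
  img
}

# Rotation about the image center, output size preserved, black fill.
rotate_image <- function(img, angle_deg) {
  h <- dim(img)[1]
  w <- dim(img)[2]
  th <- angle_deg * pi / 180
  cr <- (h + 1) / 2
  cc <- (w + 1) / 2
  inv <- function(r, c) {
    dr <- r - cr
    dc <- c - cc
    list(
      cr + cos(th) * dr - sin(th) * dc,
      cc + sin(th) * dr + cos(th) * dc
    )
  }
  warp_image(img, inv, h, w, fill = 0)
}

# Coarse occlusion: one black rectangle of area <= max_frac of the image.
cutout_image <- function(img, max_frac) {
  h <- dim(img)[1]
  w <- dim(img)[2]
  frac <- stats::runif(1, 0, max_frac)
  ch <- max(1L, as.integer(round(h * sqrt(frac))))
  cw <- max(1L, as.integer(round(w * sqrt(frac))))
  r0 <- sample.int(h - ch + 1L, 1L)
  c0 <- sample.int(w - cw + 1L, 1L)
  img[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), ] <- 0
  img
}

# Random projective distortion: the four output corners map to input
# corners displaced inward/outward by up to `scale` of each dimension.
perspective_image <- function(img, scale) {
  h <- dim(img)[1]
  w <- dim(img)[2]
  corners_out <- cbind(c(1, 1, h, h), c(1, w, 1, w))
  jitter_r <- stats::runif(4, -scale * h, scale * h)
  jitter_c <- stats::runif(4, -scale * w, scale * w)
  corners_in <- corners_out + cbind(jitter_r, jitter_c)
  H <- solve_homography(corners_out, corners_in)
  inv <- function(r, c) {
    den <- H[3, 1] * r + H[3, 2] * c + H[3, 3]
    list(
      (H[1, 1] * r + H[1, 2] * c + H[1, 3]) / den,
      (H[2, 1] * r + H[2, 2] * c + H[2, 3]) / den
    )
  }
  warp_image(img, inv, h, w, fill = 0)
}

# Random affine: isotropic scale + translation about the center.
affine_image <- function(img, max_translate, scale_range) {
  h <- dim(img)[1]
  w <- dim(img)[2]
  s <- stats::runif(1, scale_range[1], scale_range[2])
  tr <- stats::runif(1, -max_translate, max_translate) * h
  tc <- stats::runif(1, -max_translate, max_translate) * w
  cr <- (h + 1) / 2
  cc <- (w + 1) / 2
  inv <- function(r, c) {
    list(cr + (r - cr - tr) / s, cc + (c - cc - tc) / s)
  }
  warp_image(img, inv, h, w, fill = 0)
}

# Direct linear transform for the homography mapping (r, c) -> (r', c')
# through 4 point correspondences; returns the 3x3 matrix.
solve_homography <- function(from, to) {
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    r <- from[i, 1]
    c <- from[i, 2]
    rp <- to[i, 1]
    cp <- to[i, 2]
    A[2 * i - 1, ] <- c(r, c, 1, 0, 0, 0, -r * rp, -c * rp)
    A[2 * i, ] <- c(0, 0, 0, r, c, 1, -r * cp, -c * cp)
    b[2 * i - 1] <- rp
    b[2 * i] <- cp
  }
  sol <- solve(A, b)
  matrix(c(sol, 1), 3, 3, byrow = TRUE)
}
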