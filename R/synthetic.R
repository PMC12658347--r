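# Seeded synthetic dermoscopy generator.
#
# Emulates the structure of dermoscopic lesion datasets — a single irregular,
# quasi-elliptical lesion of variable scale and contrast on a textured
# skin-tone background, with optional dark hair strokes and a multiplicative
# illumination gradient — so that every pipeline stage can be exercised
# without external data. Lesion boundaries are radial-Fourier perturbed
# circles r(theta) = r0 * (1 + sum_k a_k cos(k theta + phi_k)): smooth and
# star-convex, which guarantees a single 4-connected mask component with
# controllable irregularity. Not modelled: multi-lesion scenes, ruler or gel
# artifacts, photorealistic chromophore distributions.

#' Specification of the synthetic lesion image distribution
#'
#' @param image_size integer pair `(H, W)`.
#' @param radius_frac range of the base lesion radius as a fraction of
#'   `min(H, W)`.
#' @param n_harmonics number of radial Fourier harmonics on the boundary.
#' @param harmonic_amp total amplitude budget `sum(a_k)` of the boundary
#'   perturbation (must stay below 1 to keep the radius positive).
#' @param skin_color,lesion_jitter base skin RGB and per-channel jitter s.d.
#' @param contrast mean intensity gap between skin and lesion.
#' @param texture_sigma s.d. of the per-pixel skin texture noise.
#' @param hair_count integer range of overlaid dark hair strokes.
#' @param illumination amplitude of the multiplicative linear illumination
#'   gradient.
#' @param seed integer seed for [generate_dataset()].
#' @return a `lesion_spec` list.
#' @export
lesion_spec <- function(image_size = c(256L, 256L),
                        radius_frac = c(0.15, 0.40),
                        n_harmonics = 5L,
                        harmonic_amp = 0.3,
                        skin_color = c(0.80, 0.62, 0.55),
                        lesion_jitter = 0.04,
                        contrast = 0.35,
                        texture_sigma = 0.03,
                        hair_count = c(0L, 8L),
                        illumination = 0.1,
                        seed = 1L) {
  if (any(radius_frac <= 0) || any(radius_frac >= 0.5)) {
    stop("radius_frac must lie inside (0, 0.5)", call. = FALSE)
  }
  if (harmonic_amp < 0 || harmonic_amp >= 1) {
    stop("harmonic_amp must lie in [0, 1)", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 radius_frac = radius_frac,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_amp = harmonic_amp,
                 skin_color = skin_color,
                 lesion_jitter = lesion_jitter,
                 contrast = contrast,
                 texture_sigma = texture_sigma,
                 hair_count = as.integer(hair_count),
                 illumination = illumination,
                 seed = as.integer(seed)),
            class = "lesion_spec")
}

#' Generate one binary lesion mask
#'
#' Uses the current RNG state; seed externally (or via [generate_dataset()])
#' for reproducibility.
#'
#' @param spec a [lesion_spec()].
#' @return integer matrix `(H, W)` of 0/1 with a single 4-connected
#'   foreground component.
#' @export
generate_lesion_mask <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  r0 <- stats::runif(1, spec$radius_frac[1], spec$radius_frac[2]) * min(H, W)
  if (r0 <= 0) stop("degenerate lesion radius", call. = FALSE)
  nk <- spec$n_harmonics
  if (nk > 0 && spec$harmonic_amp > 0) {
    w <- stats::runif(nk)
    a <- spec$harmonic_amp * w / sum(w)
    phi <- stats::runif(nk, 0, 2 * pi)
  } else {
    a <- numeric(0); phi <- numeric(0)
  }
  # keep the lesion inside the frame where possible; on small frames the
  # centre stays centred and the boundary may touch the border
  margin_y <- min(r0 * (1 + sum(a)) + 2, (H - 1) / 2)
  margin_x <- min(r0 * (1 + sum(a)) + 2, (W - 1) / 2)
  cy <- stats::runif(1, margin_y, H - margin_y)
  cx <- stats::runif(1, margin_x, W - margin_x)
  dy <- matrix(seq_len(H) - cy, H, W)
  dx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  th <- atan2(dy, dx)
  rb <- r0
  for (k in seq_along(a)) rb <- rb + r0 * a[k] * cos(k * th + phi[k])
  mask <- (dy * dy + dx * dx) <= rb * rb
  matrix(as.integer(mask), H, W)
}

# one dark hair stroke: a random cubic Bezier curve stamped with soft
# (distance-weighted) intensity attenuation around its sampled points
draw_hair <- function(img, spec) {
  H <- dim(img)[2]; W <- dim(img)[3]
  ctrl <- cbind(stats::runif(4, 1, H), stats::runif(4, 1, W))
  t <- seq(0, 1, length.out = 3L * max(H, W))
  b <- function(col) {
    (1 - t)^3 * ctrl[1, col] + 3 * (1 - t)^2 * t * ctrl[2, col] +
      3 * (1 - t) * t^2 * ctrl[3, col] + t^3 * ctrl[4, col]
  }
  y <- b(1); x <- b(2)
  shade <- stats::runif(1, 0.55, 0.85)           # fraction of light removed
  tint <- c(1, 0.92, 0.85)                       # hair is slightly warm-dark
  # anti-aliasing: spread each sample over its 4 nearest pixels with
  # bilinear weights
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  for (k in 0:3) {
    yy <- y0 + k %% 2; xx <- x0 + k %/% 2
    wgt <- (if (k %% 2 == 0) 1 - fy else fy) * (if (k %/% 2 == 0) 1 - fx else fx)
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    idx <- cbind(yy[ok], xx[ok])
    att <- 1 - shade * pmin(wgt[ok], 1)
    for (c in 1:3) {
      f <- att^tint[c]
      img[cbind(c, idx)] <- img[cbind(c, idx)] * f
    }
  }
  img
}

#' Render an RGB dermoscopy-style image for a lesion mask
#'
#' Background pixels are skin-toned with Gaussian texture noise, lesion
#' pixels are darker by `contrast`, optional hair strokes are overlaid, and a
#' multiplicative linear illumination gradient is applied before clipping to
#' `[0, 1]`.
#'
#' @param mask binary matrix `(H, W)`.
#' @param spec a [lesion_spec()].
#' @return numeric array `(3, H, W)` in `[0, 1]`.
#' @export
render_image <- function(mask, spec) {
  H <- nrow(mask); W <- ncol(mask)
  if (!identical(c(H, W), as.integer(spec$image_size))) {
    stop("mask size does not match spec image_size", call. = FALSE)
  }
  skin <- pmin(pmax(spec$skin_color +
                      stats::rnorm(3, 0, spec$lesion_jitter), 0), 1)
  lesion <- pmax(skin - spec$contrast +
                   stats::rnorm(3, 0, spec$lesion_jitter / 2), 0)
  img <- array(0, c(3, H, W))
  inside <- mask > 0
  for (c in 1:3) {
    plane <- matrix(skin[c], H, W)
    plane[inside] <- lesion[c]
    if (spec$texture_sigma > 0) {
      plane <- plane + matrix(stats::rnorm(H * W, 0, spec$texture_sigma), H, W)
    }
    img[c, , ] <- plane
  }
  nh <- if (spec$hair_count[2] > 0) {
    sample(spec$hair_count[1]:spec$hair_count[2], 1)
  } else 0L
  if (nh > 0) for (i in seq_len(nh)) img <- draw_hair(img, spec)
  if (spec$illumination > 0) {
    ang <- stats::runif(1, 0, 2 * pi)
    gy <- matrix((seq_len(H) - (H + 1) / 2) / H, H, W)
    gx <- matrix((seq_len(W) - (W + 1) / 2) / W, H, W, byrow = TRUE)
    field <- 1 + 2 * spec$illumination * (cos(ang) * gx + sin(ang) * gy)
    for (c in 1:3) img[c, , ] <- img[c, , ] * field
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` image PNGs under `out_dir/images/` and matching 0/255 mask PNGs
#' under `out_dir/masks/`, named by zero-padded index, plus a
#' `manifest.json` recording the spec and seed. Byte-identical under a fixed
#' seed.
#'
#' @param n number of image/mask pairs.
#' @param spec a [lesion_spec()]; its `seed` drives all randomness.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
generate_dataset <- function(n, spec = lesion_spec(), out_dir) {
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  for (d in c(img_dir, msk_dir)) {
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE)) {
      stop("cannot create output directory: ", d, call. = FALSE)
    }
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(spec$seed)
  stems <- character(n)
  for (i in seq_len(n)) {
    stem <- sprintf("%04d", i)
    mask <- generate_lesion_mask(spec)
    img <- render_image(mask, spec)
    png::writePNG(aperm(img, c(2, 3, 1)), file.path(img_dir, paste0(stem, ".png")))
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                  file.path(msk_dir, paste0(stem, ".png")))
    stems[i] <- stem
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  manifest <- list(n = n, seed = spec$seed, stems = as.list(stems),
                   spec = unclass(spec))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
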