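# Synthetic fiber-textured phase maps.
#
# Stand-in for internal-capsule white matter: a Poisson number of straight
# fiber segments with von Mises-distributed orientations, Gaussian
# cross-sections and additive phase accumulation, over a uniform
# background with Gaussian noise. Two binary factors (gestational size
# AGA/SGA, diet HF/CON) multiply the expected fiber count, encoding "AGA
# and HF carry more myelin"; classes therefore differ mainly in fiber
# density and spatial texture while their pixel histograms overlap
# heavily, which is the regime the classifier stage is meant to resolve.

TISSUE_CLASSES <- c("AGA_CON", "AGA_HF", "SGA_CON", "SGA_HF")

#' Tissue class label (gestational size x diet)
#'
#' @param size `"AGA"` (appropriate for gestational age) or `"SGA"` (small
#'   for gestational age).
#' @param diet `"CON"` (control) or `"HF"` (hydrolyzed fat).
#' @return object of class `tissue_label`.
#' @export
tissue_label <- function(size = c("AGA", "SGA"), diet = c("CON", "HF")) {
  size <- match.arg(size)
  diet <- match.arg(diet)
  structure(list(size = size, diet = diet,
                 class = paste(size, diet, sep = "_")),
            class = "tissue_label")
}

#' @export
format.tissue_label <- function(x, ...) x$class

#' @export
print.tissue_label <- function(x, ...) {
  cat("<tissue_label>", x$class, "\n")
  invisible(x)
}

#' Fiber texture generator parameters
#'
#' Defaults describe a desk-scale internal-capsule-like field: a 192 x 256
#' px frame (the 4:3 aspect of the 1624 x 1224 px scanner frames), about
#' 80 fibers of ~60 px length and 3 px width, orientations concentrated
#' around the horizontal (von Mises kappa = 4, as in a coherent fiber
#' tract), 0.4 rad peak phase per fiber over a 0.1 rad background with
#' 0.02 rad measurement noise. Effect multipliers >= 1 scale the expected
#' fiber count for the AGA (size_effect) and HF (diet_effect) levels.
#'
#' @param image_shape integer (height, width) in pixels.
#' @param fiber_count expected number of fiber segments for the baseline
#'   class (SGA_CON).
#' @param fiber_width_px mean fiber width (Gaussian cross-section sigma is
#'   `fiber_width_px / 2`).
#' @param fiber_length_px mean fiber length in pixels.
#' @param orientation_kappa von Mises concentration of fiber orientations
#'   (0 = isotropic).
#' @param phase_amplitude mean peak phase added by one fiber (radians).
#' @param background_phase mean background phase (radians).
#' @param noise_sd additive Gaussian phase noise (radians).
#' @param size_effect multiplier on `fiber_count` for AGA vs SGA (>= 1).
#' @param diet_effect multiplier on `fiber_count` for HF vs CON (>= 1).
#' @param seed integer master seed.
#' @param pixel_pitch pixel size (um).
#' @return object of class `fiber_texture_params`.
#' @export
fiber_texture_params <- function(image_shape = c(192, 256),
                                 fiber_count = 80,
                                 fiber_width_px = 3,
                                 fiber_length_px = 60,
                                 orientation_kappa = 4,
                                 phase_amplitude = 0.4,
                                 background_phase = 0.1,
                                 noise_sd = 0.02,
                                 size_effect = 1.5,
                                 diet_effect = 1.3,
                                 seed = 1L,
                                 pixel_pitch = 255 / 1624) {
  if (length(image_shape) != 2 || any(image_shape < 1)) {
    stop("image_shape must be positive (height, width)", call. = FALSE)
  }
  if (fiber_count < 0 || fiber_width_px < 0 || fiber_length_px < 0 ||
      phase_amplitude < 0 || noise_sd < 0 || orientation_kappa < 0) {
    stop("counts, widths, lengths, amplitudes and kappa must be >= 0",
         call. = FALSE)
  }
  if (size_effect < 1 || diet_effect < 1) {
    stop("effect multipliers must be >= 1 (AGA and HF have more myelin)",
         call. = FALSE)
  }
  structure(list(image_shape = as.integer(image_shape),
                 fiber_count = fiber_count, fiber_width_px = fiber_width_px,
                 fiber_length_px = fiber_length_px,
                 orientation_kappa = orientation_kappa,
                 phase_amplitude = phase_amplitude,
                 background_phase = background_phase, noise_sd = noise_sd,
                 size_effect = size_effect, diet_effect = diet_effect,
                 seed = as.integer(seed), pixel_pitch = pixel_pitch),
            class = "fiber_texture_params")
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), mean direction
# mu, concentration kappa; kappa = 0 falls back to the uniform circle.
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- wrap_phase(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1
    }
  }
  out
}

expected_fiber_count <- function(params, label) {
  params$fiber_count *
    ifelse(label$size == "AGA", params$size_effect, 1) *
    ifelse(label$diet == "HF", params$diet_effect, 1)
}

# Add one fiber to `phi`: Gaussian profile of the distance to the segment
# (round caps), evaluated only inside the fiber's bounding box.
add_fiber <- function(phi, cy, cx, theta, len, sigma, amp) {
  h <- nrow(phi); w <- ncol(phi)
  dy <- sin(theta) * len / 2
  dx <- cos(theta) * len / 2
  pad <- 3 * sigma
  y0 <- max(1, floor(cy - abs(dy) - pad)); y1 <- min(h, ceiling(cy + abs(dy) + pad))
  x0 <- max(1, floor(cx - abs(dx) - pad)); x1 <- min(w, ceiling(cx + abs(dx) + pad))
  if (y0 > y1 || x0 > x1) return(phi)
  ys <- y0:y1; xs <- x0:x1
  py <- matrix(ys - cy, length(ys), length(xs))
  px <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  # projection of each pixel onto the segment axis, clamped to the caps
  t_ <- pmin(pmax(px * cos(theta) + py * sin(theta), -len / 2), len / 2)
  d2 <- (px - t_ * cos(theta))^2 + (py - t_ * sin(theta))^2
  phi[ys, xs] <- phi[ys, xs] + amp * exp(-d2 / (2 * sigma^2))
  phi
}

#' Generate one synthetic fiber-textured phase map
#'
#' Draws `N ~ Poisson(fiber_count * size_effect^[AGA] * diet_effect^[HF])`
#' fiber segments with von Mises orientations, uniform centers, gamma-
#' distributed lengths and per-fiber amplitudes (mean at the stated
#' parameters), rasterized as Gaussian cross-sections with additive phase
#' accumulation, then adds the background level and Gaussian noise.
#' Fully reproducible from `(params, label, seed)`.
#'
#' @param params a [fiber_texture_params()].
#' @param label a [tissue_label()].
#' @param seed integer seed; defaults to `params$seed`.
#' @return a [phase_map()]; metadata records the label, seed and realized
#'   fiber count.
#' @export
generate_fiber_phase_map <- function(params, label = tissue_label(),
                                     seed = params$seed) {
  stopifnot(inherits(params, "fiber_texture_params"),
            inherits(label, "tissue_label"))
  h <- params$image_shape[1]; w <- params$image_shape[2]
  lambda <- expected_fiber_count(params, label)
  with_seed(seed, {
    n <- stats::rpois(1, lambda)
    phi <- matrix(0, h, w)
    if (n > 0) {
      cy <- stats::runif(n, 1, h)
      cx <- stats::runif(n, 1, w)
      theta <- rvonmises(n, mu = 0, kappa = params$orientation_kappa)
      len <- stats::rgamma(n, shape = 4, scale = params$fiber_length_px / 4)
      amp <- stats::rgamma(n, shape = 9, scale = params$phase_amplitude / 9)
      sigma <- max(params$fiber_width_px / 2, 0.5)
      for (i in seq_len(n)) {
        phi <- add_fiber(phi, cy[i], cx[i], theta[i], len[i], sigma, amp[i])
      }
    }
    phi <- phi + params$background_phase
    if (params$noise_sd > 0) {
      phi <- phi + matrix(stats::rnorm(h * w, sd = params$noise_sd), h, w)
    }
    phase_map(phi, pixel_pitch = params$pixel_pitch,
              metadata = list(label = label$class, seed = seed,
                              n_fibers = n))
  })
}

#' Generate a balanced labeled dataset of phase maps
#'
#' `n_per_class` maps for each of the four classes, each map generated
#' from its own seed derived deterministically from `(seed, class index,
#' map index)` via [derive_seed()]. Maps are assigned round-robin to
#' `slides_per_class` synthetic source slides per class (ids like
#' `"AGA_HF_s1"`), mimicking tissue sections each contributing many
#' frames.
#'
#' @param params a [fiber_texture_params()].
#' @param n_per_class maps per class (>= 1).
#' @param seed master seed; defaults to `params$seed`.
#' @param slides_per_class synthetic slides per class (>= 1).
#' @return a `labeled_dataset`: list with `items` (data.frame: `id`,
#'   `size`, `diet`, `class`, `slide`, `seed`) and `images` (list of
#'   [phase_map()], same order).
#' @export
generate_labeled_dataset <- function(params, n_per_class, seed = params$seed,
                                     slides_per_class = 2L) {
  stopifnot(inherits(params, "fiber_texture_params"), n_per_class >= 1,
            slides_per_class >= 1)
  items <- list(); images <- list(); k <- 0
  for (ci in seq_along(TISSUE_CLASSES)) {
    cl <- TISSUE_CLASSES[ci]
    parts <- strsplit(cl, "_")[[1]]
    lab <- tissue_label(parts[1], parts[2])
    for (mi in seq_len(n_per_class)) {
      k <- k + 1
      s <- derive_seed(seed, ci, mi)
      images[[k]] <- generate_fiber_phase_map(params, lab, seed = s)
      items[[k]] <- data.frame(
        id = sprintf("%s_img%04d", cl, mi), size = parts[1], diet = parts[2],
        class = cl, slide = sprintf("%s_s%d", cl, (mi - 1) %% slides_per_class + 1),
        seed = s, stringsAsFactors = FALSE)
    }
  }
  structure(list(items = do.call(rbind, items), images = images),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d items, %d classes, %d slides%s\n",
              nrow(x$items), length(unique(x$items$class)),
              length(unique(x$items$slide)),
              if (!is.null(x$items$split)) " (split assigned)" else ""))
  invisible(x)
}

#' Generate a labeled interferogram dataset
#'
#' Converts each generated phase map into a field decomposition
#' (`a = 1`, `b = beta_scale`, `delta_phi` = the map's phase wrapped to
#' `(-pi, pi]`) and simulates its four-frame stack, so the whole optics
#' chain can be exercised at dataset scale.
#'
#' @param params a [fiber_texture_params()].
#' @param n_per_class maps per class.
#' @param beta_scale scattered/incident amplitude ratio in `(0, 1]`.
#' @param noise_sd intensity noise passed to [simulate_interferograms()].
#' @param seed master seed.
#' @return list with `items` (as in [generate_labeled_dataset()]),
#'   `stacks` (list of [interferogram_stack()]) and `phases` (the
#'   ground-truth [phase_map()]s).
#' @export
generate_interferogram_dataset <- function(params, n_per_class,
                                           beta_scale = 0.5, noise_sd = 0,
                                           seed = params$seed) {
  if (!is.numeric(beta_scale) || beta_scale <= 0 || beta_scale > 1) {
    stop("beta_scale must lie in (0, 1]", call. = FALSE)
  }
  ds <- generate_labeled_dataset(params, n_per_class, seed = seed)
  stacks <- lapply(seq_along(ds$images), function(i) {
    p <- ds$images[[i]]
    fd <- field_decomposition(
      matrix(1, nrow(p$phi), ncol(p$phi)),
      matrix(beta_scale, nrow(p$phi), ncol(p$phi)),
      wrap_phase(p$phi), pixel_pitch = p$pixel_pitch)
    simulate_interferograms(fd, noise_sd = noise_sd,
                            seed = derive_seed(seed, 5L, i))
  })
  list(items = ds$items, stacks = stacks, phases = ds$images)
}
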