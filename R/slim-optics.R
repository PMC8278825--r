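# SLIM forward model and phase-shifting reconstruction.
#
# The object field at the image plane is U = U_i + U_s, the sum of the
# incident (unscattered) and scattered components. The module simulates the
# four interferograms recorded while the phase delay between the two
# components is shifted in increments of pi/2, and inverts them exactly:
#
#   I(phi_m) = |U_i|^2 + |U_s|^2 + 2 |U_i||U_s| cos(delta_phi - phi_m),
#   phi_m in {0, pi/2, pi, 3*pi/2}.
#
# Sign convention (fixed here, any self-consistent one passes the round
# trip): the modulation phi_m is subtracted from the intrinsic phase
# difference delta_phi between scattered and incident field.

MOD_PHASES <- c(0, pi / 2, pi, 3 * pi / 2)

#' Incident/scattered field decomposition (forward-model ground truth)
#'
#' @param a_incident numeric matrix, incident-field amplitude `|U_i|` (>= 0,
#'   arbitrary units).
#' @param b_scattered numeric matrix, scattered-field amplitude `|U_s|`
#'   (same units and shape).
#' @param delta_phi numeric matrix, phase difference between scattered and
#'   incident field (radians; wrapped to `(-pi, pi]` on construction).
#' @param pixel_pitch physical pixel size in micrometres (> 0). The default
#'   is the scanner frame geometry 255 um / 1624 px.
#' @return an object of class `field_decomposition`.
#' @export
#' @examples
#' fd <- field_decomposition(matrix(1, 4, 4), matrix(0.5, 4, 4),
#'                           matrix(pi / 3, 4, 4))
field_decomposition <- function(a_incident, b_scattered, delta_phi,
                                pixel_pitch = 255 / 1624) {
  stop_if_not_matrix(a_incident, "a_incident")
  stop_if_not_matrix(b_scattered, "b_scattered")
  stop_if_not_matrix(delta_phi, "delta_phi")
  if (!same_shape(a_incident, b_scattered, delta_phi)) {
    stop("a_incident, b_scattered and delta_phi must share one shape",
         call. = FALSE)
  }
  if (any(a_incident < 0) || any(b_scattered < 0)) {
    stop("field amplitudes must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1 || pixel_pitch <= 0) {
    stop("pixel_pitch must be a positive scalar (micrometres)", call. = FALSE)
  }
  structure(
    list(a_incident = a_incident, b_scattered = b_scattered,
         delta_phi = wrap_phase(delta_phi), pixel_pitch = pixel_pitch),
    class = "field_decomposition"
  )
}

#' Four-frame interferogram stack
#'
#' Container for the four intensity frames recorded at modulation phases
#' `0, pi/2, pi, 3*pi/2`.
#'
#' @param frames list of exactly four numeric matrices of one shape, ordered
#'   by modulation phase; all intensities must be nonnegative.
#' @param pixel_pitch pixel size in micrometres.
#' @return an object of class `interferogram_stack`.
#' @export
interferogram_stack <- function(frames, pixel_pitch = 255 / 1624) {
  if (!is.list(frames) || length(frames) != 4) {
    stop("`frames` must be a list of exactly four matrices", call. = FALSE)
  }
  for (i in seq_len(4)) stop_if_not_matrix(frames[[i]], sprintf("frames[[%d]]", i))
  if (!same_shape(frames[[1]], frames[[2]], frames[[3]], frames[[4]])) {
    stop("all four frames must share one shape", call. = FALSE)
  }
  if (any(vapply(frames, function(f) any(f < 0), logical(1)))) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  names(frames) <- c("f0", "f90", "f180", "f270")
  structure(list(frames = frames, mod_phases = MOD_PHASES,
                 pixel_pitch = pixel_pitch),
            class = "interferogram_stack")
}

#' Reconstructed quantitative phase map
#'
#' @param phi numeric matrix of phase values (radians), finite everywhere.
#' @param pixel_pitch pixel size in micrometres.
#' @param beta optional matrix of the amplitude ratio `|U_s|/|U_i|` in
#'   `[0, 1]`.
#' @param valid optional logical matrix flagging pixels where the
#'   reconstruction was well posed; defaults to all-`TRUE`.
#' @param metadata optional named list carried along (stain-normalization
#'   coefficients, provenance, ...).
#' @return an object of class `phase_map`.
#' @export
phase_map <- function(phi, pixel_pitch = 255 / 1624, beta = NULL,
                      valid = NULL, metadata = list()) {
  stop_if_not_matrix(phi, "phi")
  if (!is.null(beta)) {
    stop_if_not_matrix(beta, "beta")
    if (!same_shape(phi, beta)) stop("phi and beta must share one shape", call. = FALSE)
    if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(valid)) valid <- matrix(TRUE, nrow(phi), ncol(phi))
  structure(list(phi = phi, pixel_pitch = pixel_pitch, beta = beta,
                 valid = valid, metadata = metadata),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px, pitch %.4g um, phi in [%.4g, %.4g] rad\n",
              nrow(x$phi), ncol(x$phi), x$pixel_pitch,
              min(x$phi), max(x$phi)))
  invisible(x)
}

#' Simulate the four phase-shifted interferograms
#'
#' Applies the two-beam interference law per pixel at the four modulation
#' phases and optionally adds Gaussian camera noise (clamped at zero
#' intensity).
#'
#' @param decomp a [field_decomposition()].
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (>= 0; same arbitrary units as the squared amplitudes).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return an [interferogram_stack()].
#' @export
#' @examples
#' fd <- field_decomposition(matrix(1, 2, 2), matrix(0.5, 2, 2),
#'                           matrix(0, 2, 2))
#' st <- simulate_interferograms(fd)
#' st$frames$f0[1, 1]   # 2.25
simulate_interferograms <- function(decomp, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(decomp, "field_decomposition"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    stop("noise_sd must be a nonnegative scalar", call. = FALSE)
  }
  a <- decomp$a_incident
  b <- decomp$b_scattered
  dphi <- decomp$delta_phi
  base <- a^2 + b^2
  cross <- 2 * a * b
  frames <- lapply(MOD_PHASES, function(pm) base + cross * cos(dphi - pm))
  if (noise_sd > 0) {
    frames <- with_seed(seed, lapply(frames, function(f) {
      pmax(f + matrix(stats::rnorm(length(f), sd = noise_sd), nrow(f)), 0)
    }))
  }
  interferogram_stack(frames, pixel_pitch = decomp$pixel_pitch)
}

#' Recover the scattered-minus-incident phase difference
#'
#' Four-frame phase-shifting inversion: the quadrature differences
#' `I(0) - I(pi)` and `I(pi/2) - I(3*pi/2)` isolate `cos(delta_phi)` and
#' `sin(delta_phi)` up to one positive factor, so the quadrant-aware
#' arctangent recovers `delta_phi` exactly in the noise-free case.
#' Pixels with no modulation (both differences zero, e.g. no scattered
#' light) are defined as 0 and flagged in the validity mask.
#'
#' @param stack an [interferogram_stack()].
#' @return list with `delta_phi` (matrix, radians in `(-pi, pi]`) and
#'   `valid` (logical matrix, `FALSE` where degenerate).
#' @export
reconstruct_delta_phi <- function(stack) {
  stopifnot(inherits(stack, "interferogram_stack"))
  f <- stack$frames
  num <- f$f90 - f$f270   # 4 a b sin(delta_phi)
  den <- f$f0 - f$f180    # 4 a b cos(delta_phi)
  valid <- !(num == 0 & den == 0)
  dphi <- atan2(num, den)
  dphi[!valid] <- 0
  list(delta_phi = dphi, valid = valid)
}

#' Recover the amplitude ratio beta = |U_s| / |U_i|
#'
#' From the frame sum `S = 4 (a^2 + b^2)` and the modulation amplitude
#' `C = 4 a b`, `a^2` and `b^2` are the roots of
#' `t^2 - (S/4) t + (C/4)^2 = 0`; the branch `a >= b` (the unscattered
#' field dominates, the standard SLIM assumption) selects which root is
#' which, so `beta = b / a <= 1`. Pixels whose discriminant is negative
#' beyond numerical tolerance (inconsistent, e.g. heavily noisy, stacks)
#' are clamped to a repeated root and flagged; dark pixels (`S = 0`)
#' return 0.
#'
#' @param stack an [interferogram_stack()].
#' @return list with `beta` (matrix in `[0, 1]`) and `valid` (logical
#'   matrix).
#' @export
estimate_beta <- function(stack) {
  stopifnot(inherits(stack, "interferogram_stack"))
  f <- stack$frames
  S <- f$f0 + f$f90 + f$f180 + f$f270
  C <- sqrt((f$f0 - f$f180)^2 + (f$f90 - f$f270)^2)
  p <- S / 4            # a^2 + b^2
  q <- (C / 4)^2        # a^2 * b^2
  disc <- p^2 - 4 * q
  tol <- 1e-9 * pmax(p^2, 1)
  valid <- disc >= -tol
  disc <- pmax(disc, 0)
  a2 <- (p + sqrt(disc)) / 2
  b2 <- (p - sqrt(disc)) / 2
  beta <- matrix(0, nrow(S), ncol(S))
  nz <- a2 > 0
  beta[nz] <- sqrt(pmax(b2[nz], 0) / a2[nz])
  beta <- pmin(pmax(beta, 0), 1)
  list(beta = beta, valid = valid)
}

#' Reconstruct the quantitative phase map
#'
#' The phase of the total field relative to the incident field is
#' `phi = arg(1 + beta * exp(1i * delta_phi))`, evaluated with the
#' quadrant-aware arctangent of `beta * sin(delta_phi)` over
#' `1 + beta * cos(delta_phi)`. Four frames shifted by pi/2 suffice to
#' extract it unambiguously.
#'
#' @param stack an [interferogram_stack()].
#' @return a [phase_map()] carrying `phi`, `beta` and the combined validity
#'   mask of the intermediate steps.
#' @export
#' @examples
#' fd <- field_decomposition(matrix(1, 2, 2), matrix(0.5, 2, 2),
#'                           matrix(pi / 3, 2, 2))
#' pm <- reconstruct_phase(simulate_interferograms(fd))
#' pm$phi[1, 1]   # arg(1 + 0.5 * exp(1i*pi/3)) = 0.33347...
reconstruct_phase <- function(stack) {
  stopifnot(inherits(stack, "interferogram_stack"))
  dp <- reconstruct_delta_phi(stack)
  be <- estimate_beta(stack)
  phi <- atan2(be$beta * sin(dp$delta_phi), 1 + be$beta * cos(dp$delta_phi))
  phase_map(phi, pixel_pitch = stack$pixel_pitch, beta = be$beta,
            valid = dp$valid & be$valid)
}
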