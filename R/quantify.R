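# Dry-mass densitometry, stain normalization, myelin masks and pooled
# phase histograms.
#
# The phase shift through a thin tissue section is proportional to the
# dry-mass surface density: rho = lambda * phi / (2 * pi * gamma), with
# lambda the central illumination wavelength and gamma the refractive
# increment of the (proteolipid) dry matter.

#' Stain-effect normalization of a phase map
#'
#' Histology stains (here Luxol Fast Blue) change the refractive index of
#' the tissue and therefore bias the measured phase. The correction applied
#' is a global affine map `phi' = gain * phi + offset` with coefficients
#' calibrated externally (e.g. from paired stained/unstained scans of the
#' same sections); the applied coefficients are recorded in the map
#' metadata.
#'
#' @param phase a [phase_map()].
#' @param gain multiplicative coefficient (nonzero).
#' @param offset additive coefficient (radians).
#' @return a [phase_map()] with transformed phase and recorded coefficients.
#' @export
stain_normalize <- function(phase, gain = 1, offset = 0) {
  stopifnot(inherits(phase, "phase_map"))
  if (!is.numeric(gain) || length(gain) != 1 || gain == 0) {
    stop("`gain` must be a single nonzero number", call. = FALSE)
  }
  md <- phase$metadata
  md$stain_normalization <- list(gain = gain, offset = offset)
  phase_map(gain * phase$phi + offset, pixel_pitch = phase$pixel_pitch,
            beta = phase$beta, valid = phase$valid, metadata = md)
}

#' Dry-mass surface density map
#'
#' @param density numeric matrix of dry-mass surface density (pg/um^2).
#' @param wavelength central illumination wavelength (um, > 0).
#' @param refractive_increment refractive increment gamma (um^3/pg, > 0).
#' @param pixel_pitch pixel size (um).
#' @return an object of class `dry_mass_map`.
#' @export
dry_mass_map <- function(density, wavelength, refractive_increment,
                         pixel_pitch = 255 / 1624) {
  stop_if_not_matrix(density, "density")
  if (wavelength <= 0) stop("wavelength must be > 0", call. = FALSE)
  if (refractive_increment <= 0) {
    stop("refractive_increment must be > 0", call. = FALSE)
  }
  structure(list(density = density, wavelength = wavelength,
                 refractive_increment = refractive_increment,
                 pixel_pitch = pixel_pitch),
            class = "dry_mass_map")
}

#' Convert phase to dry-mass surface density
#'
#' `rho = wavelength * phi / (2 * pi * refractive_increment)`, per pixel.
#' Defaults: `wavelength = 0.55` um (central wavelength of broadband
#' white-light illumination) and `refractive_increment = 0.2` um^3/pg, the
#' standard protein/lipid value from the QPI literature; both are
#' configurable.
#'
#' @param phase a [phase_map()].
#' @param wavelength central wavelength (um, > 0).
#' @param refractive_increment gamma (um^3/pg, > 0).
#' @return a [dry_mass_map()].
#' @export
#' @examples
#' pm <- phase_map(matrix(2 * pi, 2, 2))
#' phase_to_dry_mass(pm)$density[1, 1]   # 0.55 / 0.2 = 2.75 pg/um^2
phase_to_dry_mass <- function(phase, wavelength = 0.55,
                              refractive_increment = 0.2) {
  stopifnot(inherits(phase, "phase_map"))
  if (!is.numeric(wavelength) || length(wavelength) != 1 || wavelength <= 0) {
    stop("wavelength must be a positive scalar (um)", call. = FALSE)
  }
  if (!is.numeric(refractive_increment) || length(refractive_increment) != 1 ||
      refractive_increment <= 0) {
    stop("refractive_increment must be a positive scalar (um^3/pg)",
         call. = FALSE)
  }
  rho <- wavelength * phase$phi / (2 * pi * refractive_increment)
  dry_mass_map(rho, wavelength, refractive_increment,
               pixel_pitch = phase$pixel_pitch)
}

# Otsu's method on a value vector: exhaustive scan of histogram cut points
# maximizing the between-class variance. Returns NA for (near-)constant
# input.
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- bin_counts(x, edges)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[length(mu)]
  k <- seq_len(n_bins - 1)
  denom <- omega[k] * (1 - omega[k])
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega[k] - mu[k])^2 / denom, -Inf)
  # midpoint of the maximal plateau (a two-level image maximizes the
  # between-class variance on every cut between the levels)
  ties <- which(sigma_b2 >= max(sigma_b2) * (1 - 1e-12))
  edges[round(mean(range(ties))) + 1]
}

#' Binary myelin mask from a phase map
#'
#' Myelinated fibers carry higher dry mass, hence higher phase, than the
#' surrounding parenchyma; a binary mask isolates them before computing
#' masked dry-mass statistics. The threshold is either supplied (`fixed`)
#' or chosen by Otsu's between-class variance criterion on the phase
#' histogram (the default).
#'
#' @param phase a [phase_map()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold phase threshold in radians; required for
#'   `method = "fixed"`.
#' @return an object of class `myelin_mask`: list with logical `mask`,
#'   the `threshold` used and the `method` label.
#' @export
myelin_mask <- function(phase, method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot(inherits(phase, "phase_map"))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold) || !is.numeric(threshold) || length(threshold) != 1) {
      stop("method = \"fixed\" requires a scalar `threshold` (radians)",
           call. = FALSE)
    }
  } else {
    threshold <- otsu_threshold(as.vector(phase$phi))
    if (is.na(threshold)) {
      warning("constant phase image: Otsu threshold undefined, mask all-FALSE")
      return(structure(list(mask = matrix(FALSE, nrow(phase$phi), ncol(phase$phi)),
                            threshold = NA_real_, method = "otsu"),
                       class = "myelin_mask"))
    }
  }
  structure(list(mask = phase$phi >= threshold, threshold = threshold,
                 method = method),
            class = "myelin_mask")
}

#' Dry-mass statistics over a myelin mask
#'
#' @param mass a [dry_mass_map()].
#' @param mask a [myelin_mask()] (or logical matrix) of the same shape.
#' @return list with `total_mass_pg` (sum of density times pixel area over
#'   the mask), `mean_density_pg_um2`, `area_um2` and `n_pixels`. An empty
#'   mask yields all zeros.
#' @export
masked_dry_mass_stats <- function(mass, mask) {
  stopifnot(inherits(mass, "dry_mass_map"))
  m <- if (inherits(mask, "myelin_mask")) mask$mask else mask
  if (!is.logical(m) || !same_shape(mass$density, m)) {
    stop("mask must be a logical matrix matching the density map shape",
         call. = FALSE)
  }
  n <- sum(m)
  px_area <- mass$pixel_pitch^2
  if (n == 0) {
    return(list(total_mass_pg = 0, mean_density_pg_um2 = 0,
                area_um2 = 0, n_pixels = 0L))
  }
  vals <- mass$density[m]
  list(total_mass_pg = sum(vals) * px_area,
       mean_density_pg_um2 = mean(vals),
       area_um2 = n * px_area,
       n_pixels = as.integer(n))
}

# Half-open binning [e_i, e_{i+1}) with the last bin closed; values outside
# [e_1, e_K] are dropped.
bin_counts <- function(x, edges) {
  k <- length(edges) - 1
  idx <- findInterval(x, edges)
  idx[x == edges[k + 1]] <- k
  idx <- idx[idx >= 1 & idx <= k]
  tabulate(idx, nbins = k)
}

#' Default phase-histogram bin edges
#'
#' 256 uniform bins over `[-0.5, 3.0]` radians, the working range of
#' fiber-tissue phase maps.
#'
#' @param n_bins number of bins.
#' @param range length-2 phase range (radians).
#' @return numeric vector of `n_bins + 1` edges.
#' @export
default_phase_edges <- function(n_bins = 256, range = c(-0.5, 3.0)) {
  seq(range[1], range[2], length.out = n_bins + 1)
}

#' Pooled phase histogram of one or more phase maps
#'
#' Pools every pixel of every supplied map and bins into half-open bins
#' `[e_i, e_{i+1})`, the last bin closed. Pixels outside the edge range are
#' excluded from the counts.
#'
#' @param phases a [phase_map()] or list of them.
#' @param bin_edges strictly increasing numeric vector of bin edges
#'   (radians).
#' @return object of class `phase_histogram`: list with `bin_edges`,
#'   integer `counts` and `normalized` fractions summing to 1.
#' @export
phase_histogram <- function(phases, bin_edges = default_phase_edges()) {
  if (inherits(phases, "phase_map")) phases <- list(phases)
  if (!length(phases) || !all(vapply(phases, inherits, logical(1), "phase_map"))) {
    stop("`phases` must be a phase_map or a non-empty list of phase_map",
         call. = FALSE)
  }
  if (any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  x <- unlist(lapply(phases, function(p) as.vector(p$phi)), use.names = FALSE)
  counts <- bin_counts(x, bin_edges)
  total <- sum(counts)
  structure(list(bin_edges = bin_edges, counts = counts,
                 normalized = if (total > 0) counts / total else counts * 0),
            class = "phase_histogram")
}

#' Histogram intersection overlap
#'
#' `sum_i min(p_i, q_i)` over the normalized bin fractions of two
#' histograms on identical edges: 1 for identical distributions, 0 for
#' disjoint support, symmetric in its arguments.
#'
#' @param h1,h2 [phase_histogram()] objects with identical `bin_edges`.
#' @return scalar overlap in `[0, 1]`.
#' @export
histogram_overlap <- function(h1, h2) {
  stopifnot(inherits(h1, "phase_histogram"), inherits(h2, "phase_histogram"))
  if (length(h1$bin_edges) != length(h2$bin_edges) ||
      !isTRUE(all.equal(h1$bin_edges, h2$bin_edges, tolerance = 1e-12))) {
    stop("histograms must share identical bin edges", call. = FALSE)
  }
  sum(pmin(h1$normalized, h2$normalized))
}

#' All six pairwise class-overlap statistics
#'
#' Builds one pooled phase histogram per class (AGA_CON, AGA_HF, SGA_CON,
#' SGA_HF) and returns the histogram-intersection overlap for each of the
#' six unordered class pairings.
#'
#' @param class_maps named list with one entry per class label, each a list
#'   of [phase_map()] objects. All four classes must be present.
#' @param bin_edges common bin edges (radians).
#' @return data.frame with columns `class_a`, `class_b`, `overlap` (six
#'   rows).
#' @export
group_pairwise_overlaps <- function(class_maps,
                                    bin_edges = default_phase_edges()) {
  missing <- setdiff(TISSUE_CLASSES, names(class_maps))
  if (length(missing)) {
    stop("missing class(es): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  hists <- lapply(TISSUE_CLASSES, function(cl) {
    phase_histogram(class_maps[[cl]], bin_edges)
  })
  names(hists) <- TISSUE_CLASSES
  pairs <- utils::combn(TISSUE_CLASSES, 2)
  data.frame(
    class_a = pairs[1, ],
    class_b = pairs[2, ],
    overlap = apply(pairs, 2, function(p) {
      histogram_overlap(hists[[p[1]]], hists[[p[2]]])
    }),
    stringsAsFactors = FALSE
  )
}
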