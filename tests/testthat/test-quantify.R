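test_that("stain normalization is the stated affine map with recorded coefficients", {
  pm <- phase_map(matrix(0.3, 4, 4))
  expect_equal(stain_normalize(pm, 1, 0)$phi, pm$phi)
  expect_equal(stain_normalize(pm, 2, 0)$phi, matrix(0.6, 4, 4))
  set.seed(3)
  fix <- phase_map(matrix(rnorm(20), 4, 5))
  out <- stain_normalize(fix, gain = 0.8, offset = -0.05)
  expect_equal(out$phi, 0.8 * fix$phi - 0.05)   # elementwise oracle
  expect_equal(out$metadata$stain_normalization, list(gain = 0.8, offset = -0.05))
  expect_error(stain_normalize(pm, gain = 0), "nonzero")
})

test_that("dry-mass conversion follows rho = lambda phi / (2 pi gamma)", {
  expect_equal(phase_to_dry_mass(phase_map(matrix(0, 3, 3)))$density,
               matrix(0, 3, 3))
  dm <- phase_to_dry_mass(phase_map(matrix(2 * pi, 2, 2)),
                          wavelength = 0.55, refractive_increment = 0.2)
  expect_equal(dm$density, matrix(2.75, 2, 2))
  # linearity and commutation with gain-only stain normalization
  set.seed(4)
  pm <- phase_map(matrix(runif(12), 3, 4))
  expect_equal(phase_to_dry_mass(stain_normalize(pm, 2, 0))$density,
               2 * phase_to_dry_mass(pm)$density)
  expect_error(phase_to_dry_mass(pm, wavelength = -1), "positive")
})

test_that("Otsu threshold separates a two-level image exactly", {
  two <- phase_map(cbind(matrix(0.1, 6, 4), matrix(0.9, 6, 4)))
  mk <- myelin_mask(two)
  expect_gt(mk$threshold, 0.1)
  expect_lt(mk$threshold, 0.9)
  expect_equal(mk$mask, cbind(matrix(FALSE, 6, 4), matrix(TRUE, 6, 4)))
  # independent oracle: exhaustive scan of all candidate cuts
  vals <- as.vector(two$phi)
  cand <- seq(min(vals), max(vals), length.out = 512)
  bcv <- vapply(cand, function(t) {
    w1 <- mean(vals < t)
    if (w1 %in% c(0, 1)) return(-Inf)
    w1 * (1 - w1) * (mean(vals[vals < t]) - mean(vals[vals >= t]))^2
  }, numeric(1))
  best <- range(cand[bcv >= max(bcv) - 1e-12])
  expect_gte(mk$threshold, best[1] - 1e-6)
  expect_lte(mk$threshold, best[2] + 1e-6)
})

test_that("fixed thresholds and degenerate masks behave as stated", {
  pm <- phase_map(matrix(0.5, 3, 3))
  expect_true(all(myelin_mask(pm, "fixed", threshold = 0.2)$mask))
  expect_false(any(myelin_mask(pm, "fixed", threshold = 0.6)$mask))
  expect_warning(mk <- myelin_mask(pm, "otsu"), "constant")
  expect_false(any(mk$mask))
  expect_error(myelin_mask(pm, "fixed"), "threshold")
})

test_that("masked dry-mass statistics match hand arithmetic", {
  dm <- dry_mass_map(matrix(2, 4, 5), 0.55, 0.2, pixel_pitch = 1)
  mask <- matrix(FALSE, 4, 5); mask[1:2, 1:5] <- TRUE   # 10 pixels
  st <- masked_dry_mass_stats(dm, mask)
  expect_equal(st[c("total_mass_pg", "mean_density_pg_um2", "area_um2", "n_pixels")],
               list(total_mass_pg = 20, mean_density_pg_um2 = 2,
                    area_um2 = 10, n_pixels = 10L))
  empty <- masked_dry_mass_stats(dm, matrix(FALSE, 4, 5))
  expect_equal(unlist(empty), c(total_mass_pg = 0, mean_density_pg_um2 = 0,
                                area_um2 = 0, n_pixels = 0))
  # all-true mask against the elementwise-sum oracle, physical pixel pitch
  set.seed(5)
  dm2 <- dry_mass_map(matrix(runif(20), 4, 5), 0.55, 0.2, pixel_pitch = 0.5)
  st2 <- masked_dry_mass_stats(dm2, matrix(TRUE, 4, 5))
  expect_equal(st2$total_mass_pg, sum(dm2$density) * 0.25)
  expect_error(masked_dry_mass_stats(dm, matrix(TRUE, 2, 2)), "shape")
})

test_that("phase histograms pool pixels with half-open bins, last closed", {
  h <- phase_histogram(phase_map(matrix(0.5, 2, 2)), c(0, 1))
  expect_equal(h$counts, 4L)
  expect_equal(h$normalized, 1)
  h2 <- phase_histogram(phase_map(matrix(c(0.1, 0.1, 0.6, 0.9), 2, 2)),
                        c(0, 0.5, 1.0))
  expect_equal(h2$counts, c(2L, 2L))
  # boundary pixel at the last edge falls in the last (closed) bin
  h3 <- phase_histogram(phase_map(matrix(c(0.5, 1.0), 1, 2)), c(0, 0.5, 1.0))
  expect_equal(h3$counts, c(0L, 2L))
  # additivity: two copies double the counts and conserve the total
  pm <- phase_map(matrix(runif(30, 0, 1), 5, 6))
  ha <- phase_histogram(pm, seq(0, 1, 0.1))
  hb <- phase_histogram(list(pm, pm), seq(0, 1, 0.1))
  expect_equal(hb$counts, 2L * ha$counts)
  expect_equal(sum(ha$counts), 30)
  expect_equal(sum(ha$normalized), 1, tolerance = 1e-12)
  expect_error(phase_histogram(pm, c(0, 0, 1)), "increasing")
})

test_that("histogram intersection overlap has the stated algebra", {
  mk_hist <- function(norm) {
    structure(list(bin_edges = seq(0, 1, length.out = length(norm) + 1),
                   counts = as.integer(norm * 100), normalized = norm),
              class = "phase_histogram")
  }
  h <- phase_histogram(phase_map(matrix(runif(50), 5, 10)), seq(0, 1, 0.25))
  expect_equal(histogram_overlap(h, h), 1.0)
  expect_equal(histogram_overlap(mk_hist(c(1, 0)), mk_hist(c(0, 1))), 0.0)
  expect_equal(histogram_overlap(mk_hist(c(0.5, 0.5)), mk_hist(c(0.25, 0.75))),
               0.75)
  # symmetry and bounds on random pairs
  set.seed(6)
  for (i in 1:5) {
    p <- runif(8); p <- p / sum(p)
    q <- runif(8); q <- q / sum(q)
    o <- histogram_overlap(mk_hist(p), mk_hist(q))
    expect_equal(o, histogram_overlap(mk_hist(q), mk_hist(p)))
    expect_gte(o, 0); expect_lte(o, 1)
  }
  h1 <- phase_histogram(phase_map(matrix(0.5, 2, 2)), c(0, 1))
  h2 <- phase_histogram(phase_map(matrix(0.5, 2, 2)), c(0, 2))
  expect_error(histogram_overlap(h1, h2), "edges")
})

test_that("six-pairing class overlaps reflect the generating distributions", {
  classes <- c("AGA_CON", "AGA_HF", "SGA_CON", "SGA_HF")
  mk_maps <- function(vals) list(phase_map(matrix(vals, 40, 50)))
  # all classes one distribution: overlaps near 1
  set.seed(7)
  same <- lapply(classes, function(cl) mk_maps(rnorm(2000, 1, 0.2)))
  names(same) <- classes
  tab <- group_pairwise_overlaps(same, seq(0, 2, length.out = 65))
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$overlap >= 0.9))
  # disjoint phase ranges: all six overlaps zero
  disj <- lapply(seq_along(classes), function(i) mk_maps(runif(2000, i, i + 0.5)))
  names(disj) <- classes
  tab0 <- group_pairwise_overlaps(disj, seq(0, 6, length.out = 121))
  expect_true(all(tab0$overlap == 0))
  # only diet shifts the mean: diet pairings overlap less than size pairings
  shift <- list(AGA_CON = mk_maps(rnorm(2000, 1, 0.2)),
                AGA_HF = mk_maps(rnorm(2000, 1.6, 0.2)),
                SGA_CON = mk_maps(rnorm(2000, 1, 0.2)),
                SGA_HF = mk_maps(rnorm(2000, 1.6, 0.2)))
  tabs <- group_pairwise_overlaps(shift, seq(0, 3, length.out = 121))
  key <- paste(tabs$class_a, tabs$class_b)
  diet_pairs <- tabs$overlap[key %in% c("AGA_CON AGA_HF", "SGA_CON SGA_HF")]
  size_pairs <- tabs$overlap[key %in% c("AGA_CON SGA_CON", "AGA_HF SGA_HF")]
  expect_true(max(diet_pairs) < min(size_pairs))
  expect_error(group_pairwise_overlaps(same[1:3]), "SGA_HF")
})
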