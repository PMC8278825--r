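test_that("simulated interferograms match the complex-arithmetic oracle", {
  cases <- list(list(b = 0, dphi = 0.7), list(b = 0.5, dphi = 0),
                list(b = 0.5, dphi = pi / 2), list(b = 0.3, dphi = -2.1))
  for (cs in cases) {
    st <- simulate_interferograms(const_decomp(b = cs$b, dphi = cs$dphi))
    expected <- oracle_frames(1, cs$b, matrix(cs$dphi, 6, 8))
    for (i in 1:4) expect_equal(st$frames[[i]], expected[[i]], tolerance = 1e-12)
  }
  # frozen values from the oracle
  st <- simulate_interferograms(const_decomp(b = 0.5, dphi = 0))
  expect_equal(unname(sapply(st$frames, function(f) f[1, 1])),
               c(2.25, 1.25, 0.25, 1.25))
  st <- simulate_interferograms(const_decomp(b = 0.5, dphi = pi / 2))
  expect_equal(unname(sapply(st$frames, function(f) f[1, 1])),
               c(1.25, 2.25, 1.25, 0.25))
  # no scattered field: all frames equal a^2
  st0 <- simulate_interferograms(const_decomp(b = 0, dphi = 1.1))
  for (f in st0$frames) expect_true(all(f == 1))
})

test_that("noise-free stacks satisfy the frame-sum conservation law", {
  for (seed in 1:3) {
    d <- random_dphi(seed = seed)
    st <- simulate_interferograms(const_decomp(b = 0.4, dphi = 0, shape = dim(d)))
    st <- simulate_interferograms(
      field_decomposition(matrix(1, 6, 8), matrix(0.4, 6, 8), d))
    expect_lt(max(abs(st$frames$f0 + st$frames$f180 -
                      st$frames$f90 - st$frames$f270)), 1e-12)
  }
})

test_that("delta-phi reconstruction round-trips the forward model", {
  st <- simulate_interferograms(const_decomp(b = 0.5, dphi = pi / 3))
  dp <- reconstruct_delta_phi(st)
  expect_lt(max(abs(dp$delta_phi - pi / 3)), 1e-9)
  expect_true(all(dp$valid))
  # random field property, fixed seeds
  for (seed in 1:5) {
    d <- random_dphi(seed = seed)
    st <- simulate_interferograms(
      field_decomposition(matrix(1, 6, 8), matrix(0.3, 6, 8), d))
    expect_lt(max(abs(reconstruct_delta_phi(st)$delta_phi - d)), 1e-9)
  }
})

test_that("degenerate stacks (no modulation) yield zero with all-false mask", {
  flat <- matrix(2, 5, 5)
  st <- interferogram_stack(list(flat, flat, flat, flat))
  dp <- reconstruct_delta_phi(st)
  expect_true(all(dp$delta_phi == 0))
  expect_false(any(dp$valid))
})

test_that("beta recovery takes the incident-dominant branch", {
  expect_equal(estimate_beta(simulate_interferograms(const_decomp(b = 0)))$beta,
               matrix(0, 6, 8))
  for (dphi in c(0, 1.2, -2.5)) {
    be <- estimate_beta(simulate_interferograms(const_decomp(b = 0.5, dphi = dphi)))
    expect_lt(max(abs(be$beta - 0.5)), 1e-9)
    expect_true(all(be$valid))
  }
  # equal amplitudes: repeated root, boundary branch
  be1 <- estimate_beta(simulate_interferograms(const_decomp(b = 1, dphi = 0.4)))
  expect_equal(be1$beta, matrix(1, 6, 8), tolerance = 1e-7)
})

test_that("phase reconstruction matches arg(a + b e^{i dphi})", {
  pm <- reconstruct_phase(simulate_interferograms(const_decomp(b = 0.5, dphi = pi / 3)))
  expect_equal(pm$phi, matrix(Arg(1 + 0.5 * exp(1i * pi / 3)), 6, 8),
               tolerance = 1e-9)
  expect_equal(pm$phi[1, 1], 0.33347, tolerance = 1e-4)
  # b = 0: total field equals incident field
  pm0 <- reconstruct_phase(simulate_interferograms(const_decomp(b = 0, dphi = 2)))
  expect_true(all(pm0$phi == 0))
  # random-field oracle property
  for (seed in 1:5) {
    d <- random_dphi(seed = seed)
    pm <- reconstruct_phase(simulate_interferograms(
      field_decomposition(matrix(1, 6, 8), matrix(0.3, 6, 8), d)))
    expect_lt(max(abs(pm$phi - Arg(1 + 0.3 * exp(1i * d)))), 1e-9)
    expect_lt(max(abs(pm$beta - 0.3)), 1e-9)
  }
})

test_that("reconstruction error degrades monotonically with noise", {
  d <- random_dphi(shape = c(24, 32), seed = 9)
  fd <- field_decomposition(matrix(1, 24, 32), matrix(0.4, 24, 32), d)
  truth <- Arg(1 + 0.4 * exp(1i * d))
  rms <- vapply(c(0, 0.01, 0.05, 0.2), function(ns) {
    errs <- vapply(1:5, function(s) {
      pm <- reconstruct_phase(simulate_interferograms(fd, noise_sd = ns, seed = s))
      sqrt(mean((pm$phi - truth)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("noise is reproducible from the seed and clamped at zero", {
  fd <- const_decomp(b = 0.9, dphi = pi)   # dark fringe near zero intensity
  s1 <- simulate_interferograms(fd, noise_sd = 0.5, seed = 7)
  s2 <- simulate_interferograms(fd, noise_sd = 0.5, seed = 7)
  s3 <- simulate_interferograms(fd, noise_sd = 0.5, seed = 8)
  expect_identical(s1$frames, s2$frames)
  expect_false(identical(s1$frames, s3$frames))
  expect_true(all(s1$frames$f0 >= 0))
})

test_that("constructors validate shapes and arguments", {
  expect_error(field_decomposition(matrix(1, 2, 2), matrix(1, 3, 3),
                                   matrix(0, 2, 2)), "shape")
  expect_error(field_decomposition(matrix(-1, 2, 2), matrix(1, 2, 2),
                                   matrix(0, 2, 2)), "nonnegative")
  expect_error(simulate_interferograms(const_decomp(), noise_sd = -1),
               "nonnegative")
  expect_error(interferogram_stack(list(matrix(1, 2, 2))), "four")
  expect_error(phase_map(matrix(c(0, NA), 1, 2)), "finite")
})
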