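test_that("amplitude scaling recovers known global factors", {
  toy <- toy4()
  sf <- structure_factors_direct(toy)
  r <- sf$reflections
  sc <- scale_amplitudes(r, r, mode = "global")
  expect_equal(sc$k, 1, tolerance = 1e-12)
  dark2 <- reflection_set(r$cell, r$hkl, 2 * r$f)
  sc2 <- scale_amplitudes(r, dark2, mode = "global")
  expect_equal(sc2$k, 2, tolerance = 1e-12)
  expect_equal(sc2$light$f, dark2$f, tolerance = 1e-12)
  expect_error(scale_amplitudes(
    reflection_set(r$cell, matrix(c(1, 0, 0), 1), 1),
    reflection_set(r$cell, matrix(c(0, 2, 0), 1), 1)), "no common")
})

test_that("shell scaling beats global scaling under a B-factor-like falloff", {
  toy <- toy4()
  r <- structure_factors_direct(toy)$reflections
  # resolution-dependent falloff emulating a relative B factor
  s2 <- 1 / d_spacing(r$cell, r$hkl)^2
  light <- reflection_set(r$cell, r$hkl, r$f * exp(-5 * s2))
  g <- scale_amplitudes(light, r, mode = "global")
  s <- scale_amplitudes(light, r, mode = "shells")
  expect_lt(s$residual, g$residual)
})

test_that("light = dark yields the all-zero difference map", {
  toy <- toy4()
  sf <- structure_factors_direct(toy)
  map <- compute_difference_map(sf$reflections, sf$reflections, sf$phases)
  expect_equal(max(abs(map$values)), 0, tolerance = 1e-12)
  expect_equal(map$sigma, 0, tolerance = 1e-12)
})

test_that("deleting an atom produces a negative feature at its site", {
  toy <- toy4()
  dark <- structure_factors_direct(toy)
  lt <- perturb_crystal(toy, "delete_atom", atom = 4)
  light <- structure_factors_direct(lt)
  map <- compute_difference_map(light$reflections, dark$reflections,
                                dark$phases, scale_mode = "none")
  # minimum within one grid step of the deleted water position
  imin <- which(map$values == min(map$values), arr.ind = TRUE)[1, ]
  frac_min <- (imin - 1) / map$dim
  site <- unlist(toy$atoms[4, c("fx", "fy", "fz")])
  step <- max(map$cell[1:3] / map$dim)
  d <- sqrt(sum((orthogonalization_matrix(map$cell) %*%
                   ((frac_min - site) - round(frac_min - site)))^2))
  expect_lt(d, step + 1e-9)
  expect_lt(min(map$values), 0)
  # peak search assigns the strongest negative feature to the deleted water
  feats <- peak_search(map, 3, crystal_sites(toy))
  neg <- feats[feats$value_sigma < 0, ]
  expect_equal(neg$resid[1], 4)
  expect_equal(neg$atom[1], "O")
  expect_lt(neg$value_sigma[1], -3)
})

test_that("map variance obeys the Parseval identity", {
  toy <- toy4()
  dark <- structure_factors_direct(toy)
  lt <- perturb_crystal(toy, "shift_atom", atom = 2,
                        shift_frac = c(0.02, 0, -0.015))
  light <- structure_factors_direct(lt)
  map <- compute_difference_map(light$reflections, dark$reflections,
                                dark$phases, scale_mode = "none")
  df <- light$reflections$f - dark$reflections$f
  V <- cell_volume(toy$cell)
  # Friedel completion doubles the half-set power sum
  expect_equal(mean(map$values^2), 2 * sum(df^2) / V^2, tolerance = 1e-6)
})

test_that("difference synthesis is linear in the coefficients", {
  toy <- toy4()
  dark <- structure_factors_direct(toy)
  l1 <- structure_factors_direct(perturb_crystal(toy, "delete_atom", atom = 4))
  l2 <- structure_factors_direct(perturb_crystal(toy, "scale_weight",
                                                 atom = 1, factor = 0.7))
  grid <- c(32, 28, 24)
  m1 <- compute_difference_map(l1$reflections, dark$reflections, dark$phases,
                               grid = grid, scale_mode = "none")
  m2 <- compute_difference_map(l2$reflections, dark$reflections, dark$phases,
                               grid = grid, scale_mode = "none")
  # a combined light set whose dF is the sum of the two perturbations' dF
  fsum <- l1$reflections$f + l2$reflections$f - dark$reflections$f
  lsum <- reflection_set(toy$cell, dark$reflections$hkl, pmax(fsum, 0))
  msum <- compute_difference_map(lsum, dark$reflections, dark$phases,
                                 grid = grid, scale_mode = "none")
  expect_equal(msum$values, m1$values + m2$values,
               tolerance = 1e-10 * max(abs(msum$values)))
})

test_that("FFT synthesis agrees with brute-force direct summation", {
  toy <- toy_small()
  dark <- structure_factors_direct(toy)
  light <- structure_factors_direct(
    perturb_crystal(toy, "delete_atom", atom = 2))
  map <- compute_difference_map(light$reflections, dark$reflections,
                                dark$phases, scale_mode = "none",
                                grid = c(15, 15, 15))
  df <- light$reflections$f - dark$reflections$f
  coeff <- df * exp(1i * dark$phases$phi * pi / 180)
  # sample a handful of grid points against the independent oracle
  pts <- rbind(c(0, 0, 0), c(3, 5, 7), c(10, 1, 4), c(7, 14, 9), c(2, 9, 12))
  frac <- sweep(pts, 2, c(15, 15, 15), "/")
  oracle <- direct_synthesis_oracle(toy$cell, dark$phases$hkl, coeff, frac)
  got <- map$values[pts + 1]
  expect_equal(got, oracle, tolerance = 1e-6 * max(abs(oracle)))
})

test_that("missing phases for retained reflections are an error", {
  toy <- toy_small()
  sf <- structure_factors_direct(toy)
  light <- structure_factors_direct(
    perturb_crystal(toy, "delete_atom", atom = 2))
  short <- phase_set(sf$phases$hkl[-1, , drop = FALSE], sf$phases$phi[-1])
  expect_error(compute_difference_map(light$reflections, sf$reflections,
                                      short, scale_mode = "none"),
               "missing phase")
})

test_that("peak search is antisymmetric under a map sign flip", {
  toy <- toy4()
  dark <- structure_factors_direct(toy)
  light <- structure_factors_direct(
    perturb_crystal(toy, "delete_atom", atom = 4))
  map <- compute_difference_map(light$reflections, dark$reflections,
                                dark$phases, scale_mode = "none")
  flipped <- real_space_map(map$cell, -map$values)
  f1 <- peak_search(map, 3, crystal_sites(toy))
  f2 <- peak_search(flipped, 3, crystal_sites(toy))
  expect_equal(nrow(f1), nrow(f2))
  expect_equal(f1[, c("fx", "fy", "fz")], f2[, c("fx", "fy", "fz")])
  expect_equal(f1$value_sigma, -f2$value_sigma, tolerance = 1e-12)
  # zero map: empty feature list
  zero <- real_space_map(map$cell, array(0, map$dim))
  expect_equal(nrow(peak_search(zero, 3, crystal_sites(toy))), 0)
})

test_that("site features report the signed extremum found by exhaustive scan", {
  toy <- toy4()
  dark <- structure_factors_direct(toy)
  light <- structure_factors_direct(
    perturb_crystal(toy, "delete_atom", atom = 4))
  map <- compute_difference_map(light$reflections, dark$reflections,
                                dark$phases, scale_mode = "none")
  site <- unlist(toy$atoms[4, c("fx", "fy", "fz")])
  v <- feature_at_site(map, site, 1.5)
  # oracle: exhaustive grid scan within the radius
  O <- orthogonalization_matrix(map$cell)
  d <- map$dim
  best <- 0
  for (i in 0:(d[1] - 1)) for (j in 0:(d[2] - 1)) for (k in 0:(d[3] - 1)) {
    df <- c(i / d[1], j / d[2], k / d[3]) - site
    df <- df - round(df)
    if (sqrt(sum((O %*% df)^2)) <= 1.5) {
      val <- map$values[i + 1, j + 1, k + 1]
      if (abs(val) > abs(best)) best <- val
    }
  }
  expect_equal(v, best / map$sigma, tolerance = 1e-12)
  expect_lt(v, 0)
  # zero map gives 0; radius below grid spacing refused
  zero <- real_space_map(map$cell, array(0, map$dim))
  expect_equal(feature_at_site(zero, site, 1.5), 0)
  expect_error(feature_at_site(map, site, 0.1), "grid spacing")
  # locality: a site far from the perturbation sees < 1 sigma. Constructed
  # with a phase-preserving perturbation (weight scaling of a one-atom
  # crystal) so the synthesis equals the exact difference density and the
  # far-site value is only the small F(000) offset, not the background the
  # dark-phase approximation scatters from large perturbations.
  one <- toy_crystal(c(10, 10, 10, 90, 90, 90),
                     data.frame(chain = "A", resid = 1, atom = "O",
                                fx = 0.3, fy = 0.3, fz = 0.3,
                                width = 1, weight = 10), d_min = 1.2)
  done <- structure_factors_direct(one)
  lone <- structure_factors_direct(
    perturb_crystal(one, "scale_weight", atom = 1, factor = 0.5))
  mone <- compute_difference_map(lone$reflections, done$reflections,
                                 done$phases, scale_mode = "none")
  expect_lt(abs(feature_at_site(mone, c(0.8, 0.8, 0.8), 0.8)), 1)
})
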