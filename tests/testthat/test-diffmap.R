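cell <- c(20, 24, 28, 90, 90, 90)

make_refl <- function(f, sigf = 0, seed = NULL, d_min = 3) {
  hkl <- generate_hkl(cell, d_min, include_f000 = FALSE)
  n <- nrow(hkl)
  reflection_set(hkl, f(n), rep(sigf, length.out = n), cell = cell,
                 d_min = d_min)
}

test_that("least-squares scaling recovers exact and noisy scale factors", {
  wt <- make_refl(function(n) runif(n, 1, 10))
  mut <- wt; mut$F <- 2 * wt$F
  sc <- scale_to_reference(mut, wt)
  expect_equal(attr(sc, "scale"), 0.5)
  expect_equal(sc$F, wt$F)

  expect_equal(attr(scale_to_reference(wt, wt), "scale"), 1)

  set.seed(42)
  mut3 <- wt
  mut3$F <- 3 * wt$F + rnorm(nrow(wt), sd = 0.01 * 3 * wt$F)
  sc3 <- scale_to_reference(mut3, wt)
  # closed-form least squares as oracle
  k_oracle <- sum(mut3$F * wt$F) / sum(mut3$F^2)
  expect_equal(attr(sc3, "scale"), k_oracle, tolerance = 1e-12)
  expect_lt(abs(attr(sc3, "scale") - 1 / 3), 0.01 / 3)
})

test_that("scaling rejects incompatible or insufficient data", {
  wt <- make_refl(function(n) runif(n, 1, 10))
  small <- wt[1:5, ]
  attributes(small)[c("cell", "spacegroup", "d_min", "d_max")] <-
    attributes(wt)[c("cell", "spacegroup", "d_min", "d_max")]
  class(small) <- class(wt)
  expect_error(scale_to_reference(small, wt), "10 common")
  wt2 <- reflection_set(as.matrix(wt[, c("h", "k", "l")]), wt$F, wt$sigF,
                        cell = cell * c(1.1, 1, 1, 1, 1, 1))
  expect_error(scale_to_reference(wt2, wt), "unit cell")
})

test_that("difference weights follow the error-model formula", {
  model <- random_toy_model(5, cell, seed = 1)
  wt <- make_refl(function(n) runif(n, 5, 10))
  # all sigma = 0, alpha = 0 -> every weight 1
  mut <- wt; mut$F <- wt$F + runif(nrow(wt), -1, 1)
  wd0 <- weighted_differences(mut, wt, alpha = 0, phase_source = model)
  expect_true(all(wd0$w == 1))

  # sigma = 0, alpha = 0.05, all |dF| equal so dF^2 = <dF^2> -> w = 1/1.05
  mut2 <- wt; mut2$F <- wt$F + 2
  wd1 <- weighted_differences(mut2, wt, alpha = 0.05, phase_source = model)
  expect_equal(wd1$w, rep(1 / 1.05, nrow(wd1)), tolerance = 1e-12)

  # random fixture vs an independent one-line evaluation of the formula
  set.seed(7)
  hkl <- generate_hkl(cell, 5, include_f000 = FALSE)[1:20, ]
  fw <- runif(20, 5, 15); fm <- fw + rnorm(20)
  sw <- runif(20, 0.1, 0.5); sm <- runif(20, 0.1, 0.5)
  wtr <- reflection_set(hkl, fw, sw, cell = cell)
  mur <- reflection_set(hkl, fm, sm, cell = cell)
  wd <- weighted_differences(mur, wtr, alpha = 0.05, phase_source = model)
  key <- paste(wd$h, wd$k, wd$l)
  ord <- match(paste(hkl[, 1], hkl[, 2], hkl[, 3]), key)
  dF <- fm - fw; s2 <- sm^2 + sw^2
  w_oracle <- 1 / (1 + s2 / mean(s2) + 0.05 * dF^2 / mean(dF^2))
  expect_equal(wd$w[ord], w_oracle, tolerance = 1e-12)

  expect_error(weighted_differences(mur, wtr, alpha = -1,
                                    phase_source = model), "alpha")
})

test_that("map synthesis matches the direct Fourier sum and is linear", {
  model <- random_toy_model(5, cell, seed = 2)
  # all-zero amplitudes -> exactly zero grid
  wd0 <- structure(
    data.frame(h = c(1L, 2L), k = 0L, l = 0L, dF = 0, sigdF = 0, w = 1,
               wdF = 0, phi = 0),
    cell = cell, d_min = 3, alpha = 0,
    class = c("weighted_differences", "data.frame"))
  expect_true(all(synthesize_map(wd0)$data == 0))

  # single reflection (1,0,0), amplitude A, phase 0 -> cosine along x with
  # peak 2A/V at the origin; compare against direct evaluation at 8 points
  A_amp <- 3.7
  V <- prod(cell[1:3])
  wd1 <- structure(
    data.frame(h = 1L, k = 0L, l = 0L, dF = A_amp, sigdF = 0, w = 1,
               wdF = A_amp, phi = 0),
    cell = cell, d_min = 3, alpha = 0,
    class = c("weighted_differences", "data.frame"))
  g <- synthesize_map(wd1)
  dims <- dim(g$data)
  expect_equal(g$data[1, 1, 1], 2 * A_amp / V, tolerance = 1e-12)
  for (i in seq(1, dims[1], length.out = 8)) {
    i <- round(i)
    x <- (i - 1) / dims[1]
    expect_equal(g$data[i, 1, 1], 2 * A_amp * cos(2 * pi * x) / V,
                 tolerance = 1e-10)
  }
  # linearity: doubling all amplitudes doubles every voxel
  wd2 <- wd1; wd2$wdF <- 2 * wd1$wdF
  attributes(wd2)[c("cell", "d_min")] <- list(cell, 3)
  class(wd2) <- class(wd1)
  expect_equal(synthesize_map(wd2)$data, 2 * g$data, tolerance = 1e-12)
})

test_that("grid variance obeys Parseval on complete synthetic data", {
  m <- make_toy_crystal(15, seed = 6)
  wt <- simulate_reflections(m, d_min = 2.5, noise_frac = 0, seed = 6)
  mut <- simulate_reflections(m, d_min = 2.5, noise_frac = 0.05, seed = 8)
  wd <- weighted_differences(mut, wt, alpha = 0.05, phase_source = m)
  g <- synthesize_map(wd)
  V <- prod(m$cell[1:3])
  f000 <- wd$h == 0 & wd$k == 0 & wd$l == 0
  expected <- 2 * sum(wd$wdF[!f000]^2) / V^2
  observed <- mean(g$data^2) - mean(g$data)^2
  expect_equal(observed, expected, tolerance = 0.01)
})

test_that("iaddat resolves a single hand-placed voxel correctly", {
  gcell <- c(16, 16, 16, 90, 90, 90)
  dims <- c(16, 16, 16)
  # residue 5 has one heavy atom at (4, 4, 4); voxel at (5, 4, 4) is 1.0 A
  # away
  at <- make_atoms("A", c(4, 5, 6), "ALA", "CA", "C",
                   rbind(c(10, 12, 4), c(4, 4, 4), c(12, 4, 12)))
  model <- atomic_model(at, cell = gcell)
  arr <- array(0, dims)
  arr[6, 5, 5] <- 0.08   # grid step 1 A; fractional (5,4,4)/16
  g <- density_grid(arr, gcell)
  tr <- iaddat(g, model, threshold = 0.04, radius = 1.5)
  expect_track_scores(tr, list("A:5" = 0.08, "A:4" = 0, "A:6" = 0))
  # raising the threshold above the voxel silences everything
  tr2 <- iaddat(g, model, threshold = 0.10, radius = 1.5)
  expect_true(all(tr2$score == 0))
  # zero grid -> all zero
  tr3 <- iaddat(density_grid(array(0, dims), gcell), model)
  expect_true(all(tr3$score == 0))
})

test_that("iaddat equals the brute-force voxel-scan oracle on random cases", {
  for (seed in 1:8) {
    set.seed(seed + 100)
    gcell <- c(12, 14, 10, 90, 90, 90)
    dims <- c(sample(8:16, 1), sample(8:16, 1), sample(8:16, 1))
    model <- random_toy_model(6, gcell, seed = seed)
    arr <- array(rnorm(prod(dims), sd = 0.05), dims)
    g <- density_grid(arr, gcell)
    got <- iaddat(g, model, threshold = 0.04, radius = 1.5)
    want <- iaddat_oracle(g, model, threshold = 0.04, radius = 1.5)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("iaddat is monotone in threshold and radius, linear in density", {
  gcell <- c(12, 12, 12, 90, 90, 90)
  model <- random_toy_model(5, gcell, seed = 3)
  set.seed(33)
  g <- density_grid(array(rnorm(12^3, sd = 0.05), c(12, 12, 12)), gcell)
  lo <- iaddat(g, model, threshold = 0.02, radius = 1.5)
  hi <- iaddat(g, model, threshold = 0.08, radius = 1.5)
  expect_true(all(hi$score <= lo$score + 1e-14))
  narrow <- iaddat(g, model, threshold = 0.02, radius = 1.0)
  wide <- iaddat(g, model, threshold = 0.02, radius = 2.5)
  expect_true(all(narrow$score <= wide$score + 1e-14))
  # with threshold 0, scaling the map scales every residue score
  base <- iaddat(g, model, threshold = 0, radius = 1.5)
  g3 <- density_grid(3 * g$data, gcell)
  scaled <- iaddat(g3, model, threshold = 0, radius = 1.5)
  expect_equal(scaled$score, 3 * base$score, tolerance = 1e-12)
})

test_that("normalization and display capping behave as specified", {
  tr <- residue_track(data.frame(chain = "A", resnum = 1:3,
                                 score = c(2, 1, 0.4)), modality = "iaddat")
  nt <- normalize_track(tr)
  expect_equal(nt$score, c(1, 0.5, 0.2))
  # all-zero track is untouched
  z <- residue_track(data.frame(chain = "A", resnum = 1:2, score = c(0, 0)),
                     modality = "iaddat")
  expect_equal(normalize_track(z)$score, c(0, 0))
  # capping writes a display column, raw values preserved
  capped <- normalize_track(tr, cap = 0.3)
  expect_equal(capped$display, c(0.3, 0.3, 0.2))
  expect_equal(capped$score, c(1, 0.5, 0.2))
  neg <- residue_track(data.frame(chain = "A", resnum = 1, score = -1),
                       modality = "iaddat")
  expect_error(normalize_track(neg), "non-negative")
})

test_that("reflection CSV input/output round-trips", {
  wt <- make_refl(function(n) runif(n, 1, 10), sigf = 0.3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_reflections_csv(wt, f)
  back <- read_reflections_csv(f, cell = cell)
  expect_equal(back$F, wt$F, tolerance = 1e-12)
  expect_equal(back$sigF, wt$sigF, tolerance = 1e-12)
  expect_identical(back$h, wt$h)
})
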