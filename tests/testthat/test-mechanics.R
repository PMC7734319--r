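test_that("K_A direct evaluation matches the closed form", {
  # alternating series: mean exactly 100 nm^2, population variance 0.1 nm^4
  x <- rep(c(100 + sqrt(0.1), 100 - sqrt(0.1)), 50)
  ka <- area_compressibility(x, 303)
  want <- kBT(303) * 100 / 0.1 * 1e21
  expect_equal(ka$K_A, want, tolerance = 1e-12)
  expect_equal(ka$mean_area, 100, tolerance = 1e-12)
  expect_equal(ka$var_area, 0.1, tolerance = 1e-12)
})

test_that("constant area series is flagged degenerate", {
  expect_warning(ka <- area_compressibility(rep(64, 500), 303),
                 "degenerate")
  expect_identical(ka$K_A, Inf)
  expect_identical(ka$flag, "degenerate")
})

test_that("long-correlation series is flagged unreliable", {
  set.seed(301)
  n <- 400
  x <- numeric(n); x[1] <- 0
  phi <- exp(-1 / 60)            # correlation time 60 frames > n/20
  for (t in 2:n) x[t] <- phi * x[t - 1] + rnorm(1, 0, sqrt(1 - phi^2))
  ka <- area_compressibility(100 + x, 303)
  expect_identical(ka$flag, "unreliable")
  expect_gt(ka$corr_time, n / 20)
})

test_that("area series reports APL with and without sterols", {
  out <- small_fixture()
  ar <- area_series(out$view)
  a1 <- unname(out$view$box[1, 1] * out$view$box[1, 2])
  expect_equal(ar$area[1], a1, tolerance = 1e-12)
  expect_equal(ar$apl[1], 100 * a1 / 36, tolerance = 1e-12)
  n_chol <- sum(out$truth$lipid_type == "CHOL")
  expect_equal(ar$apl_excl_chol[1], 100 * a1 / ((72 - n_chol) / 2),
               tolerance = 1e-12)
})

test_that("bending modulus is exact on a noiseless q^-2 spectrum", {
  K_C <- 1.3e-19
  q <- c(0.3, 0.42, 0.6, 0.85, 1.2)
  spec <- structure(data.frame(q = q, power = kBT(303) / (K_C * q^2),
                               n_modes = c(8, 4, 8, 12, 4)),
                    class = c("director_spectrum", "data.frame"))
  est <- bending_modulus(spec, 303, bilayer_thickness = 1.5)
  expect_equal(est$K_C, K_C, tolerance = 1e-6)
  expect_equal(est$se, 0, tolerance = 1e-20)
  # bins beyond the 3-thickness wavelength cutoff are excluded from the fit
  spoiled <- rbind(spec, data.frame(q = 2.5, power = 99, n_modes = 100))
  class(spoiled) <- class(spec)
  est2 <- bending_modulus(spoiled, 303, bilayer_thickness = 1.5)
  expect_equal(est2$K_C, K_C, tolerance = 1e-6)
  expect_equal(est2$n_bins, 5L, ignore_attr = TRUE)
  expect_lte(est2$q_fit_max, 2 * pi / (3 * 1.5))
  # too few admissible bins is an error, not a silent extrapolation
  expect_error(bending_modulus(spec[1:2, ], 303, 1.5), "4 q-bins")
})

test_that("lateral diffusion recovers a known random-walk D", {
  set.seed(302)
  nf <- 1500L; n <- 120L
  sigma <- 0.05                  # nm per step per axis; dt = 1 ns
  xy <- array(0, c(nf, n, 2))
  xy[1, , ] <- matrix(runif(2 * n, 0, 500), n, 2)
  for (t in 2:nf) xy[t, , ] <- xy[t - 1, , ] + rnorm(2 * n, 0, sigma)
  v <- walk_view(xy)
  D_true <- sigma^2 / 2 * 1e-14 / 1e-9     # nm^2/ns -> cm^2/s
  est <- lateral_diffusion(v, leaflets = NULL, fit_window = c(1, 50))
  expect_equal(est$D_cm2_s, D_true, tolerance = 0.05)
  expect_false(est$anomalous)
})

test_that("static lipids give near-zero D and an anomalous warning", {
  set.seed(303)
  nf <- 400L; n <- 30L
  xy <- array(rep(matrix(runif(2 * n, 0, 50), n, 2), each = nf),
              c(nf, n, 2))
  xy <- xy + array(rnorm(nf * n * 2, 0, 0.02), c(nf, n, 2))  # pure jitter
  v <- walk_view(xy)
  expect_warning(est <- lateral_diffusion(v, leaflets = NULL,
                                          fit_window = c(5, 100)),
                 "anomalous|sublinear")
  expect_lt(est$D_cm2_s, 1e-8)
})

test_that("contact counts respect the xy minimum image", {
  defs <- list(AAA = lipid_definition(
    "AAA", "sterol", tail_vectors = list(c("HD", "T1E")),
    head_ref_atom = "HD"),
    BBB = lipid_definition(
      "BBB", "sterol", tail_vectors = list(c("HD", "T1E")),
      head_ref_atom = "HD"))
  at <- data.frame(resid = c(1L, 1L, 2L, 2L),
                   resname = c("AAA", "AAA", "BBB", "BBB"),
                   atom = c("HD", "T1E", "HD", "T1E"))
  co <- array(0, c(1, 4, 3))
  co[1, 1, ] <- c(0.2, 1, 1); co[1, 2, ] <- c(0.2, 1, 0.5)
  # across the periodic x boundary: true dx = 0.4
  co[1, 3, ] <- c(4.8, 1, 1); co[1, 4, ] <- c(4.8, 1, 0.5)
  v <- trajectory_view(co, c(5, 5, 3), 0, at, defs)
  expect_equal(contact_counts(v, "AAA", "BBB", cutoff = 0.5)$contacts, 2)
  expect_equal(contact_counts(v, "AAA", "BBB", cutoff = 0.3)$contacts, 0)
})

test_that("director spectrum recovers K_C from the synthetic field", {
  # thin proxy geometry: >= 4 q-bins inside the 3-thickness window
  spec <- synthetic_spec(seed = 4, n_lipids_per_leaflet = 128,
                         n_frames = 300, solute = list(n = 0L),
                         director_model = list(K_C = 1.3e-19, n_max = 3L),
                         geometry = list(head_z = 0.55, backbone_dz = 0.2,
                                         chain_top_dz = 0.25, box_z = 4))
  out <- gen_bilayer_trajectory(spec)
  lf <- assign_leaflets(out$view)
  ds <- director_spectrum(out$view, lf, n_max = 3L)
  est <- bending_modulus(ds, 303, bilayer_thickness = 1.1)
  expect_equal(est$K_C, 1.3e-19, tolerance = 0.1)
  expect_gte(est$n_bins, 4L)
})
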