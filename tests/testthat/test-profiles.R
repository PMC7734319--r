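srt_view <- function(rot = diag(3), shift = c(2, 2, 2)) {
  tmpl <- memdomain:::solute_template()
  pos <- t(rot %*% t(tmpl)) + matrix(shift, nrow(tmpl), 3, byrow = TRUE)
  defs <- list(SRT = lipid_definition(
    "SRT", "solute", probe_atom = "O1",
    com_atoms = c(sprintf("B%d", 1:6), "N1", "CP1", "CP2", "O1"),
    ring_atoms = list(benzene = sprintf("B%d", 1:6),
                      pyrrole = c("B1", "B2", "N1", "CP1", "CP2"))))
  at <- data.frame(resid = 1L, resname = "SRT",
                   atom = c(sprintf("B%d", 1:6), "N1", "CP1", "CP2", "O1"))
  trajectory_view(array(pos, c(1, nrow(pos), 3)), c(4, 4, 4), 0, at, defs)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

test_that("probability density integrates to one; number mode counts", {
  out <- small_fixture()
  v <- out$view
  heads <- select_atoms(v, atom = "HD")
  dp <- density_profile(v, atoms = heads)
  bw <- attr(dp, "bin_width")
  expect_equal(sum(dp$density) * bw, 1, tolerance = 1e-9)
  dn <- density_profile(v, atoms = heads, mode = "number")
  expect_equal(sum(dn$density) * bw, length(heads), tolerance = 1e-9)
  # two head peaks on opposite sides of the center
  expect_gt(max(dp$density[dp$z > 0]), 0)
  expect_gt(max(dp$density[dp$z < 0]), 0)
  sym <- density_profile(v, atoms = heads, symmetrize = TRUE)
  ds <- sym$density
  expect_equal(ds, rev(ds), tolerance = 0.3, ignore_attr = TRUE)
})

test_that("region boundaries and classify_z on hand-made profiles", {
  z <- seq(-3.05, 3.05, by = 0.1)
  mk <- function(lo, hi) {
    d <- as.numeric((abs(z) >= lo) & (abs(z) <= hi))
    structure(data.frame(z = z, density = d / (sum(d) * 0.1)),
              class = c("density_profile", "data.frame"),
              mode = "probability", symmetrized = FALSE, bin_width = 0.1)
  }
  choline <- mk(1.8, 2.2)
  backbone <- mk(1.3, 1.7)
  b <- region_boundaries(choline, backbone)
  # supports are bin-center ranges: choline centers span 1.85..2.15
  expect_equal(b$headgroup_upper, c(1.35, 2.15), tolerance = 0.011)
  expect_equal(b$headgroup_lower, c(-2.15, -1.35), tolerance = 0.011)
  expect_equal(b$core_halfwidth, 1.35, tolerance = 0.011)
  got <- classify_z(c(0, 1.5, 2.5, -2.0, -0.5), b)
  expect_equal(got, c("core", "headgroup", "solvent", "headgroup", "core"))
})

test_that("solute binding classification matches generator truth", {
  out <- small_fixture()
  v <- out$view
  den_h <- density_profile(v, atoms = select_atoms(v, atom = "HD"))
  den_b <- density_profile(v, atoms = select_atoms(v, atom = "BB"))
  bnd <- region_boundaries(den_h, den_b)
  cb <- classify_binding(v, "SRT", bnd)
  truth <- out$truth$solute_regions_realized
  expect_equal(cb$summary$percent, unname(unlist(truth)),
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(cb$summary$region, c("core", "headgroup", "solvent"))
  # contact percentages are defined and sum to 100
  expect_equal(sum(cb$contact_summary$percent), 100, tolerance = 1e-9)
})

test_that("PMF of Gaussian samples is harmonic with min at zero", {
  set.seed(501)
  sig <- 0.25
  x <- rnorm(20000, 0, sig)
  pmf <- pmf_from_density(x, 303)
  expect_equal(min(pmf$F), 0)
  expect_equal(attr(pmf, "components"), 1L, ignore_attr = TRUE)
  kT <- kBT(303, "kcal/mol")
  sel <- abs(pmf$z) < 2 * sig & !pmf$censored
  expect_equal(pmf$F[sel],
               kT * (pmf$z[sel] - pmf$z[which.min(pmf$F)])^2 / (2 * sig^2),
               tolerance = 0.08, ignore_attr = TRUE)
  expect_error(pmf_from_density(rnorm(50), 303), "100")
})

test_that("indole frame: theta tracks out-of-plane tilt, alpha azimuth", {
  # flat template: plane normal along +/- lab z
  o0 <- indole_orientation(srt_view(), "SRT")
  expect_equal(nrow(o0), 1L)
  theta0 <- o0$theta
  expect_true(abs(theta0) < 1e-6 || abs(theta0 - 180) < 1e-6)
  s <- if (theta0 < 90) 1 else -1
  for (a in c(30, 60, 90)) {
    oa <- indole_orientation(srt_view(rot_x(a)), "SRT")
    want <- if (s > 0) a else 180 - a
    expect_equal(oa$theta, want, tolerance = 1e-6)
  }
  # rotating the molecule about the lab normal changes neither angle
  o1 <- indole_orientation(srt_view(rot_x(40)), "SRT")
  o2 <- indole_orientation(srt_view(rot_z(73) %*% rot_x(40)), "SRT")
  expect_equal(o2$theta, o1$theta, tolerance = 1e-6)
  expect_equal(o2$alpha, o1$alpha, tolerance = 1e-6)
})

test_that("orientation histogram bins all samples", {
  out <- small_fixture()
  den_h <- density_profile(out$view, atoms = select_atoms(out$view,
                                                          atom = "HD"))
  den_b <- density_profile(out$view, atoms = select_atoms(out$view,
                                                          atom = "BB"))
  bnd <- region_boundaries(den_h, den_b)
  ori <- indole_orientation(out$view, "SRT", bnd)
  h <- orientation_histogram(ori)
  expect_equal(sum(h$count), nrow(ori))
  expect_true(all(h$theta >= 0 & h$theta <= 180))
  expect_true(all(h$alpha >= 0 & h$alpha < 360))
  hh <- orientation_histogram(ori, region = "headgroup")
  expect_equal(sum(hh$count), sum(ori$region == "headgroup"))
})
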