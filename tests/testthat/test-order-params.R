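# Hand-built single-lipid views with prescribed bond/tail angles.
angle_view <- function(theta_deg, species = "phospholipid") {
  th <- theta_deg * pi / 180
  dirv <- c(sin(th), 0, cos(th))
  if (species == "phospholipid") {
    defs <- list(LIP = lipid_definition(
      "LIP", "phospholipid", tail_vectors = list(c("T1S", "T1E")),
      ch_pairs = list(list(c("C01", "H01A"))), head_ref_atom = "HD"))
    at <- data.frame(resid = 1L, resname = "LIP",
                     atom = c("HD", "T1S", "T1E", "C01", "H01A"))
    co <- array(0, c(1, 5, 3))
    co[1, 1, ] <- c(5, 5, 7)
    co[1, 2, ] <- c(5, 5, 6)
    co[1, 3, ] <- c(5, 5, 6) - 1.2 * dirv
    co[1, 4, ] <- c(5, 5, 5.5)
    co[1, 5, ] <- c(5, 5, 5.5) + 0.109 * dirv
  } else {
    defs <- list(LIP = lipid_definition(
      "LIP", "sterol", tail_vectors = list(c("T1S", "T1E")),
      head_ref_atom = "HD"))
    at <- data.frame(resid = 1L, resname = "LIP",
                     atom = c("HD", "T1S", "T1E"))
    co <- array(0, c(1, 3, 3))
    co[1, 1, ] <- c(5, 5, 7)
    co[1, 2, ] <- c(5, 5, 6)
    co[1, 3, ] <- c(5, 5, 6) - 1.2 * dirv
  }
  trajectory_view(co, c(10, 10, 14), 0, at, defs)
}

test_that("P2 follows the second Legendre polynomial of the tail angle", {
  for (th in c(0, 30, 90)) {
    p2_expected <- (3 * cos(th * pi / 180)^2 - 1) / 2
    v2 <- two_lipid_view(th)
    lf2 <- suppressWarnings(assign_leaflets(v2))
    p2 <- compute_p2(v2, lf2)
    # phospholipids store |P2| averaged over tails
    expect_equal(unname(p2$values[1, 1]), abs(p2_expected),
                 tolerance = 1e-12)
  }
})

test_that("S_CH is exact for 0, 90, magic-angle and 45-degree bonds", {
  magic <- acos(1 / sqrt(3)) * 180 / pi
  cases <- list(c(0, 1), c(90, -0.5), c(magic, 0), c(45, 0.25))
  for (cs in cases) {
    v <- two_lipid_view(cs[1])
    sch <- compute_sch(v)
    got <- sch$s_ch[sch$stratum == "all"][1]
    expect_equal(got, cs[2], tolerance = 1e-12,
                 label = sprintf("S_CH at %.4f degrees", cs[1]))
  }
})

test_that("sterol P2 keeps its sign; phospholipid P2 is |P2|", {
  # a sterol tilted past the magic angle has negative P2
  v <- angle_view(70, species = "sterol")
  lf <- list(lipid_ids = 1L,
             leaflet = matrix("upper", 1, 1),
             center_z = 0, frames = 1L)
  class(lf) <- "leaflet_assignment"
  p2 <- compute_p2(v, lf)
  expect_lt(p2$values[1, 1], 0)
  expect_equal(unname(p2$values[1, 1]),
               (3 * cos(70 * pi / 180)^2 - 1) / 2, tolerance = 1e-12)
})

test_that("zero-length tail vectors warn and give NaN/NA", {
  defs <- list(LIP = lipid_definition(
    "LIP", "phospholipid", tail_vectors = list(c("T1S", "T1E")),
    ch_pairs = list(list(c("T1S", "T1E"))), head_ref_atom = "HD"))
  at <- data.frame(resid = rep(1:2, each = 3), resname = "LIP",
                   atom = rep(c("HD", "T1S", "T1E"), 2))
  co <- array(0, c(1, 6, 3))
  co[1, 1, ] <- c(1, 1, 2); co[1, 2, ] <- c(1, 1, 1.5)
  co[1, 3, ] <- c(1, 1, 1.5)                 # degenerate tail
  co[1, 4, ] <- c(3, 3, 0); co[1, 5, ] <- c(3, 3, 0.5)
  co[1, 6, ] <- c(3, 3, 1.5)
  v <- trajectory_view(co, c(5, 5, 4), 0, at, defs)
  lf <- suppressWarnings(assign_leaflets(v))
  expect_warning(p2 <- compute_p2(v, lf), "zero-length")
  expect_true(is.na(p2$values[1, 1]))
  expect_false(is.na(p2$values[1, 2]))
})

test_that("tail vectors respect the minimum image convention", {
  defs <- list(LIP = lipid_definition(
    "LIP", "sterol", tail_vectors = list(c("T1S", "T1E")),
    head_ref_atom = "HD"))
  at <- data.frame(resid = c(1L, 1L, 1L), resname = "LIP",
                   atom = c("HD", "T1S", "T1E"))
  # tail crosses the periodic x boundary: T1S near x=0, T1E near x=L
  co <- array(0, c(1, 3, 3))
  co[1, 1, ] <- c(0.1, 2, 3)
  co[1, 2, ] <- c(0.1, 2, 2)
  co[1, 3, ] <- c(4.9, 2, 1)   # true displacement (-0.2, 0, -1)
  v <- trajectory_view(co, c(5, 5, 6), 0, at, defs)
  lf <- list(lipid_ids = 1L, leaflet = matrix("upper", 1, 1),
             center_z = 0, frames = 1L)
  class(lf) <- "leaflet_assignment"
  p2 <- compute_p2(v, lf)
  cos2 <- 1 / (1 + 0.04)        # cos^2 from (-0.2, 0, -1)
  expect_equal(unname(p2$values[1, 1]), (3 * cos2 - 1) / 2,
               tolerance = 1e-12)
})

test_that("stratified S_CH recovers generator targets on the fixture", {
  out <- small_fixture()
  spec <- synthetic_spec(seed = 11, n_lipids_per_leaflet = 36,
                         n_frames = 150)
  sch <- compute_sch(out$view)
  for (tp in c("POPC", "PSM")) {
    target <- spec$tilt_profiles[[tp]]
    rows <- sch[sch$lipid_type == tp & sch$stratum == "all", ]
    rows <- rows[order(rows$carbon), ]
    expect_equal(nrow(rows), length(target))
    dev <- abs(rows$s_ch - target)
    # family-wise calibrated bound (see ledger): per-carbon deviations
    # are standard normal in units of sem by construction
    expect_true(all(dev <= z_sidak(2 * length(target)) * rows$sem),
                info = paste(round(dev / rows$sem, 2), collapse = " "))
    expect_lt(mean(dev / rows$sem), 2)
  }
})
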