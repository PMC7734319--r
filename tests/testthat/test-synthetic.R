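test_that("spec validation and largest-remainder composition counts", {
  expect_error(synthetic_spec(composition = c(POPC = 0.5, PSM = 0.4)),
               "composition")
  expect_error(synthetic_spec(solute = list(n = 5L,
                                            fractions = c(core = 0.9))),
               "fractions")
  # 256 lipids at 0.4/0.4/0.2 cannot be a plain round() (sums to 255)
  spec <- synthetic_spec(seed = 5, n_lipids_per_leaflet = 128,
                         n_frames = 2)
  ss <- gen_state_sequences(spec)
  tab <- table(ss$lipid_type)
  expect_equal(sum(tab), 256)
  expect_equal(as.vector(tab[c("POPC", "PSM", "CHOL")]),
               c(103, 102, 51), ignore_attr = TRUE)
})

test_that("state sequences follow the prescribed Markov chain", {
  spec <- synthetic_spec(seed = 6, n_lipids_per_leaflet = 50,
                         n_frames = 2000)
  ss <- gen_state_sequences(spec)
  # empirical one-step transition frequencies close to the model
  tr <- spec$state_model$trans
  emp <- matrix(0, 3, 3, dimnames = dimnames(tr))
  from <- ss$states[-nrow(ss$states), ]
  to <- ss$states[-1, ]
  for (a in rownames(tr)) for (b in colnames(tr))
    emp[a, b] <- sum(from == a & to == b)
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - tr)), 0.005)
  # emissions: per-state P2 means and the clip range
  for (st in c("D", "I", "O")) {
    mu <- spec$state_model$emission_mean[[st]]
    expect_equal(mean(ss$p2[ss$states == st]), mu, tolerance = 0.01)
  }
  expect_true(all(ss$p2 >= -0.5 & ss$p2 <= 1))
})

test_that("generated trajectory is self-consistent with its truth", {
  out <- small_fixture()
  v <- out$view
  expect_true(all(is.finite(v$coords)))
  expect_equal(length(out$truth$states), 72L)
  expect_equal(nchar(out$truth$states[1]), 150L)
  # recovered P2 equals the emitted P2 process exactly (geometry inverts)
  lf <- assign_leaflets(v)
  p2 <- compute_p2(v, lf)
  truth_states <- do.call(cbind, lapply(strsplit(out$truth$states, ""),
                                        identity))
  for (st in c("D", "I", "O")) {
    mu <- out$truth$p2_mean_by_state[[st]]
    expect_equal(mean(p2$values[truth_states == st]), mu,
                 tolerance = 0.05)
  }
  # realized area moments are reported
  expect_equal(out$truth$area$realized_mean,
               mean(v$box[, 1] * v$box[, 2]), tolerance = 1e-9)
})

test_that("solute placement respects the declared bands", {
  out <- small_fixture()
  bands <- out$truth$solute_bands
  # probe z of every solute in every frame lies inside one of the bands
  v <- out$view
  sol <- Filter(function(e) e$species == "solute", v$index)
  z <- abs(vapply(sol, function(e) v$coords[, e$probe, 3],
                  numeric(dim(v$coords)[1])))
  in_band <- function(zz)
    (zz <= bands$core[2] + 1e-9) |
    (zz >= bands$headgroup[1] - 1e-9 & zz <= bands$headgroup[2] + 1e-9) |
    (zz >= bands$solvent[1] - 1e-9 & zz <= bands$solvent[2] + 1e-9)
  expect_true(all(in_band(as.vector(z))))
  expect_equal(sum(unlist(out$truth$solute_regions_realized)), 100,
               tolerance = 1e-9)
})

test_that("written outputs include a readable truth.json", {
  dir <- file.path(tempdir(), "memdomain-truthjson")
  spec <- synthetic_spec(seed = 21, n_lipids_per_leaflet = 6,
                         n_frames = 5, solute = list(n = 0L))
  out <- gen_bilayer_trajectory(spec, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("topol.gro", "traj.trr",
                                               "truth.json")))))
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tj$K_C, out$truth$K_C)
  expect_equal(tj$states, out$truth$states)
  expect_equal(unname(unlist(tj$stationary$POPC)),
               unname(out$truth$stationary$POPC), tolerance = 1e-12)
})
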