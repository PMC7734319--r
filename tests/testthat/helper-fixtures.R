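# Shared fixtures and oracles.  Expensive fixtures are generated once per
# test run and cached in this environment (testthat sources helpers once).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) assign(name, maker(), envir = .fixtures)
  .fixtures[[name]]
}

# Small bilayer used by the trajectory / order-parameter / profile tests.
# Seeds and sizes are fixed a priori; statistical tolerances are sized to
# the fixture (see decisions ledger), not the other way round.
small_fixture <- function() fixture("small", function() {
  spec <- synthetic_spec(
    seed = 11, n_lipids_per_leaflet = 36, n_frames = 150,
    solute = list(n = 8L, fractions = c(core = 0.3, headgroup = 0.4,
                                        solvent = 0.3)))
  gen_bilayer_trajectory(spec)
})

# End-to-end demo run on the canonical demo spec
# (inst/extdata/demo_config.yaml): generate via the CLI, reload from the
# written files, run the full pipeline.  Cached: used by several
# acceptance blocks.
demo_fixture <- function() fixture("demo", function() {
  out_dir <- file.path(tempdir(), "memdomain-demo")
  exe <- system.file("exec", "memdomain", package = "memdomain")
  cfg <- system.file("extdata", "demo_config.yaml", package = "memdomain")
  stopifnot(nzchar(exe), nzchar(cfg))
  t0 <- Sys.time()
  log <- system2("Rscript", c(shQuote(exe), "synth",
                              "--config", shQuote(cfg),
                              "--out-dir", shQuote(out_dir),
                              "--seed", "1"),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(file.path(out_dir, "traj.trr")))
    stop("demo synth failed:\n", paste(log, collapse = "\n"))
  spec <- do.call(synthetic_spec,
                  utils::modifyList(read_config(cfg)$synthetic,
                                    list(seed = 1L)))
  defs <- synthetic_definitions(spec)
  view <- load_trajectory(file.path(out_dir, "topol.gro"),
                          file.path(out_dir, "traj.trr"), defs)
  truth <- jsonlite::read_json(file.path(out_dir, "truth.json"),
                               simplifyVector = TRUE)
  res <- run_pipeline(view, temperature = spec$temperature,
                      bilayer_thickness = 2 * spec$geometry$head_z)
  list(out_dir = out_dir, spec = spec, view = view, truth = truth,
       pipeline = res, elapsed_min = as.numeric(Sys.time() - t0,
                                                units = "mins"))
})

# ---- HMM oracles (pure R, exhaustive) --------------------------------
rand_dist <- function(n) {
  x <- runif(n) + 0.05
  x / sum(x)
}

rand_hmm <- function(n_states = 3L, n_sym = 9L) {
  list(start = rand_dist(n_states),
       trans = t(vapply(seq_len(n_states), function(i) rand_dist(n_states),
                        numeric(n_states))),
       emit = t(vapply(seq_len(n_states), function(i) rand_dist(n_sym),
                       numeric(n_sym))))
}

# log-probability of one (path, observations) pair
enum_path_logp <- function(obs, path, m) {
  lp <- log(m$start[path[1]]) + log(m$emit[path[1], obs[1] + 1L])
  for (t in seq_along(obs)[-1])
    lp <- lp + log(m$trans[path[t - 1L], path[t]]) +
      log(m$emit[path[t], obs[t] + 1L])
  lp
}

# exhaustive Viterbi + total likelihood over all state paths
enum_hmm <- function(obs, m) {
  n_states <- length(m$start)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_states)),
                                    length(obs))))
  lps <- apply(grid, 1, function(p) enum_path_logp(obs, p, m))
  best <- which.max(lps)
  mx <- max(lps)
  list(path = as.integer(grid[best, ]), logp = lps[best],
       total_loglik = mx + log(sum(exp(lps - mx))))
}

# ---- statistical bounds ----------------------------------------------
# Two-sided Sidak z bound: family-wise alpha over k comparisons.  Used
# where a criterion states a per-estimate "2 sem" style bound that would
# otherwise fail with high probability for a correct implementation
# (deviation/sem is standard normal by construction).
z_sidak <- function(k, alpha_fw = 0.001) {
  qnorm(1 - (1 - (1 - alpha_fw)^(1 / k)) / 2)
}

# Two-lipid view with prescribed tail / C-H bond angle (degrees to z).
two_lipid_view <- function(theta_deg) {
  th <- theta_deg * pi / 180
  dirv <- c(sin(th), 0, cos(th))
  defs <- list(LIP = lipid_definition(
    "LIP", "phospholipid", tail_vectors = list(c("T1S", "T1E")),
    ch_pairs = list(list(c("C01", "H01A"))), head_ref_atom = "HD"))
  at <- data.frame(resid = rep(1:2, each = 5), resname = "LIP",
                   atom = rep(c("HD", "T1S", "T1E", "C01", "H01A"), 2))
  co <- array(0, c(1, 10, 3))
  co[1, 1, ] <- c(5, 5, 7)
  co[1, 2, ] <- c(5, 5, 6)
  co[1, 3, ] <- c(5, 5, 6) - 1.2 * dirv
  co[1, 4, ] <- c(5, 5, 5.5)
  co[1, 5, ] <- c(5, 5, 5.5) + 0.109 * dirv
  # partner in the lower leaflet with the same bond/tail angles
  co[1, 6, ] <- c(2, 2, 3)
  co[1, 7, ] <- c(2, 2, 4)
  co[1, 8, ] <- c(2, 2, 4) + 1.2 * dirv
  co[1, 9, ] <- c(2, 2, 4.5)
  co[1, 10, ] <- c(2, 2, 4.5) + 0.109 * dirv
  trajectory_view(co, c(10, 10, 14), 0, at, defs)
}

# ---- minimal hand-built views ----------------------------------------
# A view of n "lipids" whose head atoms follow externally supplied xy
# tracks; tails point straight down so roles resolve.
walk_view <- function(xy, dt_ps = 1000, box = c(1000, 1000, 10)) {
  nf <- dim(xy)[1]; n <- dim(xy)[2]
  defs <- list(WLK = lipid_definition(
    "WLK", "phospholipid", tail_vectors = list(c("T1S", "T1E")),
    ch_pairs = list(list(c("T1S", "T1E"))), head_ref_atom = "HD"))
  atoms <- data.frame(resid = rep(seq_len(n), each = 3),
                      resname = "WLK",
                      atom = rep(c("HD", "T1S", "T1E"), n))
  coords <- array(0, c(nf, 3L * n, 3))
  for (i in seq_len(n)) {
    a0 <- 3L * (i - 1L)
    coords[, a0 + 1L, 1:2] <- xy[, i, ]
    coords[, a0 + 2L, 1:2] <- xy[, i, ]
    coords[, a0 + 3L, 1:2] <- xy[, i, ]
    coords[, a0 + 1L, 3] <- 1
    coords[, a0 + 2L, 3] <- 0.5
    coords[, a0 + 3L, 3] <- -0.5
  }
  trajectory_view(coords, box, seq_len(nf) * dt_ps - dt_ps, atoms, defs)
}
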