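# Synthetic bilayer trajectories with known ground truth.  Lipids are
# geometric proxies (head bead, director bead, backbone bead, tail
# end-to-end vectors, a short C-H chain), not chemically valid molecules:
# sufficient for every analysis in the package, by construction.

#' Specification of a synthetic bilayer trajectory
#'
#' Defaults describe the canonical demo system: a ternary
#' POPC/PSM/cholesterol 4:4:2 mixture at 303 K, 128 lipids per leaflet,
#' 2000 frames 1 ns apart, order-state dynamics with Table-3-like
#' stationary occupancies, area fluctuations consistent with an area
#' compressibility of ~550 mN/m at an area per lipid of 45.1 A^2, a
#' director field sampled from a kB T/(K_C q^2) spectrum with
#' K_C = 1.3e-19 J, and solutes placed 3% core / 37% headgroup /
#' 60% solvent.
#'
#' @param seed integer seed; all stochastic output is reproducible from it.
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param composition named fractions by residue type (must sum to 1);
#'   names ending `CHOL`/`CHL` are sterols.
#' @param n_frames number of frames.
#' @param frame_spacing ns between frames.
#' @param temperature K.
#' @param state_model list with `labels`, row-stochastic `trans`,
#'   `emission_mean`, `emission_sd` (per hidden state P2 normals); either
#'   one model shared by all types or a named list per type.
#' @param tilt_profiles named list (per phospholipid type) of per-carbon
#'   target S_CH values.
#' @param solute list `n` (count; 0 disables solutes) and `fractions`
#'   (named core/headgroup/solvent placement fractions summing to 1).
#' @param area_model list `mean_apl` (nm^2), `var` (nm^4 of the total
#'   area), `corr_time` (ns).
#' @param director_model list `K_C` (J) and `n_max` (Fourier mode range);
#'   `NULL` disables the tilt field.
#' @param geometry bead geometry overrides (nm), see defaults in the code.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_lipids_per_leaflet = 128L,
                           composition = c(POPC = 0.4, PSM = 0.4,
                                           CHOL = 0.2),
                           n_frames = 2000L,
                           frame_spacing = 1,
                           temperature = 303,
                           state_model = NULL,
                           tilt_profiles = NULL,
                           solute = list(n = 26L,
                                         fractions = c(core = 0.03,
                                                       headgroup = 0.37,
                                                       solvent = 0.60)),
                           area_model = list(mean_apl = 0.451,
                                             var = NULL, corr_time = 10),
                           director_model = list(K_C = 1.3e-19,
                                                 n_max = 3L),
                           geometry = list()) {
  stopifnot(abs(sum(composition) - 1) < 1e-9)
  if (is.null(state_model)) state_model <- default_state_model()
  check_sm <- function(sm)
    stopifnot(all(abs(rowSums(sm$trans) - 1) < 1e-9),
              length(sm$emission_mean) == nrow(sm$trans))
  if (!is.null(state_model$trans)) check_sm(state_model)
  else lapply(state_model, check_sm)
  if (!is.null(solute) && solute$n > 0)
    stopifnot(abs(sum(solute$fractions) - 1) < 1e-9)
  if (is.null(tilt_profiles))
    tilt_profiles <- list(
      POPC = c(0.22, 0.22, 0.21, 0.19, 0.16, 0.12),
      PSM = c(0.32, 0.32, 0.31, 0.29, 0.25, 0.19))
  geom <- utils::modifyList(list(
    head_z = 1.9, backbone_dz = 0.45, box_z = 6, jitter = 0.04,
    tail_len = 1.2, dir_len = 1.5, chain_top_dz = 0.6,
    chain_spacing = 0.127, ch_bond = 0.109, ch_noise = 0.1), geometry)
  if (is.null(area_model$var)) {
    # var chosen so K_A = 552 mN/m at the given mean area
    mean_area <- n_lipids_per_leaflet * area_model$mean_apl
    area_model$var <- kB_J * temperature * mean_area / (552 * 1e-21)
  }
  structure(list(seed = as.integer(seed),
                 n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 composition = composition, n_frames = as.integer(n_frames),
                 frame_spacing = frame_spacing, temperature = temperature,
                 state_model = state_model, tilt_profiles = tilt_profiles,
                 solute = solute, area_model = area_model,
                 director_model = director_model, geometry = geom),
            class = "synthetic_spec")
}

# Reversible sticky chain with an ordered-majority stationary occupancy
# (D 40%, I 12%, O 48%) and P2 emission normals per hidden state.  The
# intermediate state is a low-weight transition state with a broad
# emission (sd = (mu_O - mu_L)/6, i.e. 3 sigma between the two anchor
# means), so the pooled P2 distribution stays well approximated by a
# two-component normal mixture -- the operating assumption of the
# GMM-anchored emission binning.  A heavy, narrow third mode would make
# the two-component anchor fit ambiguous and the downstream state
# assignment unstable.
default_state_model <- function(pi = c(D = 0.40, I = 0.12, O = 0.48),
                                rate = 0.02,
                                emission_mean = c(D = 0.15, I = 0.35,
                                                  O = 0.55),
                                emission_sd = c(D = 0.05, I = 0.4 / 6,
                                                O = 0.05)) {
  n <- length(pi)
  tr <- rate * matrix(pi, n, n, byrow = TRUE)
  diag(tr) <- 0
  diag(tr) <- 1 - rowSums(tr)
  dimnames(tr) <- list(names(pi), names(pi))
  list(labels = names(pi), trans = tr,
       emission_mean = emission_mean, emission_sd = emission_sd)
}

#' Simulate hidden order-state sequences and P2 emissions
#'
#' Per lipid: a Markov chain over the hidden states of the spec's state
#' model, with P2 drawn from each state's normal distribution (clipped to
#' the valid P2 range).  Ground-truth state paths are retained; emission
#' symbols are attached when a binning is supplied.
#'
#' @param spec a [synthetic_spec()].
#' @param binning optional [emission_binning()] used to discretize P2.
#' @param n_lipids override the number of chains (default: all membrane
#'   lipids of the spec).
#' @return list with `states` (frames x lipids character matrix of true
#'   hidden labels), `p2` (same shape), `symbols` (or `NULL`),
#'   `lipid_type`, `leaflet`, `stationary` (per type).
#' @export
gen_state_sequences <- function(spec, binning = NULL, n_lipids = NULL) {
  set.seed(spec$seed)
  nl_tot <- n_lipids %||% (2L * spec$n_lipids_per_leaflet)
  # largest-remainder allocation so counts always sum to nl_tot
  exact <- spec$composition * nl_tot
  cnt <- floor(exact)
  short <- nl_tot - sum(cnt)
  if (short > 0) {
    add <- order(exact - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[add] <- cnt[add] + 1L
  }
  types <- sample(rep(names(spec$composition), cnt))
  leaflet <- rep(c("upper", "lower"), length.out = nl_tot)
  nf <- spec$n_frames
  model_for <- function(tp)
    if (!is.null(spec$state_model$trans)) spec$state_model
  else spec$state_model[[tp]]
  states <- matrix(NA_character_, nf, nl_tot)
  p2 <- matrix(NA_real_, nf, nl_tot)
  stationary <- list()
  for (tp in unique(types)) {
    sm <- model_for(tp)
    cols <- which(types == tp)
    k <- length(sm$labels)
    cum <- t(apply(sm$trans, 1, cumsum))
    s <- matrix(NA_integer_, nf, length(cols))
    pi0 <- stationary_distribution(sm$trans)
    stationary[[tp]] <- pi0
    s[1, ] <- sample.int(k, length(cols), replace = TRUE, prob = pi0)
    if (nf > 1L) for (t in 2:nf) {
      u <- runif(length(cols))
      s[t, ] <- 1L + rowSums(u > cum[s[t - 1L, ], , drop = FALSE])
    }
    states[, cols] <- sm$labels[s]
    p2[, cols] <- pmin(0.995, pmax(-0.495,
      rnorm(nf * length(cols), sm$emission_mean[as.vector(s)],
            sm$emission_sd[as.vector(s)])))
  }
  symbols <- if (!is.null(binning)) bin_emissions(p2, binning) else NULL
  list(states = states, p2 = p2, symbols = symbols, lipid_type = types,
       leaflet = leaflet, stationary = stationary)
}

# lipid definitions matching the synthetic bead layout
#' Lipid definitions for the synthetic bead geometry
#' @param spec a [synthetic_spec()].
#' @return named list of [lipid_definition()] objects.
#' @export
synthetic_definitions <- function(spec) {
  defs <- list()
  for (tp in names(spec$composition)) {
    sterol <- grepl("CHO?L", tp)
    if (sterol) {
      defs[[tp]] <- lipid_definition(
        tp, "sterol", tail_vectors = list(c("T1S", "T1E")),
        head_ref_atom = "HD", director_vector = c("HD", "DE"))
    } else {
      k <- length(spec$tilt_profiles[[tp]] %||% numeric(0))
      ch <- if (k > 0) list(unlist(lapply(seq_len(k), function(j)
        list(c(sprintf("C%02d", j), sprintf("H%02dA", j)),
             c(sprintf("C%02d", j), sprintf("H%02dB", j)))),
        recursive = FALSE)) else list()
      defs[[tp]] <- lipid_definition(
        tp, "phospholipid",
        tail_vectors = list(c("T1S", "T1E"), c("T2S", "T2E")),
        ch_pairs = ch, head_ref_atom = "HD",
        director_vector = c("HD", "DE"))
    }
  }
  if (!is.null(spec$solute) && spec$solute$n > 0) {
    benz <- sprintf("B%d", 1:6)
    pyr <- c("B1", "B2", "N1", "CP1", "CP2")
    defs$SRT <- lipid_definition(
      "SRT", "solute", probe_atom = "O1",
      com_atoms = c(benz, "N1", "CP1", "CP2", "O1"),
      ring_atoms = list(benzene = benz, pyrrole = pyr))
  }
  defs
}

# planar indole-like template in the molecular frame (z = 0 plane), nm
solute_template <- function() {
  r <- 0.14
  ang <- seq(0, by = -pi / 3, length.out = 6)
  benz <- cbind(r * cos(ang), r * sin(ang), 0)
  # fused five-ring on the B1-B2 edge, pointing -x
  mid <- (benz[1, ] + benz[2, ]) / 2
  pyr <- rbind(mid + c(-0.20, 0.10, 0),
               mid + c(-0.28, 0.00, 0),
               mid + c(-0.20, -0.10, 0))
  oh <- c(r + 0.12, 0, 0)
  rbind(benz, pyr, oh)  # rows: B1..B6, N1, CP1, CP2, O1
}

rand_rotation <- function() {
  # uniform SO(3) via quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic bilayer trajectory with ground truth
#'
#' Lipids sit on a perturbed square lattice per leaflet.  Hidden-state
#' dynamics drive the tail end-to-end vectors (P2), per-carbon target
#' profiles drive the C-H bond orientations (S_CH), a Fourier tilt field
#' sampled from kB T/(K_C q^2) drives the director beads, the box area
#' follows an AR(1) process with the prescribed moments, and solutes are
#' placed per frame by region with uniform random orientation.  All ground
#' truth is returned (and written to a JSON sidecar when files are
#' written).
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir optional directory; when given, writes `topol.gro`,
#'   `traj.trr` and `truth.json` there.
#' @return list with `view` (a [trajectory_view()]), `definitions`,
#'   `truth` (list of generator parameters and realized values) and
#'   `paths` (when files were written).
#' @export
gen_bilayer_trajectory <- function(spec, out_dir = NULL) {
  ss <- gen_state_sequences(spec)       # seeds RNG with spec$seed
  nf <- spec$n_frames
  nl <- 2L * spec$n_lipids_per_leaflet
  g <- spec$geometry
  types <- ss$lipid_type
  upper <- ss$leaflet == "upper"

  # --- box area AR(1) -------------------------------------------------
  am <- spec$area_model
  mean_area <- spec$n_lipids_per_leaflet * am$mean_apl
  sd_stat <- sqrt(am$var)
  phi <- exp(-spec$frame_spacing / am$corr_time)
  area <- numeric(nf)
  area[1] <- rnorm(1, mean_area, sd_stat)
  if (sd_stat == 0) area[] <- mean_area
  else if (nf > 1) for (t in 2:nf)
    area[t] <- mean_area + phi * (area[t - 1] - mean_area) +
      rnorm(1, 0, sd_stat * sqrt(1 - phi^2))
  L <- sqrt(area)
  L0 <- sqrt(mean_area)

  # --- base lattice (fractional coordinates reused every frame) --------
  n_side <- ceiling(sqrt(spec$n_lipids_per_leaflet))
  frac_xy <- function(n) {
    gidx <- (seq_len(n) - 1L)
    cbind((gidx %% n_side + 0.5) / n_side,
          (gidx %/% n_side + 0.5) / n_side)
  }
  fxy <- matrix(NA_real_, nl, 2)
  fxy[upper, ] <- frac_xy(sum(upper))
  fxy[!upper, ] <- frac_xy(sum(!upper))
  jit <- matrix(rnorm(nl * 2, 0, g$jitter), nl, 2)
  zjit <- rnorm(nl, 0, g$jitter)

  # --- atom layout -----------------------------------------------------
  defs <- synthetic_definitions(spec)
  atom_names_for <- function(tp) {
    if (grepl("CHO?L", tp)) c("HD", "DE", "T1S", "T1E")
    else {
      k <- length(spec$tilt_profiles[[tp]] %||% numeric(0))
      c("HD", "DE", "BB", "T1S", "T1E", "T2S", "T2E",
        if (k > 0) as.vector(t(cbind(sprintf("C%02d", 1:k),
                                     sprintf("H%02dA", 1:k),
                                     sprintf("H%02dB", 1:k)))))
    }
  }
  sol_names <- c(sprintf("B%d", 1:6), "N1", "CP1", "CP2", "O1")
  n_sol <- if (!is.null(spec$solute)) spec$solute$n else 0L
  atoms <- list()
  for (i in seq_len(nl))
    atoms[[i]] <- data.frame(resid = i, resname = types[i],
                             atom = atom_names_for(types[i]))
  for (s in seq_len(n_sol))
    atoms[[nl + s]] <- data.frame(resid = nl + s, resname = "SRT",
                                  atom = sol_names)
  atoms <- do.call(rbind, atoms)
  natoms <- nrow(atoms)
  first_atom <- match(unique(atoms$resid), atoms$resid)

  # --- director tilt field settings ------------------------------------
  dm <- spec$director_model
  tilt_modes <- NULL
  if (!is.null(dm)) {
    mg <- expand.grid(nx = -dm$n_max:dm$n_max, ny = -dm$n_max:dm$n_max)
    mg <- mg[!(mg$nx == 0 & mg$ny == 0), ]
    # half grid: one representative per +/- q pair
    half <- mg$nx > 0 | (mg$nx == 0 & mg$ny > 0)
    tilt_modes <- as.matrix(mg[half, ])
  }
  kT <- kB_J * spec$temperature

  # --- solute placement bands (generator truth) ------------------------
  z_bb <- g$head_z - g$backbone_dz
  bands <- list(core = c(0, z_bb - 0.30),
                headgroup = c(z_bb + 0.05, g$head_z - 0.05),
                solvent = c(g$head_z + 0.30, g$box_z / 2 - 0.30))

  coords <- array(0, c(nf, natoms, 3))
  sol_regions <- if (n_sol > 0)
    matrix(NA_character_, nf, n_sol) else NULL
  ch_noise <- g$ch_noise
  sgn <- ifelse(upper, 1, -1)

  for (fr in seq_len(nf)) {
    scale_xy <- L[fr]
    xy <- (fxy * scale_xy) + jit
    # tilt field for this frame (shared across leaflets independently)
    tilt <- matrix(0, nl, 2)
    if (!is.null(tilt_modes)) {
      for (lf in c(TRUE, FALSE)) {
        sel <- upper == lf
        qx <- 2 * pi * tilt_modes[, 1] / L[fr]
        qy <- 2 * pi * tilt_modes[, 2] / L[fr]
        qn2 <- qx^2 + qy^2
        sd_c <- sqrt(2 * kT / (area[fr] * dm$K_C * qn2))
        cre <- rnorm(length(qx), 0, sd_c)
        cim <- rnorm(length(qx), 0, sd_c)
        phase <- (xy[sel, 1] %o% qx) + (xy[sel, 2] %o% qy)
        re_part <- cos(phase) %*% diag(cre, length(cre)) -
          sin(phase) %*% diag(cim, length(cim))
        qhx <- qx / sqrt(qn2); qhy <- qy / sqrt(qn2)
        tilt[sel, 1] <- as.vector(re_part %*% qhx)
        tilt[sel, 2] <- as.vector(re_part %*% qhy)
      }
    }
    for (i in seq_len(nl)) {
      a0 <- first_atom[i]
      s <- sgn[i]
      hz <- s * (g$head_z + zjit[i])
      hd <- c(xy[i, 1], xy[i, 2], hz)
      u <- c(tilt[i, 1], tilt[i, 2], -s)
      u <- u / sqrt(sum(u^2))
      de <- hd + g$dir_len * u
      # tails from the state-process P2 value
      v <- ss$p2[fr, i]
      ca <- sqrt((2 * v + 1) / 3)
      sa <- sqrt(max(0, 1 - ca^2))
      sterol <- grepl("CHO?L", types[i])
      ntail <- if (sterol) 1L else 2L
      tail_xyz <- lapply(seq_len(ntail), function(k) {
        az <- runif(1, 0, 2 * pi)
        dirv <- c(sa * cos(az), sa * sin(az), -s * ca)
        start <- c(xy[i, 1] + 0.08 * (k - 1), xy[i, 2],
                   s * (g$head_z - 0.5))
        rbind(start, start + g$tail_len * dirv)
      })
      if (sterol) {
        coords[fr, a0:(a0 + 3L), ] <- rbind(hd, de, tail_xyz[[1]])
      } else {
        bb <- c(xy[i, 1], xy[i, 2], s * (z_bb + zjit[i]))
        rows <- rbind(hd, de, bb, tail_xyz[[1]], tail_xyz[[2]])
        prof <- spec$tilt_profiles[[types[i]]]
        k <- length(prof)
        if (k > 0) {
          cz <- s * (g$head_z - g$chain_top_dz -
                       g$chain_spacing * (seq_len(k) - 1L))
          c2 <- (2 * prof + 1) / 3
          delta <- pmin(ch_noise, c2, 1 - c2)
          ch_rows <- matrix(NA_real_, 3L * k, 3L)
          for (j in seq_len(k)) {
            cpos <- c(xy[i, 1] + 0.05, xy[i, 2], cz[j])
            cth2 <- c2[j] + runif(2, -delta[j], delta[j])
            cth <- sqrt(cth2) * sample(c(-1, 1), 2, replace = TRUE)
            sth <- sqrt(pmax(0, 1 - cth2))
            az <- runif(2, 0, 2 * pi)
            h1 <- cpos + g$ch_bond * c(sth[1] * cos(az[1]),
                                       sth[1] * sin(az[1]), cth[1])
            h2 <- cpos + g$ch_bond * c(sth[2] * cos(az[2]),
                                       sth[2] * sin(az[2]), cth[2])
            ch_rows[(3 * j - 2):(3 * j), ] <- rbind(cpos, h1, h2)
          }
          rows <- rbind(rows, ch_rows)
        }
        coords[fr, a0:(a0 + nrow(rows) - 1L), ] <- rows
      }
    }
    if (n_sol > 0) {
      tmpl <- solute_template()
      for (sidx in seq_len(n_sol)) {
        reg <- sample(names(spec$solute$fractions), 1,
                      prob = spec$solute$fractions)
        b <- bands[[reg]]
        zt <- runif(1, b[1], b[2]) * sample(c(-1, 1), 1)
        if (reg == "core") zt <- runif(1, -b[2], b[2])
        xyt <- runif(2, 0, L[fr])
        rot <- rand_rotation()
        pts <- tmpl %*% t(rot)
        # translate so the probe O lands at the sampled z
        shift <- c(xyt[1], xyt[2], zt) - pts[10, ]
        pts <- sweep(pts, 2, shift, "+")
        a0 <- first_atom[nl + sidx]
        coords[fr, a0:(a0 + 9L), ] <- pts
        sol_regions[fr, sidx] <- reg
      }
    }
  }

  box <- cbind(L, L, g$box_z)
  times <- (seq_len(nf) - 1L) * spec$frame_spacing * 1000
  view <- trajectory_view(coords, box, times, atoms, defs)
  truth <- list(
    seed = spec$seed, n_lipids = nl, n_frames = nf,
    temperature = spec$temperature,
    lipid_type = types, leaflet = ss$leaflet,
    states = apply(ss$states, 2, paste, collapse = ""),
    stationary = ss$stationary,
    p2_mean_by_state = if (!is.null(spec$state_model$trans))
      spec$state_model$emission_mean else NULL,
    tilt_profiles = spec$tilt_profiles,
    area = list(mean = mean_area, var = am$var,
                corr_time = am$corr_time,
                realized_mean = mean(area), realized_var = var(area)),
    K_C = if (!is.null(dm)) dm$K_C else NULL,
    solute_bands = bands,
    solute_fractions = if (n_sol > 0) spec$solute$fractions else NULL,
    solute_regions_realized = if (n_sol > 0)
      as.vector(100 * table(factor(sol_regions,
        levels = c("core", "headgroup", "solvent"))) /
        length(sol_regions)) else NULL)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    topol <- file.path(out_dir, "topol.gro")
    traj <- file.path(out_dir, "traj.trr")
    truth_p <- file.path(out_dir, "truth.json")
    write_gro(list(time = times[1], resid = atoms$resid,
                   resname = atoms$resname, atom = atoms$atom,
                   pos = coords[1, , ], box = box[1, ]), topol)
    write_trr(coords, box, times, traj)
    jsonlite::write_json(truth, truth_p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- list(topology = topol, trajectory = traj, truth = truth_p)
  }
  list(view = view, definitions = defs, truth = truth, paths = paths)
}
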