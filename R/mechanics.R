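# Mechanical and dynamical observables: area per lipid and area
# compressibility K_A from equilibrium area fluctuations, bending modulus
# K_C from the longitudinal director fluctuation spectrum, lateral
# diffusion from mean squared displacements, and contact counts.

#' Area series and area per lipid from a trajectory
#'
#' @param view a [trajectory_view()].
#' @param lipids_per_leaflet divisor for the area per lipid; defaults to
#'   half the number of non-solute residues.
#' @param exclude_sterols additionally report APL with sterols excluded
#'   from the divisor.
#' @return data.frame of class `area_series` with `time` (ns), `area`
#'   (total xy area, nm^2), `apl` (Angstrom^2) and, when sterols exist,
#'   `apl_excl_chol`.
#' @export
area_series <- function(view, lipids_per_leaflet = NULL,
                        exclude_sterols = TRUE) {
  res <- lipid_residues(view)
  memb <- res[res$species != "solute", ]
  npl <- lipids_per_leaflet %||% (nrow(memb) / 2)
  a <- view$box[, 1] * view$box[, 2]
  out <- data.frame(time = view$times / 1000, area = a,
                    apl = 100 * a / npl)   # nm^2 -> A^2
  nst <- sum(memb$species == "sterol")
  if (exclude_sterols && nst > 0)
    out$apl_excl_chol <- 100 * a / ((nrow(memb) - nst) / 2)
  structure(out, class = c("area_series", "data.frame"))
}

#' Area compressibility modulus from area fluctuations
#'
#' K_A = kB T <A> / <dA^2>.  The correlation time of the area series is
#' estimated from the first 1/e crossing of its normalized autocorrelation;
#' blocks of twice the correlation time give the block-averaged standard
#' error (variance of per-block K_A estimates).
#'
#' @param areas numeric vector of total areas (nm^2) or an [area_series()].
#' @param temperature K.
#' @param dt_ns frame spacing in ns (taken from an `area_series` input).
#' @param block_length_ns optional explicit block length, ns.
#' @return object of class `mechanical_estimate` with `K_A` (mN/m), `se`,
#'   `mean_area` (nm^2), `var_area` (nm^4), `corr_time` and `block_length`
#'   (ns), `n_blocks` and a `flag` (`"ok"`, `"unreliable"` or
#'   `"degenerate"`).
#' @export
area_compressibility <- function(areas, temperature, dt_ns = 1,
                                 block_length_ns = NULL) {
  if (inherits(areas, "area_series")) {
    if (nrow(areas) > 1L) dt_ns <- diff(areas$time[1:2])
    areas <- areas$area
  }
  n <- length(areas)
  mA <- mean(areas); vA <- mean((areas - mA)^2)
  if (vA <= 0) {
    warning("constant area series: K_A is infinite (degenerate input)")
    return(structure(list(K_A = Inf, se = NA_real_, mean_area = mA,
                          var_area = 0, corr_time = NA_real_,
                          block_length = NA_real_, n_blocks = 0L,
                          temperature = temperature, flag = "degenerate"),
                     class = "mechanical_estimate"))
  }
  ka_of <- function(x) kB_J * temperature * mean(x) /
    mean((x - mean(x))^2) * 1e21          # J/nm^2 -> mN/m
  # correlation time: first 1/e crossing of the normalized autocorrelation
  ac <- acf(areas, lag.max = min(n - 1L, 2000L), plot = FALSE,
            demean = TRUE)$acf[, 1, 1]
  below <- which(ac < exp(-1))
  corr_frames <- if (length(below)) max(1L, below[1] - 1L) else
    length(ac) - 1L
  corr_time <- corr_frames * dt_ns
  flag <- if (corr_frames > n / 20) "unreliable" else "ok"
  bl_frames <- if (!is.null(block_length_ns))
    max(2L, round(block_length_ns / dt_ns)) else max(2L, 2L * corr_frames)
  nb <- n %/% bl_frames
  se <- NA_real_
  if (nb >= 2L) {
    kb <- vapply(seq_len(nb), function(b)
      ka_of(areas[((b - 1L) * bl_frames + 1L):(b * bl_frames)]),
      numeric(1))
    se <- sd(kb) / sqrt(nb)
  }
  structure(list(K_A = ka_of(areas), se = se, mean_area = mA,
                 var_area = vA, corr_time = corr_time,
                 block_length = bl_frames * dt_ns, n_blocks = nb,
                 temperature = temperature, flag = flag),
            class = "mechanical_estimate")
}

#' @export
print.mechanical_estimate <- function(x, ...) {
  cat("<mechanical_estimate>\n")
  if (!is.null(x$K_A))
    cat(sprintf("  K_A = %.4g mN/m (SE %.3g, %d blocks of %.3g ns) [%s]\n",
                x$K_A, x$se, x$n_blocks, x$block_length, x$flag))
  if (!is.null(x$K_C))
    cat(sprintf("  K_C = %.4g x 1e-20 J (SE %.3g), %d q-bins <= %.3g 1/nm\n",
                x$K_C * 1e20, x$se * 1e20, x$n_bins, x$q_fit_max))
  invisible(x)
}

#' Longitudinal director fluctuation spectrum
#'
#' Per frame and leaflet, unit lipid directors (head to tail end, or the
#' dedicated director vector) are Fourier-summed at box-commensurate wave
#' vectors: n_q = (sqrt(A)/N) sum_j n_j,xy exp(-i q r_j), evaluated at the
#' lipid head xy positions, and the longitudinal component is the
#' projection on the unit wave vector.  Power is averaged over frames,
#' leaflets and symmetry-equivalent |q|.  With this normalization the
#' spectrum has units nm^2 and the small-q prediction is kB T / (K_C q^2).
#'
#' @param view a [trajectory_view()].
#' @param leaflets an [assign_leaflets()] result.
#' @param n_max maximum Fourier index per axis (q grid spans -n_max..n_max).
#' @return data.frame of class `director_spectrum` with `q` (1/nm),
#'   `power` (nm^2) and `n_modes` per |q| bin.
#' @export
director_spectrum <- function(view, leaflets, n_max = 4L) {
  nf <- dim(view$coords)[1]
  memb <- Filter(function(e) e$species != "solute" && !is.null(e$director),
                 view$index)
  ids <- vapply(memb, `[[`, integer(1), "resid")
  stopifnot(identical(ids, leaflets$lipid_ids))
  heads <- vapply(memb, `[[`, integer(1), "head")
  d_from <- vapply(memb, function(e) e$director[1], integer(1))
  d_to <- vapply(memb, function(e) e$director[2], integer(1))
  # integer mode grid; equivalent-|q| grouping uses the mean box so that
  # small area fluctuations do not smear the bins
  g <- expand.grid(nx = -n_max:n_max, ny = -n_max:n_max)
  g <- as.matrix(g[!(g$nx == 0 & g$ny == 0), ])
  box0 <- colMeans(view$box[, 1:2, drop = FALSE])
  q0 <- sqrt((2 * pi * g[, 1] / box0[1])^2 + (2 * pi * g[, 2] / box0[2])^2)
  grp <- factor(round(q0, 9))
  acc <- setNames(numeric(nlevels(grp)), levels(grp))
  cnt <- acc
  for (fr in seq_len(nf)) {
    bx <- view$box[fr, ]
    qx <- 2 * pi * g[, 1] / bx[1]
    qy <- 2 * pi * g[, 2] / bx[2]
    qn <- sqrt(qx^2 + qy^2)
    dx <- view$coords[fr, d_to, , drop = TRUE] -
      view$coords[fr, d_from, , drop = TRUE]
    dx <- dx - round(dx / matrix(bx, nrow(dx), 3, byrow = TRUE)) *
      matrix(bx, nrow(dx), 3, byrow = TRUE)
    nxy <- dx[, 1:2] / sqrt(rowSums(dx^2))
    A <- bx[1] * bx[2]
    pos <- view$coords[fr, heads, 1:2, drop = TRUE]
    for (lf in c("upper", "lower")) {
      sel <- leaflets$leaflet[fr, ] == lf
      if (sum(sel) < 2L) next
      N <- sum(sel)
      phase <- exp(-1i * (qx %o% pos[sel, 1] + qy %o% pos[sel, 2]))
      nq_x <- as.vector(phase %*% nxy[sel, 1]) * sqrt(A) / N
      nq_y <- as.vector(phase %*% nxy[sel, 2]) * sqrt(A) / N
      p_long <- Mod((qx / qn) * nq_x + (qy / qn) * nq_y)^2
      acc <- acc + as.vector(rowsum(p_long, grp))
      cnt <- cnt + as.vector(rowsum(rep(1, length(p_long)), grp))
    }
  }
  spec <- data.frame(q = as.numeric(names(acc)),
                     power = as.vector(acc / cnt),
                     n_modes = as.vector(cnt))
  spec <- spec[order(spec$q), ]
  rownames(spec) <- NULL
  structure(spec, class = c("director_spectrum", "data.frame"))
}

#' Bending modulus from a director spectrum
#'
#' Weighted least squares of the theoretical spectrum kB T / (K_C q^2)
#' against the measured power, restricted to wavelengths longer than three
#' bilayer thicknesses (q <= 2 pi / (3 d)); mode counts weight the fit.
#'
#' @param spectrum a [director_spectrum()].
#' @param temperature K.
#' @param bilayer_thickness nm (sets the q cutoff).
#' @return `mechanical_estimate` with `K_C` (J), `se`, `q_fit_max`,
#'   `n_bins`.
#' @export
bending_modulus <- function(spectrum, temperature, bilayer_thickness = 4) {
  q_max <- 2 * pi / (3 * bilayer_thickness)
  sel <- spectrum$q <= q_max & spectrum$power > 0
  if (sum(sel) < 4L)
    stop("fewer than 4 q-bins below q_fit_max = ", signif(q_max, 3),
         " 1/nm; use a larger box or more frames")
  s <- spectrum[sel, ]
  # linear in 1/K_C: power = (kB T / q^2) * (1/K_C); WLS through origin
  x <- kB_J * temperature / s$q^2
  w <- s$n_modes
  inv_kc <- sum(w * x * s$power) / sum(w * x^2)
  if (inv_kc <= 0) {
    print(s)
    stop("non-positive fitted K_C; spectrum dumped above")
  }
  resid <- s$power - x * inv_kc
  var_inv <- sum(w * resid^2) / ((sum(sel) - 1) * sum(w * x^2))
  K_C <- 1 / inv_kc
  se <- sqrt(var_inv) * K_C^2      # delta method on 1/x
  structure(list(K_C = K_C, se = se, q_fit_max = q_max,
                 n_bins = sum(sel), temperature = temperature,
                 flag = "ok"),
            class = "mechanical_estimate")
}

#' Lateral diffusion coefficient from mean squared displacements
#'
#' Time-origin-averaged MSD of lipid head xy positions (coordinates must be
#' unwrapped); per-leaflet center-of-mass drift is removed per frame.  The
#' 2-D diffusion coefficient is slope/4 of a linear fit over the lag
#' window.
#'
#' @param view a [trajectory_view()] with unwrapped coordinates.
#' @param leaflets an [assign_leaflets()] result (drift removal per
#'   leaflet); pass `NULL` to skip drift removal.
#' @param stratum optional `state_trajectory` plus `state` restricting the
#'   MSD to lipids that spend at least `min_frac` of frames in `state`.
#' @param state,min_frac see `stratum`.
#' @param fit_window lag range `c(lo, hi)` in ns for the linear fit.
#' @return object of class `diffusion_estimate`: `D_cm2_s`, `msd`
#'   (data.frame lag_ns, msd_nm2), `fit_window`, `anomalous` flag.
#' @export
lateral_diffusion <- function(view, leaflets = NULL, stratum = NULL,
                              state = "D", min_frac = 0.5,
                              fit_window = c(10, 100)) {
  nf <- dim(view$coords)[1]
  memb <- Filter(function(e) e$species != "solute", view$index)
  heads <- vapply(memb, `[[`, integer(1), "head")
  ids <- vapply(memb, `[[`, integer(1), "resid")
  xy <- view$coords[, heads, 1:2, drop = FALSE]
  dim(xy) <- c(nf, length(heads), 2L)
  if (!is.null(leaflets)) {
    for (lf in c("upper", "lower")) {
      sel <- leaflets$leaflet[1, ] == lf
      if (!any(sel)) next
      for (ax in 1:2) {
        drift <- rowMeans(xy[, sel, ax, drop = FALSE])
        xy[, sel, ax] <- xy[, sel, ax] - drift
      }
    }
  }
  keep <- rep(TRUE, length(heads))
  if (!is.null(stratum)) {
    frac <- vapply(ids, function(id) {
      j <- match(id, stratum$lipid_ids)
      if (is.na(j)) return(0)
      mean(stratum$states[, j] == state)
    }, numeric(1))
    keep <- frac >= min_frac
    if (!any(keep)) stop("no lipids satisfy the stratum requirement")
  }
  xy <- xy[, keep, , drop = FALSE]
  dt_ns <- if (nf > 1L) diff(view$times[1:2]) / 1000 else 1
  lags <- seq_len(min(nf - 1L, max(2L, floor(nf / 2))))
  msd <- vapply(lags, function(L) {
    d <- xy[(1 + L):nf, , , drop = FALSE] - xy[1:(nf - L), , , drop = FALSE]
    mean(d[, , 1]^2 + d[, , 2]^2)
  }, numeric(1))
  msd_df <- data.frame(lag_ns = lags * dt_ns, msd_nm2 = msd)
  sel <- msd_df$lag_ns >= fit_window[1] & msd_df$lag_ns <= fit_window[2]
  if (sum(sel) < 2L) sel <- seq_len(nrow(msd_df)) > nrow(msd_df) / 4
  fit <- lm(msd_nm2 ~ lag_ns, data = msd_df[sel, ])
  slope <- coef(fit)[["lag_ns"]]               # nm^2 / ns
  D <- slope / 4 * 1e-14 / 1e-9                # nm^2/ns -> cm^2/s
  anomalous <- FALSE
  pos <- msd_df[sel, ]
  pos <- pos[pos$msd_nm2 > 0, ]
  if (nrow(pos) >= 3L) {
    lg <- lm(log(msd_nm2) ~ log(lag_ns), data = pos)
    if (coef(lg)[[2]] < 0.8) {
      anomalous <- TRUE
      warning("sublinear MSD (log-log slope ",
              signif(coef(lg)[[2]], 3), "): anomalous diffusion?")
    }
  }
  structure(list(D_cm2_s = max(D, 0), msd = msd_df,
                 fit_window = fit_window, anomalous = anomalous),
            class = "diffusion_estimate")
}

#' Contact counts between two residue types over time
#'
#' Counts atom pairs (or residue-center pairs) of types a and b within a
#' cutoff, using the xy minimum image convention.
#'
#' @param view a [trajectory_view()].
#' @param type_a,type_b residue names.
#' @param cutoff nm.
#' @param com count residue geometric-center pairs instead of atom pairs.
#' @return data.frame `time` (ns), `contacts`.
#' @export
contact_counts <- function(view, type_a, type_b, cutoff, com = FALSE) {
  stopifnot(cutoff > 0)
  nf <- dim(view$coords)[1]
  pick <- function(tp) {
    res <- Filter(function(e) e$resname == tp, view$index)
    if (com) list(kind = "com", res = res)
    else list(kind = "atoms", ids = unlist(lapply(res, `[[`, "atoms")))
  }
  a <- pick(type_a); b <- pick(type_b)
  get_pts <- function(sel, fr) {
    if (sel$kind == "atoms")
      view$coords[fr, sel$ids, , drop = FALSE][1, , ]
    else t(vapply(sel$res, function(e)
      colMeans(view$coords[fr, e$com, , drop = TRUE]), numeric(3)))
  }
  counts <- vapply(seq_len(nf), function(fr) {
    pa <- get_pts(a, fr); pb <- get_pts(b, fr)
    bx <- view$box[fr, ]
    dxx <- outer(pa[, 1], pb[, 1], "-")
    dyy <- outer(pa[, 2], pb[, 2], "-")
    dzz <- outer(pa[, 3], pb[, 3], "-")
    dxx <- min_image_xy(dxx, bx[1]); dyy <- min_image_xy(dyy, bx[2])
    d2 <- dxx^2 + dyy^2 + dzz^2
    if (identical(type_a, type_b)) sum(d2 < cutoff^2 & upper.tri(d2))
    else sum(d2 < cutoff^2)
  }, numeric(1))
  data.frame(time = view$times / 1000, contacts = counts)
}
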