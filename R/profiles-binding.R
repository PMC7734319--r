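# Density profiles along the bilayer normal, PMF from Gaussian-mixture
# density estimation, binding-region classification and ring-system
# (indole) orientation analysis.

#' Select atom indices by residue/atom name
#'
#' @param view a [trajectory_view()].
#' @param resname optional residue name filter.
#' @param atom optional atom name filter (vector allowed).
#' @return integer atom row indices.
#' @export
select_atoms <- function(view, resname = NULL, atom = NULL) {
  keep <- rep(TRUE, nrow(view$atoms))
  if (!is.null(resname)) keep <- keep & view$atoms$resname %in% resname
  if (!is.null(atom)) keep <- keep & view$atoms$atom %in% atom
  which(keep)
}

bilayer_center <- function(view) {
  memb <- Filter(function(e) e$species != "solute", view$index)
  heads <- vapply(memb, `[[`, integer(1), "head")
  zs <- view$coords[, heads, 3, drop = FALSE]
  dim(zs) <- c(dim(view$coords)[1], length(heads))
  rowMeans(zs)
}

# per-frame centered z of either raw atoms or per-residue geometric centers
centered_z <- function(view, atoms = NULL, resname = NULL, com = FALSE) {
  ctr <- bilayer_center(view)
  nf <- dim(view$coords)[1]
  if (com) {
    res <- Filter(function(e) e$resname %in% resname, view$index)
    if (length(res) == 0L) stop("empty selection: no residue '", resname, "'")
    z <- vapply(res, function(e) {
      zz <- view$coords[, e$com, 3, drop = FALSE]
      dim(zz) <- c(nf, length(e$com))
      rowMeans(zz)
    }, numeric(nf))
    dim(z) <- c(nf, length(res))
  } else {
    ids <- atoms %||% select_atoms(view, resname = resname)
    if (length(ids) == 0L) stop("empty selection")
    z <- view$coords[, ids, 3, drop = FALSE]
    dim(z) <- c(nf, length(ids))
  }
  z - ctr
}

#' Density profile along the bilayer normal
#'
#' Histogram of (bilayer-centered) z positions of an atom selection or of
#' per-residue geometric centers, averaged over frames.  Profiles are not
#' symmetrized unless requested.
#'
#' @param view a [trajectory_view()].
#' @param atoms explicit atom indices, or
#' @param resname residue name selecting atoms / residues.
#' @param com use per-residue geometric centers of `resname`'s com atoms.
#' @param bin_width bin width, nm.
#' @param mode `"probability"` (density integrating to 1, units 1/nm) or
#'   `"number"` (mean count per frame per nm).
#' @param symmetrize average p(z) with p(-z).
#' @param range z range `c(lo, hi)`; default spans the data.
#' @return data.frame of class `density_profile` with `z` (bin centers, nm)
#'   and `density`; attributes `mode`, `symmetrized`, `bin_width`.
#' @export
density_profile <- function(view, atoms = NULL, resname = NULL, com = FALSE,
                            bin_width = 0.1,
                            mode = c("probability", "number"),
                            symmetrize = FALSE, range = NULL) {
  mode <- match.arg(mode)
  z <- centered_z(view, atoms, resname, com)
  zv <- as.vector(z)
  if (is.null(range)) {
    lim <- max(abs(zv)) + bin_width
    range <- c(-lim, lim)
  }
  breaks <- seq(range[1], range[2], by = bin_width)
  if (max(breaks) < range[2]) breaks <- c(breaks, max(breaks) + bin_width)
  nb <- length(breaks) - 1L
  zi <- findInterval(zv, breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  cnt <- tabulate(zi, nbins = nb)
  dens <- switch(mode,
    probability = cnt / (sum(cnt) * bin_width),
    number = cnt / (nrow(z) * bin_width))
  centers <- head(breaks, -1) + bin_width / 2
  if (symmetrize) {
    rev_d <- approx(-centers, dens, xout = centers, rule = 2)$y
    dens <- (dens + rev_d) / 2
  }
  structure(data.frame(z = centers, density = dens),
            class = c("density_profile", "data.frame"),
            mode = mode, symmetrized = symmetrize, bin_width = bin_width)
}

#' Potential of mean force from sampled solute positions
#'
#' Fits a K-component univariate Gaussian mixture to the z samples (K by
#' BIC over 1..6 unless fixed) and evaluates F(z) = -kB T ln p(z) on a
#' uniform grid, with the minimum shifted to zero.  Grid points whose
#' fitted density falls below 1e-12 of the maximum are reported censored.
#'
#' @param samples numeric z samples, nm (>= 100).
#' @param temperature K.
#' @param components integer K, or `"auto"` for BIC selection over 1..6.
#' @param grid evaluation grid, nm (default 400 points over the sample
#'   range extended by 5%).
#' @param units energy units for F.
#' @return data.frame of class `pmf_profile` with `z`, `F`, `censored`;
#'   attributes `temperature`, `components`, `units`, `mixture`
#'   (means/sds/weights).
#' @export
pmf_from_density <- function(samples, temperature,
                             components = "auto", grid = NULL,
                             units = "kcal/mol") {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100L) stop("need at least 100 samples for the PMF")
  G <- if (identical(components, "auto")) 1:6 else as.integer(components)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  fit <- mclust::Mclust(samples, G = G, modelNames = "V", verbose = FALSE)
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1L) sig <- rep(sig, length(mu))
  w <- fit$parameters$pro
  if (is.null(grid)) {
    r <- range(samples); pad <- 0.05 * diff(r)
    grid <- seq(r[1] - pad, r[2] + pad, length.out = 400L)
  }
  p <- vapply(grid, function(zz) sum(w * dnorm(zz, mu, sig)), numeric(1))
  floor_p <- 1e-12 * max(p)
  censored <- p < floor_p
  p_f <- pmax(p, floor_p)
  e <- -kBT(temperature, units) * log(p_f)
  e <- e - min(e[!censored])
  structure(data.frame(z = grid, F = e, censored = censored),
            class = c("pmf_profile", "data.frame"),
            temperature = temperature, components = length(mu),
            units = units,
            mixture = list(mean = mu, sd = sig, weight = w))
}

#' Region boundaries from headgroup density supports
#'
#' The headgroup band of each leaflet spans from the inner edge of the
#' backbone (glycerol/sphingosine) density support to the outer edge of the
#' choline density support; the hydrophobic core is everything closer to
#' the bilayer center than the backbone inner edge.  Supports are taken at
#' a fraction of each profile's peak.
#'
#' @param choline a [density_profile()] of the choline/head atoms.
#' @param backbone a [density_profile()] of the backbone atoms.
#' @param frac support threshold as a fraction of the peak density.
#' @return object of class `region_boundaries`: `headgroup_upper`,
#'   `headgroup_lower` (each `c(lo, hi)` in signed z, nm) and
#'   `core_halfwidth` (nm).
#' @export
region_boundaries <- function(choline, backbone, frac = 0.1) {
  support <- function(prof, side) {
    sel <- if (side > 0) prof$z > 0 else prof$z < 0
    zz <- prof$z[sel]; dd <- prof$density[sel]
    on <- dd >= frac * max(dd)
    range(zz[on])
  }
  bu <- support(backbone, +1); bl <- support(backbone, -1)
  cu <- support(choline, +1); cl <- support(choline, -1)
  hu <- c(bu[1], max(cu[2], bu[2]))
  hl <- c(min(cl[1], bl[1]), bl[2])
  core <- min(bu[1], -bl[2])
  if (core <= 0 || hu[1] >= hu[2] || hl[1] >= hl[2])
    stop("degenerate region boundaries: check density profiles")
  structure(list(headgroup_upper = hu, headgroup_lower = hl,
                 core_halfwidth = core),
            class = "region_boundaries")
}

classify_z <- function(z, boundaries) {
  out <- rep("solvent", length(z))
  out[abs(z) < boundaries$core_halfwidth] <- "core"
  hu <- boundaries$headgroup_upper; hl <- boundaries$headgroup_lower
  out[(z >= hu[1] & z <= hu[2]) | (z >= hl[1] & z <= hl[2])] <- "headgroup"
  out
}

#' Classify solute binding regions
#'
#' Primary classification uses the probe atom's bilayer-centered z against
#' the region bands; contact-based percentages (solute center of mass
#' within `cutoff` of head/phosphate atoms vs chain carbons, xy minimum
#' image) are reported alongside for the membrane-bound population.
#'
#' @param view a [trajectory_view()].
#' @param solute residue name of the solute.
#' @param boundaries a [region_boundaries()].
#' @param cutoff contact cutoff, nm.
#' @return list with `regions` (frames x solutes character matrix),
#'   `summary` (data.frame region/percent), `contact_summary` (data.frame
#'   with contact-based core/headgroup percentages among bound solutes).
#' @export
classify_binding <- function(view, solute, boundaries, cutoff = 0.6) {
  sol <- Filter(function(e) e$resname == solute, view$index)
  if (length(sol) == 0L) stop("no solute residues named '", solute, "'")
  ctr <- bilayer_center(view)
  nf <- dim(view$coords)[1]
  probes <- vapply(sol, function(e)
    if (is.na(e$probe)) e$com[1] else e$probe, integer(1))
  z <- view$coords[, probes, 3, drop = FALSE]
  dim(z) <- c(nf, length(sol))
  z <- z - ctr
  regions <- matrix(classify_z(as.vector(z), boundaries), nf, length(sol))
  tab <- table(factor(regions, levels = c("core", "headgroup", "solvent")))
  summary <- data.frame(region = names(tab),
                        percent = 100 * as.vector(tab) / sum(tab))
  # contact route: solute COM vs head atoms / chain carbons
  memb <- Filter(function(e) e$species != "solute", view$index)
  head_ids <- vapply(memb, `[[`, integer(1), "head")
  chain_ids <- unique(unlist(lapply(memb, function(e)
    lapply(e$chains, function(m) m[, 1]))))
  n_core <- 0; n_head <- 0
  for (k in seq_along(sol)) {
    e <- sol[[k]]
    com <- apply(view$coords[, e$com, , drop = FALSE], c(1, 3), mean)
    bound <- regions[, k] != "solvent"
    if (!any(bound)) next
    for (fr in which(bound)) {
      bx <- view$box[fr, ]
      d_head <- contacts_one(com[fr, ], view$coords[fr, head_ids, ,
                                                    drop = TRUE], bx, cutoff)
      d_chain <- contacts_one(com[fr, ], view$coords[fr, chain_ids, ,
                                                     drop = TRUE], bx, cutoff)
      n_head <- n_head + d_head
      n_core <- n_core + d_chain
    }
  }
  tot <- n_core + n_head
  contact_summary <- data.frame(
    region = c("core", "headgroup"),
    percent = if (tot > 0) 100 * c(n_core, n_head) / tot else c(NA, NA))
  list(regions = regions, summary = summary,
       contact_summary = contact_summary)
}

contacts_one <- function(p, coords, box, cutoff) {
  d <- sweep(coords, 2, p)
  d[, 1] <- min_image_xy(d[, 1], box[1])
  d[, 2] <- min_image_xy(d[, 2], box[2])
  sum(rowSums(d^2) < cutoff^2)
}

#' Indole orientation angles of a ring-system solute
#'
#' Builds a molecule-fixed orthonormal frame per frame: the indole z-axis
#' is the unit normal of the best-fit ring plane (SVD of the centered ring
#' atoms, sign fixed by the atom ordering so the frame is molecule-fixed);
#' the x-axis is the in-plane unit vector from the ring-system centroid
#' through the benzene-ring centroid; y completes the right-handed frame.
#' theta is the angle between the indole z-axis and the bilayer normal;
#' alpha the azimuth of the bilayer normal projected into the indole x-y
#' plane, measured from x, in \[0, 360).
#'
#' @param view a [trajectory_view()].
#' @param solute residue name (its definition must carry `ring_atoms`).
#' @param boundaries optional [region_boundaries()] to attach a region
#'   label per sample.
#' @return data.frame with `frame`, `time`, `solute`, `theta`, `alpha`
#'   (degrees) and `region` (`NA` without boundaries).
#' @export
indole_orientation <- function(view, solute, boundaries = NULL) {
  sol <- Filter(function(e) e$resname == solute && !is.null(e$ring),
                view$index)
  if (length(sol) == 0L)
    stop("no ring atoms defined for solute '", solute, "'")
  ctr <- if (!is.null(boundaries)) bilayer_center(view) else NULL
  nf <- dim(view$coords)[1]
  out <- list()
  for (e in sol) {
    ring_ids <- unique(c(e$ring$benzene, e$ring$pyrrole))
    for (fr in seq_len(nf)) {
      rc <- view$coords[fr, ring_ids, , drop = TRUE]
      cen <- colMeans(rc)
      m <- sweep(rc, 2, cen)
      sv <- svd(m)
      if (sv$d[3] / sv$d[1] > 0.5 || sv$d[1] < 1e-9) {
        warning("ill-defined ring plane for resid ", e$resid,
                " frame ", fr, "; skipped")
        next
      }
      zi <- sv$v[, 3]
      # deterministic sign: align with the ring's atom-ordering circulation
      v1 <- rc[1, ] - cen; v2 <- rc[2, ] - cen
      ref <- c(v1[2] * v2[3] - v1[3] * v2[2],
               v1[3] * v2[1] - v1[1] * v2[3],
               v1[1] * v2[2] - v1[2] * v2[1])
      if (sum(zi * ref) < 0) zi <- -zi
      bcen <- colMeans(view$coords[fr, e$ring$benzene, , drop = TRUE])
      xr <- bcen - cen
      xr <- xr - sum(xr * zi) * zi
      if (sqrt(sum(xr^2)) < 1e-9) next
      xi <- xr / sqrt(sum(xr^2))
      yi <- c(zi[2] * xi[3] - zi[3] * xi[2],
              zi[3] * xi[1] - zi[1] * xi[3],
              zi[1] * xi[2] - zi[2] * xi[1])
      lab_z <- c(0, 0, 1)
      theta <- acos(pmin(1, pmax(-1, sum(zi * lab_z)))) * 180 / pi
      alpha <- atan2(sum(yi * lab_z), sum(xi * lab_z)) * 180 / pi
      alpha <- alpha %% 360
      region <- NA_character_
      if (!is.null(boundaries)) {
        pz <- if (is.na(e$probe))
          mean(view$coords[fr, e$com, 3]) else view$coords[fr, e$probe, 3]
        region <- classify_z(pz - ctr[fr], boundaries)
      }
      out[[length(out) + 1L]] <- data.frame(
        frame = fr, time = view$times[fr], solute = e$resid,
        theta = theta, alpha = alpha, region = region)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' 2-D orientation histogram
#' @param orient output of [indole_orientation()].
#' @param theta_bin,alpha_bin bin widths in degrees.
#' @param region optional region filter.
#' @return data.frame `theta`, `alpha`, `count` over occupied bins.
#' @export
orientation_histogram <- function(orient, theta_bin = 5, alpha_bin = 10,
                                  region = NULL) {
  if (!is.null(region)) orient <- orient[orient$region %in% region, ]
  tb <- floor(orient$theta / theta_bin) * theta_bin + theta_bin / 2
  ab <- floor(orient$alpha / alpha_bin) * alpha_bin + alpha_bin / 2
  agg <- aggregate(list(count = rep(1L, nrow(orient))),
                   by = list(theta = tb, alpha = ab), FUN = sum)
  agg[order(agg$theta, agg$alpha), ]
}
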