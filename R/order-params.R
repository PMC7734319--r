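# Director order parameter P2 (the HMM observable) and deuterium order
# parameters S_CH along the acyl chains, optionally stratified by HMM state.

# displacement end - start with minimum image in all three box dimensions
mi_disp <- function(coords, box, i, j) {
  d <- coords[, j, , drop = FALSE] - coords[, i, , drop = FALSE]
  d <- matrix(d, nrow = dim(coords)[1], ncol = 3)
  d - round(d / box) * box
}

second_legendre <- function(cos_a) (3 * cos_a^2 - 1) / 2

#' Director order parameter P2 per lipid
#'
#' P2 = (3 cos^2(alpha) - 1)/2 where alpha is the angle between the membrane
#' normal (z) and the end-to-end vector of each hydrophobic tail.  For
#' phospholipids the stored value is the average over tails of |P2_tail|
#' (hence in \[0, 1\]); for sterols it is the signed P2 of the single tail
#' vector.
#'
#' @param view a [trajectory_view()].
#' @param leaflets a [assign_leaflets()] result for the same frames.
#' @return object of class `p2_series`: list with `values` (n_frames x
#'   n_lipids matrix), `lipid_ids`, `lipid_type`, `leaflet` (n_frames x
#'   n_lipids), `times` (ps).
#' @export
compute_p2 <- function(view, leaflets) {
  memb <- Filter(function(e) e$species != "solute", view$index)
  nf <- dim(view$coords)[1]
  vals <- matrix(NA_real_, nf, length(memb))
  for (k in seq_along(memb)) {
    e <- memb[[k]]
    tails <- vapply(e$tails, function(tv) {
      d <- mi_disp(view$coords, view$box, tv[1], tv[2])
      nrm <- sqrt(rowSums(d^2))
      bad <- nrm < 1e-12
      if (any(bad)) {
        warning("zero-length tail vector for resid ", e$resid,
                " in ", sum(bad), " frame(s)")
        nrm[bad] <- NA_real_
      }
      second_legendre(d[, 3] / nrm)
    }, numeric(nf))
    dim(tails) <- c(nf, length(e$tails))
    vals[, k] <- if (e$species == "phospholipid")
      rowMeans(abs(tails)) else tails[, 1]
  }
  ids <- vapply(memb, `[[`, integer(1), "resid")
  stopifnot(identical(ids, leaflets$lipid_ids))
  structure(list(values = vals, lipid_ids = ids,
                 lipid_type = vapply(memb, `[[`, character(1), "resname"),
                 leaflet = leaflets$leaflet, times = view$times),
            class = "p2_series")
}

#' Deuterium order parameter profiles S_CH
#'
#' S_CH = (3 cos^2(theta) - 1)/2 with theta the angle between each C-H bond
#' and the membrane normal.  Averaging is two-stage: first over time (and
#' hydrogens of the same carbon) separately for each lipid, then mean and
#' standard error of the mean over lipids.  With `strata`, each lipid's time
#' average for a stratum runs over the frames it spends in that HMM state;
#' lipids with zero dwell in a stratum are excluded from its mean.
#'
#' @param view a [trajectory_view()].
#' @param strata optional `state_trajectory` (see [decode_states()]) aligned
#'   with the view's frames; adds per-state strata to the `"all"` stratum.
#' @param first_carbon index assigned to the first C-H pair of each chain
#'   (carbons conventionally numbered from the carbonyl/amide carbon).
#' @param min_dwell minimum fraction of frames a lipid must spend in a
#'   stratum to contribute to it.
#' @return data.frame with columns `lipid_type`, `chain`, `carbon`,
#'   `stratum`, `s_ch`, `sem`, `n_lipids`.  `sem` is `NA` when fewer than
#'   two lipids contribute.
#' @export
compute_sch <- function(view, strata = NULL, first_carbon = 2L,
                        min_dwell = 0) {
  memb <- Filter(function(e) length(e$chains) > 0L, view$index)
  nf <- dim(view$coords)[1]
  strata_names <- "all"
  if (!is.null(strata)) {
    stopifnot(nrow(strata$states) == nf)
    strata_names <- c("all", sort(unique(as.vector(strata$states))))
  }
  # per-lipid, per-frame, per-carbon S_CH (hydrogens of a carbon averaged)
  rows <- list()
  types <- unique(vapply(memb, `[[`, character(1), "resname"))
  for (tp in types) {
    lip <- Filter(function(e) e$resname == tp, memb)
    n_chains <- length(lip[[1]]$chains)
    for (ci in seq_len(n_chains)) {
      pairs <- lip[[1]]$chains[[ci]]
      carbons <- pairs[, 1]
      ucarb <- unique(carbons)          # local carbon ids within template
      # per lipid: frame x carbon matrix of S_CH
      per_lipid <- lapply(lip, function(e) {
        pr <- e$chains[[ci]]
        s <- vapply(seq_len(nrow(pr)), function(r) {
          d <- mi_disp(view$coords, view$box, pr[r, 1], pr[r, 2])
          second_legendre(d[, 3] / sqrt(rowSums(d^2)))
        }, numeric(nf))
        dim(s) <- c(nf, nrow(pr))
        grp <- match(pr[, 1], unique(pr[, 1]))
        # average hydrogens sharing a carbon, per frame
        t(rowsum(t(s), grp) / as.vector(table(grp)))
      })
      carb_pos <- seq_along(ucarb) + first_carbon - 1L
      for (st in strata_names) {
        means <- vapply(seq_along(lip), function(li) {
          m <- per_lipid[[li]]
          if (st != "all") {
            col <- match(lip[[li]]$resid, strata$lipid_ids)
            if (is.na(col)) return(rep(NA_real_, ncol(m)))
            keep <- strata$states[, col] == st
            if (mean(keep) <= min_dwell || !any(keep))
              return(rep(NA_real_, ncol(m)))
            m <- m[keep, , drop = FALSE]
          }
          colMeans(m)
        }, numeric(length(carb_pos)))
        dim(means) <- c(length(carb_pos), length(lip))
        n_ok <- rowSums(!is.na(means))
        s_ch <- rowMeans(means, na.rm = TRUE)
        sem <- apply(means, 1, function(v) {
          v <- v[!is.na(v)]
          if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))
        })
        rows[[length(rows) + 1L]] <- data.frame(
          lipid_type = tp, chain = ci, carbon = carb_pos, stratum = st,
          s_ch = ifelse(n_ok > 0, s_ch, NA_real_), sem = sem,
          n_lipids = n_ok, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
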