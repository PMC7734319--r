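# End-to-end pipeline: run every analysis stage on a trajectory view and
# write the standard CSV/JSON outputs.

write_with_sidecar <- function(df, path, meta = list()) {
  write.csv(df, path, row.names = FALSE)
  meta$written <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path),
                                    ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full membrane-domain analysis pipeline
#'
#' Leaflet assignment, P2, HMM classification, domain fractions, dwell
#' lifetimes, state-stratified S_CH profiles, density profiles, solute
#' PMF/binding/orientation (when a solute with a probe atom is present),
#' area compressibility, director spectrum + bending modulus, and lateral
#' diffusion.  Tabular outputs are written as CSV with JSON metadata
#' sidecars when `out_dir` is given.
#'
#' @param view a [trajectory_view()].
#' @param temperature K.
#' @param out_dir optional output directory.
#' @param solute residue name of the solute (default: first solute species
#'   found, if any).
#' @param bilayer_thickness nm, for the bending-modulus q cutoff; default
#'   derived from twice the head-atom |z|.
#' @param contact_cutoff nm for the solute contact percentages.
#' @param fit_window ns window for the dwell-time fits.
#' @return list with all stage results.
#' @export
run_pipeline <- function(view, temperature = 303, out_dir = NULL,
                         solute = NULL, bilayer_thickness = NULL,
                         contact_cutoff = 0.6, fit_window = 300) {
  res <- list()
  lf <- assign_leaflets(view)
  p2 <- compute_p2(view, lf)
  res$p2 <- p2
  cls <- hmm_classify(p2)
  res$hmm <- cls
  res$fractions <- domain_fractions(cls$states)
  res$lifetimes <- list(
    D = dwell_lifetimes(cls$states, "D", fit_window),
    O = dwell_lifetimes(cls$states, "O", fit_window))
  res$sch <- compute_sch(view, strata = cls$states)
  res$density <- list(
    head = density_profile(view,
      atoms = vapply(Filter(function(e) e$species != "solute",
                            view$index), `[[`, integer(1), "head")),
    backbone = tryCatch(density_profile(view, atom_bb(view)),
                        error = function(e) NULL))
  ar <- area_series(view)
  res$area <- ar
  res$K_A <- area_compressibility(ar, temperature)
  spec <- director_spectrum(view, lf)
  res$spectrum <- spec
  if (is.null(bilayer_thickness)) {
    memb <- Filter(function(e) e$species != "solute", view$index)
    heads <- vapply(memb, `[[`, integer(1), "head")
    bilayer_thickness <- 2 * mean(abs(view$coords[1, heads, 3] -
                                        mean(view$coords[1, heads, 3])))
  }
  res$K_C <- tryCatch(
    bending_modulus(spec, temperature, bilayer_thickness),
    error = function(e) { message("K_C fit skipped: ", e$message); NULL })
  res$diffusion <- tryCatch(
    lateral_diffusion(view, lf,
                      fit_window = c(diff(view$times[1:2]) / 1000,
                                     diff(range(view$times)) / 4000)),
    error = function(e) NULL)
  if (is.null(solute)) {
    sol_types <- unique(vapply(Filter(function(e) e$species == "solute",
                                      view$index), `[[`, character(1),
                               "resname"))
    solute <- if (length(sol_types)) sol_types[1] else NULL
  }
  if (!is.null(solute)) {
    sol_z <- centered_z(view, resname = solute, com = TRUE)
    res$pmf <- tryCatch(pmf_from_density(as.vector(sol_z), temperature),
                        error = function(e) NULL)
    bnd <- tryCatch({
      bb <- res$density$backbone %||% res$density$head
      region_boundaries(res$density$head, bb)
    }, error = function(e) NULL)
    if (!is.null(bnd)) {
      res$boundaries <- bnd
      res$binding <- classify_binding(view, solute, bnd, contact_cutoff)
      res$orientation <- tryCatch(indole_orientation(view, solute, bnd),
                                  error = function(e) NULL)
    }
  }
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir, temperature)
  res
}

atom_bb <- function(view) {
  ids <- select_atoms(view, atom = "BB")
  if (!length(ids)) stop("no backbone atoms")
  ids
}

write_pipeline_outputs <- function(res, out_dir, temperature) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(out_dir, x)
  meta <- list(units = list(length = "nm", time = "ps", energy = "kcal/mol",
                            K_A = "mN/m", K_C = "J"),
               temperature_K = temperature)
  # P2 wide table
  p2w <- data.frame(time = res$p2$times, res$p2$values)
  names(p2w) <- c("time", paste0("lipid_", res$p2$lipid_ids))
  write_with_sidecar(p2w, f("p2_series.csv"), meta)
  st <- res$hmm$states
  stw <- data.frame(time = st$times, st$states)
  names(stw) <- c("time", paste0("lipid_", st$lipid_ids))
  write_with_sidecar(stw, f("states.csv"), meta)
  write_with_sidecar(res$fractions$composition, f("domain_fractions.csv"),
                     c(meta, list(distribution = res$fractions$distribution)))
  lt <- do.call(rbind, lapply(names(res$lifetimes), function(s) {
    d <- res$lifetimes[[s]]
    data.frame(state = s, tau1 = d$fit_tau1, tau2 = d$fit_tau2,
               a1 = d$fit_a1, a2 = d$fit_a2,
               n_dwells = sum(!d$dwells$censored))
  }))
  write_with_sidecar(lt, f("lifetimes.csv"), meta)
  write_with_sidecar(res$sch, f("sch_profile.csv"), meta)
  for (nm in names(res$density))
    if (!is.null(res$density[[nm]]))
      write_with_sidecar(as.data.frame(res$density[[nm]]),
                         f(sprintf("density_%s.csv", nm)), meta)
  if (!is.null(res$pmf))
    write_with_sidecar(as.data.frame(res$pmf), f("pmf.csv"),
                       c(meta, list(gmm_components =
                                      attr(res$pmf, "components"))))
  if (!is.null(res$binding))
    jsonlite::write_json(list(summary = res$binding$summary,
                              contact_summary = res$binding$contact_summary),
                         f("binding_summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(res$orientation))
    write_with_sidecar(orientation_histogram(res$orientation),
                       f("orientation_hist.csv"), meta)
  write_with_sidecar(as.data.frame(res$spectrum), f("spectrum.csv"), meta)
  mech <- list(K_A_mN_m = res$K_A$K_A, K_A_se = res$K_A$se,
               mean_area_nm2 = res$K_A$mean_area,
               apl_A2 = mean(res$area$apl),
               apl_excl_chol_A2 = if (!is.null(res$area$apl_excl_chol))
                 mean(res$area$apl_excl_chol) else NULL,
               K_C_J = res$K_C$K_C, K_C_se = res$K_C$se,
               block_length_ns = res$K_A$block_length,
               corr_time_ns = res$K_A$corr_time)
  jsonlite::write_json(c(meta, mech), f("mechanics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$diffusion))
    write_with_sidecar(res$diffusion$msd, f("msd.csv"),
                       c(meta, list(D_cm2_s = res$diffusion$D_cm2_s)))
  invisible(out_dir)
}
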