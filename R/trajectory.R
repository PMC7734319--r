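# TrajectoryView: the in-memory substrate of all analyses.  Frames carry
# positions (nm) and orthorhombic box edges; per-residue atom roles are
# resolved once against the lipid definitions.

#' Build a trajectory view from in-memory arrays
#'
#' Low-level constructor used by [load_trajectory()] and by the synthetic
#' generator; also convenient for building small views directly in tests.
#'
#' @param coords array n_frames x natoms x 3, nm.
#' @param box n_frames x 3 matrix (or length-3 vector recycled) of box edge
#'   lengths, nm.
#' @param times frame times, ps; must be strictly increasing.
#' @param atoms data.frame with columns `resid`, `resname`, `atom`.
#' @param definitions named list of [lipid_definition()] objects keyed by
#'   residue name.
#' @return an object of class `trajectory_view`.
#' @export
trajectory_view <- function(coords, box, times, atoms, definitions) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(1L, dim(coords)))
  nf <- dim(coords)[1]
  if (is.null(dim(box))) box <- matrix(box, nf, 3L, byrow = TRUE)
  stopifnot(dim(coords)[2] == nrow(atoms), nrow(box) == nf,
            length(times) == nf, all(box > 0), all(is.finite(coords)))
  if (nf > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  idx <- resolve_roles(atoms, definitions)
  structure(list(coords = coords, box = box, times = times, atoms = atoms,
                 definitions = definitions, index = idx),
            class = "trajectory_view")
}

#' @export
print.trajectory_view <- function(x, ...) {
  cat("<trajectory_view>", dim(x$coords)[1], "frames,",
      dim(x$coords)[2], "atoms,", length(x$index), "residues\n")
  cat("  time:", min(x$times), "-", max(x$times), "ps;  box:",
      paste(signif(x$box[1, ], 4), collapse = " x "), "nm\n")
  invisible(x)
}

# Resolve every defined residue's atom names to global atom row indices.
resolve_roles <- function(atoms, definitions) {
  key <- paste(atoms$resid, atoms$resname)
  split_idx <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  out <- list()
  for (ids in split_idx) {
    rn <- atoms$resname[ids[1]]
    def <- definitions[[rn]]
    if (is.null(def)) {
      if (rn %in% c("SOL", "W", "WAT", "NA", "CL", "K", "ION")) next
      stop("no lipid definition for residue name '", rn,
           "' (resid ", atoms$resid[ids[1]], ")")
    }
    names_here <- atoms$atom[ids]
    find1 <- function(an, role) {
      hit <- ids[names_here == an]
      if (length(hit) != 1L)
        stop("residue '", rn, "' (resid ", atoms$resid[ids[1]], "): atom '",
             an, "' for role ", role, " matched ", length(hit),
             " atoms; available: ", paste(unique(names_here), collapse = " "))
      hit
    }
    entry <- list(
      resid = atoms$resid[ids[1]], resname = rn, species = def$species,
      atoms = ids,
      head = if (!is.null(def$head_ref_atom))
        find1(def$head_ref_atom, "head_ref") else NA_integer_,
      tails = lapply(def$tail_vectors, function(tv)
        c(find1(tv[1], "tail start"), find1(tv[2], "tail end"))),
      chains = lapply(def$ch_pairs, function(ch)
        t(vapply(ch, function(p)
          c(find1(p[1], "C-H carbon"), find1(p[2], "C-H hydrogen")),
          integer(2)))),
      com = if (!is.null(def$com_atoms))
        vapply(def$com_atoms, find1, integer(1), role = "com") else ids,
      probe = if (!is.null(def$probe_atom))
        find1(def$probe_atom, "probe") else NA_integer_,
      ring = if (!is.null(def$ring_atoms)) list(
        benzene = vapply(def$ring_atoms$benzene, find1, integer(1),
                         role = "ring"),
        pyrrole = vapply(def$ring_atoms$pyrrole, find1, integer(1),
                         role = "ring")) else NULL
    )
    entry$director <- if (!is.null(def$director_vector)) {
      c(find1(def$director_vector[1], "director start"),
        find1(def$director_vector[2], "director end"))
    } else if (def$species != "solute" && length(entry$tails) >= 1L) {
      c(entry$head, entry$tails[[length(entry$tails)]][2])
    } else NULL
    out[[length(out) + 1L]] <- entry
  }
  out
}

#' Load a trajectory from structure and trajectory files
#'
#' Reads a GRO or PDB topology plus an optional TRR or multi-frame GRO
#' trajectory, resolves atom roles against the lipid definitions, and
#' returns a [trajectory_view()].  XTC input is not supported (its lossy
#' compressed coordinate encoding is out of scope); convert to TRR.
#'
#' @param topology_path GRO or PDB file.
#' @param trajectory_path optional TRR or multi-frame GRO file; when absent
#'   the topology's single frame is used.
#' @param definitions named list of [lipid_definition()].
#' @param stride optional retention interval in ps; frames at times
#'   t0, t0+stride, t0+2*stride, ... are kept.
#' @return a `trajectory_view`.
#' @export
load_trajectory <- function(topology_path, trajectory_path = NULL,
                            definitions, stride = NULL) {
  stopifnot(file.exists(topology_path))
  ext <- tolower(tools::file_ext(topology_path))
  if (ext == "gro") {
    top <- read_gro(topology_path)[[1]]
    atoms <- data.frame(resid = top$resid, resname = top$resname,
                        atom = top$atom, stringsAsFactors = FALSE)
  } else if (ext == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("PDB input requires the 'bio3d' package")
    pdb <- bio3d::read.pdb(topology_path)
    atoms <- data.frame(resid = pdb$atom$resno, resname = pdb$atom$resid,
                        atom = pdb$atom$elety, stringsAsFactors = FALSE)
    top <- list(pos = cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z) / 10,
                box = rep(10, 3), time = 0)
  } else stop("unsupported topology format: .", ext)

  if (is.null(trajectory_path)) {
    coords <- array(top$pos, c(1L, nrow(top$pos), 3L))
    box <- matrix(top$box, 1L, 3L)
    times <- if (is.finite(top$time %||% NA)) top$time else 0
  } else {
    text <- tolower(tools::file_ext(trajectory_path))
    if (text == "xtc")
      stop("XTC trajectories are not supported (compressed coordinate ",
           "encoding); convert to TRR, e.g. `gmx trjconv -o traj.trr`")
    if (text == "trr") {
      trr <- read_trr(trajectory_path)
      stopifnot(trr$natoms == nrow(atoms))
      coords <- trr$coords; box <- trr$box; times <- trr$times
    } else if (text == "gro") {
      frames <- read_gro(trajectory_path)
      coords <- array(NA_real_, c(length(frames), nrow(atoms), 3L))
      for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]$pos
      box <- do.call(rbind, lapply(frames, `[[`, "box"))
      times <- vapply(frames, `[[`, numeric(1), "time")
      if (anyNA(times)) times <- seq_along(frames) - 1
    } else stop("unsupported trajectory format: .", text)
  }

  if (!is.null(stride)) {
    k <- (times - times[1]) / stride
    keep <- abs(k - round(k)) < 1e-6
    coords <- coords[keep, , , drop = FALSE]
    box <- box[keep, , drop = FALSE]
    times <- times[keep]
  }
  trajectory_view(coords, box, times, atoms, definitions)
}

#' Assign lipids to bilayer leaflets
#'
#' A lipid belongs to the upper leaflet when its head reference atom lies
#' above the instantaneous bilayer center (the mean z of all head atoms).
#' Solutes are never assigned.  By default the assignment is recomputed for
#' every frame; `frozen = TRUE` freezes the first frame's assignment.
#'
#' @param view a [trajectory_view()].
#' @param frame optional single frame index; default all frames.
#' @param frozen use the first evaluated frame's assignment for all frames.
#' @return object of class `leaflet_assignment`: list with `lipid_ids`
#'   (resids), `leaflet` (n_frames x n_lipids character matrix, `"upper"` /
#'   `"lower"`), `center_z` (per frame, nm) and `frames` (frame indices).
#' @export
assign_leaflets <- function(view, frame = NULL, frozen = FALSE) {
  memb <- Filter(function(e) e$species != "solute", view$index)
  if (length(memb) < 2L) stop("need at least 2 membrane lipids")
  heads <- vapply(memb, `[[`, integer(1), "head")
  ids <- vapply(memb, `[[`, integer(1), "resid")
  frames <- if (is.null(frame)) seq_len(dim(view$coords)[1]) else frame
  zs <- view$coords[frames, heads, 3, drop = FALSE]
  dim(zs) <- c(length(frames), length(heads))
  center <- rowMeans(zs)
  lab <- ifelse(zs > center, "upper", "lower")
  if (frozen && length(frames) > 1L)
    lab <- matrix(lab[1, ], length(frames), length(heads), byrow = TRUE)
  one_sided <- apply(lab, 1, function(r) length(unique(r)) == 1L)
  if (any(one_sided))
    warning("degenerate bilayer: all lipids on one side in ",
            sum(one_sided), " frame(s)")
  structure(list(lipid_ids = ids, leaflet = lab, center_z = center,
                 frames = frames),
            class = "leaflet_assignment")
}

# Residues of a view as a small data.frame.
#' Summarize the residues resolved in a view
#' @param view a [trajectory_view()].
#' @return data.frame with `resid`, `resname`, `species`.
#' @export
lipid_residues <- function(view) {
  data.frame(
    resid = vapply(view$index, `[[`, integer(1), "resid"),
    resname = vapply(view$index, `[[`, character(1), "resname"),
    species = vapply(view$index, `[[`, character(1), "species"),
    stringsAsFactors = FALSE
  )
}

# minimum-image displacement in xy for an orthorhombic box
min_image_xy <- function(d, box_xy) {
  d - round(d / box_xy) * box_xy
}
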