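#' Define the atom roles of a membrane residue
#'
#' A lipid definition maps the atom names of one residue type onto the roles
#' the analyses need: the head reference atom (leaflet assignment, headgroup
#' density, director origin), hydrophobic tail end-to-end vectors (P2 order
#' parameter), C-H bond pairs per acyl chain (deuterium order parameters),
#' center-of-mass atoms (density profiles), a probe atom (binding
#' classification, e.g. the hydroxyl oxygen of serotonin) and, for solutes
#' with an aromatic ring system, the ring atoms defining the molecular
#' orientation frame.
#'
#' @param residue_name residue name as it appears in the topology.
#' @param species one of `"phospholipid"`, `"sterol"`, `"solute"`.
#' @param tail_vectors list of length-2 character vectors
#'   `c(start_atom, end_atom)`; phospholipids need at least one, sterols
#'   exactly one.
#' @param ch_pairs list of chains; each chain is a list of length-2
#'   character vectors `c(carbon_atom, hydrogen_atom)` ordered along the
#'   chain from the carbonyl/amide carbon.
#' @param head_ref_atom atom name used for leaflet assignment and as the
#'   default director origin.
#' @param com_atoms atom names entering center-of-mass profiles (defaults to
#'   all atoms of the residue).
#' @param probe_atom atom name used for binding-region classification.
#' @param director_vector optional `c(start_atom, end_atom)` overriding the
#'   default head-to-tail director used in the fluctuation spectrum.
#' @param ring_atoms optional list with elements `benzene` (6 atom names)
#'   and `pyrrole` (5 atom names, sharing two with `benzene`) for the
#'   indole-type orientation frame.
#' @return an object of class `lipid_definition`.
#' @export
lipid_definition <- function(residue_name, species,
                             tail_vectors = list(), ch_pairs = list(),
                             head_ref_atom = NULL, com_atoms = NULL,
                             probe_atom = NULL, director_vector = NULL,
                             ring_atoms = NULL) {
  species <- match.arg(species, c("phospholipid", "sterol", "solute"))
  if (species == "phospholipid") {
    if (length(tail_vectors) < 1L)
      stop("phospholipid '", residue_name, "' needs at least one tail vector")
    if (length(ch_pairs) < 1L)
      stop("phospholipid '", residue_name, "' needs at least one C-H chain")
  }
  if (species == "sterol" && length(tail_vectors) != 1L)
    stop("sterol '", residue_name, "' needs exactly one tail vector")
  if (species != "solute" && is.null(head_ref_atom))
    stop("'", residue_name, "': head_ref_atom is required for membrane lipids")
  structure(list(
    residue_name = residue_name, species = species,
    tail_vectors = tail_vectors, ch_pairs = ch_pairs,
    head_ref_atom = head_ref_atom, com_atoms = com_atoms,
    probe_atom = probe_atom, director_vector = director_vector,
    ring_atoms = ring_atoms
  ), class = "lipid_definition")
}

#' @export
print.lipid_definition <- function(x, ...) {
  cat("<lipid_definition>", x$residue_name, "(", x$species, ")\n")
  cat("  tails:", length(x$tail_vectors),
      " chains:", length(x$ch_pairs),
      " head:", x$head_ref_atom %||% "-", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read lipid definitions and analysis settings from a YAML config
#'
#' The config has blocks `lipids:` (one entry per residue name, fields as in
#' [lipid_definition()]), and optional `analysis:`, `hmm:`, `mechanics:` and
#' `synthetic:` blocks passed through as lists.
#'
#' @param path path to a YAML file.
#' @return list with elements `definitions` (named list of
#'   `lipid_definition`), `analysis`, `hmm`, `mechanics`, `synthetic`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defs <- lapply(names(cfg$lipids %||% list()), function(rn) {
    b <- cfg$lipids[[rn]]
    lipid_definition(
      residue_name = rn, species = b$species,
      tail_vectors = lapply(b$tail_vectors %||% list(), unlist),
      ch_pairs = lapply(b$ch_pairs %||% list(),
                        function(ch) lapply(ch, unlist)),
      head_ref_atom = b$head_ref_atom, com_atoms = unlist(b$com_atoms),
      probe_atom = b$probe_atom,
      director_vector = unlist(b$director_vector),
      ring_atoms = b$ring_atoms
    )
  })
  names(defs) <- names(cfg$lipids %||% list())
  list(definitions = defs,
       analysis = cfg$analysis %||% list(),
       hmm = cfg$hmm %||% list(),
       mechanics = cfg$mechanics %||% list(),
       synthetic = cfg$synthetic %||% list())
}
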