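#' Read a GRO structure or multi-frame GRO trajectory
#'
#' Parses the fixed-column GROMACS GRO format.  Multiple concatenated frames
#' are supported; the box line must describe an orthorhombic cell (a box
#' line with any non-zero off-diagonal component is rejected).
#'
#' @param path path to a `.gro` file.
#' @return a list of frames; each frame is a list with elements
#'   `time` (ps, `NA` if not encoded in the title), `resid`, `resname`,
#'   `atom` (atom names), `pos` (n x 3 matrix, nm) and `box`
#'   (length-3 vector of edge lengths, nm).
#' @seealso [write_gro()], [read_trr()]
#' @export
read_gro <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    natoms <- as.integer(trimws(lines[i + 1L]))
    if (is.na(natoms)) stop("malformed GRO: bad atom count at line ", i + 1L)
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- lines[i + 2L + natoms]
    time <- NA_real_
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(tm) == 1L) time <- as.numeric(sub("t=\\s*", "", tm))
    resid <- as.integer(substr(atom_lines, 1L, 5L))
    resname <- trimws(substr(atom_lines, 6L, 10L))
    atom <- trimws(substr(atom_lines, 11L, 15L))
    x <- as.numeric(substr(atom_lines, 21L, 28L))
    y <- as.numeric(substr(atom_lines, 29L, 36L))
    z <- as.numeric(substr(atom_lines, 37L, 44L))
    box_v <- as.numeric(strsplit(trimws(box_line), "\\s+")[[1]])
    if (length(box_v) >= 9L && any(abs(box_v[4:9]) > 1e-9))
      stop("triclinic boxes are not supported; only orthorhombic cells")
    frames[[length(frames) + 1L]] <- list(
      time = time, resid = resid, resname = resname, atom = atom,
      pos = cbind(x = x, y = y, z = z), box = box_v[1:3]
    )
    i <- i + 3L + natoms
  }
  frames
}

#' Write a GRO file (one or more frames)
#'
#' @param frames a single frame list (as returned by [read_gro()]) or a list
#'   of such frames.
#' @param path output path.
#' @param title title string for each frame.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frames, path, title = "memdomain synthetic bilayer") {
  if (!is.null(frames$pos)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$pos)
    hdr <- if (!is.null(fr$time) && is.finite(fr$time)) {
      sprintf("%s t= %.3f", title, fr$time)
    } else title
    writeLines(hdr, con)
    writeLines(sprintf("%5d", n), con)
    # atom numbers wrap at 100000 per format
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     fr$resid %% 100000L, fr$resname, fr$atom,
                     seq_len(n) %% 100000L,
                     fr$pos[, 1], fr$pos[, 2], fr$pos[, 3])
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]),
               con)
  }
  invisible(path)
}
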