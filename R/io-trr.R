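# TRR is the uncompressed GROMACS trajectory container: a sequence of XDR
# (big-endian) frames, each with a fixed header of section byte-sizes
# followed by box, coordinate, velocity and force blocks.  Only the blocks
# present (size > 0) are stored; single or double precision is inferred
# from x_size / (3 * natoms).

TRR_MAGIC <- 1993L
TRR_VERSION <- "GMX_trn_file"

read_xdr_string <- function(con) {
  readBin(con, "integer", 1L, endian = "big")          # strlen + 1
  len <- readBin(con, "integer", 1L, endian = "big")
  s <- rawToChar(readBin(con, "raw", len))
  pad <- (4L - len %% 4L) %% 4L
  if (pad > 0L) readBin(con, "raw", pad)
  s
}

write_xdr_string <- function(con, s) {
  len <- nchar(s, type = "bytes")
  writeBin(c(len + 1L, len), con, endian = "big")
  writeBin(charToRaw(s), con)
  pad <- (4L - len %% 4L) %% 4L
  if (pad > 0L) writeBin(raw(pad), con)
}

#' Read a TRR trajectory
#'
#' Pure-R reader for the GROMACS TRR format (single or double precision).
#' Velocities and forces, if present, are skipped.  Triclinic boxes are
#' rejected.
#'
#' @param path path to a `.trr` file.
#' @return list with `natoms`, `times` (ps), `steps`, `box` (n_frames x 3
#'   matrix, nm) and `coords` (array n_frames x natoms x 3, nm).
#' @seealso [write_trr()]
#' @export
read_trr <- function(path) {
  stopifnot(file.exists(path))
  con <- file(path, "rb")
  on.exit(close(con))
  times <- numeric(); steps <- integer()
  boxes <- list(); coords <- list()
  natoms <- NA_integer_
  repeat {
    magic <- readBin(con, "integer", 1L, endian = "big")
    if (length(magic) == 0L) break
    if (magic != TRR_MAGIC) stop("not a TRR file (bad magic ", magic, ")")
    read_xdr_string(con)
    sizes <- readBin(con, "integer", 13L, endian = "big")
    names(sizes) <- c("ir", "e", "box", "vir", "pres", "top", "sym",
                      "x", "v", "f", "natoms", "step", "nre")
    na <- sizes[["natoms"]]
    if (is.na(natoms)) natoms <- na
    if (na != natoms) stop("variable atom count across TRR frames")
    fsize <- if (sizes[["x"]] > 0L) sizes[["x"]] / (3L * na) else
      if (sizes[["box"]] > 0L) sizes[["box"]] / 9L else 4L
    if (!fsize %in% c(4, 8)) stop("cannot infer TRR precision")
    rd <- function(n) readBin(con, "double", n, size = fsize, endian = "big")
    times <- c(times, rd(1L))
    rd(1L)                                              # lambda
    if (sizes[["box"]] > 0L) {
      b <- rd(9L)
      if (any(abs(b[c(2, 3, 4, 6, 7, 8)]) > 1e-9))
        stop("triclinic boxes are not supported; only orthorhombic cells")
      boxes[[length(boxes) + 1L]] <- b[c(1, 5, 9)]
    } else boxes[[length(boxes) + 1L]] <- rep(NA_real_, 3L)
    if (sizes[["x"]] > 0L) {
      xyz <- rd(3L * na)
      coords[[length(coords) + 1L]] <- matrix(xyz, ncol = 3L, byrow = TRUE)
    }
    if (sizes[["v"]] > 0L) rd(3L * na)
    if (sizes[["f"]] > 0L) rd(3L * na)
    steps <- c(steps, sizes[["step"]])
  }
  nf <- length(coords)
  arr <- array(NA_real_, dim = c(nf, natoms, 3L))
  for (k in seq_len(nf)) arr[k, , ] <- coords[[k]]
  list(natoms = natoms, times = times, steps = steps,
       box = do.call(rbind, boxes), coords = arr)
}

#' Write a TRR trajectory
#'
#' Writes single-precision coordinate frames with an orthorhombic box.
#'
#' @param coords array n_frames x natoms x 3 (nm), or a natoms x 3 matrix
#'   for a single frame.
#' @param box n_frames x 3 matrix (or length-3 vector recycled) of edge
#'   lengths, nm.
#' @param times frame times, ps.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trr <- function(coords, box, times, path) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(1L, dim(coords)))
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  if (is.null(dim(box))) box <- matrix(box, nf, 3L, byrow = TRUE)
  stopifnot(nrow(box) == nf, length(times) == nf)
  con <- file(path, "wb")
  on.exit(close(con))
  for (k in seq_len(nf)) {
    writeBin(TRR_MAGIC, con, endian = "big")
    write_xdr_string(con, TRR_VERSION)
    sizes <- integer(13L)
    sizes[3] <- 36L                       # box: 9 floats
    sizes[8] <- 12L * na                  # x
    sizes[11] <- na
    sizes[12] <- k - 1L                   # step
    writeBin(sizes, con, endian = "big")
    wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "big")
    wf(c(times[k], 0))
    b <- numeric(9L); b[c(1, 5, 9)] <- box[k, ]
    wf(b)
    wf(as.vector(t(coords[k, , ])))
  }
  invisible(path)
}
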