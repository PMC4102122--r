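# In-memory trajectory container plus CHARMM-style DCD binary I/O.
# Coordinates are stored in Angstrom, times in ns, boxes as orthogonal
# lengths in Angstrom. DCD stores single-precision coordinates, so file
# round trips are exact only to ~1e-3 A at typical coordinate magnitudes.

# AKMA time unit in ps (CHARMM DCD delta convention)
.akma_ps <- 0.04888821

#' Construct an in-memory trajectory
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param times numeric vector of frame times (ns), non-decreasing.
#' @param box `n_frames x 3` matrix of orthogonal box lengths (Angstrom),
#'   or a single length-3 vector recycled to all frames.
#' @return an object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, times, box) {
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 3L) abort("coords must be n_atoms x 3 x n_frames")
  nf <- d[3]
  if (length(times) != nf) abort("times length (%d) != n_frames (%d)", length(times), nf)
  if (is.unsorted(times)) abort("frame times must be non-decreasing")
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (nrow(box) != nf || ncol(box) != 3L) abort("box must be n_frames x 3")
  if (any(box <= 0)) abort("box lengths must be positive")
  structure(list(coords = coords, times = times, box = box),
            class = "md_trajectory")
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return list with `time` (ns), `coords` (n x 3, Angstrom), `box`.
#' @export
get_frame <- function(traj, i) {
  nf <- n_frames(traj)
  if (i < 1L || i > nf) abort("frame index %d out of range 1..%d", i, nf)
  list(time = traj$times[i], coords = traj$coords[, , i, drop = TRUE],
       box = traj$box[i, ])
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d atoms, %d frames, t = %.4g..%.4g ns\n",
              dim(x$coords)[1], n_frames(x), x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

dcd_record <- function(con, payload_writer, nbytes) {
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  payload_writer()
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
}

#' Write a trajectory to a DCD file
#'
#' CHARMM-format DCD with the crystal (unit-cell) flag set; coordinates are
#' written single precision, orthogonal boxes as (A, 0, B, 0, 0, C). The
#' frame interval is stored in the header (AKMA units), so times survive a
#' round trip through [read_trajectory()].
#'
#' @param traj an [md_trajectory()]; frame times must be uniformly spaced.
#' @param path output path (`.dcd`).
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  nf <- n_frames(traj)
  na <- dim(traj$coords)[1]
  dt_ns <- if (nf > 1L) traj$times[2] - traj$times[1] else 0
  if (nf > 2L && max(abs(diff(traj$times) - dt_ns)) > 1e-9) {
    abort("DCD requires uniformly spaced frame times")
  }
  delta <- (dt_ns * 1000) / .akma_ps
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  # header record: "CORD" + 20 int32 control words (delta as float bits)
  dcd_record(con, function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf          # frames in file
    icntrl[2] <- 0L          # first step
    icntrl[3] <- 1L          # steps between frames
    icntrl[4] <- nf          # total steps
    icntrl[11] <- 1L         # unit cell present
    icntrl[20] <- 24L        # CHARMM version tag
    writeBin(icntrl[1:9], con, size = 4, endian = "little")
    writeBin(as.numeric(delta), con, size = 4, endian = "little")
    writeBin(icntrl[11:20], con, size = 4, endian = "little")
  }, 84L)
  title <- sprintf("%-80s", "poregate synthetic trajectory")
  dcd_record(con, function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84L)
  dcd_record(con, function() {
    writeBin(as.integer(na), con, size = 4, endian = "little")
  }, 4L)
  for (i in seq_len(nf)) {
    b <- traj$box[i, ]
    dcd_record(con, function() {
      writeBin(as.numeric(c(b[1], 0, b[2], 0, 0, b[3])), con,
               size = 8, endian = "little")
    }, 48L)
    for (ax in 1:3) {
      v <- traj$coords[, ax, i]
      dcd_record(con, function() {
        writeBin(as.numeric(v), con, size = 4, endian = "little")
      }, 4L * na)
    }
  }
  invisible(path)
}

read_dcd_record <- function(con, what, size, n, ctx) {
  lead <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(lead) == 0L) abort("corrupt DCD: unexpected end of file at %s", ctx)
  payload <- readBin(con, what, n = n, size = size, endian = "little")
  if (length(payload) != n) abort("corrupt DCD: truncated record at %s", ctx)
  trail <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(trail) != 1L || trail != lead) {
    abort("corrupt DCD: record marker mismatch at %s", ctx)
  }
  payload
}

#' Read a DCD trajectory
#'
#' @param path path to a `.dcd` file.
#' @param stride keep every `stride`-th frame (default 1).
#' @return an [md_trajectory()]; frame times are reconstructed from the
#'   header's step interval.
#' @keywords internal
read_dcd <- function(path, stride = 1L) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  lead <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(lead) != 1L || lead != 84L) abort("corrupt DCD %s: bad header record", path)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "CORD")) abort("corrupt DCD %s: magic '%s'", path, magic)
  icntrl_a <- readBin(con, "integer", n = 9, size = 4, endian = "little")
  delta <- readBin(con, "numeric", n = 1, size = 4, endian = "little")
  icntrl_b <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  readBin(con, "integer", n = 1, size = 4, endian = "little")
  nf <- icntrl_a[1]; istart <- icntrl_a[2]; nsavc <- max(icntrl_a[3], 1L)
  has_cell <- icntrl_b[1] == 1L
  ntitle_rec <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  ntitle <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  readChar(con, 80L * ntitle, useBytes = TRUE)
  readBin(con, "integer", n = 1, size = 4, endian = "little")
  na <- read_dcd_record(con, "integer", 4, 1, "atom-count block")
  dt_ns <- delta * .akma_ps / 1000 * nsavc
  coords <- array(NA_real_, dim = c(na, 3, nf))
  box <- matrix(NA_real_, nrow = nf, ncol = 3)
  for (i in seq_len(nf)) {
    ctx <- sprintf("frame %d", i)
    if (has_cell) {
      cell <- read_dcd_record(con, "numeric", 8, 6, ctx)
      box[i, ] <- cell[c(1, 3, 6)]
    }
    for (ax in 1:3) coords[, ax, i] <- read_dcd_record(con, "numeric", 4, na, ctx)
  }
  times <- (istart + (seq_len(nf) - 1L) * nsavc) * delta * .akma_ps / 1000
  if (!has_cell) box[] <- 1
  keep <- seq(1L, nf, by = stride)
  md_trajectory(coords[, , keep, drop = FALSE], times[keep],
                box[keep, , drop = FALSE])
}

#' Read a trajectory file
#'
#' Currently supports the DCD format. The atom count is checked against
#' `struct` when one is given.
#'
#' @param path path to a trajectory file (`.dcd`).
#' @param struct optional [md_structure()] for an atom-count check.
#' @param stride keep every `stride`-th frame.
#' @return an [md_trajectory()].
#' @export
read_trajectory <- function(path, struct = NULL, stride = 1L) {
  if (!file.exists(path)) abort("trajectory file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xtc") {
    abort("XTC trajectories are not supported; convert to DCD")
  }
  if (ext != "dcd") abort("unsupported trajectory format '.%s'", ext)
  traj <- read_dcd(path, stride = stride)
  if (!is.null(struct) && dim(traj$coords)[1] != n_atoms(struct)) {
    abort("atom-count mismatch: trajectory has %d atoms, structure has %d",
          dim(traj$coords)[1], n_atoms(struct))
  }
  traj
}
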