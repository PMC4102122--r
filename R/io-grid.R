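# OpenDX scalar-field export/import for density grids. Values are written
# in the standard OpenDX order (last index, z, varies fastest) so files load
# directly in VMD/PyMOL and gridDataFormats.

#' Write a density grid as an OpenDX scalar field
#'
#' Writes the bulk-normalized values (1 = bulk water density). Voxel values
#' are emitted z-fastest per the OpenDX convention, three per line.
#'
#' @param grid a [density_grid()].
#' @param path output path (`.dx`).
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  v <- grid$normalized
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1, ]
    abort("grid contains non-finite value at voxel (%d, %d, %d)",
          bad[1], bad[2], bad[3])
  }
  d <- grid$dims; o <- grid$origin; s <- grid$spacing
  n <- prod(d)
  # flatten with z fastest, then y, then x
  flat <- as.vector(aperm(v, c(3, 2, 1)))
  pad <- (-n) %% 3
  flat_p <- c(flat, rep(NA_real_, pad))
  m <- matrix(flat_p, ncol = 3, byrow = TRUE)
  rows <- apply(m, 1, function(r) paste(fmt_num(r[!is.na(r)]), collapse = " "))
  header <- c(
    sprintf("# OpenDX scalar field: water density normalized to bulk (%g A^-3)",
            grid$bulk_density),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %s %s %s", fmt_num(o[1]), fmt_num(o[2]), fmt_num(o[3])),
    sprintf("delta %s 0 0", fmt_num(s[1])),
    sprintf("delta 0 %s 0", fmt_num(s[2])),
    sprintf("delta 0 0 %s", fmt_num(s[3])),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  )
  footer <- c("attribute \"dep\" string \"positions\"",
              "object \"density\" class field",
              "component \"positions\" value 1",
              "component \"connections\" value 2",
              "component \"data\" value 3")
  writeLines(c(header, rows, footer), path)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_dx()]
#'
#' @param path path to a `.dx` file.
#' @return list with `origin`, `spacing`, `dims` and `values` (3D array,
#'   same orientation as `density_grid$normalized`).
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(gp)) abort("%s: not an OpenDX gridpositions file", path)
  d <- as.integer(strsplit(sub(".*counts\\s+", "", gp), "\\s+")[[1]])
  origin <- as.numeric(strsplit(sub("^origin\\s+", "",
                                    grep("^origin", lines, value = TRUE)[1]), "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dm <- t(vapply(deltas, function(l) {
    as.numeric(strsplit(sub("^delta\\s+", "", l), "\\s+")[[1]])
  }, numeric(3)))
  spacing <- unname(c(dm[1, 1], dm[2, 2], dm[3, 3]))
  origin <- unname(origin)
  start <- grep("data follows", lines)[1]
  items <- as.integer(sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1", lines[start]))
  vals <- numeric(0)
  i <- start + 1L
  while (length(vals) < items && i <= length(lines)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (any(is.na(row))) break
    vals <- c(vals, row)
    i <- i + 1L
  }
  if (length(vals) != items) {
    abort("%s: expected %d values, parsed %d", path, items, length(vals))
  }
  values <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  list(origin = origin, spacing = spacing, dims = d, values = values)
}
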