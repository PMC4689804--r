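## legacy ASCII VTK polydata export of colored streamlines

#' Write a streamline set as legacy ASCII VTK polydata
#'
#' Emits POINTS (z = 0), LINES connectivity, and a per-point
#' unsigned-char RGB array named `eigvec_color` holding the orientation
#' hue-wheel color of the local principal-eigenvector direction (the same
#' wheel as the HSB render). An empty set writes a header-only file with a
#' warning.
#'
#' @param ss a `streamline_set`
#' @param path output .vtk path
#' @return `path`, invisibly
#' @export
write_vtk <- function(ss, path) {
  stopifnot(inherits(ss, "streamline_set"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write VTK file '", path, "': ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  sl <- ss$streamlines
  if (length(sl) == 0) warning("empty streamline set: writing header-only VTK")
  npts <- vapply(sl, function(s) nrow(s$points), integer(1))
  total <- sum(npts)
  writeLines(c("# vtk DataFile Version 3.0",
               "histology-based tractography streamlines",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", total)), con)
  fmt_num <- function(x) formatC(x, format = "g", digits = 9)
  for (s in sl) {
    writeLines(paste(fmt_num(s$points[, 1]), fmt_num(s$points[, 2]), "0"), con)
  }
  writeLines(sprintf("LINES %d %d", length(sl), length(sl) + total), con)
  offset <- 0L
  for (i in seq_along(sl)) {
    idx <- seq.int(offset, length.out = npts[i]) # 0-based indices
    writeLines(paste(npts[i], paste(idx, collapse = " ")), con)
    offset <- offset + npts[i]
  }
  if (total > 0) {
    writeLines(c(sprintf("POINT_DATA %d", total),
                 "SCALARS eigvec_color unsigned_char 3",
                 "LOOKUP_TABLE default"), con)
    for (s in sl) {
      writeLines(paste(s$colors[, 1], s$colors[, 2], s$colors[, 3]), con)
    }
  }
  invisible(path)
}

#' Read back a VTK polydata file written by [write_vtk()]
#'
#' Minimal parser for round-trip checks and downstream use: recovers
#' points, line connectivity and the per-point colors.
#'
#' @param path .vtk path
#' @return list with `points` (n x 3 matrix), `lines` (list of 1-based
#'   index vectors), `colors` (n x 3 integer matrix or NULL)
#' @export
read_vtk <- function(path) {
  txt <- readLines(path)
  pt_line <- grep("^POINTS ", txt)[1]
  n <- as.integer(strsplit(txt[pt_line], "\\s+")[[1]][2])
  pts <- if (n > 0) {
    matrix(scan(text = txt[(pt_line + 1):(pt_line + n)], quiet = TRUE),
           ncol = 3, byrow = TRUE)
  } else matrix(numeric(0), 0, 3)
  ln_line <- grep("^LINES ", txt)[1]
  nl <- as.integer(strsplit(txt[ln_line], "\\s+")[[1]][2])
  lines <- vector("list", nl)
  if (nl > 0) {
    for (i in seq_len(nl)) {
      v <- scan(text = txt[ln_line + i], quiet = TRUE)
      lines[[i]] <- as.integer(v[-1]) + 1L
    }
  }
  colors <- NULL
  sc_line <- grep("^SCALARS eigvec_color", txt)
  if (length(sc_line) == 1 && n > 0) {
    colors <- matrix(as.integer(scan(
      text = txt[(sc_line + 2):(sc_line + 1 + n)], quiet = TRUE)),
      ncol = 3, byrow = TRUE)
  }
  list(points = pts, lines = lines, colors = colors)
}
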