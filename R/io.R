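#' Read a 3D point set from PLY, XYZ or CSV
#'
#' PLY supports the ASCII and binary little-endian dialects (vertex x/y/z
#' properties; other elements and properties are skipped). XYZ expects
#' whitespace-separated coordinate triples, CSV a header containing
#' `x,y,z` columns.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"ply"`, `"xyz"` or `"csv"`.
#' @param label point-set label for the result.
#' @return a [point_set()].
#' @export
read_point_set <- function(path, format = c("auto", "ply", "xyz", "csv"),
                           label = "moving") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", xyz = "xyz", txt = "xyz",
                     csv = "csv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  coords <- switch(format, ply = read_ply(path), xyz = read_xyz(path),
                   csv = read_csv_points(path))
  point_set(coords, label = label, source = path)
}

read_xyz <- function(path) {
  m <- tryCatch(as.matrix(utils::read.table(path, header = FALSE)),
                error = function(e) stop("malformed XYZ file ", path, ": ",
                                         conditionMessage(e)))
  if (ncol(m) < 3L) stop("XYZ file ", path, " has fewer than 3 columns")
  m <- m[, 1:3, drop = FALSE]
  check_finite_rows(m, path)
  m
}

read_csv_points <- function(path) {
  d <- tryCatch(utils::read.csv(path),
                error = function(e) stop("malformed CSV file ", path, ": ",
                                         conditionMessage(e)))
  need <- c("x", "y", "z")
  if (!all(need %in% tolower(names(d))))
    stop("CSV file ", path, " needs header columns x, y, z")
  names(d) <- tolower(names(d))
  m <- as.matrix(d[, need])
  check_finite_rows(m, path)
  m
}

check_finite_rows <- function(m, path) {
  storage.mode(m) <- "double"
  bad <- which(!apply(is.finite(m), 1L, all))
  if (length(bad))
    stop("non-finite coordinates in ", path, " at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(m)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop(path, " is not a PLY file")
  fmt <- NULL
  n_vertex <- NA_integer_
  elements <- list()  # name -> list(count, props = data.frame(type, name))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header in ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
    } else if (tok[1L] == "element") {
      cur <- tok[2L]
      elements[[cur]] <- list(count = as.integer(tok[3L]),
                              types = character(0), names = character(0))
    } else if (tok[1L] == "property") {
      if (is.null(cur)) stop("PLY property before element in ", path)
      if (tok[2L] == "list") {
        elements[[cur]]$types <- c(elements[[cur]]$types,
                                   paste("list", tok[3L], tok[4L]))
        elements[[cur]]$names <- c(elements[[cur]]$names, tok[5L])
      } else {
        elements[[cur]]$types <- c(elements[[cur]]$types, tok[2L])
        elements[[cur]]$names <- c(elements[[cur]]$names, tok[3L])
      }
    } else if (tok[1L] == "end_header") break
  }
  if (is.null(fmt)) stop("PLY file ", path, " has no format line")
  if (!"vertex" %in% names(elements))
    stop("PLY file ", path, " has no vertex element")
  if (fmt == "ascii") return(read_ply_ascii(con, path, elements))
  if (fmt == "binary_little_endian")
    return(read_ply_binary(con, path, elements))
  stop("unsupported PLY format '", fmt, "' in ", path,
       " (ascii and binary_little_endian are supported)")
}

ply_scalar_size <- function(type) {
  switch(type, char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L,
         float32 = 4L, double = 8L, float64 = 8L,
         stop("unsupported PLY property type '", type, "'"))
}

read_ply_ascii <- function(con, path, elements) {
  out <- NULL
  for (el in names(elements)) {
    e <- elements[[el]]
    lines <- readLines(con, n = e$count)
    if (length(lines) < e$count)
      stop("PLY file ", path, ": element ", el, " truncated (",
           length(lines), " of ", e$count, " rows)")
    if (el == "vertex") {
      cols <- match(c("x", "y", "z"), e$names)
      if (anyNA(cols)) stop("PLY vertex element lacks x/y/z in ", path)
      vals <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
      m <- t(vapply(vals, function(v) v[cols], numeric(3L)))
      check_finite_rows(m, path)
      out <- m
    }
  }
  out
}

read_ply_binary <- function(con, path, elements) {
  out <- NULL
  for (el in names(elements)) {
    e <- elements[[el]]
    if (any(startsWith(e$types, "list")) && el != "vertex") {
      # variable-length rows (e.g. faces): consume to end only if last
      if (el != names(elements)[length(elements)])
        stop("PLY file ", path,
             ": list properties in non-terminal element '", el,
             "' are not supported")
      break
    }
    sizes <- vapply(e$types, ply_scalar_size, integer(1L))
    row_bytes <- sum(sizes)
    raw <- readBin(con, "raw", n = row_bytes * e$count)
    if (length(raw) < row_bytes * e$count)
      stop("PLY file ", path, ": element ", el, " truncated")
    if (el == "vertex") {
      cols <- match(c("x", "y", "z"), e$names)
      if (anyNA(cols)) stop("PLY vertex element lacks x/y/z in ", path)
      offs <- c(0L, cumsum(sizes))
      m <- matrix(NA_real_, e$count, 3L)
      for (k in 1:3) {
        j <- cols[k]
        type <- e$types[j]
        sz <- sizes[j]
        starts <- (seq_len(e$count) - 1L) * row_bytes + offs[j]
        bytes <- raw[rep(starts, each = sz) + seq_len(sz)]
        what <- if (type %in% c("float", "float32", "double", "float64"))
          "double" else "integer"
        m[, k] <- readBin(bytes, what, n = e$count, size = sz,
                          endian = "little",
                          signed = !(type %in% c("uchar", "uint8", "ushort",
                                                 "uint16")))
      }
      check_finite_rows(m, path)
      out <- m
    }
  }
  out
}

#' Write a point set to PLY (ASCII), XYZ or CSV
#'
#' @param ps a [point_set()] or n x 3 matrix.
#' @param path output file.
#' @param format `"auto"` (by extension), `"ply"`, `"xyz"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_point_set <- function(ps, path, format = c("auto", "ply", "xyz", "csv")) {
  format <- match.arg(format)
  m <- if (inherits(ps, "point_set")) as_coord_matrix(ps) else as.matrix(ps)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", xyz = "xyz", txt = "xyz", csv = "csv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "ply") {
    header <- c("ply", "format ascii 1.0",
                paste("element vertex", nrow(m)),
                "property double x", "property double y", "property double z",
                "end_header")
    body <- apply(m, 1L, function(r) paste(format(r, digits = 17),
                                           collapse = " "))
    writeLines(c(header, body), path)
  } else if (format == "xyz") {
    utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  } else {
    colnames(m) <- c("x", "y", "z")
    utils::write.csv(m, path, row.names = FALSE)
  }
  invisible(path)
}

#' Normalize a point set to the unit cube
#'
#' Centers the set on its bounding-box midpoint and applies one isotropic
#' scale so it fits `[-1, 1]^3` (touching the boundary along the largest
#' extent). Returns the normalization so results can be mapped back:
#' `normalized = scale * (x + offset)`.
#'
#' @param ps a [point_set()] or matrix with non-degenerate extent.
#' @return list with `points` (normalized, same class as input), `scale`,
#'   `offset`.
#' @export
normalize_to_unit_cube <- function(ps) {
  m <- if (inherits(ps, "point_set")) as_coord_matrix(ps) else as.matrix(ps)
  if (nrow(m) == 0L) stop("empty point set")
  lo <- apply(m, 2L, min)
  hi <- apply(m, 2L, max)
  half <- max(hi - lo) / 2
  if (half <= 0) stop("degenerate extent: all points coincide")
  offset <- -(lo + hi) / 2
  s <- 1 / half
  out <- s * (m + matrix(offset, nrow(m), 3L, byrow = TRUE))
  pts <- if (inherits(ps, "point_set"))
    point_set(out, attr(ps, "label"), attr(ps, "source")) else out
  list(points = pts, scale = s, offset = offset)
}

#' Voxel-grid downsampling
#'
#' Partitions space into cubic voxels of side `grid_size` and replaces the
#' points of each occupied voxel by their centroid.
#'
#' @param ps a [point_set()] or matrix.
#' @param grid_size positive voxel edge length.
#' @return downsampled points, same class as the input.
#' @export
voxel_downsample <- function(ps, grid_size) {
  stopifnot(is.finite(grid_size), grid_size > 0)
  m <- if (inherits(ps, "point_set")) as_coord_matrix(ps) else as.matrix(ps)
  if (nrow(m) == 0L) return(ps)
  key <- paste(floor(m[, 1L] / grid_size), floor(m[, 2L] / grid_size),
               floor(m[, 3L] / grid_size))
  idx <- split(seq_len(nrow(m)), key)
  cent <- t(vapply(idx, function(i) colMeans(m[i, , drop = FALSE]),
                   numeric(3L)))
  cent <- cent[order(vapply(idx, min, integer(1L))), , drop = FALSE]
  if (inherits(ps, "point_set"))
    point_set(cent, attr(ps, "label"), attr(ps, "source"))
  else cent
}
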