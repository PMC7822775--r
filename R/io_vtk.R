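#' Triangle/polygon surface mesh
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param polygons List of integer vectors (1-based vertex indices).
#' @param normals Optional n x 3 per-vertex normals.
#' @return A `surface_mesh`.
#' @export
surface_mesh <- function(vertices, polygons, normals = NULL) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3, all(is.finite(vertices)))
  idx <- unlist(polygons)
  if (length(idx) && (min(idx) < 1 || max(idx) > nrow(vertices)))
    stop("polygon indices out of range")
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    stopifnot(all(dim(normals) == dim(vertices)))
  }
  structure(list(vertices = vertices,
                 polygons = lapply(polygons, as.integer),
                 normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface mesh: %d vertices, %d polygons%s\n",
              nrow(x$vertices), length(x$polygons),
              if (is.null(x$normals)) "" else ", with normals"))
  invisible(x)
}

#' UV-sphere surface mesh
#'
#' Latitude/longitude triangulated sphere, used by the simulator to emit
#' phantom sphere meshes.
#'
#' @param center Length-3 center, mm.
#' @param diameter Sphere diameter, mm.
#' @param n_lat,n_lon Latitude bands / longitude segments.
#' @return A [surface_mesh()] with `2 + (n_lat - 1) * n_lon` vertices.
#' @export
sphere_mesh <- function(center = c(0, 0, 0), diameter = 10,
                        n_lat = 8, n_lon = 12) {
  r <- diameter / 2
  verts <- rbind(c(0, 0, r))
  for (i in seq_len(n_lat - 1)) {
    th <- pi * i / n_lat
    for (j in seq_len(n_lon) - 1) {
      ph <- 2 * pi * j / n_lon
      verts <- rbind(verts, r * c(sin(th) * cos(ph), sin(th) * sin(ph),
                                  cos(th)))
    }
  }
  verts <- rbind(verts, c(0, 0, -r))
  verts <- sweep(verts, 2, -center)
  n <- nrow(verts)
  ring <- function(i) 1 + (i - 1) * n_lon + seq_len(n_lon)
  polys <- list()
  top <- ring(1)
  for (j in seq_len(n_lon))
    polys <- c(polys, list(c(1, top[j], top[j %% n_lon + 1])))
  if (n_lat > 2) for (i in seq_len(n_lat - 2)) {
    a <- ring(i); b <- ring(i + 1)
    for (j in seq_len(n_lon)) {
      jn <- j %% n_lon + 1
      polys <- c(polys, list(c(a[j], b[j], b[jn]), c(a[j], b[jn], a[jn])))
    }
  }
  bot <- ring(n_lat - 1)
  for (j in seq_len(n_lon))
    polys <- c(polys, list(c(n, bot[j %% n_lon + 1], bot[j])))
  surface_mesh(verts, polys)
}

#' Write a mesh as legacy VTK POLYDATA
#'
#' ASCII or binary (big-endian, float32/int32 as the legacy format
#' specifies); readable back with [read_vtk_polydata()].
#'
#' @param mesh A [surface_mesh()].
#' @param path Output file.
#' @param binary Write binary point/polygon payloads.
#' @export
write_vtk_polydata <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  wl <- function(s) writeBin(charToRaw(paste0(s, "\n")), con)
  wl("# vtk DataFile Version 3.0")
  wl("surface mesh")
  wl(if (binary) "BINARY" else "ASCII")
  wl("DATASET POLYDATA")
  nv <- nrow(mesh$vertices)
  wl(sprintf("POINTS %d float", nv))
  pts <- as.numeric(t(mesh$vertices))
  if (binary) {
    writeBin(pts, con, size = 4, endian = "big")
    wl("")
  } else {
    wl(paste(apply(mesh$vertices, 1, function(p)
      paste(format(p, trim = TRUE, scientific = FALSE, digits = 9),
            collapse = " ")), collapse = "\n"))
  }
  conn <- unlist(lapply(mesh$polygons, function(p)
    c(length(p), p - 1L)))
  wl(sprintf("POLYGONS %d %d", length(mesh$polygons), length(conn)))
  if (binary) {
    writeBin(as.integer(conn), con, size = 4, endian = "big")
    wl("")
  } else {
    wl(paste(vapply(mesh$polygons, function(p)
      paste(c(length(p), p - 1L), collapse = " "), ""), collapse = "\n"))
  }
  if (!is.null(mesh$normals)) {
    wl(sprintf("POINT_DATA %d", nv))
    wl("NORMALS normals float")
    if (binary) {
      writeBin(as.numeric(t(mesh$normals)), con, size = 4, endian = "big")
      wl("")
    } else {
      wl(paste(apply(mesh$normals, 1, function(p)
        paste(format(p, trim = TRUE, scientific = FALSE, digits = 9),
              collapse = " ")), collapse = "\n"))
    }
  }
  invisible(path)
}

#' Read a legacy VTK POLYDATA mesh
#'
#' Supports ASCII and binary (big-endian) legacy files containing POINTS and
#' POLYGONS (optional POINT_DATA NORMALS are read too). XML-based VTK files
#' and other dataset types raise a clear unsupported-format error.
#'
#' @param path Path to a `.vtk` legacy POLYDATA file.
#' @return A [surface_mesh()].
#' @export
read_vtk_polydata <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_line <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (!length(b) || b == as.raw(10)) break
      chars <- c(chars, b)
    }
    sub("\r$", "", rawToChar(chars))
  }
  header <- read_line()
  if (grepl("^\\s*<\\?xml", header) || grepl("^\\s*<VTKFile", header))
    stop("XML VTK files are not supported; expected a legacy .vtk file")
  if (!grepl("^# vtk DataFile", header))
    stop("malformed VTK header: ", header)
  read_line()  # title
  fmt <- toupper(trimws(read_line()))
  if (!fmt %in% c("ASCII", "BINARY"))
    stop("unsupported VTK format tag: ", fmt)
  ds <- toupper(trimws(read_line()))
  if (!grepl("^DATASET\\s+POLYDATA", ds))
    stop("unsupported dataset type (need POLYDATA): ", ds)
  binary <- fmt == "BINARY"
  verts <- NULL; polys <- NULL; normals <- NULL
  read_numeric <- function(n) {
    if (binary) readBin(con, "numeric", n, size = 4, endian = "big")
    else {
      out <- numeric(0)
      while (length(out) < n) {
        ln <- read_line()
        if (!nzchar(trimws(ln))) next
        out <- c(out, as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      }
      out
    }
  }
  read_int <- function(n) {
    if (binary) readBin(con, "integer", n, size = 4, endian = "big")
    else as.integer(read_numeric(n))
  }
  repeat {
    ln <- read_line()
    if (!length(ln) || (!nzchar(trimws(ln)) && !isIncomplete(con))) {
      if (seek(con) >= file.size(path)) break
      next
    }
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) next
    key <- toupper(tok[1])
    if (key == "POINTS") {
      nv <- as.integer(tok[2])
      verts <- matrix(read_numeric(3 * nv), nv, 3, byrow = TRUE)
    } else if (key == "POLYGONS") {
      np <- as.integer(tok[2]); sz <- as.integer(tok[3])
      conn <- read_int(sz)
      polys <- vector("list", np)
      k <- 1
      for (i in seq_len(np)) {
        m <- conn[k]
        polys[[i]] <- conn[(k + 1):(k + m)] + 1L
        k <- k + m + 1
      }
    } else if (key == "POINT_DATA") {
      # fall through; next keyword decides
    } else if (key == "NORMALS") {
      normals <- matrix(read_numeric(3 * nrow(verts)), nrow(verts), 3,
                        byrow = TRUE)
    } else if (key %in% c("VERTICES", "LINES", "TRIANGLE_STRIPS")) {
      read_int(as.integer(tok[3]))  # skip payload
    }
    if (seek(con) >= file.size(path)) break
  }
  if (is.null(verts)) stop("no POINTS section found")
  surface_mesh(verts, polys %||% list(), normals)
}
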