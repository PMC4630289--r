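# Readers and writers for the standard triangle-mesh exchange formats.
# PLY (ascii and binary_little_endian) is the canonical annotated format:
# per-vertex scalars are written as a float "quality" property and colors
# as uchar red/green/blue.

#' Read a triangle mesh from disk
#'
#' Supports PLY (ascii and binary little-endian), OFF, OBJ and STL (ascii
#' and binary). Polygonal faces are fan-triangulated. Degenerate
#' (repeated-index or zero-area) and duplicate faces are dropped with a
#' message. STL carries no vertex indexing, so exactly coincident vertices
#' are merged to recover the topology; for the indexed formats duplicate
#' vertices are kept unless `merge_vertices` is set.
#'
#' @param path file to read.
#' @param format one of `"auto"` (by extension), `"ply"`, `"off"`, `"obj"`,
#'   `"stl"`.
#' @param merge_vertices merge duplicate vertices closer than `tol`
#'   (default off).
#' @param tol merge tolerance (length units).
#' @return a [trimesh()]; per-vertex normals are computed (outward) if the
#'   file carries none. PLY quality/color properties are attached as
#'   `vertex_scalars` / `vertex_colors` attributes.
#' @export
read_mesh <- function(path, format = c("auto", "ply", "off", "obj", "stl"),
                      merge_vertices = FALSE, tol = 1e-8) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", off = "off", obj = "obj", stl = "stl",
                     stop("cannot infer mesh format from extension: ", path))
  }
  raw <- switch(format,
                ply = read_ply(path),
                off = read_off(path),
                obj = read_obj(path),
                stl = read_stl(path))
  v <- raw$vertices
  f <- raw$faces
  if (format == "stl" || merge_vertices) {
    merged <- merge_duplicate_vertices(v, f, tol = if (format == "stl" &&
                                                       !merge_vertices) 0 else tol)
    v <- merged$vertices
    f <- merged$faces
  }
  mesh <- trimesh(v, f, clean = TRUE)
  mesh <- drop_zero_area_faces(mesh)
  if (!is.null(raw$normals) && nrow(raw$normals) == n_vertices(mesh)) {
    len <- sqrt(rowSums(raw$normals^2))
    if (all(len > 0)) {
      mesh$normals <- raw$normals / len
      mesh$orientation <- "outward"
    }
  }
  if (is.null(mesh$normals) && n_faces(mesh) > 0L)
    mesh <- compute_vertex_normals(mesh, "outward")
  if (!is.null(raw$scalars)) attr(mesh, "vertex_scalars") <- raw$scalars
  if (!is.null(raw$colors)) attr(mesh, "vertex_colors") <- raw$colors
  mesh
}

drop_zero_area_faces <- function(mesh) {
  if (n_faces(mesh) == 0L) return(mesh)
  a <- face_areas(mesh)
  bad <- a == 0
  if (any(bad)) {
    message("dropping ", sum(bad), " zero-area face(s)")
    mesh$faces <- mesh$faces[!bad, , drop = FALSE]
  }
  mesh
}

merge_duplicate_vertices <- function(v, f, tol = 0) {
  if (tol > 0) vq <- round(v / tol) else vq <- v
  key <- paste(vq[, 1], vq[, 2], vq[, 3], sep = "|")
  first <- match(key, key)
  keep <- sort(unique(first))
  remap <- match(first, keep)
  f[] <- remap[f]
  list(vertices = v[keep, , drop = FALSE], faces = f)
}

fan_triangulate <- function(poly_list) {
  out <- lapply(poly_list, function(p) {
    if (length(p) < 3L) stop("face with fewer than 3 vertices")
    if (length(p) == 3L) return(matrix(p, 1L, 3L))
    cbind(p[1L], p[2:(length(p) - 1L)], p[3:length(p)])
  })
  do.call(rbind, out)
}

## ---- OFF ----------------------------------------------------------------

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L || toupper(lines[1]) != "OFF")
    stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) stop("truncated OFF file: ", path)
  v <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), nv, byrow = TRUE)
  if (ncol(v) < 3) stop("OFF vertex lines need 3 coordinates")
  polys <- lapply(lines[(3 + nv):(2 + nv + nf)], function(ln) {
    x <- scan(text = ln, quiet = TRUE)
    k <- x[1]
    if (length(x) < k + 1) stop("malformed OFF face line: ", ln)
    as.integer(x[2:(k + 1)]) + 1L
  })
  list(vertices = v[, 1:3, drop = FALSE], faces = fan_triangulate(polys))
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", n_vertices(mesh), n_faces(mesh)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}

## ---- OBJ ----------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L) stop("OBJ file has no vertices: ", path)
  v <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE),
              length(vl), byrow = TRUE)[, 1:3, drop = FALSE]
  nv <- nrow(v)
  polys <- lapply(fl, function(ln) {
    toks <- strsplit(trimws(sub("^f ", "", ln)), "[[:space:]]+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, "", 1L))
    ifelse(idx < 0L, nv + idx + 1L, idx) # negative = relative indexing
  })
  list(vertices = v, faces = fan_triangulate(polys))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

## ---- PLY ----------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_bin_scalar <- function(con, type, n = 1L) {
  switch(type,
         char = , int8 = readBin(con, integer(), n, size = 1L, signed = TRUE),
         uchar = , uint8 = readBin(con, integer(), n, size = 1L, signed = FALSE),
         short = , int16 = readBin(con, integer(), n, size = 2L, signed = TRUE,
                                   endian = "little"),
         ushort = , uint16 = readBin(con, integer(), n, size = 2L, signed = FALSE,
                                     endian = "little"),
         int = , int32 = , uint = , uint32 =
           readBin(con, integer(), n, size = 4L, endian = "little"),
         float = , float32 = readBin(con, numeric(), n, size = 4L,
                                     endian = "little"),
         double = , float64 = readBin(con, numeric(), n, size = 8L,
                                      endian = "little"),
         stop("unsupported PLY property type: ", type))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("truncated PLY header: ", path)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 1000L) stop("PLY header too large: ", path)
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("unsupported PLY format (only ascii and binary_little_endian): ",
         fmt_line)
  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (ln in header) {
    toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (toks[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = toks[2], count = as.integer(toks[3]), props = list())
    } else if (toks[1] == "property") {
      if (toks[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = toks[5], list = TRUE, count_type = toks[3],
               value_type = toks[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = toks[3], list = FALSE, type = toks[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur

  read_element_ascii <- function(el, lines) {
    if (any(vapply(el$props, `[[`, TRUE, "list"))) {
      lapply(lines, function(ln) scan(text = ln, quiet = TRUE))
    } else {
      m <- matrix(scan(text = lines, quiet = TRUE), el$count, byrow = TRUE)
      colnames(m) <- vapply(el$props, `[[`, "", "name")
      m
    }
  }
  out <- list()
  if (binary) {
    for (el in elements) {
      if (all(!vapply(el$props, `[[`, TRUE, "list"))) {
        types <- vapply(el$props, `[[`, "", "type")
        m <- matrix(0, el$count, length(types))
        colnames(m) <- vapply(el$props, `[[`, "", "name")
        for (i in seq_len(el$count))
          for (p in seq_along(types))
            m[i, p] <- ply_read_bin_scalar(con, types[p])
        out[[el$name]] <- m
      } else {
        rows <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          row <- numeric(0)
          for (pr in el$props) {
            if (pr$list) {
              k <- ply_read_bin_scalar(con, pr$count_type)
              row <- c(row, k, ply_read_bin_scalar(con, pr$value_type, k))
            } else {
              row <- c(row, ply_read_bin_scalar(con, pr$type))
            }
          }
          rows[[i]] <- row
        }
        out[[el$name]] <- rows
      }
    }
  } else {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    for (el in elements) {
      out[[el$name]] <- read_element_ascii(el, body[(pos + 1L):(pos + el$count)])
      pos <- pos + el$count
    }
  }
  ve <- out[["vertex"]]
  if (is.null(ve)) stop("PLY file has no vertex element: ", path)
  v <- ve[, c("x", "y", "z"), drop = FALSE]
  scalars <- if ("quality" %in% colnames(ve)) ve[, "quality"] else NULL
  colors <- if (all(c("red", "green", "blue") %in% colnames(ve)))
    ve[, c("red", "green", "blue"), drop = FALSE] else NULL
  normals <- if (all(c("nx", "ny", "nz") %in% colnames(ve)))
    ve[, c("nx", "ny", "nz"), drop = FALSE] else NULL
  fe <- out[["face"]]
  faces <- if (is.null(fe) || length(fe) == 0L) {
    matrix(integer(0), 0L, 3L)
  } else {
    fan_triangulate(lapply(fe, function(row) {
      k <- row[1]
      as.integer(row[2:(k + 1)]) + 1L
    }))
  }
  list(vertices = v, faces = faces, scalars = scalars, colors = colors,
       normals = normals)
}

write_ply <- function(mesh, path, vertex_scalars = NULL, vertex_colors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment written by somamesh",
               sprintf("element vertex %d", n_vertices(mesh)),
               "property float x", "property float y", "property float z"),
             con)
  if (!is.null(vertex_scalars)) writeLines("property float quality", con)
  if (!is.null(vertex_colors))
    writeLines(c("property uchar red", "property uchar green",
                 "property uchar blue"), con)
  writeLines(c(sprintf("element face %d", n_faces(mesh)),
               "property list uchar int vertex_indices", "end_header"), con)
  v <- sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
               mesh$vertices[, 3])
  if (!is.null(vertex_scalars))
    v <- paste(v, sprintf("%.9g", vertex_scalars))
  if (!is.null(vertex_colors))
    v <- paste(v, vertex_colors[, 1], vertex_colors[, 2], vertex_colors[, 3])
  writeLines(v, con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}

## ---- STL ----------------------------------------------------------------

read_stl <- function(path) {
  # sniff: ascii STL starts with "solid" and contains "facet" early on
  head_bytes <- readBin(path, "raw", n = 512L)
  head_txt <- rawToChar(head_bytes[head_bytes != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ascii STL: ", path)
  v <- matrix(scan(text = sub("^\\s*vertex\\s+", "", vl), quiet = TRUE),
              length(vl), byrow = TRUE)
  faces <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = faces)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  v <- matrix(0, 3L * n, 3L)
  for (i in seq_len(n)) {
    vals <- readBin(con, numeric(), 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    v[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3L, byrow = TRUE)
  }
  faces <- matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = faces)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fc <- face_cross_products(mesh)
  len <- sqrt(rowSums(fc^2))
  len[len == 0] <- 1
  fn <- fc / len
  writeLines("solid somamesh", con)
  for (i in seq_len(n_faces(mesh))) {
    writeLines(sprintf("facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2],
                       fn[i, 3]), con)
    writeLines("  outer loop", con)
    for (c in 1:3) {
      vtx <- mesh$vertices[mesh$faces[i, c], ]
      writeLines(sprintf("    vertex %.9g %.9g %.9g", vtx[1], vtx[2], vtx[3]),
                 con)
    }
    writeLines(c("  endloop", "endfacet"), con)
  }
  writeLines("endsolid somamesh", con)
}

#' Write a triangle mesh to disk
#'
#' PLY (ascii) supports optional per-vertex scalar annotation (as a float
#' `quality` property) and RGB colors (uchar); requesting annotations in
#' any other format is an error.
#'
#' @param mesh a [trimesh()] with at least one face.
#' @param path output file.
#' @param format `"auto"` (by extension), `"ply"`, `"off"`, `"obj"` or
#'   `"stl"`.
#' @param vertex_scalars optional numeric vector, one value per vertex.
#' @param vertex_colors optional integer matrix (`n x 3`, values 0-255).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "off", "obj", "stl"),
                       vertex_scalars = NULL, vertex_colors = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", off = "off", obj = "obj", stl = "stl",
                     stop("cannot infer mesh format from extension: ", path))
  }
  if (n_faces(mesh) == 0L) stop("refusing to write a mesh with no faces")
  if (!is.null(vertex_scalars) && length(vertex_scalars) != n_vertices(mesh))
    stop("vertex_scalars must have one value per vertex")
  if (!is.null(vertex_colors)) {
    vertex_colors <- as.matrix(vertex_colors)
    if (nrow(vertex_colors) != n_vertices(mesh) || ncol(vertex_colors) != 3L)
      stop("vertex_colors must be an n x 3 matrix")
  }
  if (format != "ply" && (!is.null(vertex_scalars) || !is.null(vertex_colors)))
    stop("per-vertex scalars/colors are only supported for PLY output")
  switch(format,
         ply = write_ply(mesh, path, vertex_scalars, vertex_colors),
         off = write_off(mesh, path),
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path))
  invisible(path)
}
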