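#' Read a triangle mesh from file
#'
#' Supports PLY (ASCII and binary little-endian), OBJ (ASCII) and STL
#' (ASCII). Units are taken to be millimetres. After reading, face
#' orientation is made consistent and outward (positive signed volume) when
#' the mesh is closed.
#'
#' @param path Path to a `.ply`, `.obj` or `.stl` file.
#' @param orient Enforce outward orientation for closed meshes (default TRUE).
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, orient = TRUE) {
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl_ascii(path),
    stop("unrecognized mesh extension '.", ext, "' (expected .ply/.stl/.obj)")
  )
  if (nrow(mesh$vertices) < 3L || nrow(mesh$faces) < 1L)
    stop("degenerate mesh file (", nrow(mesh$vertices), " vertices, ",
         nrow(mesh$faces), " faces): ", path)
  if (orient && is_watertight(mesh)) mesh <- orient_mesh(mesh)
  mesh
}

#' Write a triangle mesh to file
#'
#' Format is chosen from the extension: binary little-endian PLY (default
#' interchange format), ASCII PLY (`binary = FALSE`), OBJ, or ASCII STL.
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path ending in `.ply`, `.obj` or `.stl`.
#' @param binary For PLY, write binary little-endian (default TRUE).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path, binary = binary),
    obj = write_obj(mesh, path),
    stl = write_stl_ascii(mesh, path),
    stop("unrecognized mesh extension '.", ext, "' (expected .ply/.stl/.obj)")
  )
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; nv <- NA_integer_; nf <- NA_integer_
  in_vertex <- FALSE
  vertex_props <- character(0); vertex_types <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header: ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (tok[2] == "vertex") nv <- as.integer(tok[3])
      if (tok[2] == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      vertex_props <- c(vertex_props, tok[length(tok)])
      vertex_types <- c(vertex_types, tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (is.na(nv) || is.na(nf)) stop("PLY header lacks vertex/face counts: ", path)
  if (!all(c("x", "y", "z") %in% vertex_props))
    stop("PLY vertex element lacks x/y/z properties: ", path)
  np <- length(vertex_props)
  xyz_cols <- match(c("x", "y", "z"), vertex_props)
  if (identical(fmt, "ascii")) {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    if (length(rest) < nv + nf) stop("truncated PLY body: ", path)
    vdat <- do.call(rbind, lapply(rest[seq_len(nv)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]][seq_len(np)])))
    fdat <- lapply(rest[nv + seq_len(nf)], function(s) {
      t <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
      if (t[1] != 3L) stop("PLY contains a non-triangular face (", t[1], " vertices)")
      t[2:4] + 1L
    })
    faces <- do.call(rbind, fdat)
    verts <- vdat[, xyz_cols, drop = FALSE]
  } else if (identical(fmt, "binary_little_endian")) {
    if (length(unique(vertex_types)) != 1L ||
        !unique(vertex_types) %in% c("float", "float32", "double", "float64"))
      stop("binary PLY reader supports uniform float/double vertex properties only")
    sz <- if (unique(vertex_types) %in% c("double", "float64")) 8L else 4L
    vdat <- readBin(con, "numeric", n = nv * np, size = sz, endian = "little")
    verts <- matrix(vdat, ncol = np, byrow = TRUE)[, xyz_cols, drop = FALSE]
    faces <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
      if (cnt != 3L) stop("PLY contains a non-triangular face (", cnt, " vertices)")
      faces[i, ] <- readBin(con, "integer", n = 3L, size = 4L, endian = "little") + 1L
    }
  } else stop("unsupported PLY format '", fmt, "' (ascii or binary_little_endian)")
  triangle_mesh(verts, faces, validate = FALSE)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8L, endian = "little")
    f0 <- t(mesh$faces) - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[, i]), con, size = 4L, endian = "little")
    }
  } else {
    vtxt <- apply(mesh$vertices, 1, function(p) paste(format(p, digits = 17, trim = TRUE), collapse = " "))
    ftxt <- apply(mesh$faces - 1L, 1, function(f) paste(c(3L, f), collapse = " "))
    writeLines(c(hdr, vtxt, ftxt), path)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(vlines, function(s)
    as.numeric(strsplit(trimws(substring(s, 3)), "\\s+")[[1]][1:3])))
  faces <- do.call(rbind, lapply(flines, function(s) {
    tok <- strsplit(trimws(substring(s, 3)), "\\s+")[[1]]
    if (length(tok) != 3L) stop("OBJ contains a non-triangular face")
    as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1L))
  }))
  if (is.null(verts) || is.null(faces)) stop("OBJ file has no vertices or faces: ", path)
  triangle_mesh(verts, faces, validate = FALSE)
}

write_obj <- function(mesh, path) {
  vtxt <- apply(mesh$vertices, 1, function(p)
    paste("v", paste(format(p, digits = 17, trim = TRUE), collapse = " ")))
  ftxt <- apply(mesh$faces, 1, function(f) paste("f", f[1], f[2], f[3]))
  writeLines(c(vtxt, ftxt), path)
  invisible(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1]))
    stop("only ASCII STL is supported (file does not start with 'solid'): ", path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) stop("malformed STL (vertex count not a multiple of 3)")
  pts <- do.call(rbind, lapply(vl, function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][2:4])))
  # merge coincident vertices exactly
  key <- apply(pts, 1, function(p) paste(format(p, digits = 17), collapse = ","))
  uidx <- !duplicated(key)
  verts <- pts[uidx, , drop = FALSE]
  map <- match(key, key[uidx])
  faces <- matrix(map, ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces, validate = FALSE)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]; p3 <- v[f[, 3], , drop = FALSE]
  n <- cross3_rows(p2 - p1, p3 - p1)
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  fmt <- function(p) paste(format(p, digits = 17, trim = TRUE), collapse = " ")
  out <- character(2 + 7 * nrow(f))
  out[1] <- "solid mesh"
  k <- 2L
  for (i in seq_len(nrow(f))) {
    out[k:(k + 6L)] <- c(paste(" facet normal", fmt(n[i, ])),
                         "  outer loop",
                         paste("   vertex", fmt(p1[i, ])),
                         paste("   vertex", fmt(p2[i, ])),
                         paste("   vertex", fmt(p3[i, ])),
                         "  endloop",
                         " endfacet")
    k <- k + 7L
  }
  out[k] <- "endsolid mesh"
  writeLines(out, path)
  invisible(path)
}
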