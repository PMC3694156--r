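# Mesh file formats: STL (ascii and binary read, ascii write), OFF, PLY
# (ascii), legacy-VTK unstructured grids with integer "region" cell data,
# and landmark CSV. Round trips preserve coordinates to float precision
# and labels exactly.

#' Read a triangle surface (STL, OFF or PLY)
#'
#' @param path file path; format from the extension (`.stl`, `.off`,
#'   `.ply`). Both ascii and binary STL are detected.
#' @return list with `nodes` (n x 3) and `tri` (k x 3); face normals are
#'   recomputed from the geometry on read.
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) {
    stop_craniofem(sprintf("file not found: %s", path), "craniofem_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         off = read_off(path),
         ply = read_ply(path),
         stop_craniofem(sprintf("unsupported surface format '.%s'", ext),
                        "craniofem_io_error"))
}

#' Write a triangle surface (STL, OFF or PLY)
#'
#' @param surface list with `nodes` and `tri`.
#' @param path output path; format from the extension.
#' @return the path, invisibly.
#' @export
write_surface <- function(surface, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(surface, path),
         off = write_off(surface, path),
         ply = write_ply(surface, path),
         stop_craniofem(sprintf("unsupported surface format '.%s'", ext),
                        "craniofem_io_error"))
  invisible(path)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  n_bin <- tryCatch(readBin(con, "integer", 1, size = 4, endian = "little"),
                    error = function(e) NA_integer_)
  close(con)
  size <- file.info(path)$size
  is_binary <- length(n_bin) == 1L && !is.na(n_bin) &&
    size == 84 + 50 * as.numeric(n_bin)
  if (is_binary) read_stl_binary(path, n_bin) else read_stl_ascii(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (!length(lines) || !grepl("^\\s*solid", lines[1])) {
    stop_craniofem(sprintf("%s: not an ascii STL (line 1)", path), "craniofem_io_error")
  }
  if (length(vl) %% 3 != 0 || !length(vl)) {
    stop_craniofem(sprintf("%s: truncated STL (%d vertex lines at line %d)",
                           path, length(vl), utils::tail(vl, 1) %||% 1),
                   "craniofem_io_error")
  }
  xyz <- t(vapply(strsplit(trimws(lines[vl]), "\\s+"),
                  function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(xyz)) {
    stop_craniofem(sprintf("%s: malformed vertex near line %d", path,
                           vl[which(is.na(rowSums(xyz)))[1]]), "craniofem_io_error")
  }
  dedupe_surface(xyz)
}

read_stl_binary <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84)
  xyz <- matrix(NA_real_, 3 * n, 3)
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12) {
      stop_craniofem(sprintf("%s: truncated binary STL at facet %d (byte %d)",
                             path, i, 84 + (i - 1) * 50), "craniofem_io_error")
    }
    xyz[3 * i - 2:0, ] <- matrix(rec[4:12], 3, byrow = TRUE)
    readBin(con, "raw", 2)
  }
  dedupe_surface(xyz)
}

# collapse repeated vertices (exact float match) into an indexed surface
dedupe_surface <- function(xyz) {
  key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
  idx <- match(key, unique(key))
  nodes <- xyz[!duplicated(key), , drop = FALSE]
  list(nodes = nodes, tri = matrix(idx, ncol = 3, byrow = TRUE))
}

write_stl <- function(surface, path) {
  nd <- surface$nodes; tri <- surface$tri
  nrm <- triangle_normals(nd, tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid craniofem", con)
  for (i in seq_len(nrow(tri))) {
    writeLines(c(sprintf("  facet normal %s %s %s", num_fmt(nrm[i, 1]),
                         num_fmt(nrm[i, 2]), num_fmt(nrm[i, 3])),
                 "    outer loop",
                 sprintf("      vertex %s %s %s",
                         num_fmt(nd[tri[i, ], 1], 17), num_fmt(nd[tri[i, ], 2], 17),
                         num_fmt(nd[tri[i, ], 3], 17)),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid craniofem", con)
}

read_off <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (!length(toks) || toks[1] != "OFF") {
    stop_craniofem(sprintf("%s: missing OFF header", path), "craniofem_io_error")
  }
  nv <- as.integer(toks[2]); nf <- as.integer(toks[3])
  off <- 5
  if (length(toks) < off - 1 + 3 * nv) {
    stop_craniofem(sprintf("%s: truncated OFF vertex block", path), "craniofem_io_error")
  }
  nodes <- matrix(as.numeric(toks[off:(off - 1 + 3 * nv)]), nv, 3, byrow = TRUE)
  p <- off + 3 * nv
  tri <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    k <- as.integer(toks[p])
    if (is.na(k) || k != 3) {
      stop_craniofem(sprintf("%s: face %d is not a triangle", path, i),
                     "craniofem_io_error")
    }
    tri[i, ] <- as.integer(toks[(p + 1):(p + 3)]) + 1L
    p <- p + 4
  }
  list(nodes = nodes, tri = tri)
}

write_off <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(surface$nodes), nrow(surface$tri)), con)
  writeLines(apply(surface$nodes, 1, function(v)
    paste(num_fmt(v, 17), collapse = " ")), con)
  writeLines(apply(surface$tri - 1L, 1, function(f)
    paste(c(3L, f), collapse = " ")), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "ply") {
    stop_craniofem(sprintf("%s: missing ply header", path), "craniofem_io_error")
  }
  endh <- match("end_header", lines)
  if (is.na(endh)) stop_craniofem(sprintf("%s: unterminated ply header", path),
                                  "craniofem_io_error")
  if (!any(grepl("^format ascii", lines[1:endh]))) {
    stop_craniofem(sprintf("%s: only ascii PLY supported", path), "craniofem_io_error")
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   lines[1:endh], value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 lines[1:endh], value = TRUE)[1]))
  vb <- lines[(endh + 1):(endh + nv)]
  nodes <- t(vapply(strsplit(trimws(vb), "\\s+"),
                    function(p) as.numeric(p[1:3]), numeric(3)))
  fb <- lines[(endh + nv + 1):(endh + nv + nf)]
  tri <- t(vapply(strsplit(trimws(fb), "\\s+"), function(p) {
    if (as.integer(p[1]) != 3) stop_craniofem("non-triangle PLY face",
                                              "craniofem_io_error")
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  list(nodes = nodes, tri = tri)
}

write_ply <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(surface$nodes)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(surface$tri)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(surface$nodes, 1, function(v)
    paste(num_fmt(v, 17), collapse = " ")), con)
  writeLines(apply(surface$tri - 1L, 1, function(f)
    paste(c(3L, f), collapse = " ")), con)
}

#' Write a tet mesh as a legacy-VTK unstructured grid
#'
#' Cell data `region` is written as integers (0 = bone, 1 = dentine,
#' 2 = enamel); optional extra per-cell scalars (e.g. von Mises stress)
#' and per-point vectors (e.g. displacement) may be attached.
#'
#' @param mesh a [tet_mesh()].
#' @param path output `.vtk` path.
#' @param cell_scalars optional named list of numeric per-cell vectors.
#' @param point_vectors optional named list of `n x 3` matrices.
#' @return the path, invisibly.
#' @export
write_volume <- function(mesh, path, cell_scalars = NULL, point_vectors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "craniofem unstructured grid",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(apply(mesh$nodes, 1, function(v) paste(num_fmt(v, 17), collapse = " ")), con)
  m <- nrow(mesh$tets)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(apply(mesh$tets - 1L, 1, function(t) paste(c(4L, t), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  region_code <- c(bone = 0L, dentine = 1L, enamel = 2L)[mesh$region]
  region_code[is.na(region_code)] <- 0L
  writeLines(c(sprintf("CELL_DATA %d", m), "SCALARS region int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(region_code), con)
  for (nm in names(cell_scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(num_fmt(cell_scalars[[nm]], 17), con)
  }
  if (length(point_vectors)) {
    writeLines(sprintf("POINT_DATA %d", nrow(mesh$nodes)), con)
    for (nm in names(point_vectors)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(apply(point_vectors[[nm]], 1, function(v)
        paste(num_fmt(v, 17), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a legacy-VTK unstructured grid of tet4 cells
#'
#' @param path `.vtk` path (ASCII legacy format).
#' @return a [tet_mesh()]; a missing `region` cell array defaults to
#'   `"bone"` with a warning; non-tet cells are rejected with their index.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop_craniofem(sprintf("file not found: %s", path), "craniofem_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  pts_i <- grep("^POINTS", lines)[1]
  if (is.na(pts_i)) stop_craniofem(sprintf("%s: no POINTS block", path),
                                   "craniofem_io_error")
  np <- as.integer(strsplit(lines[pts_i], "\\s+")[[1]][2])
  coords <- scan(text = lines[(pts_i + 1):length(lines)], n = 3 * np, quiet = TRUE)
  nodes <- matrix(coords, np, 3, byrow = TRUE)
  cel_i <- grep("^CELLS", lines)[1]
  hdr <- strsplit(lines[cel_i], "\\s+")[[1]]
  m <- as.integer(hdr[2])
  ints <- scan(text = lines[(cel_i + 1):length(lines)],
               n = as.integer(hdr[3]), quiet = TRUE)
  tets <- matrix(0L, m, 4)
  p <- 1
  for (i in seq_len(m)) {
    k <- ints[p]
    if (k != 4) stop_craniofem(sprintf("%s: cell %d has %d vertices (tet4 required)",
                                       path, i, k), "craniofem_io_error")
    tets[i, ] <- ints[(p + 1):(p + 4)] + 1L
    p <- p + 5
  }
  ct_i <- grep("^CELL_TYPES", lines)[1]
  types <- scan(text = lines[(ct_i + 1):length(lines)], n = m, quiet = TRUE)
  if (any(types != 10)) {
    stop_craniofem(sprintf("%s: cell %d has VTK type %d (10 = tetra required)",
                           path, which(types != 10)[1], types[types != 10][1]),
                   "craniofem_io_error")
  }
  reg_i <- grep("^SCALARS region", lines)[1]
  if (is.na(reg_i)) {
    warning(sprintf("%s: no region cell data; defaulting all cells to bone", path))
    region <- rep("bone", m)
  } else {
    codes <- scan(text = lines[(reg_i + 2):length(lines)], n = m, quiet = TRUE)
    region <- c("bone", "dentine", "enamel")[codes + 1]
  }
  tet_mesh(nodes, tets, region = region)
}

#' Write / read landmarks as CSV (name, x, y, z in mm)
#'
#' @param landmarks named matrix `k x 3`.
#' @param path CSV path.
#' @return the path (write) or the named matrix (read).
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(name = rownames(landmarks),
                   x = num_fmt(landmarks[, 1], 17),
                   y = num_fmt(landmarks[, 2], 17),
                   z = num_fmt(landmarks[, 3], 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$name
  m
}
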