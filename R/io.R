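# File formats: STL (ASCII and binary) and PLY (ASCII and
# binary_little_endian) for meshes; CSV with a '#'-comment convention
# header for poses, contours and tables; YAML for configuration.

#' Write a mesh to STL or PLY
#'
#' Format is chosen by extension (`.stl` / `.ply`).
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param binary write the binary flavor (default ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = .write_stl(mesh, path, binary),
         ply = .write_ply(mesh, path, binary),
         stop("write_mesh: unsupported format '", ext, "'"))
  invisible(path)
}

#' Read a mesh from STL or PLY
#'
#' Accepts ASCII and binary STL, and ASCII / binary_little_endian PLY.
#' Truncated or malformed files raise a parse error rather than returning
#' a partial mesh.  STL files (whose facets do not share vertices) are
#' welded on read.
#'
#' @param path input path.
#' @param frame_label coordinate-frame label for the result.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, frame_label = "component") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = .read_stl(path, frame_label),
         ply = .read_ply(path, frame_label),
         stop("read_mesh: unsupported format '", ext, "'"))
}

.write_stl <- function(mesh, path, binary) {
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    tri <- matrix(0, nrow(f), 12)
    tri[, 1:3] <- n
    tri[, 4:6] <- v[f[, 1], ]
    tri[, 7:9] <- v[f[, 2], ]
    tri[, 10:12] <- v[f[, 3], ]
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
}

.read_stl <- function(path, frame_label) {
  # sniff: binary STL has facet count consistent with file size
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", 84)
  close(con)
  is_binary <- FALSE
  if (length(head) == 84) {
    cnt <- readBin(head[81:84], "integer", 1, size = 4, endian = "little")
    if (!is.na(cnt) && sz == 84 + 50 * cnt) is_binary <- TRUE
  }
  if (!is_binary) {
    # an ASCII file starts with 'solid' and contains no NUL bytes
    is_ascii <- length(head) >= 5 &&
      identical(tryCatch(rawToChar(head[1:5]), error = function(e) ""),
                "solid") && !any(head == as.raw(0))
    if (!is_ascii)
      stop("read_mesh: truncated binary STL (size inconsistent with facet count)")
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    cnt <- readBin(con, "integer", 1, size = 4, endian = "little")
    tri <- matrix(NA_real_, cnt, 9)
    for (i in seq_len(cnt)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      attr_b <- readBin(con, "raw", 2)
      if (length(vals) < 12 || length(attr_b) < 2)
        stop("read_mesh: truncated binary STL")
      tri[i, ] <- vals[4:12]
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vl) || length(vl) %% 3 != 0)
      stop("read_mesh: malformed ASCII STL (vertex count not multiple of 3)")
    if (!length(grep("^\\s*endsolid", lines)))
      stop("read_mesh: truncated ASCII STL (missing endsolid)")
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4]))
    if (any(vapply(nums, function(x) any(is.na(x)), logical(1))))
      stop("read_mesh: malformed vertex line in ASCII STL")
    vm <- t(vapply(nums, identity, numeric(3)))       # one vertex per row
    tri <- matrix(as.vector(t(vm)), ncol = 9, byrow = TRUE)
  }
  nf <- nrow(tri)
  V <- matrix(0, 3 * nf, 3)
  V[seq(1, 3 * nf, 3), ] <- tri[, 1:3]
  V[seq(2, 3 * nf, 3), ] <- tri[, 4:6]
  V[seq(3, 3 * nf, 3), ] <- tri[, 7:9]
  F <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  w <- weld_mesh(V, F, tol = 1e-6)
  surface_mesh(w$vertices, w$faces, frame_label = frame_label)
}

.write_ply <- function(mesh, path, binary) {
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else
             "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(v)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L,
                       f[, 3] - 1L), con)
  }
}

.read_ply <- function(path, frame_label) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln)) stop("read_mesh: truncated PLY header")
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
    if (length(hdr) > 100) stop("read_mesh: malformed PLY header")
  }
  fmt <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt)) stop("read_mesh: PLY missing format line")
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", hdr, value = TRUE)))
  if (!length(nv) || !length(nf) || is.na(nv) || is.na(nf))
    stop("read_mesh: PLY missing element counts")
  vprops <- grep("^property (double|float)", hdr, value = TRUE)
  dbl <- grepl("double", vprops[1])
  if (binary) {
    V <- matrix(readBin(con, "numeric", nv * 3, size = if (dbl) 8 else 4,
                        endian = "little"), ncol = 3, byrow = TRUE)
    F <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (!length(cnt) || cnt != 3L)
        stop("read_mesh: PLY face is not a triangle or file truncated")
      F[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
    if (nrow(V) < nv) stop("read_mesh: truncated PLY")
  } else {
    txt <- readLines(con, warn = FALSE)
    if (length(txt) < nv + nf) stop("read_mesh: truncated PLY body")
    V <- do.call(rbind, lapply(strsplit(trimws(txt[seq_len(nv)]), "\\s+"),
                               function(p) as.numeric(p[1:3])))
    Fl <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    if (any(vapply(Fl, function(p) p[1] != "3", logical(1))))
      stop("read_mesh: PLY face is not a triangle")
    F <- do.call(rbind, lapply(Fl, function(p)
      as.integer(p[2:4]) + 1L))
  }
  if (any(is.na(V)) || any(is.na(F)))
    stop("read_mesh: malformed PLY values")
  surface_mesh(V, F, frame_label = frame_label)
}

.convention_header <- c(
  "# coordinate convention: right knee, x anterior(+), y medial(+), z proximal(+); mm and degrees",
  "# pose parameters: intrinsic Z-X-Y Euler angles (rx, ry, rz) in degrees; translations (tx, ty, tz) in mm")

#' Write / read a trajectory pose table as CSV
#'
#' Columns: `phase`, then six pose parameters per component
#' (`fem_rx ... fem_tz`, `tib_rx ... tib_tz`); the coordinate convention
#' is recorded in `#` comment lines.
#'
#' @param trajectory a `motion_trajectory` (write) / path (read).
#' @param path output path.
#' @return `path` invisibly (write); a data frame with attribute
#'   `activity` (read).
#' @export
write_poses <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.convention_header,
               sprintf("# activity: %s", trajectory$activity)), con)
  utils::write.csv(cbind(phase = trajectory$phase, trajectory$poses),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_poses
#' @param check.names passed to `read.csv`.
#' @export
read_poses <- function(path, check.names = TRUE) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  df <- utils::read.csv(text = paste(lines[body], collapse = "\n"),
                        check.names = check.names)
  if (!"phase" %in% names(df))
    stop("read_poses: missing 'phase' column")
  act <- sub("# activity: ", "", grep("^# activity:", meta, value = TRUE))
  attr(df, "activity") <- if (length(act)) act else NA_character_
  df
}

#' Write / read silhouette contours as CSV
#'
#' Columns `view_id`, `u_mm`, `v_mm`.
#'
#' @param contours list of [contour_2d()] (write) / path (read).
#' @param path file path.
#' @return `path` invisibly (write); list of [contour_2d()] (read).
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "contour_2d")) contours <- list(contours)
  df <- do.call(rbind, lapply(contours, function(ct)
    data.frame(view_id = ct$view_id, u_mm = ct$points[, 1],
               v_mm = ct$points[, 2])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# silhouette contour points, detector-plane mm", con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- grep("^#", lines, invert = TRUE)
  df <- utils::read.csv(text = paste(lines[body], collapse = "\n"))
  if (!all(c("view_id", "u_mm", "v_mm") %in% names(df)))
    stop("read_contours: missing columns")
  lapply(split(df, df$view_id), function(g)
    contour_2d(cbind(g$u_mm, g$v_mm), view_id = as.character(g$view_id[1])))
}

#' Write / read a generic results table as CSV with a units header
#'
#' @param df data frame (write) / path (read).
#' @param path file path.
#' @param units character vector of `# key: value` style header comments.
#' @return `path` invisibly (write); data frame (read).
#' @export
write_table <- function(df, path, units = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.convention_header, paste0("# ", units)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- grep("^#", lines, invert = TRUE)
  utils::read.csv(text = paste(lines[body], collapse = "\n"))
}
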