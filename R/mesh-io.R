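#' Read a triangle-mesh surface model
#'
#' Reads PLY (ASCII or binary little-endian, the canonical interchange
#' format; an optional integer vertex property `label` carries tissue
#' labels), ASCII/binary STL, or Wavefront OBJ. STL and OBJ are read-only
#' formats without labels. Coordinates are taken as millimetres verbatim —
#' no unit auto-detection.
#'
#' @param path file path.
#' @param format `"ply"`, `"stl"` or `"obj"`; inferred from the extension by
#'   default.
#' @param frame frame name recorded on the mesh.
#' @return An `osteo_mesh`.
#' @seealso [write_mesh()]
#' @export
load_mesh <- function(path, format = c("auto", "ply", "stl", "obj"),
                      frame = "unspecified") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "stl", "obj")) {
      abort(sprintf("Cannot infer mesh format from extension '.%s'.", format))
    }
  }
  if (!file.exists(path)) abort(sprintf("Mesh file not found: %s", path))
  out <- switch(format,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path)
  )
  triangle_mesh(out$vertices, out$faces, labels = out$labels, frame = frame)
}

#' Write a mesh to PLY
#'
#' ASCII PLY with x/y/z vertex properties; per-vertex tissue labels (if
#' present) are written as an integer `label` property with the code-to-name
#' mapping stored in header comments, so a round trip preserves them.
#' Optional per-vertex colours (for topographic maps) are written as
#' `red`/`green`/`blue` uchar properties.
#'
#' @param mesh an `osteo_mesh`.
#' @param path output path.
#' @param colors optional n x 3 integer matrix of 0-255 RGB per vertex.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, colors = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c("ply", "format ascii 1.0", "comment written by osteorms")
  lab_codes <- NULL
  if (!is.null(mesh$labels)) {
    levs <- sort(unique(mesh$labels))
    lab_codes <- match(mesh$labels, levs) - 1L
    header <- c(header,
                sprintf("comment label_map %d %s", seq_along(levs) - 1L, levs))
  }
  header <- c(header, sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z")
  if (!is.null(lab_codes)) header <- c(header, "property int label")
  if (!is.null(colors)) {
    header <- c(header, "property uchar red", "property uchar green",
                "property uchar blue")
  }
  header <- c(header, sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  writeLines(header, con)
  vtxt <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  if (!is.null(lab_codes)) vtxt <- paste(vtxt, lab_codes)
  if (!is.null(colors)) {
    vtxt <- paste(vtxt, colors[, 1], colors[, 2], colors[, 3])
  }
  writeLines(vtxt, con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  switch(type,
    char = , int8 = readBin(con, integer(), 1, size = 1, signed = TRUE),
    uchar = , uint8 = readBin(con, integer(), 1, size = 1, signed = FALSE),
    short = , int16 = readBin(con, integer(), 1, size = 2, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(con, integer(), 1, size = 2, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(con, integer(), 1, size = 4, endian = "little"),
    float = , float32 = readBin(con, double(), 1, size = 4, endian = "little"),
    double = , float64 = readBin(con, double(), 1, size = 8, endian = "little"),
    abort(sprintf("Unsupported PLY property type '%s'.", type))
  )
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) abort("Malformed PLY: header not terminated.")
    lines <- c(lines, ln)
    if (ln == "end_header") break
  }
  if (lines[1] != "ply") abort("Not a PLY file.")
  fmt_line <- grep("^format ", lines, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line)) {
    abort("Only ASCII and binary_little_endian PLY are supported.")
  }
  label_map <- NULL
  for (ln in grep("^comment label_map ", lines, value = TRUE)) {
    parts <- strsplit(sub("^comment label_map ", "", ln), " ")[[1]]
    label_map <- c(label_map, setNames(paste(parts[-1], collapse = " "), parts[1]))
  }
  # parse elements
  elements <- list()
  cur <- NULL
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face)) {
    abort("PLY file lacks vertex or face elements.")
  }

  if (binary) {
    read_element <- function(el) {
      rows <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        rec <- list()
        for (p in el$props) {
          if (p$list) {
            n <- ply_read_scalar(con, p$count_type)
            rec[[p$name]] <- vapply(seq_len(n), function(j)
              ply_read_scalar(con, p$type), numeric(1))
          } else {
            rec[[p$name]] <- ply_read_scalar(con, p$type)
          }
        }
        rows[[i]] <- rec
      }
      rows
    }
    vrows <- read_element(elements$vertex)
    frows <- read_element(elements$face)
    vertices <- t(vapply(vrows, function(r) c(r$x, r$y, r$z), numeric(3)))
    labels <- if (!is.null(vrows[[1]]$label)) {
      vapply(vrows, function(r) as.character(r$label), character(1))
    } else NULL
    face_list <- lapply(frows, function(r)
      r$vertex_indices %||% r$vertex_index)
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    nv <- elements$vertex$count
    nf <- elements$face$count
    if (length(body) < nv + nf) abort("PLY body shorter than declared element counts.")
    pnames <- vapply(elements$vertex$props, `[[`, "", "name")
    vdat <- utils::read.table(text = body[seq_len(nv)], col.names = pnames,
                              colClasses = "numeric")
    vertices <- as.matrix(vdat[, c("x", "y", "z")])
    labels <- if ("label" %in% pnames) as.character(vdat$label) else NULL
    face_list <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                        function(tok) as.integer(tok[-1][seq_len(as.integer(tok[1]))]))
  }
  if (any(vapply(face_list, length, 1L) != 3L)) {
    abort("Only pure triangle meshes are supported (found a non-triangle face).")
  }
  faces <- do.call(rbind, face_list) + 1L
  if (!is.null(labels) && !is.null(label_map)) {
    labels <- unname(label_map[labels])
  }
  list(vertices = vertices, faces = faces, labels = labels)
}

read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 84)
  is_ascii <- identical(rawToChar(hdr[1:5]), "solid")
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (!length(vl)) is_ascii <- FALSE  # "solid"-prefixed binary file
    else {
      coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok)
        as.numeric(tok[2:4])))
      nv <- nrow(coords)
      if (nv %% 3 != 0) abort("Malformed ASCII STL: vertex count not a multiple of 3.")
      out <- clean_mesh_arrays(coords, matrix(seq_len(nv), ncol = 3, byrow = TRUE))
      return(list(vertices = out$vertices, faces = out$faces, labels = NULL))
    }
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, integer(), 1, size = 4, endian = "little")
  rec <- readBin(con, "raw", n = ntri * 50)
  if (length(rec) < ntri * 50) abort("Truncated binary STL.")
  m <- matrix(rec, nrow = 50)
  floats <- readBin(as.vector(m[1:48, ]), double(), n = 12 * ntri, size = 4,
                    endian = "little")
  fm <- matrix(floats, nrow = 12)
  coords <- matrix(as.vector(fm[4:12, ]), ncol = 3, byrow = TRUE)
  out <- clean_mesh_arrays(coords, matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE))
  list(vertices = out$vertices, faces = out$faces, labels = NULL)
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (!length(vl) || !length(fl)) abort("OBJ file has no vertices or faces.")
  vertices <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok)
    as.numeric(tok[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(tok) {
    idx <- as.integer(sub("/.*$", "", tok[-1]))
    if (length(idx) != 3L) abort("Only triangle OBJ faces are supported.")
    idx
  }))
  neg <- faces < 0
  if (any(neg)) faces[neg] <- nrow(vertices) + 1L + faces[neg]
  list(vertices = vertices, faces = faces, labels = NULL)
}
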