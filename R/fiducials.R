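#' Fiducial / landmark point sets
#'
#' An ordered, named set of 3D points (mm) in a named frame: the bone-screw
#' fiducials used to initialise 3D-US-to-CT registration, or the anatomical
#' landmarks used to initialise SLS-to-CT registration. At least three
#' non-collinear points with unique names are required (fewer, or a
#' degenerate configuration, cannot pin down a rigid pose).
#'
#' @param points an n x 3 numeric matrix or a data frame with columns
#'   `name`, `x`, `y`, `z`.
#' @param names character vector of point names (ignored when `points` is a
#'   data frame carrying them).
#' @param frame coordinate-frame name.
#' @return An object of class `fiducial_set`: a tibble with columns `name`,
#'   `x`, `y`, `z` plus a `frame` attribute.
#' @export
fiducial_set <- function(points, names = NULL, frame = "unspecified") {
  if (is.data.frame(points)) {
    stopifnot(all(c("name", "x", "y", "z") %in% base::names(points)))
    df <- tibble(name = as.character(points$name),
                 x = as.numeric(points$x), y = as.numeric(points$y),
                 z = as.numeric(points$z))
  } else {
    p <- as.matrix(points)
    if (ncol(p) != 3L) abort("`points` must be n x 3.")
    names <- names %||% paste0("F", seq_len(nrow(p)))
    df <- tibble(name = as.character(names), x = p[, 1], y = p[, 2], z = p[, 3])
  }
  if (nrow(df) < 3L) abort("A fiducial set needs at least 3 points.")
  if (anyDuplicated(df$name)) abort("Fiducial names must be unique.")
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    abort("Fiducial coordinates must be finite.")
  }
  m <- as.matrix(df[, c("x", "y", "z")])
  sv <- svd(scale(m, center = TRUE, scale = FALSE))$d
  if (sv[2] <= 1e-9) abort("Fiducial points are collinear; cannot define a rigid pose.")
  structure(df, frame = frame, class = c("fiducial_set", class(df)))
}

fid_matrix <- function(fs) unname(as.matrix(fs[, c("x", "y", "z")]))

fid_frame <- function(fs) attr(fs, "frame") %||% "unspecified"

#' Transform a fiducial set by a rigid pose
#' @param fs a [fiducial_set()].
#' @param transform a `rigid_transform`.
#' @param frame frame name of the result.
#' @return The transformed `fiducial_set`.
#' @export
transform_fiducials <- function(fs, transform, frame = fid_frame(fs)) {
  p <- rt_apply(transform, fid_matrix(fs))
  fiducial_set(p, names = fs$name, frame = frame)
}

#' Read and write fiducial files
#'
#' CSV files have columns `name,x,y,z` (mm); the JSON equivalent is an array
#' of `{name, x, y, z}` objects. Format is inferred from the extension.
#'
#' @param path file path (`.csv` or `.json`).
#' @param frame frame name recorded on the set.
#' @return `read_fiducials()`: a [fiducial_set()].
#' @export
read_fiducials <- function(path, frame = "unspecified") {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path)),
    abort(sprintf("Unsupported fiducial format '.%s' (use .csv or .json).", ext))
  )
  fiducial_set(df, frame = frame)
}

#' @rdname read_fiducials
#' @param fs a [fiducial_set()].
#' @export
write_fiducials <- function(fs, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(fs)[, c("name", "x", "y", "z")]
  switch(ext,
    csv = utils::write.csv(df, path, row.names = FALSE),
    json = jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA),
    abort(sprintf("Unsupported fiducial format '.%s' (use .csv or .json).", ext))
  )
  invisible(path)
}
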