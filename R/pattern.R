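#' Lattice point pattern
#'
#' A point pattern on an `X` by `X` square pixel lattice. Coordinates are
#' 1-based integers in `1:X`, the convention used when object centroids are
#' marked on an image whose pixels are indexed from 1. `X` must be even: the
#' periodic pair-distance support `0:(X/2)` and the spectral grid both assume
#' an integral half-width.
#'
#' @param x,y integer coordinates of the objects, each in `1:X`.
#' @param X lattice side length in pixels; a positive even integer.
#' @param label optional free-text sample identifier.
#' @param pixel_size optional physical length of one pixel in micrometres,
#'   used by [to_physical()] to report length scales in microns.
#'
#' @return An object of class `"point_pattern"`: a list with elements
#'   `x`, `y`, `X`, `label`, `pixel_size`.
#' @seealso [read_pattern_csv()], [sample_set()], [isotropic_pcf()]
#' @examples
#' p <- point_pattern(c(10, 40), c(10, 10), X = 100)
#' npoints(p)
#' @export
point_pattern <- function(x, y, X, label = NULL, pixel_size = NULL) {
  X <- check_lattice_side(X)
  x <- check_coords(x, X, "x")
  y <- check_coords(y, X, "y")
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have the same length", call. = FALSE)
  }
  structure(
    list(x = x, y = y, X = X,
         label = if (is.null(label)) NULL else as.character(label)[1L],
         pixel_size = if (is.null(pixel_size)) NULL else as.numeric(pixel_size)[1L]),
    class = "point_pattern"
  )
}

check_lattice_side <- function(X) {
  if (length(X) != 1L || !is.finite(X) || X <= 0 || X != round(X)) {
    stop("'X' must be a single positive integer", call. = FALSE)
  }
  X <- as.integer(X)
  if (X %% 2L != 0L) {
    stop("'X' must be even (X = ", X, " is odd)", call. = FALSE)
  }
  X
}

check_coords <- function(v, X, axis) {
  if (length(v) == 0L) return(integer(0))
  if (any(!is.finite(v)) || any(v != round(v))) {
    stop("'", axis, "' coordinates must be integers", call. = FALSE)
  }
  bad <- which(v < 1 | v > X)
  if (length(bad)) {
    stop("coordinate out of range [1, ", X, "]: ", axis, " = ", v[bad[1L]],
         " at row ", bad[1L], call. = FALSE)
  }
  as.integer(v)
}

#' Number of objects in a point pattern
#'
#' @param pattern a [point_pattern()].
#' @return Integer count of objects.
#' @export
npoints <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  length(pattern$x)
}

#' @export
print.point_pattern <- function(x, ...) {
  cat("Lattice point pattern", if (!is.null(x$label)) paste0(" '", x$label, "'"),
      "\n  window: ", x$X, " x ", x$X, " pixels",
      if (!is.null(x$pixel_size)) sprintf(" (1 pixel = %g um)", x$pixel_size),
      "\n  objects: ", length(x$x), "\n", sep = "")
  invisible(x)
}

#' Replicate sample set
#'
#' Bundles `N` point patterns treated as independent, identically prepared
#' samples of the same process (e.g. several sub-images cut from one
#' experiment, or replicate simulations). All patterns must share the same
#' lattice side `X`.
#'
#' @param samples a list of [point_pattern()] objects, `N >= 1`.
#' @param label optional identifier for the set.
#' @return An object of class `"sample_set"`: list with `samples`, `X`, `N`,
#'   `pixel_size` (taken from the first sample), `label`.
#' @examples
#' ss <- sample_set(list(point_pattern(1:5, 1:5, 10),
#'                       point_pattern(2:6, 2:6, 10)))
#' ss$N
#' @export
sample_set <- function(samples, label = NULL) {
  if (!is.list(samples) || length(samples) < 1L ||
      !all(vapply(samples, inherits, logical(1), "point_pattern"))) {
    stop("'samples' must be a non-empty list of point_pattern objects",
         call. = FALSE)
  }
  Xs <- vapply(samples, function(p) p$X, integer(1))
  if (length(unique(Xs)) != 1L) {
    stop("all samples must share the same lattice side X; found: ",
         paste(unique(Xs), collapse = ", "), call. = FALSE)
  }
  structure(
    list(samples = samples, X = Xs[1L], N = length(samples),
         pixel_size = samples[[1L]]$pixel_size,
         label = if (is.null(label)) NULL else as.character(label)[1L]),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  n <- vapply(x$samples, npoints, integer(1))
  cat("Sample set", if (!is.null(x$label)) paste0(" '", x$label, "'"),
      "\n  N = ", x$N, " samples on a ", x$X, " x ", x$X, " lattice",
      "\n  objects per sample: mean ", round(mean(n), 2),
      " (range ", min(n), "-", max(n), ")\n", sep = "")
  invisible(x)
}

#' Read a point pattern from CSV
#'
#' Reads a coordinate file with header `x,y` and one integer row per object.
#' Duplicate coordinates are retained with a warning (two cells can be marked
#' at the same pixel); coordinates outside `[1, X]` are a hard error naming
#' the offending row.
#'
#' @param path path to the CSV file.
#' @param X lattice side length (even positive integer).
#' @param pixel_size optional physical pixel size in micrometres.
#' @param label sample identifier; defaults to the file name.
#' @return A [point_pattern()].
#' @export
read_pattern_csv <- function(path, X, pixel_size = NULL, label = NULL) {
  X <- check_lattice_side(X)
  df <- read.csv(path, colClasses = "numeric")
  if (!all(c("x", "y") %in% names(df))) {
    stop("'", path, "' must have columns 'x' and 'y'", call. = FALSE)
  }
  if (is.null(label)) label <- basename(path)
  if (nrow(df) > 0L && anyDuplicated(df[c("x", "y")])) {
    warning("duplicate coordinates in '", path, "' retained", call. = FALSE)
  }
  point_pattern(df$x, df$y, X = X, label = label, pixel_size = pixel_size)
}

#' Write a point pattern to CSV
#'
#' Inverse of [read_pattern_csv()]: writes the `x,y` header and one integer
#' row per object.
#'
#' @param pattern a [point_pattern()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pattern_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  write.csv(data.frame(x = pattern$x, y = pattern$y), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a directory of pattern CSVs as a sample set
#'
#' The directory holds one CSV per sample plus a `manifest.json` with fields
#' `X` (lattice side), `pixel_size_um` (or `null`) and `label`. Samples are
#' ordered lexicographically by file name.
#'
#' @param path directory path.
#' @param X lattice side; overrides the manifest if given.
#' @return A [sample_set()].
#' @seealso [write_sampleset_dir()]
#' @export
read_sampleset_dir <- function(path, X = NULL) {
  if (!dir.exists(path)) stop("no such directory: '", path, "'", call. = FALSE)
  manifest_path <- file.path(path, "manifest.json")
  pixel_size <- NULL
  label <- NULL
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path)
    if (is.null(X)) X <- man$X
    if (!is.null(man$pixel_size_um)) pixel_size <- man$pixel_size_um
    if (!is.null(man$label)) label <- man$label
  }
  if (is.null(X)) {
    stop("lattice side X not given and no manifest.json in '", path, "'",
         call. = FALSE)
  }
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) {
    stop("no pattern CSV files in '", path, "'", call. = FALSE)
  }
  samples <- lapply(files, function(f) {
    read_pattern_csv(f, X = X, pixel_size = pixel_size)
  })
  sample_set(samples, label = label)
}

#' Write a sample set as a directory of CSVs plus manifest
#'
#' @param samples a [sample_set()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_sampleset_dir <- function(samples, path) {
  stopifnot(inherits(samples, "sample_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  width <- max(3L, nchar(samples$N))
  for (i in seq_len(samples$N)) {
    fn <- sprintf("sample_%0*d.csv", width, i)
    write_pattern_csv(samples$samples[[i]], file.path(path, fn))
  }
  jsonlite::write_json(
    list(X = samples$X,
         pixel_size_um = if (is.null(samples$pixel_size)) NULL else samples$pixel_size,
         label = if (is.null(samples$label)) "" else samples$label),
    file.path(path, "manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}
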