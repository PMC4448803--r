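# Minimal little-endian MAT v5 reader, sufficient for coordinate files:
# numeric matrices and cell arrays of numeric matrices, plain or
# zlib-compressed elements. Not a general MAT implementation.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L

read_mat5 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128L ||
      !identical(rawToChar(raw[1:10]), "MATLAB 5.0")) {
    stop("'", path, "' is not a MAT v5 file", call. = FALSE)
  }
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") {
    stop("big-endian MAT files are not supported", call. = FALSE)
  }
  vars <- list()
  pos <- 129L
  while (pos + 7L <= length(raw)) {
    el <- mat5_element(raw, pos)
    pos <- el$next_pos
    body <- el$data
    type <- el$type
    if (type == MI_COMPRESSED) {
      body <- memDecompress(body, type = "gzip")
      sub <- mat5_element(body, 1L)
      type <- sub$type
      body <- sub$data
    }
    if (type == MI_MATRIX) {
      v <- mat5_matrix(body)
      if (!is.null(v)) vars[[v$name]] <- v$value
    }
  }
  vars
}

# One tagged data element starting at pos; handles the packed small-element
# format (nbytes in the upper 16 bits of the type word, data in 4 bytes).
mat5_element <- function(raw, pos) {
  word <- readBin(raw[pos:(pos + 3L)], "integer", 1L, size = 4L,
                  endian = "little")
  upper <- word %/% 65536L
  if (upper != 0L) {
    type <- word %% 65536L
    nbytes <- upper
    data <- raw[(pos + 4L):(pos + 3L + nbytes)]
    next_pos <- pos + 8L
  } else {
    type <- word
    nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1L, size = 4L,
                      endian = "little")
    data <- if (nbytes > 0L) raw[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
    pad <- (8L - nbytes %% 8L) %% 8L
    next_pos <- pos + 8L + nbytes + pad
  }
  list(type = type, data = data, next_pos = next_pos)
}

mat5_numeric <- function(type, data) {
  switch(as.character(type),
    "1" = readBin(data, "integer", length(data), size = 1L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(data, "integer", length(data), size = 1L, signed = FALSE,
                  endian = "little"),
    "3" = readBin(data, "integer", length(data) %/% 2L, size = 2L,
                  signed = TRUE, endian = "little"),
    "4" = readBin(data, "integer", length(data) %/% 2L, size = 2L,
                  signed = FALSE, endian = "little"),
    "5" = readBin(data, "integer", length(data) %/% 4L, size = 4L,
                  endian = "little"),
    "6" = readBin(data, "integer", length(data) %/% 4L, size = 4L,
                  endian = "little"),  # uint32 read as int32; adequate here
    "7" = readBin(data, "numeric", length(data) %/% 4L, size = 4L,
                  endian = "little"),
    "9" = readBin(data, "numeric", length(data) %/% 8L, size = 8L,
                  endian = "little"),
    NULL)
}

# Parse the body of a miMATRIX element: array flags, dims, name, data.
mat5_matrix <- function(body) {
  flags_el <- mat5_element(body, 1L)
  flags <- readBin(flags_el$data[1:4], "integer", 1L, size = 4L,
                   endian = "little")
  klass <- flags %% 256L
  dims_el <- mat5_element(body, flags_el$next_pos)
  dims <- readBin(dims_el$data, "integer", length(dims_el$data) %/% 4L,
                  size = 4L, endian = "little")
  name_el <- mat5_element(body, dims_el$next_pos)
  name <- rawToChar(name_el$data)
  pos <- name_el$next_pos
  if (klass %in% 6:15) {             # numeric classes
    pr <- mat5_element(body, pos)
    vals <- mat5_numeric(pr$type, pr$data)
    if (is.null(vals)) return(list(name = name, value = NULL))
    value <- if (length(dims) == 2L) {
      matrix(as.numeric(vals), nrow = dims[1L], ncol = dims[2L])
    } else as.numeric(vals)
    list(name = name, value = value)
  } else if (klass == 1L) {          # cell array
    cells <- list()
    while (pos + 7L <= length(body)) {
      el <- mat5_element(body, pos)
      pos <- el$next_pos
      if (el$type == MI_MATRIX && length(el$data)) {
        sub <- mat5_matrix(el$data)
        cells[[length(cells) + 1L]] <- sub$value
      } else {
        cells[[length(cells) + 1L]] <- NULL
      }
    }
    list(name = name, value = cells)
  } else {
    list(name = name, value = structure(list(), mat_class = klass))
  }
}

#' Read per-image coordinates from a MAT v5 file
#'
#' Best-effort reader for MATLAB coordinate files in which each image's marked
#' object locations are stored either as a cell array of two-column matrices
#' or as separate two-column numeric variables (one per image). The mapping
#' is heuristic by necessity: the reader introspects variable names and
#' shapes, treats each two-column (or two-row, transposed) numeric array as
#' one sample's `(x, y)` coordinates, rounds non-integer centroids to the
#' nearest pixel, and shifts 0-based coordinates to the 1-based lattice
#' convention. If no variable looks like coordinates it fails, listing what
#' was found.
#'
#' @param path path to the MAT file.
#' @param X lattice side; if `NULL`, inferred as the maximum coordinate
#'   rounded up to the next even integer.
#' @param pixel_size optional physical pixel size in micrometres.
#' @return A [sample_set()] with one sample per coordinate array.
#' @export
read_mat_coordinates <- function(path, X = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  vars <- read_mat5(path)
  vars <- vars[!grepl("^__", names(vars))]
  is_coord <- function(m) {
    is.matrix(m) && is.numeric(m) && any(dim(m) == 2L) && all(is.finite(m))
  }
  coords <- list()
  # cell array variable holding all samples
  for (v in vars) {
    if (is.list(v) && length(v) > 0L && all(vapply(v, is_coord, logical(1)))) {
      coords <- v
      break
    }
  }
  if (length(coords) == 0L) {
    coords <- Filter(is_coord, vars)
    coords <- coords[order(names(coords))]
  }
  if (length(coords) == 0L) {
    shapes <- vapply(seq_along(vars), function(i) {
      d <- dim(vars[[i]])
      paste0(names(vars)[i], " [",
             if (is.null(d)) length(vars[[i]]) else paste(d, collapse = "x"),
             "]")
    }, character(1))
    stop("no coordinate-like arrays found in '", path, "'; variables: ",
         paste(shapes, collapse = ", "), call. = FALSE)
  }
  coords <- lapply(coords, function(m) {
    if (ncol(m) != 2L) m <- t(m)
    m
  })
  allv <- unlist(coords)
  if (any(allv != round(allv))) {
    warning("non-integer coordinates rounded to the nearest pixel",
            call. = FALSE)
    coords <- lapply(coords, round)
  }
  if (min(unlist(coords)) < 1) {
    shift <- 1 - min(unlist(coords))
    coords <- lapply(coords, function(m) m + shift)
  }
  if (is.null(X)) {
    X <- max(unlist(coords))
    X <- as.integer(X + X %% 2)
  }
  samples <- lapply(seq_along(coords), function(i) {
    m <- coords[[i]]
    point_pattern(m[, 1L], m[, 2L], X = X,
                  label = paste0("mat_sample_", i), pixel_size = pixel_size)
  })
  sample_set(samples, label = basename(path))
}
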