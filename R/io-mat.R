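# Minimal MATLAB level-5 MAT-file reader.
#
# Scope: the subset the competition files and common scientific writers
# (e.g. scipy.io.savemat) produce -- 2-D numeric arrays, stored either
# plain or as zlib-compressed miCOMPRESSED elements. Cell arrays, structs,
# sparse, character and complex data are skipped with a warning. MAT v7.3
# files are HDF5 underneath and belong to the HDF5 path instead.

MI_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L,
                  `6` = 4L, `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L)

read_mi_numeric <- function(bytes, type, endian) {
  n <- length(bytes) %/% MI_TYPE_SIZE[[as.character(type)]]
  switch(as.character(type),
    `1` = readBin(bytes, "integer", n, 1L, signed = TRUE, endian = endian),
    `2` = readBin(bytes, "integer", n, 1L, signed = FALSE, endian = endian),
    `3` = readBin(bytes, "integer", n, 2L, signed = TRUE, endian = endian),
    `4` = readBin(bytes, "integer", n, 2L, signed = FALSE, endian = endian),
    `5` = readBin(bytes, "integer", n, 4L, endian = endian),
    `6` = { x <- readBin(bytes, "integer", n, 4L, endian = endian)
            ifelse(x < 0, x + 2^32, x) },
    `7` = readBin(bytes, "double", n, 4L, endian = endian),
    `9` = readBin(bytes, "double", n, 8L, endian = endian),
    `12` = readBin(bytes, "double", n, 8L, endian = endian),
    `13` = readBin(bytes, "double", n, 8L, endian = endian),
    stop("unsupported MAT data type ", type, call. = FALSE))
}

# Parse one data element starting at `pos` (1-based) in `raw`.
# Returns list(type, data = raw payload, next_pos).
read_element <- function(raw, pos, endian) {
  if (pos + 7L > length(raw) + 1L)
    stop("corrupt or truncated MAT-file: element tag past end of file",
         call. = FALSE)
  u32 <- readBin(raw[pos:(pos + 3L)], "integer", 1L, 4L, endian = endian)
  if (u32 < 0) stop("corrupt MAT-file: negative element tag", call. = FALSE)
  if (u32 > 65535L) {            # small data element: size packed in tag
    type <- u32 %% 65536L
    size <- u32 %/% 65536L
    data <- if (size > 0) raw[(pos + 4L):(pos + 3L + size)] else raw(0)
    return(list(type = type, data = data, next_pos = pos + 8L))
  }
  type <- u32
  size <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1L, 4L,
                  endian = endian)
  if (size < 0 || pos + 7L + size > length(raw))
    stop("corrupt or truncated MAT-file: element of ", size,
         " bytes exceeds file size", call. = FALSE)
  data <- if (size > 0) raw[(pos + 8L):(pos + 7L + size)] else raw(0)
  pad <- (8L - size %% 8L) %% 8L
  # miCOMPRESSED (type 15) elements are stored unpadded
  list(type = type, data = data,
       next_pos = pos + 8L + size + (if (type == 15L) 0L else pad))
}

parse_matrix_element <- function(bytes, endian) {
  pos <- 1L
  flags_el <- read_element(bytes, pos, endian); pos <- flags_el$next_pos
  flags <- readBin(flags_el$data[1:4], "integer", 1L, 4L, endian = endian)
  class_id <- flags %% 256L
  is_complex <- (flags %/% 2048L) %% 2L == 1L
  dims_el <- read_element(bytes, pos, endian); pos <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer",
                  length(dims_el$data) %/% 4L, 4L, endian = endian)
  name_el <- read_element(bytes, pos, endian); pos <- name_el$next_pos
  name <- rawToChar(name_el$data)
  if (!class_id %in% 6:13) {
    warning("skipping MAT variable '", name, "': unsupported class ",
            class_id)
    return(list(name = name, value = NULL))
  }
  if (is_complex) {
    warning("skipping MAT variable '", name, "': complex data unsupported")
    return(list(name = name, value = NULL))
  }
  data_el <- read_element(bytes, pos, endian)
  values <- read_mi_numeric(data_el$data, data_el$type, endian)
  if (length(values) != prod(dims))
    stop("corrupt MAT-file: variable '", name, "' holds ", length(values),
         " values for dimensions ", paste(dims, collapse = "x"),
         call. = FALSE)
  value <- if (length(dims) == 2L) matrix(values, dims[1], dims[2])
           else array(values, dims)   # MATLAB and R are both column-major
  list(name = name, value = value)
}

#' Read numeric variables from a MATLAB level-5 MAT-file
#'
#' @param path MAT-file path.
#' @return Named list of numeric matrices/arrays, one per readable
#'   variable.
#' @seealso [load_mat_recording()] for turning a pair of variables into a
#'   [recording()].
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128L)
    stop("corrupt or truncated MAT-file: shorter than the 128-byte header",
         call. = FALSE)
  endian_tag <- rawToChar(raw[127:128])
  endian <- if (endian_tag == "IM") "little"
            else if (endian_tag == "MI") "big"
            else stop("not a level-5 MAT-file (bad endian indicator); ",
                      "v7.3 files are HDF5 -- use load_recording()",
                      call. = FALSE)
  vars <- list()
  pos <- 129L
  while (pos + 7L <= length(raw)) {
    el <- read_element(raw, pos, endian)
    pos <- el$next_pos
    payload <- el$data
    type <- el$type
    if (type == 15L) {  # miCOMPRESSED: zlib stream wrapping one element
      payload <- memDecompress(payload, type = "gzip")
      inner <- read_element(payload, 1L, endian)
      type <- inner$type
      payload <- inner$data
    }
    if (type == 14L) {  # miMATRIX
      parsed <- parse_matrix_element(payload, endian)
      if (!is.null(parsed$value)) vars[[parsed$name]] <- parsed$value
    }
  }
  vars
}
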