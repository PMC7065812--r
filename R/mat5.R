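# Minimal reader for MATLAB Level-5 MAT containers (little-endian), covering
# the element classes needed for behavioural session tables: numeric and
# logical arrays, character arrays, cell arrays, structs, and zlib-compressed
# elements. Not a general MAT implementation (no sparse, complex, objects,
# or big-endian files).

MI_TYPES <- c(`1` = "int8", `2` = "uint8", `3` = "int16", `4` = "uint16",
              `5` = "int32", `6` = "uint32", `7` = "single", `9` = "double",
              `12` = "int64", `13` = "uint64", `16` = "utf8")

mat5_read_numeric <- function(raw, type) {
  switch(type,
    int8 = readBin(raw, "integer", length(raw), size = 1L, signed = TRUE,
                   endian = "little"),
    uint8 = as.integer(raw),
    int16 = readBin(raw, "integer", length(raw) / 2L, size = 2L,
                    signed = TRUE, endian = "little"),
    uint16 = readBin(raw, "integer", length(raw) / 2L, size = 2L,
                     signed = FALSE, endian = "little"),
    int32 = readBin(raw, "integer", length(raw) / 4L, size = 4L,
                    endian = "little"),
    uint32 = {
      v <- readBin(raw, "integer", length(raw) / 4L, size = 4L,
                   endian = "little")
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    single = readBin(raw, "double", length(raw) / 4L, size = 4L,
                     endian = "little"),
    double = readBin(raw, "double", length(raw) / 8L, size = 8L,
                     endian = "little"),
    int64 = ,
    uint64 = readBin(raw, "double", length(raw) / 8L, size = 8L,
                     endian = "little"), # lossy past 2^53; fine for counts
    utf8 = rawToChar(raw),
    abort(paste0("unsupported MAT data type: ", type))
  )
}

# one tagged data element starting at `pos` (1-based); returns value + new pos
mat5_element <- function(buf, pos) {
  if (pos + 7L > length(buf) + 1L) abort("truncated MAT element tag.")
  t1 <- readBin(buf[pos:(pos + 3L)], "integer", 1L, size = 4L,
                endian = "little")
  small_size <- bitwAnd(bitwShiftR(t1, 16L), 0xFFFFL)
  if (small_size > 0L) { # small element: data packed into the tag
    type_id <- bitwAnd(t1, 0xFFFFL)
    data <- buf[(pos + 4L):(pos + 3L + small_size)]
    return(list(type = type_id, raw = data, next_pos = pos + 8L))
  }
  type_id <- t1
  size <- readBin(buf[(pos + 4L):(pos + 7L)], "integer", 1L, size = 4L,
                  endian = "little")
  data <- if (size > 0L) buf[(pos + 8L):(pos + 7L + size)] else raw(0)
  adv <- 8L + size
  if (type_id != 15L) adv <- adv + ((8L - size %% 8L) %% 8L) # pad to 8
  list(type = type_id, raw = data, next_pos = pos + adv)
}

mat5_matrix <- function(raw) {
  # array flags
  el <- mat5_element(raw, 1L)
  flags <- readBin(el$raw[1:4], "integer", 1L, size = 4L, endian = "little")
  class_id <- bitwAnd(flags, 0xFFL)
  logical_flag <- bitwAnd(bitwShiftR(flags, 9L), 1L) == 1L
  # dimensions
  el2 <- mat5_element(raw, el$next_pos)
  dims <- mat5_read_numeric(el2$raw, "int32")
  # name
  el3 <- mat5_element(raw, el2$next_pos)
  name <- rawToChar(el3$raw[el3$raw != as.raw(0)])
  pos <- el3$next_pos

  value <- switch(as.character(class_id),
    # numeric classes (mxDOUBLE..mxUINT32 and friends)
    `6` = , `7` = , `8` = , `9` = , `10` = , `11` = , `12` = , `13` = ,
    `14` = , `15` = {
      el4 <- mat5_element(raw, pos)
      v <- mat5_read_numeric(el4$raw, MI_TYPES[[as.character(el4$type)]])
      if (logical_flag) v <- v != 0
      if (length(dims) > 2L || (length(dims) == 2L && all(dims > 1L))) {
        array(v, dim = dims)
      } else {
        as.vector(v)
      }
    },
    `4` = { # char
      el4 <- mat5_element(raw, pos)
      type <- MI_TYPES[[as.character(el4$type)]]
      if (type == "utf8") {
        rawToChar(el4$raw)
      } else {
        chars <- mat5_read_numeric(el4$raw, type)
        intToUtf8(chars[chars > 0])
      }
    },
    `1` = { # cell array
      n <- prod(dims)
      out <- vector("list", n)
      for (i in seq_len(n)) {
        el4 <- mat5_element(raw, pos)
        out[[i]] <- if (length(el4$raw)) mat5_matrix(el4$raw)$value else NULL
        pos <- el4$next_pos
      }
      out
    },
    `2` = { # struct
      el_len <- mat5_element(raw, pos)
      fname_len <- mat5_read_numeric(el_len$raw, "int32")
      el_names <- mat5_element(raw, el_len$next_pos)
      nfields <- length(el_names$raw) %/% fname_len
      fnames <- vapply(seq_len(nfields), function(i) {
        chunk <- el_names$raw[((i - 1L) * fname_len + 1L):(i * fname_len)]
        rawToChar(chunk[chunk != as.raw(0)])
      }, character(1))
      pos <- el_names$next_pos
      n_elem <- prod(dims)
      recs <- vector("list", n_elem)
      for (e in seq_len(n_elem)) {
        rec <- setNames(vector("list", nfields), fnames)
        for (f in seq_len(nfields)) {
          el4 <- mat5_element(raw, pos)
          rec[[f]] <- if (length(el4$raw)) mat5_matrix(el4$raw)$value else NULL
          pos <- el4$next_pos
        }
        recs[[e]] <- rec
      }
      if (n_elem == 1L) recs[[1L]] else recs
    },
    abort(paste0("unsupported MAT array class: ", class_id))
  )
  list(name = name, value = value)
}

#' Read a MATLAB Level-5 MAT container
#'
#' Parses the little-endian Level-5 format directly: numeric, logical, and
#' character arrays, cell arrays, structs, and zlib-compressed elements.
#' Sparse, complex, and object classes are not supported.
#'
#' @param path Path to a `.mat` file.
#' @return A named list of the file's variables. Structs become named
#'   lists, cell arrays become lists, matrices keep their dimensions.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 128L) abort("not a Level-5 MAT file (too short).")
  magic <- rawToChar(buf[127:128])
  if (magic != "IM") {
    if (magic == "MI") abort("big-endian MAT files are not supported.")
    abort("not a Level-5 MAT file (bad endian indicator).")
  }
  pos <- 129L
  out <- list()
  while (pos <= length(buf)) {
    el <- mat5_element(buf, pos)
    body <- el$raw
    if (el$type == 15L) { # compressed element wrapping a miMATRIX
      body <- memDecompress(body, type = "gzip")
      inner <- mat5_element(body, 1L)
      if (inner$type != 14L) abort("unexpected compressed element content.")
      body <- inner$raw
    } else if (el$type != 14L) {
      abort(paste0("unexpected top-level MAT element type: ", el$type))
    }
    m <- mat5_matrix(body)
    out[[m$name]] <- m$value
    pos <- el$next_pos
  }
  out
}
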