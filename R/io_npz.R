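## NumPy container I/O. No installed R package reads or writes NPY/NPZ,
## so a minimal implementation is provided: NPY format version 1.0
## (C-order, little-endian f4/f8/i4/i8) and NPZ as a stored
## (uncompressed) ZIP archive. Reading NPZ uses utils::unzip; writing
## uses a hand-built ZIP with a table-driven CRC32. Round-trips are
## cross-checked against numpy in the test suite.

npy_write <- function(x, path) {
  dims <- dim(x) %||% length(x)
  if (is.integer(x)) {
    descr <- "<i8"
  } else {
    descr <- "<f8"
    storage.mode(x) <- "double"
  }
  shape <- paste0("(", paste(dims, collapse = ", "),
                  if (length(dims) == 1L) ",", ")")
  header <- sprintf(
    "{'descr': '%s', 'fortran_order': False, 'shape': %s, }", descr, shape)
  ## total header block (magic 6 + 2 version + 2 len + dict + \n) % 64 == 0
  base_len <- 10L + nchar(header) + 1L
  pad <- (64L - base_len %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  ## C order: last axis fastest -> reverse-permute before flattening
  xc <- if (length(dims) > 1L) aperm(x, rev(seq_along(dims))) else x
  if (descr == "<i8") {
    v <- as.numeric(xc)
    lo <- v %% 2^32
    hi <- floor(v / 2^32) %% 2^32
    neg <- v < 0
    lo[neg] <- (v[neg] %% 2^32)
    hi[neg] <- floor(v[neg] / 2^32) %% 2^32
    buf <- integer(2L * length(v))
    tolow <- function(u) as.integer(u - 2^31 * (u >= 2^31)) # wrap to int32
    buf[seq(1L, by = 2L, length.out = length(v))] <- tolow(lo)
    buf[seq(2L, by = 2L, length.out = length(v))] <- tolow(hi)
    writeBin(buf, con, size = 4, endian = "little")
  } else {
    writeBin(as.numeric(xc), con, size = 8, endian = "little")
  }
  invisible(path)
}

npy_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stopf("%s is not an NPY file", path)
  }
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little",
                  signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  dims <- dims[!is.na(dims)]
  n <- if (length(dims) == 0L) 1L else prod(dims)
  x <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4, endian = "little"),
    "<i8" = {
      buf <- readBin(con, "integer", 2L * n, size = 4, endian = "little")
      lo <- buf[seq(1L, by = 2L, length.out = n)]
      hi <- buf[seq(2L, by = 2L, length.out = n)]
      lo_u <- ifelse(lo < 0, lo + 2^32, lo)
      lo_u + hi * 2^32
    },
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    "|i1" = readBin(con, "integer", n, size = 1, endian = "little"),
    stopf("unsupported dtype %s", descr))
  if (length(dims) > 1L) {
    x <- if (fortran) array(x, dims) else aperm(array(x, rev(dims)),
                                                rev(seq_along(dims)))
  }
  x
}

## ---- minimal stored-ZIP writer ----

.crc_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1), -306674912L)  # 0xEDB88320 as signed
      } else bitwShiftR(c, 1)
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(raw_bytes) {
  c <- -1L                                     # 0xFFFFFFFF
  b <- as.integer(raw_bytes)
  for (i in seq_along(b)) {
    c <- bitwXor(bitwShiftR(c, 8),
                 .crc_table[bitwAnd(bitwXor(c, b[i]), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) {
  ## x may exceed .Machine$integer.max as numeric; write 4 bytes manually
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

zip_store <- function(files, zip_path) {
  con <- file(zip_path, "wb")
  on.exit(close(con))
  offs <- numeric(length(files))
  infos <- vector("list", length(files))
  pos <- 0
  for (i in seq_along(files)) {
    nm <- names(files)[i]
    dat <- readBin(files[[i]], "raw", file.info(files[[i]])$size)
    crc <- crc32(dat)
    offs[i] <- pos
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16(20), u16(0),
                   u16(0), u16(0), u16(0), u32(crc), u32(length(dat)),
                   u32(length(dat)), u16(nchar(nm)), u16(0), charToRaw(nm))
    writeBin(local_hdr, con)
    writeBin(dat, con)
    pos <- pos + length(local_hdr) + length(dat)
    infos[[i]] <- list(nm = nm, crc = crc, size = length(dat))
  }
  cd_start <- pos
  cd_len <- 0
  for (i in seq_along(files)) {
    fi <- infos[[i]]
    hdr <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16(20), u16(20), u16(0),
             u16(0), u16(0), u16(0), u32(fi$crc), u32(fi$size), u32(fi$size),
             u16(nchar(fi$nm)), u16(0), u16(0), u16(0), u16(0), u32(0),
             u32(offs[i]), charToRaw(fi$nm))
    writeBin(hdr, con)
    cd_len <- cd_len + length(hdr)
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16(0), u16(0),
            u16(length(files)), u16(length(files)), u32(cd_len),
            u32(cd_start), u16(0))
  writeBin(eocd, con)
  invisible(zip_path)
}

#' Write a signal set to file
#'
#' `.npz` (the canonical container) stores `values` as a float array of
#' shape `(n, channels, timesteps)` and, when present, `labels` as int64;
#' a sidecar `<path>.labels.csv` is written alongside for convenience.
#' `.csv` (single-channel sets only) stores one signal per row.
#'
#' @param set A non-empty [signal_set()].
#' @param path Output path ending in `.npz` or `.csv`.
#' @return The path, invisibly.
#' @export
write_signal_set <- function(set, path) {
  stopifnot(inherits(set, "signal_set"))
  if (n_signals(set) == 0) stopf("refusing to write an empty signal set")
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    if (dim(set$values)[2] != 1L) stopf("CSV supports single-channel sets")
    m <- matrix(set$values, dim(set$values)[1], dim(set$values)[3])
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext == "npz") {
    td <- tempfile("npz")
    dir.create(td)
    on.exit(unlink(td, recursive = TRUE), add = TRUE)
    members <- c(`values.npy` = file.path(td, "values.npy"))
    npy_write(set$values, members[["values.npy"]])
    if (!is.null(set$labels)) {
      members[["labels.npy"]] <- file.path(td, "labels.npy")
      npy_write(as.integer(set$labels), members[["labels.npy"]])
      utils::write.csv(data.frame(label = set$labels),
                       paste0(path, ".labels.csv"), row.names = FALSE)
    }
    zip_store(members, path)
  } else stopf("unsupported extension .%s (use .npz or .csv)", ext)
  invisible(path)
}

#' Read a signal set from file
#'
#' Accepts `.npz` (arrays `values`, optional `labels`) or `.csv` (wide,
#' one single-channel signal per row). Values are validated for
#' non-finite entries.
#'
#' @param path Input path.
#' @return A [signal_set()].
#' @export
read_signal_set <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    return(signal_set(array(m, c(nrow(m), 1L, ncol(m)))))
  }
  if (ext != "npz") stopf("unsupported extension .%s", ext)
  td <- tempfile("unz")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  files <- utils::unzip(path, exdir = td)
  vf <- files[basename(files) == "values.npy"]
  if (length(vf) != 1L) stopf("NPZ misses a `values` array")
  vals <- npy_read(vf)
  if (length(dim(vals)) == 2L) vals <- array(vals, c(dim(vals)[1], 1L,
                                                     dim(vals)[2]))
  lf <- files[basename(files) == "labels.npy"]
  labels <- if (length(lf) == 1L) as.integer(npy_read(lf))
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(vals))
    stopf("non-finite values at %d entries (first index %d)",
          length(bad), bad[1])
  }
  signal_set(vals, labels = labels)
}
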