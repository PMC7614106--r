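# Minimal baseline TIFF codec: multi-page, single-sample grayscale, 8- or
# 16-bit unsigned, uncompressed.  No installed R package reads TIFF in this
# environment, and only the baseline subset is needed for round-trip exact
# storage of stacks, so the format is handled directly.  Reading accepts both
# byte orders; writing emits little-endian with one strip per page.

.TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
                photometric = 262L, strip_offsets = 273L, spp = 277L,
                rows_per_strip = 278L, strip_bytes = 279L)

.tiff_read <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file (truncated header): ", path)
  endian <- if (raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49)) "little"
            else if (raw[1] == as.raw(0x4d) && raw[2] == as.raw(0x4d)) "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               signed = TRUE, endian = endian)  # offsets < 2^31 here
  if (u16(2) != 42L) stop("not a TIFF file (bad magic): ", path)

  pages <- list()
  ifd <- u32(4)
  while (ifd != 0L) {
    if (ifd + 2 > length(raw)) stop("corrupt TIFF: IFD offset beyond file end")
    nent <- u16(ifd)
    tags <- list()
    for (e in seq_len(nent)) {
      off <- ifd + 2 + 12 * (e - 1)
      tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      nbytes <- count * switch(type, `1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, 0L)
      if (nbytes == 0L) next  # unsupported value type: ignore tag
      voff <- if (nbytes <= 4L) off + 8 else u32(off + 8)
      if (voff + nbytes > length(raw)) stop("corrupt TIFF: tag value beyond file end")
      vals <- if (type == 3L)
        vapply(seq_len(count), function(i) u16(voff + 2 * (i - 1)), 0L)
      else if (type %in% c(1L, 2L))
        as.integer(raw[(voff + 1):(voff + count)])
      else
        vapply(seq_len(count), function(i) u32(voff + 4 * (i - 1)), 0L)
      tags[[as.character(tag)]] <- vals
    }
    get_tag <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- get_tag(256L); h <- get_tag(257L)
    if (is.null(w) || is.null(h)) stop("corrupt TIFF: page missing width/height")
    bits <- get_tag(258L, 8L)[1]
    comp <- get_tag(259L, 1L)
    spp <- get_tag(277L, 1L)
    if (comp != 1L) stop("unsupported TIFF: compressed data (compression=", comp, ")")
    if (spp != 1L || length(get_tag(258L, 8L)) != 1L)
      stop("unsupported TIFF: not single-sample grayscale (SamplesPerPixel=", spp, ")")
    if (!bits %in% c(8L, 16L)) stop("unsupported TIFF: ", bits, "-bit samples")
    so <- get_tag(273L); sb <- get_tag(279L)
    if (is.null(so)) stop("corrupt TIFF: page missing strip offsets")
    if (is.null(sb)) sb <- rep(w * h * bits / 8 / length(so), length(so))
    pix <- integer(0)
    for (s in seq_along(so)) {
      seg <- raw[(so[s] + 1):(so[s] + sb[s])]
      pix <- c(pix, if (bits == 8L) as.integer(seg)
               else readBin(seg, "integer", n = sb[s] / 2, size = 2,
                            signed = FALSE, endian = endian))
    }
    if (length(pix) != w * h) stop("corrupt TIFF: pixel count mismatch on page ",
                                   length(pages) + 1)
    # strips are row-major (y rows of x columns) -> matrix[y, x]
    pages[[length(pages) + 1]] <- matrix(pix, nrow = h, ncol = w, byrow = TRUE)
    ifd <- u32(ifd + 2 + 12 * nent)
  }
  if (length(pages) == 0L) stop("TIFF file contains no pages: ", path)
  d <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) {
    if (!identical(dim(pages[[z]]), d)) stop("TIFF pages differ in size")
    arr[z, , ] <- pages[[z]]
  }
  list(data = arr, bits = bits)
}

.tiff_write <- function(arr, path, bits) {
  nz <- dim(arr)[1]; h <- dim(arr)[2]; w <- dim(arr)[3]
  bps <- bits / 8
  page_bytes <- w * h * bps
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x49), as.raw(0x49)), con)
  writeBin(2L * 21L, con, size = 2, endian = "little")  # 42
  # layout: header(8) | page data blocks | IFDs
  data_start <- 8
  ifd_start <- data_start + nz * page_bytes
  ifd_size <- 2 + 12 * 9 + 4
  writeBin(as.integer(ifd_start), con, size = 4, endian = "little")
  for (z in seq_len(nz)) {
    pix <- as.integer(t(arr[z, , ]))  # row-major
    if (bits == 8L) writeBin(as.raw(pix), con)
    else {
      lo <- pix %% 256L; hi <- pix %/% 256L
      writeBin(as.raw(as.vector(rbind(lo, hi))), con)
    }
  }
  for (z in seq_len(nz)) {
    here <- ifd_start + (z - 1) * ifd_size
    entry <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3L) {  # SHORT padded to 4 bytes
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else writeBin(as.integer(value), con, size = 4, endian = "little")
    }
    writeBin(9L, con, size = 2, endian = "little")
    entry(256L, 3L, 1L, w)
    entry(257L, 3L, 1L, h)
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)              # no compression
    entry(262L, 3L, 1L, 1L)              # BlackIsZero
    entry(273L, 4L, 1L, data_start + (z - 1) * page_bytes)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 3L, 1L, h)
    entry(279L, 4L, 1L, page_bytes)
    nxt <- if (z < nz) here + ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}
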