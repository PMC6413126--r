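# Minimal 16-bit grayscale PNG encoder. Depth maps are stored as integer
# millimetres, which needs the full 16-bit range; writers available to us
# only emit 8-bit, while 16-bit *reading* is standard. PNG is: 8-byte
# signature, then chunks [length|type|data|crc32]; IDAT holds a zlib stream
# of filter-byte-prefixed scanlines (big-endian 16-bit samples).

u32_be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_be(length(data)), body, u32_be(.crc32_cpp(body)))
}

write_png16_gray <- function(ints, path) {
  if (!is.matrix(ints)) stop_gait("parameter", "expected a matrix")
  ints <- round(ints)
  if (any(ints < 0 | ints > 65535))
    stop_gait("parameter", "values out of 16-bit range")
  nr <- nrow(ints); nc <- ncol(ints)
  # scanlines: filter byte 0 + row-major big-endian 16-bit samples
  hi <- as.raw(t(ints) %/% 256)
  lo <- as.raw(t(ints) %% 256)
  px <- as.vector(rbind(hi, lo))  # per-pixel big-endian interleave
  scan <- matrix(as.raw(0), nrow = 2L * nc + 1L, ncol = nr)
  scan[-1L, ] <- matrix(px, nrow = 2L * nc)
  ihdr <- c(u32_be(nc), u32_be(nr),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit, grayscale
  idat <- memCompress(as.vector(scan), "gzip")  # zlib (RFC 1950) stream
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
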