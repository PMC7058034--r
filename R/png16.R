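# Minimal 16-bit grayscale PNG encoder.  The png package reads 16-bit
# grayscale PNGs at full precision but can only write 8 bits per sample,
# which would truncate the intensity scale; plate images are therefore
# encoded here directly (IHDR/IDAT/IEND, filter type 0, zlib stream from
# memCompress, own CRC32).

write_png16 <- function(m, path) {
  stopifnot(is.matrix(m), all(m >= 0), all(m <= 65535))
  h <- nrow(m); w <- ncol(m)
  v <- as.integer(t(m))                      # row-major pixel order
  pix <- as.raw(rbind(v %/% 256L, v %% 256L))  # big-endian 16-bit samples
  stream <- raw(h * (1L + 2L * w))
  filt_pos <- (0:(h - 1)) * (1L + 2L * w) + 1L
  stream[-filt_pos] <- pix                   # filter byte 0 leads each row
  idat <- memCompress(stream, "gzip")        # zlib stream (78 9c ...)

  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                              endian = "big")
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(u32(length(data)), body, u32(png_crc32(body)))
  }
  ihdr <- c(u32(w), u32(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, gray, no interlace
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(chunk("IHDR", ihdr), con)
  writeBin(chunk("IDAT", idat), con)
  writeBin(chunk("IEND", raw(0)), con)
  invisible(path)
}

# Table-driven CRC-32 (polynomial 0xEDB88320), returned as a signed 32-bit
# integer whose bit pattern is the unsigned CRC.
png_crc32 <- function(bytes) {
  tab <- png_crc_table()
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

png_crc_env <- new.env(parent = emptyenv())
png_crc_table <- function() {
  if (!is.null(png_crc_env$tab)) return(png_crc_env$tab)
  tab <- integer(256)
  for (n in 0:255) {
    c_ <- n
    for (k in 1:8) {
      c_ <- if (bitwAnd(c_, 1L) != 0L) {
        bitwXor(-306674912L, bitwShiftR(c_, 1L))  # 0xEDB88320
      } else {
        bitwShiftR(c_, 1L)
      }
    }
    tab[n + 1L] <- c_
  }
  png_crc_env$tab <- tab
  tab
}
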