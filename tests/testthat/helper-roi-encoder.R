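# Independent ImageJ .roi encoder, written directly from the published
# ij.io.RoiDecoder byte layout.  Used to synthesize fixtures at test time
# (the paper's own ROI files are not deposited); kept free of any package
# code so decoder tests are a genuine round trip through the format.
encode_imagej_roi <- function(x, y, name = NULL, type = 0L,
                              sub_pixel = FALSE,
                              version = if (sub_pixel) 228L else 218L) {
  n <- length(x)
  left <- floor(min(x)); top <- floor(min(y))
  right <- ceiling(max(x)); bottom <- ceiling(max(y))
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "big")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "big")
  wf <- function(v) writeBin(as.double(v), con, size = 4L, endian = "big")

  writeBin(charToRaw("Iout"), con)            # bytes 0-3: magic
  w2(version)                                 # 4-5
  writeBin(as.raw(c(type, 0L)), con)          # 6: roi type, 7: pad
  w2(c(top, left, bottom, right))             # 8-15: bounding box
  w2(n)                                       # 16-17: n coordinates
  writeBin(raw(32), con)                      # 18-49: x1..y2, stroke, colors
  w2(if (sub_pixel) 128L else 0L)             # 50-51: options (SUB_PIXEL=128)
  writeBin(raw(8), con)                       # 52-59: styles, position
  coord_bytes <- 4L * n + if (sub_pixel) 8L * n else 0L
  hdr2 <- if (is.null(name)) 0L else 64L + coord_bytes
  w4(hdr2)                                    # 60-63: header2 offset
  w2(round(x - left))                         # integer offsets, x then y
  w2(round(y - top))
  if (sub_pixel) { wf(x); wf(y) }
  if (!is.null(name)) {
    name_off <- hdr2 + 64L
    w4(rep(0L, 4))                            # header2 bytes 0-15
    w4(name_off)                              # +16: name offset
    w4(nchar(name))                           # +20: name length
    writeBin(raw(64L - 24L), con)             # rest of header2
    w2(utf8ToInt(name))                       # name as 16-bit chars
  }
  rawConnectionValue(con)
}

write_roi_fixture <- function(path, ...) {
  writeBin(encode_imagej_roi(...), path)
  path
}
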