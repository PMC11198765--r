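# Minimal LAS 1.2 reader/writer (point record format 1: XYZ + GPS time),
# written against the ASPRS LAS 1.2 specification. Coordinates are stored as
# scaled 32-bit integers; the writer uses a 1 mm scale with the offset at the
# floor of the cloud centroid, so round trips are exact to 0.5 mm. Point
# times go to the GPS-time field in seconds; classifications use the ASPRS
# codes (2 ground, 5 high vegetation, 1 unclassified).

las_class_codes <- c(ground = 2L, vegetation = 5L, unclassified = 1L)

#' Write and read LAS point clouds
#'
#' Minimal LAS 1.2 support (point format 1): coordinates at a configurable
#' scale (default 1 mm, offsets at the floor of the centroid), point time in
#' the GPS-time field (seconds), ground/vegetation labels as ASPRS
#' classification codes 2/5.
#'
#' @param cloud A [point_cloud()].
#' @param path File path.
#' @param scale Coordinate scale in meters (resolution of the stored
#'   integers).
#' @return `write_las()` returns `path` invisibly; `read_las()` a
#'   [point_cloud()] (with `t_ms` and `label` when present in the file).
#' @export
write_las <- function(cloud, path, scale = 0.001) {
  stopifnot(all(c("x", "y", "z") %in% names(cloud)), scale > 0)
  n <- nrow(cloud)
  if (!n) stop("refusing to write an empty LAS file", call. = FALSE)
  off <- floor(c(mean(cloud$x), mean(cloud$y), mean(cloud$z)))
  xi <- as.integer(round((cloud$x - off[1]) / scale))
  yi <- as.integer(round((cloud$y - off[2]) / scale))
  zi <- as.integer(round((cloud$z - off[3]) / scale))
  gps <- if (!is.null(cloud$t_ms)) cloud$t_ms / 1000 else rep(0, n)
  cls <- if (!is.null(cloud$label)) {
    unname(las_class_codes[as.character(cloud$label)])
  } else rep(1L, n)
  cls[is.na(cls)] <- 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, nchars = 4, eos = NULL)
  write_u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                                    endian = "little")
  write_u32 <- function(x) writeBin(as.integer(x), con, size = 4,
                                    endian = "little")
  write_u16(0); write_u16(0)                      # file source id, encoding
  writeBin(raw(16), con)                          # project GUID
  writeBin(as.integer(c(1, 2)), con, size = 1)    # version 1.2
  writeChar(formatC("panoscan", width = -32), con, nchars = 32, eos = NULL)
  writeChar(formatC("panoscan", width = -32), con, nchars = 32, eos = NULL)
  write_u16(1); write_u16(2000)                   # creation day/year
  write_u16(227)                                  # header size
  write_u32(227)                                  # offset to point data
  write_u32(0)                                    # number of VLRs
  writeBin(as.integer(1), con, size = 1)          # point data format 1
  write_u16(28)                                   # point record length
  write_u32(n)
  write_u32(c(n, 0, 0, 0, 0))                     # points by return
  writeBin(rep(scale, 3), con, size = 8, endian = "little")
  writeBin(as.numeric(off), con, size = 8, endian = "little")
  writeBin(as.numeric(c(max(cloud$x), min(cloud$x), max(cloud$y),
                        min(cloud$y), max(cloud$z), min(cloud$z))),
           con, size = 8, endian = "little")

  # point records: interleave via a raw buffer for speed
  rec <- raw(28 * n)
  at <- function(k) rep(seq(0, by = 28, length.out = n), each = length(k)) +
    rep(k, times = n)
  rec[at(1:4)] <- writeBin(xi, raw(), size = 4, endian = "little")
  rec[at(5:8)] <- writeBin(yi, raw(), size = 4, endian = "little")
  rec[at(9:12)] <- writeBin(zi, raw(), size = 4, endian = "little")
  rec[at(15)] <- as.raw(9L)                       # return 1 of 1
  rec[at(16)] <- as.raw(cls)
  rec[at(21:28)] <- writeBin(gps, raw(), size = 8, endian = "little")
  writeBin(rec, con)
  invisible(path)
}

#' @rdname write_las
#' @export
read_las <- function(path) {
  if (!file.exists(path)) stop("LAS file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF"))
    stop("not a LAS file (bad signature): ", path, call. = FALSE)
  invisible(readBin(con, "raw", 20))              # source id .. GUID
  ver <- readBin(con, "integer", 2, size = 1)
  if (ver[1] != 1)
    stop("unsupported LAS major version ", ver[1], ": ", path, call. = FALSE)
  invisible(readBin(con, "raw", 64 + 4))          # sysid, software, day/year
  header_size <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                         endian = "little")
  data_offset <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))  # VLRs
  fmt <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  rec_len <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                     endian = "little")
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", 5, size = 4, endian = "little"))
  scales <- readBin(con, "numeric", 3, size = 8, endian = "little")
  offs <- readBin(con, "numeric", 3, size = 8, endian = "little")
  invisible(readBin(con, "numeric", 6, size = 8, endian = "little"))
  if (!fmt %in% c(0, 1))
    stop("unsupported LAS point format ", fmt, ": ", path, call. = FALSE)
  if (file.size(path) < data_offset + as.numeric(n) * rec_len)
    stop(sprintf("truncated LAS file (%d records of %d bytes expected): %s",
                 n, rec_len, path), call. = FALSE)
  seek(con, data_offset)
  rec <- readBin(con, "raw", as.numeric(n) * rec_len)
  if (length(rec) < n * rec_len)
    stop("truncated LAS file: ", path, call. = FALSE)
  idx <- seq(0, by = rec_len, length.out = n)
  take <- function(k) rec[rep(idx, each = length(k)) + rep(k, times = n)]
  xi <- readBin(take(1:4), "integer", n, size = 4, endian = "little")
  yi <- readBin(take(5:8), "integer", n, size = 4, endian = "little")
  zi <- readBin(take(9:12), "integer", n, size = 4, endian = "little")
  cls <- as.integer(take(16))
  out <- data.frame(x = xi * scales[1] + offs[1],
                    y = yi * scales[2] + offs[2],
                    z = zi * scales[3] + offs[3])
  if (fmt == 1) {
    gps <- readBin(take(21:28), "numeric", n, size = 8, endian = "little")
    out$t_ms <- gps * 1000
  }
  if (any(cls %in% las_class_codes)) {
    lab <- rep("unclassified", n)
    lab[cls == las_class_codes[["ground"]]] <- "ground"
    lab[cls == las_class_codes[["vegetation"]]] <- "vegetation"
    out$label <- lab
  }
  point_cloud(out)
}
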