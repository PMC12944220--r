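# File formats: 8/16-bit PNG frames, COCO-style RLE mask JSON, MOT Challenge
# CSV tracks, per-frame volume CSV, scene.yaml config echo.
#
# png::writePNG only emits 8-bit samples, so the 16-bit grayscale depth PNG
# is assembled here: scanlines with filter 0, a zlib stream rebuilt from
# memCompress()'s gzip output, and CRC-32/Adler-32 from compiled code.
# png::readPNG handles 16-bit input natively.

int32_be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int32_be(length(data)), body, int32_be(crc32_raw(body)))
}

zlib_deflate <- function(data) {
  out <- memCompress(data, type = "gzip")
  # R's "gzip" memCompress emits a zlib stream (0x78 header + Adler-32),
  # which is exactly the PNG IDAT payload format; verify and pass through
  if (out[1] != as.raw(0x78)) {
    # fall back to rebuilding the zlib wrapper around the raw deflate body
    out <- c(as.raw(c(0x78, 0x01)), out[11:(length(out) - 8L)],
             int32_be(adler32_raw(data)))
  }
  out
}

#' Write a 16-bit grayscale PNG
#'
#' Stores an integer matrix (e.g. depth in millimeters, 0 = missing) as a
#' single-channel 16-bit PNG, the depth-frame convention used by the clip
#' writer.
#'
#' @param img integer-valued matrix, values in \code{[0, 65535]}; rows are
#'   image rows (y down).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_png16 <- function(img, path) {
  stopifnot(is.matrix(img))
  v <- round(img)
  if (any(v < 0 | v > 65535)) stop("values out of 16-bit range")
  h <- nrow(v); w <- ncol(v)
  hi <- as.raw(v %/% 256); lo <- as.raw(v %% 256)
  # scanlines: filter byte 0 + big-endian pixels, row by row
  sl <- raw((2L * w + 1L) * h)
  row_len <- 2L * w + 1L
  for (r in seq_len(h)) {
    off <- (r - 1L) * row_len
    sl[off + 1L] <- as.raw(0)
    sl[off + 1L + seq(1L, 2L * w, 2L)] <- hi[r + h * (seq_len(w) - 1L)]
    sl[off + 1L + seq(2L, 2L * w, 2L)] <- lo[r + h * (seq_len(w) - 1L)]
  }
  ihdr <- c(int32_be(w), int32_be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", zlib_deflate(sl)), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' Read a 16-bit grayscale PNG
#'
#' @param path PNG file path.
#' @return integer matrix of raw 16-bit sample values.
#' @export
read_png16 <- function(path) {
  x <- png::readPNG(path)
  round(x * 65535)
}

write_png8 <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# ---- COCO-style run-length encoding (uncompressed counts) ----

#' Run-length encode a binary mask (COCO convention)
#'
#' Column-major runs, starting with the count of background pixels.
#'
#' @param mask logical or 0/1 matrix.
#' @return list with \code{size = c(h, w)} and integer \code{counts}.
#' @export
mask_to_rle <- function(mask) {
  v <- as.integer(as.vector(mask) != 0)  # column-major
  n <- length(v)
  ch <- c(TRUE, v[-1L] != v[-n])
  runs <- diff(c(which(ch), n + 1L))
  if (v[1L] == 1L) runs <- c(0L, runs)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(runs))
}

#' Decode a COCO run-length encoded mask
#'
#' @param rle list as produced by \code{\link{mask_to_rle}}.
#' @return logical matrix.
#' @export
rle_to_mask <- function(rle) {
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(rle$counts)), rle$counts)
  matrix(vals, rle$size[1], rle$size[2])
}

# masks: list over frames, each a named list id -> logical matrix (or pixel
# index vector with attr "dim")
write_coco_masks <- function(masks_by_frame, image_size, path) {
  anns <- list(); k <- 0L
  for (t in seq_along(masks_by_frame)) {
    fr <- masks_by_frame[[t]]
    for (nm in names(fr)) {
      m <- fr[[nm]]
      if (!is.matrix(m)) {
        mm <- matrix(FALSE, image_size[1], image_size[2]); mm[m] <- TRUE; m <- mm
      }
      if (!any(m)) next
      k <- k + 1L
      rc <- which(m, arr.ind = TRUE)
      x0 <- min(rc[, 2]) - 1L; y0 <- min(rc[, 1]) - 1L
      anns[[k]] <- list(
        id = k, image_id = t, category_id = 1L,
        track_id = as.integer(nm),
        segmentation = mask_to_rle(m),
        bbox = c(x0, y0, max(rc[, 2]) - 1L - x0 + 1L, max(rc[, 1]) - 1L - y0 + 1L),
        area = sum(m), iscrowd = 0L)
    }
  }
  doc <- list(
    images = lapply(seq_along(masks_by_frame), function(t)
      list(id = t, width = image_size[2], height = image_size[1],
           file_name = sprintf("frame_%05d.png", t - 1L))),
    annotations = anns,
    categories = list(list(id = 1L, name = "fish")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- MOT Challenge CSV ----

#' Write tracks in the MOT Challenge CSV dialect
#'
#' One row per (frame, id): \code{frame,id,bb_left,bb_top,bb_width,bb_height,
#' conf,-1,-1,-1}, frames 1-based per the MOT convention.
#'
#' @param df data frame with columns \code{frame} (1-based), \code{id},
#'   \code{x}, \code{y}, \code{w}, \code{h} and optionally \code{conf}.
#' @param path output path.
#' @export
write_mot_csv <- function(df, path) {
  conf <- if ("conf" %in% names(df)) df$conf else rep(1, nrow(df))
  out <- data.frame(df$frame, df$id, df$x, df$y, df$w, df$h, conf, -1, -1, -1)
  utils::write.table(out, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mot_csv
#' @export
read_mot_csv <- function(path) {
  d <- utils::read.table(path, sep = ",")
  names(d)[1:7] <- c("frame", "id", "x", "y", "w", "h", "conf")
  d[, 1:7]
}

write_volume_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated clip to a directory
#'
#' Produces the on-disk clip layout: \code{ir/frame_\%05d.png} and
#' \code{rgb/frame_\%05d.png} (8-bit), \code{depth/frame_\%05d.png} (16-bit,
#' millimeters), \code{masks.json} (COCO-style RLE with track ids),
#' \code{trajectories.csv}
#' (\code{frame,id,x,y,w,h,cx,cy,vx,vy,volume_cm3}) and a \code{scene.yaml}
#' echo of the configuration.
#'
#' @param clip simulated clip from \code{\link{simulate_clip}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_clip <- function(clip, dir) {
  for (d in file.path(dir, c("ir", "rgb", "depth"))) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  T_ <- length(clip$ir)
  for (t in seq_len(T_)) {
    fn <- sprintf("frame_%05d.png", t - 1L)
    write_png8(clip$ir[[t]], file.path(dir, "ir", fn))
    write_png8(clip$rgb[[t]], file.path(dir, "rgb", fn))
    write_png16(pmin(round(clip$depth[[t]] * 1000), 65535), file.path(dir, "depth", fn))
  }
  tr <- clip$truth
  sz <- dim(clip$ir[[1]])
  masks_by_frame <- lapply(seq_len(T_), function(t) {
    fr <- tr$masks[[t]]
    stats::setNames(fr, as.character(tr$ids))
  })
  write_coco_masks(masks_by_frame, sz, file.path(dir, "masks.json"))
  rows <- do.call(rbind, lapply(seq_len(T_), function(t) {
    b <- tr$boxes[[t]]
    data.frame(frame = t, id = tr$ids, x = b[, 1], y = b[, 2], w = b[, 3],
               h = b[, 4],
               cx = tr$traj$cx[tr$traj$frame == t],
               cy = tr$traj$cy[tr$traj$frame == t],
               vx = tr$traj$vx[tr$traj$frame == t],
               vy = tr$traj$vy[tr$traj$frame == t],
               volume_cm3 = tr$volumes)
  }))
  write_volume_csv(rows, file.path(dir, "trajectories.csv"))
  cfg <- clip$config
  yaml::write_yaml(cfg, file.path(dir, "scene.yaml"))
  invisible(dir)
}
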