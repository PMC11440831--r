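# Minimal DICOM series import.
#
# Supports the subset that uncompressed axial CT series use: little-endian
# transfer syntaxes (implicit 1.2.840.10008.1.2 and explicit
# 1.2.840.10008.1.2.1), single-frame 16-bit pixel data, rescale
# slope/intercept, and slice geometry from ImagePositionPatient /
# SliceLocation. Compressed or big-endian files are rejected with an error
# naming the file. DICOM is import-only; NIfTI is the interchange format.

dcm_u16 <- function(r, p) {
  readBin(r[p:(p + 1)], "integer", size = 2, endian = "little",
          signed = FALSE)
}
dcm_u32 <- function(r, p) {
  lo <- dcm_u16(r, p); hi <- dcm_u16(r, p + 2)
  lo + hi * 65536
}
dcm_str <- function(r, p, n) {
  if (n == 0) return("")
  b <- r[p:(p + n - 1)]
  b <- b[b != as.raw(0)]  # UI values are NUL-padded to even length
  trimws(rawToChar(b))
}
dcm_ds <- function(s) as.numeric(strsplit(s, "\\\\")[[1]])

LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

parse_dicom_file <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  fail <- function(msg) stop("cannot read DICOM file '", path, "': ", msg,
                             call. = FALSE)
  if (length(r) < 140) fail("file too short")
  p <- if (rawToChar(r[129:132]) == "DICM") 133L else 1L

  tags <- list()
  explicit <- TRUE  # file meta group is always explicit little-endian
  ts <- NULL
  in_meta <- TRUE
  while (p + 8 <= length(r) + 1) {
    group <- dcm_u16(r, p); elem <- dcm_u16(r, p + 2)
    if (in_meta && group != 2L) {
      # file meta ended: switch to the negotiated transfer syntax
      in_meta <- FALSE
      if (is.null(ts)) ts <- "1.2.840.10008.1.2.1"
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        fail(paste0("unsupported transfer syntax ", ts))
    }
    use_explicit <- explicit || group == 2L
    if (use_explicit) {
      vr <- rawToChar(r[(p + 4):(p + 5)])
      if (vr %in% LONG_VRS) {
        len <- dcm_u32(r, p + 8); vp <- p + 12L
      } else {
        len <- dcm_u16(r, p + 6); vp <- p + 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(r, p + 4); vp <- p + 8L
    }
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "7fe0,0010") {
      if (len == 0xFFFFFFFF) fail("encapsulated (compressed) pixel data")
      tags$pixel_offset <- vp; tags$pixel_length <- len
      break
    }
    if (len == 0xFFFFFFFF) {
      # undefined-length sequence: scan for the sequence delimiter
      q <- vp
      repeat {
        if (q + 8 > length(r) + 1) fail("unterminated sequence")
        if (dcm_u16(r, q) == 0xFFFE && dcm_u16(r, q + 2) == 0xE0DD) {
          q <- q + 8L; break
        }
        q <- q + 2L
      }
      p <- q
      next
    }
    val <- switch(key,
      "0002,0010" = dcm_str(r, vp, len),
      "0020,000e" = dcm_str(r, vp, len),
      "0020,0032" = dcm_str(r, vp, len),
      "0020,1041" = dcm_str(r, vp, len),
      "0028,0030" = dcm_str(r, vp, len),
      "0028,1052" = dcm_str(r, vp, len),
      "0028,1053" = dcm_str(r, vp, len),
      "0028,0010" = dcm_u16(r, vp),
      "0028,0011" = dcm_u16(r, vp),
      "0028,0100" = dcm_u16(r, vp),
      "0028,0103" = dcm_u16(r, vp),
      NULL)
    if (!is.null(val)) {
      if (key == "0002,0010") ts <- val
      tags[[key]] <- val
    }
    p <- vp + len
  }
  if (is.null(tags$pixel_offset)) fail("no pixel data")
  rows <- tags[["0028,0010"]]; cols <- tags[["0028,0011"]]
  bits <- tags[["0028,0100"]]
  if (is.null(rows) || is.null(cols)) fail("missing image dimensions")
  if (is.null(bits) || bits != 16) fail("only 16-bit pixel data supported")
  signed <- identical(tags[["0028,0103"]], 1L) ||
    identical(tags[["0028,0103"]], 1)
  n <- rows * cols
  if (tags$pixel_length < 2 * n) fail("truncated pixel data")
  px <- readBin(r[tags$pixel_offset:(tags$pixel_offset + 2 * n - 1)],
                "integer", n = n, size = 2, endian = "little",
                signed = signed)
  slope <- if (is.null(tags[["0028,1053"]])) 1 else dcm_ds(tags[["0028,1053"]])
  icept <- if (is.null(tags[["0028,1052"]])) 0 else dcm_ds(tags[["0028,1052"]])
  z <- if (!is.null(tags[["0020,0032"]])) dcm_ds(tags[["0020,0032"]])[3]
    else if (!is.null(tags[["0020,1041"]])) dcm_ds(tags[["0020,1041"]])
    else fail("no slice position information")
  ps <- if (!is.null(tags[["0028,0030"]])) dcm_ds(tags[["0028,0030"]])
    else c(1, 1)
  # DICOM pixel data is row-major; build the [rows, cols] = [y, x] matrix
  slice <- t(matrix(px, nrow = cols, ncol = rows))
  list(hu = slice * slope + icept, z = z,
       series_uid = tags[["0020,000e"]], pixel_spacing = ps)
}

load_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0)
    stop("no files in DICOM directory '", path, "'", call. = FALSE)
  slices <- lapply(files, parse_dicom_file)
  uids <- unique(vapply(slices, function(s)
    if (is.null(s$series_uid)) "" else s$series_uid, ""))
  if (length(uids) > 1)
    stop("directory mixes ", length(uids), " DICOM series", call. = FALSE)
  zs <- vapply(slices, `[[`, 0, "z")
  ord <- order(zs)  # caudal to cranial (DICOM patient z grows cranially)
  slices <- slices[ord]; zs <- zs[ord]
  dz <- if (length(zs) > 1) median(diff(zs)) else 1
  if (dz <= 0) stop("non-increasing slice positions", call. = FALSE)
  first <- slices[[1]]
  vox <- array(0, dim = c(length(slices), nrow(first$hu), ncol(first$hu)))
  for (k in seq_along(slices)) {
    if (!all(dim(slices[[k]]$hu) == dim(first$hu)))
      stop("inconsistent slice dimensions in series", call. = FALSE)
    vox[k, , ] <- slices[[k]]$hu
  }
  ct_volume(vox, c(dz, first$pixel_spacing[1], first$pixel_spacing[2]),
            origin_mm = c(zs[1], 0, 0))
}
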