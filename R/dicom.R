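# Minimal DICOM I/O: explicit-VR little-endian, uncompressed MONOCHROME2
# 16-bit pixel data. Covers exactly the attributes the pipeline needs
# (patient id, instance number, orientation/plane, sequence tag, matrix
# size, pixels). Written because no R DICOM package is available; files are
# standard and readable by any conformant DICOM toolkit.

.uid_root <- "1.2.826.0.1.3680043.10.1491"
.sop_mr <- "1.2.840.10008.5.1.4.1.1.4"
.ts_explicit_le <- "1.2.840.10008.1.2.1"

# plane tag <-> ImageOrientationPatient direction cosines
.plane_orientations <- list(
  axial    = c(1, 0, 0, 0, 1, 0),
  sagittal = c(0, 1, 0, 0, 0, 1),
  coronal  = c(1, 0, 0, 0, 0, 1)
)

.pad_even <- function(raw, pad = as.raw(0L)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

.str_val <- function(x, pad = as.raw(0x20)) .pad_even(charToRaw(x), pad)

# one explicit-VR element; OB/OW use the 4-byte length form
.dcm_element <- function(group, elem, vr, value_raw) {
  head <- c(
    writeBin(as.integer(group), raw(), size = 2, endian = "little"),
    writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
    charToRaw(vr)
  )
  if (vr %in% c("OB", "OW")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(head, writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

.us_val <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

#' Write one MRI slice as a DICOM file
#'
#' Serializes a single square pixel matrix plus the slice metadata the
#' preprocessing pipeline consumes. Output is an explicit-VR little-endian
#' MR Image Storage object with unsigned 16-bit pixels.
#'
#' @param path Output file path.
#' @param pixels Integer matrix (square) of pixel intensities in
#'   `[0, 65535]`.
#' @param patient_id Patient identifier string.
#' @param instance_number Positive integer acquisition index.
#' @param plane One of `"axial"`, `"sagittal"`, `"coronal"` (encoded as
#'   ImageOrientationPatient direction cosines).
#' @param sequence Sequence tag, e.g. `"T1W"`, `"T2W"`, `"FLAIR"` (stored in
#'   SequenceName and the series description).
#' @return `path`, invisibly.
#' @seealso [dcm_read()], [write_cohort()]
#' @export
dcm_write <- function(path, pixels, patient_id, instance_number,
                      plane = "axial", sequence = "T2W") {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  plane <- match.arg(plane, names(.plane_orientations))
  px <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  if (anyNA(px) || any(px < 0L) || any(px > 65535L)) {
    abort("dcm_write: pixels must be integers in [0, 65535]")
  }
  rows <- nrow(pixels); cols <- ncol(pixels)
  sop_uid <- paste(.uid_root, patient_id_hash(patient_id), sequence_code(sequence),
                   match(plane, names(.plane_orientations)), instance_number,
                   sep = ".")
  series_uid <- paste(.uid_root, patient_id_hash(patient_id),
                      sequence_code(sequence),
                      match(plane, names(.plane_orientations)), sep = ".")

  meta <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dcm_element(0x0002, 0x0002, "UI", .str_val(.sop_mr, as.raw(0))),
    .dcm_element(0x0002, 0x0003, "UI", .str_val(sop_uid, as.raw(0))),
    .dcm_element(0x0002, 0x0010, "UI", .str_val(.ts_explicit_le, as.raw(0))),
    .dcm_element(0x0002, 0x0012, "UI", .str_val(.uid_root, as.raw(0)))
  )
  group_len <- .dcm_element(0x0002, 0x0000, "UL",
                            writeBin(length(meta), raw(), size = 4,
                                     endian = "little"))

  orient <- paste(sprintf("%d", .plane_orientations[[plane]]), collapse = "\\")
  # row-major pixel order per the standard
  pix_raw <- writeBin(as.integer(t(px)), raw(), size = 2, endian = "little")

  body <- c(
    .dcm_element(0x0008, 0x0016, "UI", .str_val(.sop_mr, as.raw(0))),
    .dcm_element(0x0008, 0x0018, "UI", .str_val(sop_uid, as.raw(0))),
    .dcm_element(0x0008, 0x0060, "CS", .str_val("MR")),
    .dcm_element(0x0008, 0x103E, "LO", .str_val(paste(sequence, plane))),
    .dcm_element(0x0010, 0x0020, "LO", .str_val(patient_id)),
    .dcm_element(0x0018, 0x0024, "SH", .str_val(sequence)),
    .dcm_element(0x0020, 0x000E, "UI", .str_val(series_uid, as.raw(0))),
    .dcm_element(0x0020, 0x0013, "IS", .str_val(as.character(instance_number))),
    .dcm_element(0x0020, 0x0037, "DS", .str_val(orient)),
    .dcm_element(0x0028, 0x0002, "US", .us_val(1)),
    .dcm_element(0x0028, 0x0004, "CS", .str_val("MONOCHROME2")),
    .dcm_element(0x0028, 0x0010, "US", .us_val(rows)),
    .dcm_element(0x0028, 0x0011, "US", .us_val(cols)),
    .dcm_element(0x0028, 0x0100, "US", .us_val(16)),
    .dcm_element(0x0028, 0x0101, "US", .us_val(16)),
    .dcm_element(0x0028, 0x0102, "US", .us_val(15)),
    .dcm_element(0x0028, 0x0103, "US", .us_val(0)),
    .dcm_element(0x7FE0, 0x0010, "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), group_len, meta, body), con)
  invisible(path)
}

patient_id_hash <- function(id) {
  sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 99991L
}

sequence_code <- function(sequence) {
  code <- match(sequence, c("T1W", "T2W", "FLAIR"))
  if (is.na(code)) 9L else code
}

#' Read one DICOM slice
#'
#' Parses an explicit-VR little-endian DICOM file and returns the slice
#' metadata and pixel matrix. The plane is decoded from
#' ImageOrientationPatient and the sequence from SequenceName.
#'
#' @param path DICOM file path.
#' @return A list with `patient_id`, `instance_number`, `plane`, `sequence`,
#'   `rows`, `cols` and the integer `pixels` matrix.
#' @export
dcm_read <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 160 || rawToChar(bytes[129:132]) != "DICM") {
    abort(sprintf("not a DICOM file: %s", path))
  }
  pos <- 133L
  u16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(bytes[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  fields <- list()
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- u32(pos + 8L); data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); data_at <- pos + 8L
    }
    if (len < 0 || data_at + len - 1L > length(bytes)) {
      abort(sprintf("truncated DICOM element at byte %d: %s", pos, path))
    }
    val <- if (len > 0) bytes[data_at:(data_at + len - 1L)] else raw(0)
    key <- sprintf("%04X%04X", group, elem)
    fields[[key]] <- list(vr = vr, val = val)
    pos <- data_at + len
  }
  need <- function(key, what) {
    if (is.null(fields[[key]])) abort(sprintf("missing %s in %s", what, path))
    fields[[key]]
  }
  str_of <- function(key) trimws(gsub("\\x00", "", rawToChar(need(key, key)$val),
                                      fixed = TRUE, useBytes = TRUE))
  rows <- readBin(need("00280010", "Rows")$val, "integer", size = 2,
                  endian = "little", signed = FALSE)
  cols <- readBin(need("00280011", "Columns")$val, "integer", size = 2,
                  endian = "little", signed = FALSE)
  orient <- as.numeric(strsplit(str_of("00200037"), "\\", fixed = TRUE)[[1]])
  plane <- .decode_plane(orient)
  seq_name <- str_of("00180024")
  if (!seq_name %in% c("T1W", "T2W", "FLAIR")) seq_name <- "other"
  pix <- need("7FE00010", "PixelData")$val
  if (length(pix) != 2L * rows * cols) {
    abort(sprintf("pixel data length mismatch in %s", path))
  }
  vals <- readBin(pix, "integer", n = rows * cols, size = 2,
                  endian = "little", signed = FALSE)
  list(
    patient_id = str_of("00100020"),
    instance_number = as.integer(str_of("00200013")),
    plane = plane,
    sequence = seq_name,
    rows = rows,
    cols = cols,
    pixels = matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  )
}

.decode_plane <- function(orient) {
  if (length(orient) != 6 || anyNA(orient)) return("unknown")
  hit <- vapply(.plane_orientations, function(o) all(abs(o - orient) < 1e-4),
                logical(1))
  if (any(hit)) names(.plane_orientations)[which(hit)[1]] else "unknown"
}
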