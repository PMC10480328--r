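# Minimal DICOM Part 10 codec: enough of PS3.5 to read and write RT Plan
# (SOP class 1.2.840.10008.5.1.4.1.1.481.5) instances. Supports the two
# little-endian transfer syntaxes (implicit 1.2.840.10008.1.2 and explicit
# 1.2.840.10008.1.2.1), nested sequences with defined or undefined lengths,
# and the string/numeric VRs the RT Plan module uses. Not a general DICOM
# toolkit: big-endian and deflated syntaxes, and pixel data, are rejected.

UID_RTPLAN_STORAGE <- "1.2.840.10008.5.1.4.1.1.481.5"
UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_VR_LE <- "1.2.840.10008.1.2"
UID_IMPL_CLASS     <- "1.2.826.0.1.3680043.9.7435.1"
UID_ROOT           <- "1.2.826.0.1.3680043.9.7435"

# VRs with the 4-byte length form in explicit VR encoding
.VR_LONG <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# tag dictionary: the attributes this package reads or writes.
# Needed to resolve VRs under implicit VR little endian.
.DCM_DICT <- local({
  d <- rbind(
    c("00020002", "UI"), c("00020003", "UI"), c("00020010", "UI"),
    c("00020012", "UI"), c("00020013", "SH"),
    c("00080016", "UI"), c("00080018", "UI"), c("00080060", "CS"),
    c("00080070", "LO"), c("00100010", "PN"), c("00100020", "LO"),
    c("300A0002", "SH"), c("300A0003", "LO"), c("300A000A", "CS"),
    c("300A0070", "SQ"), c("300A0071", "IS"), c("300A0078", "IS"),
    c("300A0079", "IS"), c("300A0080", "IS"), c("300A00A0", "IS"),
    c("300A00B0", "SQ"), c("300A00C0", "IS"), c("300A00C2", "LO"),
    c("300A00C4", "CS"), c("300A00C6", "CS"), c("300A00CE", "CS"),
    c("300A010E", "DS"), c("300A0110", "IS"), c("300A0111", "SQ"),
    c("300A0112", "IS"), c("300A011E", "DS"), c("300A011F", "CS"),
    c("300A0134", "DS"),
    c("300C0004", "SQ"), c("300C0006", "IS"),
    c("300A0084", "DS"), c("300A0086", "DS")
  )
  stats::setNames(d[, 2], d[, 1])
})

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32le <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  c(.u16le(lo), .u16le(hi))
}

.tag_key <- function(group, elem) sprintf("%04X%04X", group, elem)

# ---- encoding -------------------------------------------------------------

.dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.dcm_value_bytes <- function(vr, value) {
  if (vr %in% c("UI")) {
    .dcm_pad(charToRaw(paste(value, collapse = "\\")), as.raw(0x00))
  } else if (vr %in% c("SH", "LO", "CS", "PN", "DA", "TM", "ST", "LT", "AE")) {
    .dcm_pad(charToRaw(paste(value, collapse = "\\")))
  } else if (vr == "IS") {
    .dcm_pad(charToRaw(paste(format(as.integer(value), trim = TRUE,
                                    scientific = FALSE), collapse = "\\")))
  } else if (vr == "DS") {
    # DS is limited to 16 bytes per value; %.10g stays within that
    .dcm_pad(charToRaw(paste(sprintf("%.10g", as.numeric(value)),
                             collapse = "\\")))
  } else if (vr == "UL") {
    do.call(c, lapply(value, .u32le))
  } else if (vr == "US") {
    do.call(c, lapply(value, .u16le))
  } else if (vr == "FD") {
    writeBin(as.numeric(value), raw(), size = 8L, endian = "little")
  } else if (vr %in% c("OB", "UN")) {
    .dcm_pad(as.raw(value), as.raw(0x00))
  } else {
    stop("unsupported VR for encoding: ", vr)
  }
}

# one data element, explicit VR little endian
dcm_element <- function(group, elem, vr, value) {
  bytes <- if (vr == "SQ") value else .dcm_value_bytes(vr, value)
  head <- c(.u16le(group), .u16le(elem), charToRaw(vr))
  if (vr %in% .VR_LONG) {
    c(head, as.raw(c(0, 0)), .u32le(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534L) stop("value too long for short-form VR ", vr)
    c(head, .u16le(length(bytes)), bytes)
  }
}

# sequence of items; each item is the concatenated raw encoding of a dataset
dcm_sequence <- function(group, elem, items) {
  body <- raw(0)
  for (it in items) {
    body <- c(body, .u16le(0xFFFE), .u16le(0xE000), .u32le(length(it)), it)
  }
  dcm_element(group, elem, "SQ", body)
}

# Part 10 file: 128-byte preamble, "DICM", group-0002 meta, then the dataset
# in explicit VR little endian.
dcm_write_file <- function(path, dataset_bytes, sop_class_uid, sop_instance_uid) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", c(0x00, 0x01)),
    dcm_element(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_element(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE),
    dcm_element(0x0002, 0x0012, "UI", UID_IMPL_CLASS)
  )
  out <- c(raw(128), charToRaw("DICM"),
           dcm_element(0x0002, 0x0000, "UL", length(meta)),
           meta, dataset_bytes)
  writeBin(out, path)
  invisible(path)
}

# deterministic-ish UID from a seed string; uniqueness only matters within a
# generated cohort so a hash of the label is sufficient
dcm_make_uid <- function(label) {
  h <- utils::head(strtoi(
    substring(paste(sprintf("%02d", utf8ToInt(label) %% 100), collapse = ""),
              1, 18), 10L), 1)
  if (is.na(h)) h <- 0
  paste0(UID_ROOT, ".", abs(h) %% 1e9, ".", nchar(label))
}

# ---- decoding -------------------------------------------------------------

.rd_u16 <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}
.rd_u32 <- function(buf, pos) {
  as.numeric(buf[pos]) + 256 * as.numeric(buf[pos + 1L]) +
    65536 * as.numeric(buf[pos + 2L]) + 16777216 * as.numeric(buf[pos + 3L])
}

.parse_string <- function(bytes) {
  s <- rawToChar(bytes[bytes != as.raw(0x00)])
  sub("[ ]+$", "", s)
}
.split_multi <- function(s) strsplit(s, "\\", fixed = TRUE)[[1]]

.parse_value <- function(vr, bytes) {
  if (length(bytes) == 0) {
    return(switch(vr, IS = integer(0), DS = numeric(0),
                  UL = numeric(0), US = integer(0), FD = numeric(0),
                  character(0)))
  }
  switch(vr,
    UI = , SH = , LO = , CS = , PN = , DA = , TM = , AE = , ST = , LT = , UT =
      .split_multi(.parse_string(bytes)),
    IS = as.integer(.split_multi(.parse_string(bytes))),
    DS = as.numeric(.split_multi(.parse_string(bytes))),
    UL = vapply(seq_len(length(bytes) / 4L),
                function(i) .rd_u32(bytes, 4L * (i - 1L) + 1L), numeric(1)),
    US = vapply(seq_len(length(bytes) / 2L),
                function(i) .rd_u16(bytes, 2L * (i - 1L) + 1L), integer(1)),
    FD = readBin(bytes, numeric(), n = length(bytes) / 8L, size = 8L,
                 endian = "little"),
    bytes)
}

# parse the elements of one dataset in buf[pos:end]; returns a named list
# keyed by "GGGGEEEE". SQ values are lists of item datasets.
.parse_dataset <- function(buf, pos, end, explicit) {
  out <- list()
  while (pos <= end) {
    group <- .rd_u16(buf, pos); elem <- .rd_u16(buf, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFE) {  # item/sequence delimiters at dataset level
      pos <- pos + 4L
      next
    }
    key <- .tag_key(group, elem)
    if (explicit) {
      vr <- rawToChar(buf[pos:(pos + 1L)])
      if (vr %in% .VR_LONG) {
        len <- .rd_u32(buf, pos + 4L); pos <- pos + 8L
      } else {
        len <- .rd_u16(buf, pos + 2L); pos <- pos + 4L
      }
    } else {
      vr <- if (key %in% names(.DCM_DICT)) .DCM_DICT[[key]] else "UN"
      len <- .rd_u32(buf, pos); pos <- pos + 4L
    }
    undefined <- (len == 4294967295)
    if (vr == "SQ" || (undefined && vr == "UN")) {
      parsed <- .parse_sequence(buf, pos, if (undefined) NA else len, explicit)
      out[[key]] <- list(vr = "SQ", value = parsed$items)
      pos <- parsed$pos
    } else {
      if (undefined) stop("undefined length on non-sequence element ", key)
      val_bytes <- if (len > 0) buf[pos:(pos + len - 1L)] else raw(0)
      out[[key]] <- list(vr = vr, value = .parse_value(vr, val_bytes))
      pos <- pos + len
    }
  }
  out
}

.parse_sequence <- function(buf, pos, len, explicit) {
  items <- list()
  end <- if (is.na(len)) length(buf) else pos + len - 1L
  while (pos <= end) {
    group <- .rd_u16(buf, pos); elem <- .rd_u16(buf, pos + 2L)
    ilen <- .rd_u32(buf, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && elem == 0xE0DD) break       # sequence delimiter
    if (!(group == 0xFFFE && elem == 0xE000)) {
      stop("malformed sequence: expected item tag, got ",
           .tag_key(group, elem))
    }
    if (ilen == 4294967295) {  # undefined-length item: scan to its delimiter
      iend <- .find_item_end(buf, pos, explicit)
      items[[length(items) + 1L]] <- .parse_dataset(buf, pos, iend - 1L, explicit)
      pos <- iend + 8L
    } else {
      items[[length(items) + 1L]] <-
        .parse_dataset(buf, pos, pos + ilen - 1L, explicit)
      pos <- pos + ilen
    }
  }
  list(items = items, pos = pos)
}

# locate the ItemDelimitationItem matching an undefined-length item by walking
# element headers (nested undefined-length constructs included)
.find_item_end <- function(buf, pos, explicit) {
  depth <- 0L
  while (pos + 7L <= length(buf)) {
    group <- .rd_u16(buf, pos); elem <- .rd_u16(buf, pos + 2L)
    if (group == 0xFFFE) {
      if (elem == 0xE00E && depth == 0L) return(pos)
      if (elem %in% c(0xE00E, 0xE0DD) && depth > 0L) depth <- depth - 1L
      if (elem == 0xE000) {
        ilen <- .rd_u32(buf, pos + 4L)
        if (ilen == 4294967295) depth <- depth + 1L
        else { pos <- pos + 8L + ilen; next }
      }
      pos <- pos + 8L
      next
    }
    if (explicit) {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (vr %in% .VR_LONG) { len <- .rd_u32(buf, pos + 8L); hdr <- 12L }
      else { len <- .rd_u16(buf, pos + 6L); hdr <- 8L }
    } else {
      len <- .rd_u32(buf, pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) { depth <- depth + 1L; pos <- pos + hdr }
    else pos <- pos + hdr + len
  }
  stop("unterminated undefined-length item")
}

# read a Part 10 file into (meta, dataset) element lists
dcm_read_file <- function(path) {
  buf <- readBin(path, raw(), n = file.size(path))
  if (length(buf) < 140 ||
      !identical(rawToChar(buf[129:132]), "DICM")) {
    stop_not_rtplan(path, "missing DICM magic (not a DICOM Part 10 file)")
  }
  pos <- 133L
  # file meta group (0002) is always explicit VR little endian
  meta <- list()
  while (pos + 7L <= length(buf) && .rd_u16(buf, pos) == 0x0002) {
    group <- .rd_u16(buf, pos); elem <- .rd_u16(buf, pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% .VR_LONG) {
      len <- .rd_u32(buf, pos + 8L); hdr <- 12L
    } else {
      len <- .rd_u16(buf, pos + 6L); hdr <- 8L
    }
    val <- if (len > 0) buf[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    meta[[.tag_key(group, elem)]] <- list(vr = vr, value = .parse_value(vr, val))
    pos <- pos + hdr + len
  }
  ts <- meta[["00020010"]]$value
  if (is.null(ts)) stop_not_rtplan(path, "no transfer syntax in file meta")
  explicit <- switch(ts,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2"   = FALSE,
    stop("unsupported transfer syntax: ", ts))
  ds <- .parse_dataset(buf, pos, length(buf), explicit)
  list(meta = meta, dataset = ds)
}

# convenience accessors over parsed datasets
dcm_get <- function(ds, key, default = NULL) {
  el <- ds[[key]]
  if (is.null(el)) default else el$value
}
dcm_has <- function(ds, key) !is.null(ds[[key]])
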