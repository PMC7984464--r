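# Minimal DICOM encoder/decoder: explicit VR little endian only, which is
# what this package writes and what mainstream TPS exports use. Enough of the
# standard to carry RT-DOSE and RT-STRUCT payloads; not a general toolkit.

EXPLICIT_LE_UID <- "1.2.840.10008.1.2.1"
UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
# implementation UID under the UUID-derived numeric root
UID_IMPL <- "2.25.313831415926535897932384626433832795"

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_new_uid <- function() {
  paste0("2.25.", paste0(sample.int(10, 30, replace = TRUE) - 1L, collapse = ""))
}

# ---- encoding -------------------------------------------------------------

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  c(raw_u16(lo), raw_u16(hi))
}

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

encode_value <- function(vr, value) {
  if (vr %in% c("UI")) {
    pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0x00))
  } else if (vr %in% c("DS", "IS")) {
    # DS values are limited to 16 bytes; fall back to exponent notation
    fmt1 <- function(v) {
      s <- format(v, digits = 12, trim = TRUE, scientific = FALSE)
      if (nchar(s) > 16) s <- sprintf("%.10e", v)
      if (nchar(s) > 16) s <- sprintf("%.9e", v)
      s
    }
    txt <- paste(vapply(value, fmt1, character(1)), collapse = "\\")
    pad_even(charToRaw(txt))
  } else if (vr %in% c("CS", "LO", "SH", "PN", "DA", "TM", "ST", "LT", "AE")) {
    pad_even(charToRaw(paste(value, collapse = "\\")))
  } else if (vr == "US") {
    raw_u16(value)
  } else if (vr == "UL") {
    do.call(c, lapply(value, raw_u32))
  } else if (vr == "FD") {
    writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr == "FL") {
    writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  } else if (vr %in% c("OW", "OB")) {
    stopifnot(is.raw(value))
    pad_even(value, as.raw(0x00))
  } else {
    rlang::abort(paste0("unsupported VR for encoding: ", vr))
  }
}

# one data element; `value` already encoded for SQ (list of item raws)
encode_element <- function(group, element, vr, value) {
  tag <- c(raw_u16(group), raw_u16(element))
  if (vr == "SQ") {
    body <- do.call(c, c(list(raw(0)), lapply(value, function(item) {
      c(raw_u16(0xFFFE), raw_u16(0xE000), raw_u32(length(item)), item)
    })))
    c(tag, charToRaw("SQ"), as.raw(c(0, 0)), raw_u32(length(body)), body)
  } else {
    body <- encode_value(vr, value)
    if (vr %in% LONG_VRS) {
      c(tag, charToRaw(vr), as.raw(c(0, 0)), raw_u32(length(body)), body)
    } else {
      c(tag, charToRaw(vr), raw_u16(length(body)), body)
    }
  }
}

# elements: list of list(group, element, vr, value); must be pre-sorted
encode_dataset <- function(elements) {
  do.call(c, c(list(raw(0)), lapply(elements, function(e) {
    encode_element(e$group, e$element, e$vr, e$value)
  })))
}

el <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

# Write a complete Part-10 file: preamble, DICM, file meta, dataset.
write_dicom_file <- function(path, sop_class_uid, sop_instance_uid, elements) {
  meta <- encode_dataset(list(
    el(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    el(0x0002, 0x0002, "UI", sop_class_uid),
    el(0x0002, 0x0003, "UI", sop_instance_uid),
    el(0x0002, 0x0010, "UI", EXPLICIT_LE_UID),
    el(0x0002, 0x0012, "UI", UID_IMPL)
  ))
  group_len <- encode_element(0x0002, 0x0000, "UL", length(meta))
  body <- encode_dataset(elements)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, body), con)
  invisible(path)
}

# ---- decoding -------------------------------------------------------------

dec_u16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}
dec_u32 <- function(bytes, at) {
  # as double: lengths can exceed .Machine$integer.max (undefined = 2^32-1)
  as.numeric(bytes[at]) + 256 * as.numeric(bytes[at + 1L]) +
    65536 * as.numeric(bytes[at + 2L]) + 16777216 * as.numeric(bytes[at + 3L])
}

decode_value <- function(vr, bytes) {
  txt <- function() {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    trimws(s)
  }
  split_txt <- function() strsplit(txt(), "\\", fixed = TRUE)[[1]]
  switch(vr,
    DS = as.numeric(split_txt()),
    IS = as.integer(split_txt()),
    UI = txt(),
    CS = , LO = , SH = , PN = , DA = , TM = , ST = , LT = , AE = split_txt(),
    US = {
      n <- length(bytes) %/% 2L
      readBin(bytes, "integer", n = n, size = 2, signed = FALSE,
              endian = "little")
    },
    UL = vapply(seq_len(length(bytes) %/% 4L),
                function(i) dec_u32(bytes, 4L * (i - 1L) + 1L), numeric(1)),
    FD = readBin(bytes, "double", n = length(bytes) %/% 8L, size = 8,
                 endian = "little"),
    FL = readBin(bytes, "double", n = length(bytes) %/% 4L, size = 4,
                 endian = "little"),
    bytes  # OW/OB/UN and anything else: keep raw
  )
}

tag_key <- function(group, element) sprintf("%04x%04x", group, element)

# Parse a dataset from `bytes` starting at `pos` (1-based), stopping at
# `end` (inclusive) or at a sequence/item delimiter. Returns list(ds, pos).
parse_dataset <- function(bytes, pos, end, stop_tag = NULL) {
  ds <- list()
  while (pos <= end) {
    group <- dec_u16(bytes, pos); element <- dec_u16(bytes, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFE) {
      len <- dec_u32(bytes, pos); pos <- pos + 4L
      if (element %in% c(0xE00D, 0xE0DD)) {
        # item / sequence delimiter: caller handles
        return(list(ds = ds, pos = pos, delimiter = element))
      }
      rlang::abort("unexpected item tag outside a sequence.")
    }
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      rlang::abort(
        "cannot parse data element: only explicit VR little endian is supported.")
    }
    if (vr %in% LONG_VRS) {
      len <- dec_u32(bytes, pos + 4L)
      pos <- pos + 8L
    } else {
      len <- dec_u16(bytes, pos + 2L)
      pos <- pos + 4L
    }
    undefined <- len >= 4294967295
    if (vr == "SQ" || (undefined && vr == "UN")) {
      seq_end <- if (undefined) length(bytes) else pos + len - 1
      items <- list()
      while (pos <= seq_end) {
        ig <- dec_u16(bytes, pos); ie <- dec_u16(bytes, pos + 2L)
        ilen <- dec_u32(bytes, pos + 4L)
        pos <- pos + 8L
        if (ig == 0xFFFE && ie == 0xE0DD) break     # sequence delimiter
        if (!(ig == 0xFFFE && ie == 0xE000)) {
          rlang::abort("malformed sequence: expected an item tag.")
        }
        if (ilen >= 4294967295) {                    # undefined-length item
          res <- parse_dataset(bytes, pos, length(bytes))
          items[[length(items) + 1L]] <- res$ds
          pos <- res$pos
        } else {
          res <- parse_dataset(bytes, pos, pos + ilen - 1)
          items[[length(items) + 1L]] <- res$ds
          pos <- pos + ilen
        }
      }
      ds[[tag_key(group, element)]] <- list(vr = "SQ", value = items)
    } else {
      if (undefined) rlang::abort("undefined length on a non-sequence element.")
      val <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
      ds[[tag_key(group, element)]] <- list(vr = vr,
                                            value = decode_value(vr, val))
      pos <- pos + len
    }
  }
  list(ds = ds, pos = pos, delimiter = NA)
}

read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    rlang::abort(paste0("not a DICOM Part-10 file: ", path))
  }
  parsed <- parse_dataset(bytes, 133L, length(bytes))
  ds <- parsed$ds
  ts <- ds[["00020010"]]
  if (!is.null(ts) && !identical(ts$value, EXPLICIT_LE_UID)) {
    rlang::abort(paste0("unsupported transfer syntax: ", ts$value,
                        " (only explicit VR little endian is supported)."))
  }
  ds
}

dcm_get <- function(ds, group, element, required = TRUE, what = NULL) {
  e <- ds[[tag_key(group, element)]]
  if (is.null(e)) {
    if (required) {
      rlang::abort(sprintf("missing required DICOM element (%04X,%04X)%s",
                           group, element,
                           if (is.null(what)) "" else paste0(" [", what, "]")))
    }
    return(NULL)
  }
  e$value
}
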