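# Minimal DICOM reader covering the RTPLAN / RTDOSE element subset used by
# this package. Supports Part-10 files in the Explicit VR Little Endian
# transfer syntax (1.2.840.10008.1.2.1), including nested sequences with
# defined or undefined lengths. Elements are returned in a nested list keyed
# by "GGGGEEEE" hex tags; sequences become lists of item datasets.

.tag <- function(group, elem) sprintf("%04X%04X", group, elem)

.u16 <- function(r, p) {
  readBin(r[p:(p + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
}

.u32 <- function(r, p) {
  v <- readBin(r[p:(p + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 4294967296
  v
}

.dicom_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                       "PN", "SH", "ST", "TM", "UI", "UT")

.decode_value <- function(vr, bytes) {
  n <- length(bytes)
  if (n == 0L) return(NULL)
  if (vr %in% .dicom_string_vrs) {
    s <- rawToChar(bytes[bytes != as.raw(0L)])
    s <- sub("[ ]+$", "", s)
    parts <- strsplit(s, "\\\\")[[1L]]
    if (vr == "DS") return(as.numeric(parts))
    if (vr == "IS") return(as.integer(parts))
    return(parts)
  }
  switch(vr,
    US = readBin(bytes, "integer", n = n %/% 2L, size = 2L,
                 endian = "little", signed = FALSE),
    SS = readBin(bytes, "integer", n = n %/% 2L, size = 2L,
                 endian = "little", signed = TRUE),
    UL = {
      v <- readBin(bytes, "integer", n = n %/% 4L, size = 4L,
                   endian = "little")
      ifelse(v < 0, v + 4294967296, v)
    },
    SL = readBin(bytes, "integer", n = n %/% 4L, size = 4L,
                 endian = "little"),
    FL = readBin(bytes, "numeric", n = n %/% 4L, size = 4L,
                 endian = "little"),
    FD = readBin(bytes, "numeric", n = n %/% 8L, size = 8L,
                 endian = "little"),
    bytes)  # OB/OW/UN and anything else stay raw
}

# Parse one explicit-VR element at `pos`; returns list(tag, value, next_pos).
.parse_element <- function(r, pos) {
  group <- .u16(r, pos); elem <- .u16(r, pos + 2L)
  vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    len <- .u32(r, pos + 8L)
    data_pos <- pos + 12L
  } else {
    len <- .u16(r, pos + 6L)
    data_pos <- pos + 8L
  }
  if (vr == "SQ") {
    sq <- .parse_sequence(r, data_pos, len)
    return(list(tag = .tag(group, elem), value = sq$items,
                next_pos = sq$next_pos))
  }
  if (len == 4294967295)
    stop_imrtqa("undefined-length non-sequence element ",
                .tag(group, elem), " not supported")
  value <- .decode_value(vr, if (len > 0L) r[data_pos:(data_pos + len - 1L)]
                         else raw(0L))
  list(tag = .tag(group, elem), value = value, next_pos = data_pos + len)
}

# Parse sequence items starting at `pos`; `len` is the byte length or the
# undefined-length sentinel. Returns list(items, next_pos).
.parse_sequence <- function(r, pos, len) {
  undefined <- len == 4294967295
  end <- if (undefined) length(r) else pos + len
  items <- list()
  while (pos < end) {
    g <- .u16(r, pos); e <- .u16(r, pos + 2L)
    ilen <- .u32(r, pos + 4L)
    pos <- pos + 8L
    if (g == 0xFFFE && e == 0xE0DD) break            # sequence delimiter
    if (!(g == 0xFFFE && e == 0xE000))
      stop_imrtqa("malformed sequence: expected item tag at byte ", pos - 8L)
    if (ilen == 4294967295) {
      parsed <- .parse_dataset(r, pos, length(r), stop_at_item_delim = TRUE)
    } else {
      parsed <- .parse_dataset(r, pos, pos + ilen, stop_at_item_delim = FALSE)
    }
    items[[length(items) + 1L]] <- parsed$elements
    pos <- parsed$next_pos
  }
  list(items = items, next_pos = pos)
}

.parse_dataset <- function(r, pos, end, stop_at_item_delim = FALSE) {
  out <- list()
  while (pos < end) {
    if (stop_at_item_delim) {
      g <- .u16(r, pos); e <- .u16(r, pos + 2L)
      if (g == 0xFFFE && e == 0xE00D) { pos <- pos + 8L; break }
    }
    el <- .parse_element(r, pos)
    out[[el$tag]] <- el$value
    pos <- el$next_pos
  }
  list(elements = out, next_pos = pos)
}

#' Parse a DICOM Part-10 file (explicit VR little endian)
#'
#' Low-level reader behind [read_rtplan()] and [read_rtdose()]. Returns the
#' full data set as a nested list keyed by `"GGGGEEEE"` tag strings, with
#' sequences as lists of item datasets and pixel data left as raw bytes.
#'
#' @param path Path to a DICOM file.
#' @return Named list of decoded elements.
#' @export
read_dicom <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140L || rawToChar(r[129:132]) != "DICM")
    stop_imrtqa("not a DICOM Part-10 file: ", path)
  # file meta group (0002,xxxx) is always explicit VR little endian
  meta <- list()
  pos <- 133L
  while (pos < length(r) && .u16(r, pos) == 2L) {
    el <- .parse_element(r, pos)
    meta[[el$tag]] <- el$value
    pos <- el$next_pos
  }
  ts <- meta[["00020010"]]
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop_imrtqa("unsupported transfer syntax ", ts,
                " (only explicit VR little endian is supported)")
  .parse_dataset(r, pos, length(r))$elements
}

.dicom_get <- function(ds, tag, what, context = NULL) {
  v <- ds[[tag]]
  if (is.null(v))
    stop_imrtqa("RT file missing ", what, " (", tag, ")",
                if (!is.null(context)) paste0(" in ", context) else "")
  v
}

#' Read an IMRT plan from a DICOM-RTPLAN file
#'
#' Reads the `BeamSequence`/`ControlPointSequence` subset of an RTPLAN and
#' converts each beam into step-and-shoot [mlc_segment()]s: a beam with K
#' control points yields K-1 segments, segment k using the mean of the MLCX
#' leaf positions at control points k and k+1 (positions are carried forward
#' when a control point omits them) and an MU weight equal to the cumulative
#' meterset weight difference times the beam meterset from the fraction
#' group. Leaf positions are converted from mm to cm and normalized so that
#' the opening is `left - right >= 0` for every pair.
#'
#' @param path Path to a DICOM-RTPLAN file (explicit VR little endian).
#' @return An [rt_plan()].
#' @export
read_rtplan <- function(path) {
  ds <- read_dicom(path)
  beam_items <- .dicom_get(ds, "300A00B0", "BeamSequence")
  fg <- .dicom_get(ds, "300A0070", "FractionGroupSequence")
  ref_beams <- .dicom_get(fg[[1L]], "300C0004", "ReferencedBeamSequence")
  metersets <- new.env()
  for (rb in ref_beams) {
    num <- .dicom_get(rb, "300C0006", "ReferencedBeamNumber")
    mu <- rb[["300A0086"]]
    assign(as.character(num), if (is.null(mu)) 0 else as.numeric(mu),
           envir = metersets)
  }

  beams <- list()
  for (bi in seq_along(beam_items)) {
    b <- beam_items[[bi]]
    beam_num <- b[["300A00C0"]]
    bname <- paste0("beam ", if (is.null(beam_num)) bi else beam_num)
    cps <- b[["300A0111"]]
    if (is.null(cps) || length(cps) < 1L)
      stop_imrtqa("RTPLAN ", bname, ": no control point sequence")
    beam_mu <- get0(as.character(beam_num), envir = metersets,
                    ifnotfound = NULL)
    if (is.null(beam_mu))
      stop_imrtqa("RTPLAN ", bname, ": no BeamMeterset in fraction group")

    gantry <- cps[[1L]][["300A011E"]]
    if (is.null(gantry)) gantry <- 0

    # extract MLCX positions per control point (NULL when absent)
    mlc_at <- lapply(cps, function(cp) {
      bld <- cp[["300A011A"]]
      if (is.null(bld)) return(NULL)
      for (d in bld) {
        if (identical(d[["300A00B8"]], "MLCX")) {
          pos_mm <- d[["300A011C"]]
          if (is.null(pos_mm))
            stop_imrtqa("RTPLAN ", bname, ": MLCX device without positions")
          return(as.numeric(pos_mm) / 10)  # mm -> cm
        }
      }
      NULL
    })
    if (is.null(mlc_at[[1L]]))
      stop_imrtqa("RTPLAN ", bname, ": no MLC positions at first control point")
    nl <- length(mlc_at[[1L]])
    for (m in mlc_at)
      if (!is.null(m) && length(m) != nl)
        stop_imrtqa("RTPLAN ", bname, ": unequal leaf counts across control points")

    cumw <- vapply(cps, function(cp) {
      w <- cp[["300A0134"]]
      if (is.null(w)) NA_real_ else as.numeric(w)
    }, numeric(1))
    final_w <- b[["300A010E"]]
    if (is.null(final_w)) final_w <- max(cumw, na.rm = TRUE)
    final_w <- as.numeric(final_w)
    if (!is.finite(final_w) || final_w <= 0)
      stop_imrtqa("RTPLAN ", bname, ": non-positive final cumulative meterset weight")

    if (length(cps) == 1L) {
      seg_pos <- list(mlc_at[[1L]])
      seg_mu <- beam_mu
    } else {
      # carry positions forward through control points that omit them
      for (k in seq_along(mlc_at)[-1L])
        if (is.null(mlc_at[[k]])) mlc_at[[k]] <- mlc_at[[k - 1L]]
      K <- length(cps)
      seg_pos <- lapply(seq_len(K - 1L), function(k) {
        (mlc_at[[k]] + mlc_at[[k + 1L]]) / 2
      })
      dw <- diff(cumw)
      if (any(!is.finite(dw)))
        stop_imrtqa("RTPLAN ", bname, ": missing cumulative meterset weights")
      seg_mu <- dw / final_w * beam_mu
    }

    A <- nl %/% 2L
    segs <- lapply(seq_along(seg_pos), function(k) {
      p <- seg_pos[[k]]
      right <- p[seq_len(A)]        # bank X1 (negative side)
      left <- p[A + seq_len(A)]     # bank X2
      left <- pmax(left, right)     # normalize rounding-closed pairs
      mlc_segment(left, right, max(seg_mu[k], 0))
    })
    if (beam_mu <= 0)
      stop_imrtqa("RTPLAN ", bname, ": zero-MU beam")
    beams[[length(beams) + 1L]] <-
      rt_beam(gantry_deg = as.numeric(gantry), segments = segs,
              beam_mu = sum(vapply(segs, `[[`, numeric(1), "mu_weight")))
  }
  plan_id <- ds[["00100020"]]
  if (is.null(plan_id)) plan_id <- ds[["300A0002"]]
  if (is.null(plan_id)) plan_id <- basename(path)
  rt_plan(plan_id = as.character(plan_id), beams = beams)
}

#' Read a 3D dose grid from a DICOM-RTDOSE file
#'
#' Decodes the integer pixel array, applies `DoseGridScaling`, and converts
#' the geometry (mm, voxel-center `ImagePositionPatient`) to this package's
#' cm corner-origin convention. Axes map as x = columns, y = rows, z = frames.
#'
#' @param path Path to a DICOM-RTDOSE file (explicit VR little endian,
#'   uncompressed).
#' @return A [dose_grid()] with values in Gy.
#' @export
read_rtdose <- function(path) {
  ds <- read_dicom(path)
  rows <- .dicom_get(ds, "00280010", "Rows")
  cols <- .dicom_get(ds, "00280011", "Columns")
  nframes <- ds[["00280008"]]
  nframes <- if (is.null(nframes)) 1L else as.integer(nframes)
  ps_mm <- .dicom_get(ds, "00280030", "PixelSpacing")    # [row, col]
  gfov <- ds[["3004000C"]]
  dz_mm <- if (is.null(gfov) || length(gfov) < 2L) ps_mm[1L]
           else diff(as.numeric(gfov))[1L]
  ipp_mm <- .dicom_get(ds, "00200032", "ImagePositionPatient")
  scaling <- as.numeric(.dicom_get(ds, "3004000E", "DoseGridScaling"))
  bits <- as.integer(.dicom_get(ds, "00280100", "BitsAllocated"))
  px <- .dicom_get(ds, "7FE00010", "PixelData")
  n <- as.integer(rows) * as.integer(cols) * nframes
  ints <- if (bits == 16L) {
    readBin(px, "integer", n = n, size = 2L, endian = "little",
            signed = FALSE)
  } else if (bits == 32L) {
    v <- readBin(px, "integer", n = n, size = 4L, endian = "little")
    ifelse(v < 0, v + 4294967296, v)
  } else stop_imrtqa("unsupported BitsAllocated: ", bits)
  values <- array(ints * scaling, dim = c(cols, rows, nframes))
  spacing <- c(ps_mm[2L], ps_mm[1L], dz_mm) / 10
  origin <- as.numeric(ipp_mm) / 10 - spacing / 2
  dose_grid(origin = origin, spacing = spacing, values = values)
}
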