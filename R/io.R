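## ---------------------------------------------------------------------------
## Minimal NIfTI-1 and baseline TIFF readers/writers.
##
## No NIfTI or TIFF package is assumed; this implements just the subset the
## package needs: NIfTI-1 single-file (.nii / .nii.gz), datatypes uint8,
## int16, int32, uint16, float32, float64, with scl_slope/scl_inter applied;
## TIFF: little/big-endian baseline, uncompressed, single-sample grayscale
## pages (uint8/uint16/float32), multi-page stacks, one or more strips.
## ---------------------------------------------------------------------------

nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE))

#' Read a NIfTI-1 image
#'
#' Minimal single-file NIfTI-1 reader (`.nii`, `.nii.gz`); returns the data
#' array with `scl_slope`/`scl_inter` applied. Supports the common scalar
#' datatypes; both endiannesses.
#'
#' @param path File path.
#' @return Numeric array with attribute `"pixdim"`.
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path,
                               call. = FALSE)
  rd <- function(off, what, n, size, endian) {
    readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian) != 348L) {
      stop("not a NIfTI-1 file: ", path, call. = FALSE)
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("missing NIfTI magic: ", path,
                                        call. = FALSE)
  dim0 <- rd(40L, "integer", 8L, 2L, endian)
  ndim <- dim0[1L]
  if (ndim < 2L || ndim > 4L) stop("unsupported NIfTI dimensionality ",
                                   ndim, call. = FALSE)
  dims <- dim0[2L:(1L + ndim)]
  datatype <- rd(70L, "integer", 1L, 2L, endian)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype,
                        call. = FALSE)
  pixdim <- rd(76L, "numeric", 8L, 4L, endian)
  vox_offset <- rd(108L, "numeric", 1L, 4L, endian)
  scl_slope <- rd(112L, "numeric", 1L, 4L, endian)
  scl_inter <- rd(116L, "numeric", 1L, 4L, endian)
  skip <- max(round(vox_offset), 348L) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data: ", path, call. = FALSE)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  out <- array(vals, dims)
  attr(out, "pixdim") <- pixdim[2L:(1L + ndim)]
  out
}

#' Write a NIfTI-1 image
#'
#' Minimal single-file little-endian NIfTI-1 writer; data are stored as
#' float32 (default) or float64.
#'
#' @param data Numeric array (2--4 dimensions).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param pixdim Optional per-dimension spacing.
#' @param size Bytes per sample: 4 (float32) or 8 (float64).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = NULL, size = 4L) {
  data <- as.array(data)
  nd <- length(dim(data))
  stopifnot(nd >= 2L, nd <= 4L, size %in% c(4L, 8L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(v, sz) writeBin(as.integer(v), con, size = sz,
                                 endian = "little")
  wf <- function(v, sz = 4L) writeBin(as.numeric(v), con, size = sz,
                                      endian = "little")
  zero <- function(n) writeBin(raw(n), con)
  dim8 <- rep(1L, 8L); dim8[1L] <- nd; dim8[2L:(1L + nd)] <- dim(data)
  pd8 <- rep(1, 8L); pd8[1L] <- 1
  if (!is.null(pixdim)) pd8[2L:(1L + length(pixdim))] <- pixdim

  wi(348L, 4L)                      # sizeof_hdr
  zero(36L)                         # data_type..dim_info
  wi(dim8, 2L)                      # dim
  wf(c(0, 0, 0)); wi(0L, 2L)        # intent_p1..intent_code
  wi(if (size == 4L) 16L else 64L, 2L)   # datatype
  wi(size * 8L, 2L)                 # bitpix
  wi(0L, 2L)                        # slice_start
  wf(pd8)                           # pixdim
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2L); zero(2L)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                 # cal_max..toffset
  wi(c(0L, 0L), 4L)                 # glmax, glmin
  zero(104L)                        # descrip, aux_file
  wi(c(0L, 0L), 2L)                 # qform_code, sform_code
  wf(rep(0, 6L))                    # quaternions / offsets
  wf(rep(0, 12L))                   # srow
  zero(16L)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)   # magic
  zero(4L)                          # extension flag
  wf(as.numeric(data), size)
  invisible(path)
}

## --- TIFF ------------------------------------------------------------------

tiff_read_entries <- function(bytes, off, endian) {
  n_entries <- readBin(bytes[(off + 1L):(off + 2L)], "integer", 1L, 2L,
                       endian = endian, signed = FALSE)
  entries <- list()
  for (i in seq_len(n_entries)) {
    e0 <- off + 2L + (i - 1L) * 12L
    b <- bytes[(e0 + 1L):(e0 + 12L)]
    tag <- readBin(b[1:2], "integer", 1L, 2L, endian = endian,
                   signed = FALSE)
    type <- readBin(b[3:4], "integer", 1L, 2L, endian = endian,
                    signed = FALSE)
    count <- readBin(b[5:8], "integer", 1L, 4L, endian = endian)
    tsize <- c(1L, 1L, 2L, 4L, 8L)[type]
    if (is.na(tsize)) tsize <- 4L
    nbytes <- tsize * count
    valbytes <- if (nbytes <= 4L) b[9:(8L + nbytes)] else {
      voff <- readBin(b[9:12], "integer", 1L, 4L, endian = endian)
      bytes[(voff + 1L):(voff + nbytes)]
    }
    vals <- switch(as.character(type),
      `3` = readBin(valbytes, "integer", count, 2L, endian = endian,
                    signed = FALSE),
      `4` = readBin(valbytes, "integer", count, 4L, endian = endian),
      readBin(valbytes, "integer", count, 1L, endian = endian,
              signed = FALSE))
    entries[[as.character(tag)]] <- vals
  }
  nxt <- readBin(bytes[(off + 2L + n_entries * 12L + 1L):
                       (off + 2L + n_entries * 12L + 4L)],
                 "integer", 1L, 4L, endian = endian)
  list(entries = entries, next_ifd = nxt)
}

#' Read a multi-page TIFF stack
#'
#' Minimal baseline TIFF reader: uncompressed grayscale pages of uint8,
#' uint16 or float32 samples, any strip layout, either endianness. Pages
#' become the last dimension of the returned array.
#'
#' @param path File path.
#' @return Numeric array `width x height x pages` (pages dropped if 1).
#' @export
read_tiff <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  order <- rawToChar(bytes[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file: ", path, call. = FALSE)
  ifd <- readBin(bytes[5:8], "integer", 1L, 4L, endian = endian)
  pages <- list()
  while (ifd != 0L) {
    p <- tiff_read_entries(bytes, ifd, endian)
    e <- p$entries
    w <- e[["256"]]; h <- e[["257"]]
    bps <- if (is.null(e[["258"]])) 1L else e[["258"]][1L]
    comp <- if (is.null(e[["259"]])) 1L else e[["259"]]
    fmt <- if (is.null(e[["339"]])) 1L else e[["339"]][1L]
    if (comp != 1L) stop("compressed TIFF not supported: ", path,
                         call. = FALSE)
    offs <- e[["273"]]; counts <- e[["279"]]
    raw_data <- do.call(c, lapply(seq_along(offs), function(i) {
      bytes[(offs[i] + 1L):(offs[i] + counts[i])]
    }))
    vals <- if (fmt == 3L && bps == 32L) {
      readBin(raw_data, "numeric", w * h, 4L, endian = endian)
    } else if (fmt %in% c(1L, 2L) && bps %in% c(8L, 16L)) {
      readBin(raw_data, "integer", w * h, bps / 8L, endian = endian,
              signed = fmt == 2L)
    } else {
      stop(sprintf("unsupported TIFF sample format %d / %d bits", fmt, bps),
           call. = FALSE)
    }
    pages[[length(pages) + 1L]] <- array(as.numeric(vals), c(w, h))
    ifd <- p$next_ifd
  }
  out <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  if (dim(out)[3L] == 1L) out <- array(out, dim(out)[1:2])
  out
}

#' Write a multi-page float32 TIFF stack
#'
#' Minimal little-endian baseline writer: each page is one uncompressed
#' strip of 32-bit IEEE floats. Values round-trip bit-exactly at float32
#' precision through [read_tiff()].
#'
#' @param data Numeric array `width x height` or `width x height x pages`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(data, path) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L)
  w <- dim(data)[1L]; h <- dim(data)[2L]; np <- dim(data)[3L]
  strip_bytes <- w * h * 4L
  ifd_bytes <- 2L + 10L * 12L + 4L
  data_start <- 8L
  ifd_start <- data_start + np * strip_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2L,
                             endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4L,
                             endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  writeBin(charToRaw("II"), con); w2(42L); w4(ifd_start)
  for (k in seq_len(np)) {
    writeBin(as.numeric(data[, , k]), con, size = 4L, endian = "little")
  }
  for (k in seq_len(np)) {
    w2(10L)
    entry(256L, 4L, 1L, w)                               # ImageWidth
    entry(257L, 4L, 1L, h)                               # ImageLength
    entry(258L, 3L, 1L, 32L)                             # BitsPerSample
    entry(259L, 3L, 1L, 1L)                              # Compression: none
    entry(262L, 3L, 1L, 1L)                              # Photometric
    entry(273L, 4L, 1L, data_start + (k - 1L) * strip_bytes)  # StripOffsets
    entry(277L, 3L, 1L, 1L)                              # SamplesPerPixel
    entry(278L, 4L, 1L, h)                               # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)                     # StripByteCounts
    entry(339L, 3L, 1L, 3L)                              # SampleFormat: IEEE
    w4(if (k < np) ifd_start + k * ifd_bytes else 0L)
  }
  invisible(path)
}

## --- axis / ROI / reference files ------------------------------------------

#' Read and write sampling-axis files
#'
#' CSV (one column named `value`) or JSON (bare list of numbers, or an
#' object with `values` and optionally `kind`).
#'
#' @param path File path (`.csv` or `.json`).
#' @param kind Axis kind, used unless the JSON object carries one.
#' @return A [sampled_axis()].
#' @export
read_axis <- function(path, kind = "echo_time") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    if (is.list(x) && !is.null(x$values)) {
      sampled_axis(x$values, if (!is.null(x$kind)) x$kind else kind)
    } else {
      sampled_axis(as.numeric(x), kind)
    }
  } else {
    df <- utils::read.csv(path)
    if (!"value" %in% names(df)) {
      stop("axis CSV must have a 'value' column", call. = FALSE)
    }
    sampled_axis(df$value, kind)
  }
}

#' @rdname read_axis
#' @param axis A [sampled_axis()] to write.
#' @export
write_axis <- function(axis, path) {
  stopifnot(inherits(axis, "sampled_axis"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(values = axis$values, kind = axis$kind), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(value = axis$values), path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read and write phasor-space ROI files
#'
#' JSON array of objects `{label, color, vertices: [[re, im], ...]}`.
#'
#' @param path File path.
#' @return List of [phasor_roi()]s.
#' @export
read_rois <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  lapply(x, function(r) {
    v <- do.call(rbind, lapply(r$vertices, as.numeric))
    phasor_roi(v, r$label, if (!is.null(r$color)) r$color else "red")
  })
}

#' @rdname read_rois
#' @param rois List of [phasor_roi()]s to write.
#' @export
write_rois <- function(rois, path) {
  if (inherits(rois, "phasor_roi")) rois <- list(rois)
  out <- lapply(rois, function(r) {
    list(label = r$label, color = r$color,
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) as.numeric(r$vertices[i, ])))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reference component set from JSON
#'
#' The JSON object (or array of objects) carries `label` plus either `tau`
#' (resolved to a phasor on the supplied axis, i.e. on the reference locus)
#' or raw `re`/`im` coordinates (off-locus references).
#'
#' @param path File path.
#' @param axis A [sampled_axis()], required when any reference is given as a
#'   tau value.
#' @return A [component_set()].
#' @export
read_components <- function(path, axis = NULL) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  pts <- list(); labels <- character(0); taus <- numeric(0)
  for (r in x) {
    labels <- c(labels, r$label)
    if (!is.null(r$tau)) {
      if (is.null(axis)) {
        stop("tau-valued references need a sampling axis", call. = FALSE)
      }
      g <- mono_exp_phasor(axis, r$tau)
      pts <- c(pts, list(phasor_point(Re(g), Im(g))))
      taus <- c(taus, r$tau)
    } else {
      pts <- c(pts, list(phasor_point(r$re, r$im)))
      taus <- c(taus, NA_real_)
    }
  }
  component_set(pts, labels, taus = taus)
}

#' Read an image stack with its sampling axis
#'
#' Dispatches on extension: NIfTI (`.nii`, `.nii.gz`; the non-spatial axis is
#' the 4th — or for single-slice data the 3rd — dimension) or multi-page
#' TIFF (pages = non-spatial steps). The axis length is validated against
#' the data.
#'
#' @param path Stack file.
#' @param axis_path Axis file for [read_axis()], or `NULL` when `axis` given.
#' @param axis A [sampled_axis()], alternative to `axis_path`.
#' @param kind Axis kind passed to [read_axis()].
#' @return A [signal_stack()].
#' @export
read_stack <- function(path, axis_path = NULL, axis = NULL,
                       kind = "echo_time") {
  if (is.null(axis)) {
    if (is.null(axis_path)) stop("supply axis_path or axis", call. = FALSE)
    axis <- read_axis(axis_path, kind)
  }
  data <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_nifti(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    read_tiff(path)
  } else {
    stop("unsupported stack format: ", path, call. = FALSE)
  }
  nd <- length(dim(data))
  if (nd == 4L && dim(data)[3L] == 1L) {
    data <- array(data, dim(data)[c(1L, 2L, 4L)])
    nd <- 3L
  }
  if (dim(data)[nd] != axis$n) {
    stop(sprintf("stack has %d steps but axis has %d values",
                 dim(data)[nd], axis$n), call. = FALSE)
  }
  signal_stack(data, axis, allow_negative = TRUE)
}

#' Write a stack to NIfTI or TIFF
#'
#' @param stack A [signal_stack()].
#' @param path Output path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "signal_stack"))
  d <- dim(stack$data)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    data <- if (length(d) == 3L) array(stack$data, c(d[1:2], 1L, d[3L])) else
      stack$data
    write_nifti(data, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (length(d) != 3L) {
      stop("TIFF export supports single-slice stacks only", call. = FALSE)
    }
    write_tiff(stack$data, path)
  } else {
    stop("unsupported stack format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Export a phasor field
#'
#' Writes a two-plane float TIFF (`<prefix>.tif`: Re, Im) and a CSV table
#' (`<prefix>.csv`: x, y, slice, re, im, intensity, valid).
#'
#' @param field A `phasor_field`.
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_phasor_field <- function(field, prefix) {
  stopifnot(inherits(field, "phasor_field"))
  sdim <- dim(field$re)
  re <- field$re; im <- field$im
  re[!field$valid] <- NA_real_; im[!field$valid] <- NA_real_
  tif <- paste0(prefix, ".tif")
  if (length(sdim) == 2L) {
    write_tiff(array(c(re, im), c(sdim, 2L)), tif)
  } else {
    write_tiff(array(c(re, im), c(sdim[1:2], 2L * sdim[3L])), tif)
  }
  idx <- arrayInd(seq_along(re), .dim = if (length(sdim) == 2L)
    c(sdim, 1L) else sdim)
  csv <- paste0(prefix, ".csv")
  utils::write.csv(data.frame(
    x = idx[, 1L], y = idx[, 2L],
    slice = if (ncol(idx) >= 3L) idx[, 3L] else 1L,
    re = as.vector(re), im = as.vector(im),
    intensity = as.vector(field$intensity),
    valid = as.vector(field$valid)), csv, row.names = FALSE)
  invisible(c(tif, csv))
}

#' Export a parameter map
#'
#' @param map A `param_map` (from [tau_map()] or [fit_map()]).
#' @param path Output path (`.nii`, `.nii.gz`, `.tif`); a JSON sidecar with
#'   the units is written alongside.
#' @return `path`, invisibly.
#' @export
write_param_map <- function(map, path) {
  stopifnot(inherits(map, "param_map"))
  val <- map$value
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- val; v[is.na(v)] <- 0
    write_nifti(v, path)
  } else {
    write_tiff(val, path)
  }
  jsonlite::write_json(list(units = map$units, kind = map$kind,
                            n_valid = sum(map$valid)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Export a reference locus as CSV
#'
#' @param locus A `reference_locus`.
#' @param path Output CSV path (columns tau, re, im, phase).
#' @return `path`, invisibly.
#' @export
write_locus <- function(locus, path) {
  stopifnot(inherits(locus, "reference_locus"))
  utils::write.csv(data.frame(tau = locus$taus, re = locus$re,
                              im = locus$im, phase = locus$phase),
                   path, row.names = FALSE)
  invisible(path)
}
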