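#' Read an attenuation volume or label mask from disk
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) via RNifti and MetaImage (`.mha`,
#' `.mhd` + raw). NIfTI volumes are reoriented to the canonical RAS axis
#' convention on read, so that phantoms and masks can be compared voxelwise
#' regardless of how they were stored. MetaImage axes are taken as stored.
#'
#' @param path file path; format is inferred from the extension.
#' @return a [volume_grid()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", ext)) {
    img <- RNifti::readNifti(path)
    ort <- try(RNifti::orientation(img), silent = TRUE)
    if (!inherits(ort, "try-error") && !identical(ort, "RAS")) {
      RNifti::orientation(img) <- "RAS"
    }
    spacing <- RNifti::pixdim(img)[1:3]
    if (anyNA(spacing) || any(spacing <= 0)) {
      stop("NIfTI file has undefined or non-positive voxel spacing: ", path,
           call. = FALSE)
    }
    xf <- RNifti::xform(img)
    org <- xf[1:3, 4]
    arr <- array(as.vector(img), dim = dim(img))
    volume_grid(arr, spacing = spacing, origin = org)
  } else if (grepl("\\.(mha|mhd)$", ext)) {
    read_metaimage(path)
  } else {
    stop("unsupported volume format: ", path,
         " (expected .nii, .nii.gz, .mha or .mhd)", call. = FALSE)
  }
}

#' Write a volume to disk
#'
#' The inverse of [read_volume()]: voxel values round-trip exactly and
#' spacing/origin to better than 1e-6 mm, across both supported formats.
#'
#' @param grid a [volume_grid()].
#' @param path destination path ending in `.nii`, `.nii.gz`, `.mha` or
#'   `.mhd` (the latter writes a sibling `.raw`).
#' @return invisibly, `path`.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  ext <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", ext)) {
    img <- RNifti::asNifti(grid$data)
    mat <- diag(4)
    diag(mat)[1:3] <- grid$spacing
    mat[1:3, 4] <- grid$origin
    RNifti::qform(img) <- structure(mat, code = 2L)
    RNifti::sform(img) <- structure(mat, code = 2L)
    RNifti::pixdim(img) <- grid$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(mha|mhd)$", ext)) {
    write_metaimage(grid, path)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

# MetaImage support is written out by hand: header is plain "Key = Value"
# text, voxel data little-endian raw, LOCAL (.mha) or detached (.mhd+.raw).
mi_types <- list(
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header: ", path, call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed MetaImage header line: ", line, call. = FALSE)
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["NDims"]], "3")) {
    stop("only 3-D MetaImage volumes are supported", call. = FALSE)
  }
  if (identical(hdr[["CompressedData"]], "True")) {
    stop("compressed MetaImage data is not supported", call. = FALSE)
  }
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  if (is.null(hdr[["ElementSpacing"]])) {
    stop("MetaImage file has undefined ElementSpacing: ", path, call. = FALSE)
  }
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop("MetaImage file has undefined or non-positive spacing: ", path,
         call. = FALSE)
  }
  origin <- if (!is.null(hdr[["Offset"]])) {
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  } else c(0, 0, 0)
  tinfo <- mi_types[[hdr[["ElementType"]]]]
  if (is.null(tinfo)) {
    stop("unsupported MetaImage ElementType: ", hdr[["ElementType"]], call. = FALSE)
  }
  n <- prod(dims)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path)) stop("missing raw data file: ", raw_path, call. = FALSE)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- readBin(raw_con, what = tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = "little")
  if (length(vals) != n) stop("truncated MetaImage voxel data: ", path, call. = FALSE)
  volume_grid(array(as.numeric(vals), dims), spacing = spacing, origin = origin)
}

write_metaimage <- function(grid, path) {
  vals <- as.vector(grid$data)
  int_like <- !anyNA(vals) && all(vals == round(vals)) &&
    min(vals) >= -32768 && max(vals) <= 32767
  etype <- if (int_like) "MET_SHORT" else "MET_DOUBLE"
  tinfo <- mi_types[[etype]]
  mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (mhd) paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw") else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.9g %.9g %.9g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g",
            grid$spacing[1], grid$spacing[2], grid$spacing[3]),
    sprintf("DimSize = %d %d %d", dim(grid$data)[1], dim(grid$data)[2], dim(grid$data)[3]),
    sprintf("ElementType = %s", etype),
    sprintf("ElementDataFile = %s", datafile)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  write_vals <- function(out_con) {
    if (tinfo$what == "integer") {
      writeBin(as.integer(vals), out_con, size = tinfo$size, endian = "little")
    } else {
      writeBin(as.numeric(vals), out_con, size = tinfo$size, endian = "little")
    }
  }
  if (mhd) {
    raw_con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(raw_con), add = TRUE)
    write_vals(raw_con)
  } else {
    write_vals(con)
  }
  invisible(path)
}

#' Breath-hold consistency check on a lung-volume series
#'
#' Quantitative comparison of repeated acquisitions presumes a reproducible
#' breath-hold. This check flags consecutive volume pairs whose absolute
#' relative change exceeds a threshold; the conventional acceptance level
#' for total lung volume between single acquisitions is 5%, with 10%
#' sometimes used as a laxer bound.
#'
#' @param tlv_series numeric vector of lung volumes (cm^3), one per visit,
#'   in acquisition order.
#' @param threshold maximum tolerated absolute relative change between
#'   consecutive volumes (default 0.05).
#' @return A tibble with one row per consecutive pair: `from`, `to` (visit
#'   indices), the two volumes, `rel_change` (signed, relative to the first
#'   of the pair) and `flagged`. Attributes `threshold` and `pass` give the
#'   overall verdict.
#' @examples
#' check_volume_consistency(c(4000, 4100, 4300))
#' @export
check_volume_consistency <- function(tlv_series, threshold = 0.05) {
  tlv_series <- as.numeric(tlv_series)
  if (length(tlv_series) == 0L) stop("empty volume series", call. = FALSE)
  if (length(tlv_series) < 2L) {
    stop("need at least two volumes to check consistency", call. = FALSE)
  }
  if (anyNA(tlv_series) || any(tlv_series <= 0)) {
    stop("lung volumes must be positive and non-missing", call. = FALSE)
  }
  n <- length(tlv_series)
  rel <- (tlv_series[-1] - tlv_series[-n]) / tlv_series[-n]
  out <- tibble::tibble(
    from = seq_len(n - 1L),
    to = seq_len(n - 1L) + 1L,
    volume_from_cm3 = tlv_series[-n],
    volume_to_cm3 = tlv_series[-1],
    rel_change = rel,
    flagged = abs(rel) > threshold
  )
  attr(out, "threshold") <- threshold
  attr(out, "pass") <- !any(out$flagged)
  out
}

#' Serialize a consistency report to JSON
#'
#' @param report output of [check_volume_consistency()].
#' @param path destination JSON path.
#' @return invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  obj <- list(
    threshold = attr(report, "threshold"),
    pass = attr(report, "pass"),
    pairs = as.data.frame(report)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
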