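# Minimal NIfTI-1 I/O.
#
# No NIfTI package is available in the target environment, and the format is
# small and fixed, so the package carries its own single-file reader/writer:
# uncompressed .nii, 3D, float32/float64, little- or big-endian on read,
# little-endian on write. Voxel spacing travels in pixdim; the cemct-specific
# tags (value kind, frame, protocol) travel in an optional YAML sidecar
# written by `write_volume()`.

NIFTI_HDR_SIZE <- 348L
NIFTI_DT <- c(float32 = 16L, float64 = 64L)

#' Write a volume as NIfTI-1
#'
#' @param vol A `cemct_volume`.
#' @param path Output path (`.nii`, uncompressed).
#' @param datatype `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = c("float64", "float32")) {
  stopifnot(is_volume(vol))
  datatype <- match.arg(datatype)
  dt <- NIFTI_DT[[datatype]]
  bitpix <- if (datatype == "float32") 32L else 64L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(NIFTI_HDR_SIZE, 4)                        # sizeof_hdr
  writeBin(raw(36), con)                       # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, dim(vol$data), 1L, 1L, 1L, 1L), 2)  # dim[8]
  writeBin(raw(14), con)                       # intent_p1..3, intent_code
  wi(dt, 2)                                    # datatype
  wi(bitpix, 2)                                # bitpix
  wi(0L, 2)                                    # slice_start
  wf(c(1, vol$spacing, 1, 1, 1, 1))            # pixdim[8] (mm)
  wf(352)                                      # vox_offset
  wf(1); wf(0)                                 # scl_slope, scl_inter
  writeBin(raw(224), con)                      # remaining descriptive fields
  writeChar("n+1", con, nchars = 3, eos = NULL); writeBin(as.raw(0L), con)  # magic
  writeBin(raw(4), con)                        # extension flag
  writeBin(as.vector(vol$data), con, size = bitpix %/% 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to an uncompressed `.nii` file (3D, float32/float64).
#' @param frame,kind,protocol Metadata to attach (NIfTI itself carries none of
#'   these); defaults match a freshly reconstructed HU image.
#' @return A `cemct_volume`.
#' @export
read_nifti <- function(path, frame = "ref", kind = "hu", protocol = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sz <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sz != NIFTI_HDR_SIZE) {
    endian <- "big"
    seek(con, 0)
    sz <- readBin(con, "integer", 1, size = 4, endian = endian)
  }
  if (sz != NIFTI_HDR_SIZE) abort("not a NIfTI-1 file (sizeof_hdr = %d)", sz)
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  if (dims[1] < 3L) abort("expected a 3D NIfTI volume, got %dD", dims[1])
  shp <- dims[2:4]
  if (dims[1] > 3L && any(dims[5:(1 + dims[1])] > 1L)) {
    abort("expected a 3D NIfTI volume (higher dims > 1)")
  }
  seek(con, 70)
  dt <- readBin(con, "integer", 1, size = 2, endian = endian)
  if (!dt %in% NIFTI_DT) abort("unsupported NIfTI datatype code %d", dt)
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  if (!magic %in% c("n+1", "ni1")) abort("bad NIfTI magic '%s'", magic)
  seek(con, max(vox_offset, 352))
  n <- prod(shp)
  vals <- readBin(con, "numeric", n, size = if (dt == 16L) 4 else 8,
                  endian = endian)
  if (length(vals) != n) abort("truncated NIfTI data (%d of %d values)", length(vals), n)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  new_volume(array(vals, dim = shp), spacing = pixdim[2:4], frame = frame,
             kind = kind, protocol = protocol)
}

#' Write / read a volume with its cemct metadata sidecar
#'
#' `write_volume()` writes `<path>` as NIfTI-1 plus `<path>.meta.yaml` holding
#' the value kind, frame id and protocol tag; `read_volume()` restores them.
#'
#' @param vol A `cemct_volume`.
#' @param path `.nii` path.
#' @return `write_volume()`: `path` invisibly; `read_volume()`: a `cemct_volume`.
#' @export
write_volume <- function(vol, path) {
  write_nifti(vol, path)
  meta <- list(kind = vol$kind, frame = vol$frame,
               protocol = if (is.null(vol$protocol)) NA else vol$protocol)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    prot <- meta$protocol
    if (is.null(prot) || (length(prot) == 1L && is.na(prot))) prot <- NULL
    read_nifti(path, frame = meta$frame, kind = meta$kind, protocol = prot)
  } else {
    read_nifti(path)
  }
}
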