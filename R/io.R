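# File formats.
#
# Complex k-space travels in a simple documented binary container (the MR raw
# data community standard is an HDF5/ISMRMRD container; this package's
# environment has no R HDF5 bindings, so it uses the equally explicit layout
# below, which any h5py/numpy user can read with a dozen lines):
#
#   bytes 0-15   magic "KSPACE-SIMPLE-V1"
#   int32 x 8    complex flag (1 = complex, 0 = magnitude-only),
#                Nx, Ny, Nt, readout_axis, center_kx, center_ky,
#                n_label_bytes
#   raw          n_label_bytes of UTF-8 JSON frame labels ("null" if none)
#   float64      2 * Nx * Ny * Nt doubles: Re/Im interleaved, column-major
#                over (kx, ky, frame)
#
# All integers and doubles are little-endian.

KSPACE_MAGIC <- "KSPACE-SIMPLE-V1"

#' Write a k-space series to the simple binary container
#'
#' @param series A [kspace_series()].
#' @param path Output file path (conventional extension: `.ksp`).
#' @return `path`, invisibly.
#' @seealso [read_kspace()] for the layout; the pair round-trips bit-exactly.
#' @export
write_kspace <- function(series, path) {
  stopifnot(inherits(series, "kspace_series"))
  d <- dim(series$data)
  labels_json <- if (is.null(series$frame_labels)) "null" else
    as.character(jsonlite::toJSON(series$frame_labels, digits = NA,
                                  dataframe = "columns"))
  lab_raw <- charToRaw(labels_json)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(KSPACE_MAGIC), con)
  writeBin(as.integer(c(1L, d, series$readout_axis, series$center_index,
                        length(lab_raw))),
           con, size = 4L, endian = "little")
  writeBin(lab_raw, con)
  interleaved <- as.numeric(rbind(Re(as.vector(series$data)),
                                  Im(as.vector(series$data))))
  writeBin(interleaved, con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a k-space series from the simple binary container
#'
#' Validates the container field by field and names the offending field on
#' failure. Despiking requires complex raw data: a magnitude-only container
#' (complex flag 0) is a hard error, not a degraded mode. A container whose
#' centre is recorded as `(0, 0)` (unknown) gets the default grid centre with
#' a warning.
#'
#' @param path Path to a file written by [write_kspace()].
#' @return A [kspace_series()].
#' @export
read_kspace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(KSPACE_MAGIC)))
  if (!identical(magic, KSPACE_MAGIC))
    stop("not a k-space container (bad magic): ", path, call. = FALSE)
  hdr <- readBin(con, "integer", n = 8L, size = 4L, endian = "little")
  if (length(hdr) < 8L)
    stop("truncated k-space container header", call. = FALSE)
  names(hdr) <- c("complex", "Nx", "Ny", "Nt", "readout_axis",
                  "center_kx", "center_ky", "n_label_bytes")
  if (hdr[["complex"]] != 1L)
    stop("magnitude-only data: despiking requires complex k-space data ",
         "(field `complex` = 0)", call. = FALSE)
  if (any(hdr[c("Nx", "Ny", "Nt")] < 1L))
    stop("invalid dimensions in field `Nx`/`Ny`/`Nt`", call. = FALSE)
  labels <- NULL
  if (hdr[["n_label_bytes"]] > 0L) {
    lab_raw <- readBin(con, "raw", n = hdr[["n_label_bytes"]])
    labels_json <- rawToChar(lab_raw)
    labels <- if (identical(labels_json, "null")) NULL else
      jsonlite::fromJSON(labels_json)
    if (is.list(labels) && !is.data.frame(labels))
      labels <- as.data.frame(labels)
  }
  n_vals <- 2 * prod(hdr[c("Nx", "Ny", "Nt")])
  vals <- readBin(con, "numeric", n = n_vals, size = 8L, endian = "little")
  if (length(vals) != n_vals)
    stop("truncated k-space container: field `data` has ", length(vals),
         " of ", n_vals, " expected values", call. = FALSE)
  z <- complex(real = vals[c(TRUE, FALSE)], imaginary = vals[c(FALSE, TRUE)])
  center <- hdr[c("center_kx", "center_ky")]
  if (all(center == 0L)) {
    center <- floor(hdr[c("Nx", "Ny")] / 2) + 1L
    warning("container has no k-space centre; defaulting to the grid centre (",
            center[1], ", ", center[2], ")", call. = FALSE)
  }
  kspace_series(array(z, unname(hdr[c("Nx", "Ny", "Nt")])),
                readout_axis = hdr[["readout_axis"]],
                center_index = unname(center), frame_labels = labels)
}

#' Write a magnitude image array as NIfTI-1
#'
#' Minimal single-file NIfTI-1 writer (348-byte header, float32 data,
#' little-endian), sufficient for the before/after/difference magnitude
#' volumes this package produces. No affine beyond voxel scaling is stored.
#'
#' @param img Real array, 2 or 3 dimensional.
#' @param path Output path (conventional extension `.nii`).
#' @param pixdim Voxel sizes in mm, recycled to 3 values (default 1).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, pixdim = c(1, 1, 1)) {
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  stopifnot(is.array(img), length(dim(img)) == 3L, is.numeric(img))
  d <- dim(img)
  pixdim <- rep_len(pixdim, 3)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4L, endian = "little")        # sizeof_hdr
  writeBin(raw(36L), con)                                  # unused / dim_info
  writeBin(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), con, size = 2L,
           endian = "little")                              # dim[8]
  writeBin(raw(14L), con)                    # intent_p1..p3, intent_code
  writeBin(c(16L, 32L, 0L), con, size = 2L, endian = "little")
                                             # datatype=float32, bitpix, slice_start
  writeBin(c(0, pixdim, 1, 1, 1, 1), con, size = 4L, endian = "little")
                                             # pixdim[8] (qfac 0)
  writeBin(c(352, 1, 0), con, size = 4L, endian = "little")
                                             # vox_offset, scl_slope, scl_inter
  writeBin(raw(224L), con)                   # remaining descriptive fields
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)  # magic
  writeBin(raw(4L), con)                     # extension flag
  writeBin(as.numeric(img), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 float32 volume written by [write_nifti()]
#'
#' Deliberately minimal: supports the single-file little-endian float32
#' layout this package writes (enough for round-trip checks and for reloading
#' its own outputs), not the full NIfTI-1 zoo.
#'
#' @param path Path to a `.nii` file.
#' @return Numeric array.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(sizeof_hdr, 348L))
    stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  invisible(readBin(con, "raw", 36L))
  dims <- readBin(con, "integer", 8L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 14L))
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  if (datatype != 16L)
    stop("unsupported NIfTI datatype ", datatype, " (only float32)",
         call. = FALSE)
  invisible(readBin(con, "raw", 4L))         # bitpix, slice_start
  invisible(readBin(con, "numeric", 8L, size = 4L, endian = "little"))
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  seek(con, where = vox_offset, origin = "start")
  d <- dims[1 + seq_len(dims[1])]
  array(readBin(con, "numeric", prod(d), size = 4L, endian = "little"), d)
}

#' Write the full output set of a despiking run
#'
#' Writes the despiked k-space and the sparse component as k-space
#' containers, before/after/difference magnitude volumes as NIfTI, and a JSON
#' report of the quantities worth logging: kappa, lambda_eff, iteration
#' count, final residual, rank of the low-rank component, and the per-frame
#' refilled-pixel counts.
#'
#' @param result A `despike_result` from [despike()] or [despike_grouped()].
#' @param original The input [kspace_series()] (for the "before" volume).
#' @param outdir Output directory, created if needed.
#' @param prefix File-name prefix (default `"despike"`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, original, outdir, prefix = "despike") {
  stopifnot(inherits(result, "despike_result"),
            inherits(original, "kspace_series"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(outdir, paste0(prefix, "_", name))

  before <- reconstruct_images(original)
  after <- reconstruct_images(result$clean)

  files <- c(
    clean_kspace = p("clean.ksp"),
    spikes_kspace = p("spikes.ksp"),
    before = p("before.nii"),
    after = p("after.nii"),
    difference = p("difference.nii"),
    report = p("report.json")
  )
  write_kspace(result$clean, files[["clean_kspace"]])
  write_kspace(result$spikes, files[["spikes_kspace"]])
  write_nifti(before, files[["before"]])
  write_nifti(after, files[["after"]])
  write_nifti(before - after, files[["difference"]])

  dg <- result$diagnostics
  report <- list(
    schema_version = "1.0",
    kappa = dg$kappa,
    mode = dg$mode,
    lambda_eff = dg$lambda_eff,
    n_iter = dg$n_iter,
    final_residual = dg$final_residual,
    converged = dg$converged,
    rank_L = dg$rank_L,
    refilled_pixels = dg$n_refilled_pixels
  )
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       files[["report"]], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
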