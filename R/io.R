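# On-disk formats: minimal NIfTI-1 (uncompressed .nii, float32/float64),
# FSL bval/bvec, JSON coil-coefficient files, and the L-field volume
# convention (4-D NIfTI with 9 row-major components).
#
# No NIfTI package ships with this toolchain, so the reader/writer below
# implements the public NIfTI-1 header layout directly; it intentionally
# supports only what this package writes (single-file .nii, float data,
# sform affine).

#' Write a NIfTI-1 volume
#'
#' @param data numeric array (3-D or 4-D).
#' @param path output path ending in .nii.
#' @param affine 4 x 4 voxel-to-mm matrix (stored as sform).
#' @param datatype "float32" or "float64".
#' @export
write_nifti <- function(data, path, affine = diag(4),
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  stopifnot(length(dims) %in% 3:4)
  ndim <- length(dims)
  dim8 <- c(ndim, dims, rep(1L, 7 - ndim))
  code <- if (datatype == "float32") 16L else 64L
  bits <- if (datatype == "float32") 32L else 64L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4) writeBin(as.double(x), con, size = size,
                                       endian = "little")
  wi(348L, 4)                       # sizeof_hdr
  writeBin(raw(36), con)            # unused
  wi(dim8, 2)                       # dim[8]
  wf(rep(0, 3)); wi(0L, 2)          # intent_p1..3, intent_code
  wi(code, 2); wi(bits, 2); wi(0L, 2) # datatype, bitpix, slice_start
  wf(c(1, rep(1, length(dims) - 1), rep(0, 8 - length(dims)))) # pixdim[8]
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)  # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                    # cal_max, cal_min, slice_duration
  wf(0)                             # toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  writeBin(raw(104), con)           # descrip + aux_file
  wi(0L, 2); wi(1L, 2)              # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                     # quatern b,c,d, qoffset x,y,z
  wf(t(affine[1:3, ]))              # srow_x, srow_y, srow_z
  writeBin(raw(16), con)            # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)             # extension flag
  writeBin(as.double(data), con, size = bits / 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package (or compatible)
#'
#' @param path .nii file path.
#' @return list: `data` (array), `affine` (4 x 4).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348L) stop("read_nifti: not a NIfTI-1 file (wrong header size)")
  dim8 <- ri(40, 2, 8)
  ndim <- dim8[1]
  stopifnot(ndim >= 1, ndim <= 7)
  dims <- dim8[2:(1 + ndim)]
  code <- ri(70, 2)
  size <- switch(as.character(code), "16" = 4L, "64" = 8L,
                 stop("read_nifti: unsupported datatype code ", code))
  vox_offset <- rf(108)
  srow <- rf(280, 12)
  affine <- rbind(matrix(srow, 3, 4, byrow = TRUE), c(0, 0, 0, 1))
  seek(con, vox_offset)
  n <- prod(dims)
  data <- readBin(con, "double", n = n, size = size, endian = "little")
  slope <- rf(112); inter <- rf(116)
  if (slope != 0 && !(slope == 1 && inter == 0)) data <- data * slope + inter
  list(data = array(data, dims), affine = affine)
}

#' Read / write FSL bval and bvec files
#'
#' bval: one whitespace-separated row of b-values. bvec: 3 rows x N columns.
#' @param bval_path,bvec_path file paths.
#' @return list(bval, bvec) with bvec as N x 3.
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bval <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3) stop("read_bvalbvec: bvec must have 3 rows")
  if (ncol(bv) != length(bval))
    stop("read_bvalbvec: bval/bvec volume count mismatch")
  list(bval = bval, bvec = t(bv))
}

#' @rdname read_bvalbvec
#' @param bval,bvec values to write (bvec N x 3 or 3 x N).
#' @export
write_bvalbvec <- function(bval, bvec, bval_path, bvec_path) {
  if (ncol(bvec) == 3 && nrow(bvec) != 3) bvec <- t(bvec)
  cat(paste(format(bval, trim = TRUE), collapse = " "), "\n",
      file = bval_path)
  utils::write.table(format(bvec, trim = TRUE, digits = 15), bvec_path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a DWI data set (NIfTI + bval/bvec)
#'
#' Validates direction norms (renormalized with a warning when off by more
#' than 1e-3) and auto-detects b-value units: values above 100 are taken as
#' s/mm^2 and converted to ms/um^2 (logged).
#'
#' @param nii_path 4-D NIfTI path.
#' @param bval_path,bvec_path FSL protocol files.
#' @return list: `data` (nvox x K matrix), `dim` (3-vector),
#'   `protocol` (`nominal_protocol`), `affine`.
#' @export
read_dwi <- function(nii_path, bval_path, bvec_path) {
  vol <- read_nifti(nii_path)
  stopifnot(length(dim(vol$data)) == 4)
  pr <- read_bvalbvec(bval_path, bvec_path)
  if (dim(vol$data)[4] != length(pr$bval))
    stop("read_dwi: volume count mismatch between NIfTI and bval")
  bval <- pr$bval
  if (any(bval > 100)) {
    message("read_dwi: b-values look like s/mm^2; converting to ms/um^2 (/1000)")
    bval <- bval / 1000
  }
  nrm <- sqrt(rowSums(pr$bvec^2))
  bad <- bval > 0 & abs(nrm - 1) > 1e-3
  if (any(bad))
    warning(sprintf("read_dwi: %d bvec columns off unit norm; renormalizing",
                    sum(bad)))
  if (any(bval > 0 & nrm < 1e-6))
    stop("read_dwi: zero bvec with nonzero b-value")
  prot <- nominal_protocol(bval, pr$bvec)
  d <- dim(vol$data)
  list(data = matrix(vol$data, prod(d[1:3]), d[4]), dim = d[1:3],
       protocol = prot, affine = vol$affine)
}

#' Write / read a gradient-coil tensor field as 4-D NIfTI
#'
#' Fourth dimension holds the 9 components in row-major order
#' (Lxx, Lxy, Lxz, Lyx, ..., Lzz).
#'
#' @param field `gnl_field`; @param path .nii path.
#' @export
write_lfield <- function(field, path) {
  sh <- field$grid$shape
  arr <- array(field$L, c(sh, 9))
  write_nifti(arr, path, affine = field$grid$affine, datatype = "float64")
}

#' @rdname write_lfield
#' @export
read_lfield <- function(path) {
  vol <- read_nifti(path)
  d <- dim(vol$data)
  if (length(d) != 4 || d[4] != 9)
    stop("read_lfield: expected a 4-D volume with 9 components")
  grid <- grid_geometry(d[1:3], affine = vol$affine)
  gnl_field(matrix(vol$data, prod(d[1:3]), 9), grid)
}

#' Read a coil model from a JSON coefficient file
#'
#' Format: `{"ref_radius_mm": r, "coefficients": [{"axis": "x",
#' "degree": l, "order": m, "coefficient": c}, ...]}`.
#' @param path JSON path.
#' @export
read_coilmodel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- obj$coefficients
  coil_harmonic_model(
    data.frame(axis = cf$axis, l = as.integer(cf$degree),
               m = as.integer(cf$order), coef = cf$coefficient),
    ref_radius = obj$ref_radius_mm)
}

#' @rdname read_coilmodel
#' @param model `coil_harmonic_model`.
#' @export
write_coilmodel <- function(model, path) {
  jsonlite::write_json(
    list(ref_radius_mm = model$ref_radius,
         coefficients = data.frame(axis = model$coefficients$axis,
                                   degree = model$coefficients$l,
                                   order = model$coefficients$m,
                                   coefficient = model$coefficients$coef)),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
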