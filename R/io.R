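# Minimal NIfTI-1 and MRtrix TCK I/O.
#
# No NIfTI/TCK reader is available in the installed R stack, so the two
# fixed binary layouts are implemented directly. Only the features the
# package needs are supported: single-file .nii, little-endian, datatypes
# uint8/int16/int32/float32/float64, sform affine. TCK follows the MRtrix
# track-file spec: text header, Float32LE triplets, NaN-separated
# streamlines, Inf terminator.

DT_TABLE <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  name = c("uint8", "int16", "int32", "float32", "float64"),
  bitpix = c(8L, 16L, 32L, 32L, 64L),
  stringsAsFactors = FALSE
)

#' Write a 3D or 4D array as a NIfTI-1 volume
#'
#' @param vol 3D or 4D numeric array
#' @param file output path (.nii)
#' @param affine 4x4 voxel-to-world transform (written as sform, code 2)
#' @param datatype one of "uint8", "int16", "int32", "float32", "float64"
#' @return the file path, invisibly
#' @export
write_nifti <- function(vol, file, affine = make_affine(), datatype = "float32") {
  dt <- DT_TABLE[DT_TABLE$name == datatype, ]
  if (nrow(dt) != 1) stop("unsupported datatype: ", datatype)
  dm <- dim(vol)
  if (length(dm) < 3 || length(dm) > 4) stop("vol must be a 3D or 4D array")
  ndim <- length(dm)
  dimfield <- rep(1L, 8)
  dimfield[1] <- ndim
  dimfield[1 + seq_along(dm)] <- as.integer(dm)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- file(file, "wb")
  on.exit(close(con))
  wb <- function(x, ...) writeBin(x, con, endian = "little", ...)
  pad <- function(s, n) {
    r <- charToRaw(s)
    c(r[seq_len(min(length(r), n))], raw(max(0, n - length(r))))
  }
  wb(348L)                          # sizeof_hdr
  wb(raw(36))                       # data_type..dim_info
  wb(as.integer(dimfield), size = 2)
  wb(numeric(3), size = 4)          # intent_p1..3
  wb(0L, size = 2)                  # intent_code
  wb(dt$code, size = 2)             # datatype
  wb(dt$bitpix, size = 2)           # bitpix
  wb(0L, size = 2)                  # slice_start
  wb(c(1, vs, rep(1, 8 - 4)), size = 4)  # pixdim (qfac, dx, dy, dz, ...)
  wb(352, size = 4)                 # vox_offset
  wb(c(1, 0), size = 4)             # scl_slope, scl_inter
  wb(0L, size = 2); wb(raw(2))      # slice_end, slice_code, xyzt_units
  wb(numeric(4), size = 4)          # cal_max..toffset
  wb(c(0L, 0L))                     # glmax, glmin
  wb(pad("tractgr", 80))            # descrip
  wb(raw(24))                       # aux_file
  wb(0L, size = 2)                  # qform_code
  wb(2L, size = 2)                  # sform_code
  wb(numeric(6), size = 4)          # quatern/qoffset
  wb(as.numeric(t(affine[1:3, ])), size = 4)  # srow_x/y/z
  wb(raw(16))                       # intent_name
  wb(pad("n+1", 4))                 # magic
  wb(raw(4))                        # extension indicator
  x <- as.numeric(vol)
  if (dt$name %in% c("uint8", "int16", "int32")) {
    wb(as.integer(round(x)), size = dt$bitpix / 8)
  } else {
    wb(x, size = dt$bitpix / 8)
  }
  invisible(file)
}

#' Read a NIfTI-1 volume written by this package (or any plain .nii)
#'
#' @param file path to a single-file little-endian .nii
#' @return list with elements `data` (array) and `affine` (4x4 sform)
#' @export
read_nifti <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  rb <- function(what, n, size) readBin(con, what, n = n, size = size, endian = "little")
  hdr_size <- rb(integer(), 1, 4)
  if (!identical(hdr_size, 348L)) {
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", hdr_size, ")")
  }
  invisible(rb(raw(), 36, 1))
  dimfield <- rb(integer(), 8, 2)
  invisible(rb(numeric(), 3, 4)); invisible(rb(integer(), 1, 2))
  datatype <- rb(integer(), 1, 2)
  bitpix <- rb(integer(), 1, 2)
  invisible(rb(integer(), 1, 2))
  invisible(rb(numeric(), 8, 4))
  vox_offset <- rb(numeric(), 1, 4)
  scl_slope <- rb(numeric(), 1, 4)
  scl_inter <- rb(numeric(), 1, 4)
  invisible(rb(integer(), 1, 2)); invisible(rb(raw(), 2, 1))
  invisible(rb(numeric(), 4, 4)); invisible(rb(integer(), 2, 4))
  invisible(rb(raw(), 104, 1))
  invisible(rb(integer(), 1, 2))  # qform_code
  sform_code <- rb(integer(), 1, 2)
  invisible(rb(numeric(), 6, 4))
  srow <- rb(numeric(), 12, 4)
  dt <- DT_TABLE[DT_TABLE$code == datatype, ]
  if (nrow(dt) != 1) stop("unsupported NIfTI datatype code: ", datatype)
  ndim <- dimfield[1]
  dm <- dimfield[2:(1 + ndim)]
  n <- prod(dm)
  seek(con, where = vox_offset, origin = "start")
  x <- if (dt$name %in% c("uint8", "int16", "int32")) {
    readBin(con, integer(), n = n, size = dt$bitpix / 8, endian = "little",
            signed = dt$name != "uint8")
  } else {
    readBin(con, numeric(), n = n, size = dt$bitpix / 8, endian = "little")
  }
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    x <- x * scl_slope + scl_inter
  }
  affine <- diag(4)
  if (sform_code > 0) affine[1:3, ] <- matrix(srow, 3, 4, byrow = TRUE)
  list(data = array(x, dim = dm), affine = affine)
}

#' Write streamlines to an MRtrix .tck file
#'
#' @param streamlines list of n x 3 matrices in world mm
#' @param file output path
#' @return the file path, invisibly
#' @export
write_tck <- function(streamlines, file) {
  hdr_lines <- function(off) {
    paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
           length(streamlines), "\nfile: . ", off, "\nEND\n")
  }
  # header length depends on the offset text; iterate once to fix point
  off <- nchar(hdr_lines(0), type = "bytes")
  off <- nchar(hdr_lines(off + 2), type = "bytes") + 2
  con <- file(file, "wb")
  on.exit(close(con))
  writeChar(hdr_lines(off), con, eos = NULL)
  pad <- off - nchar(hdr_lines(off), type = "bytes")
  if (pad > 0) writeChar(strrep(" ", pad), con, eos = NULL)
  for (s in streamlines) {
    writeBin(as.numeric(t(rbind_pts(s))), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(file)
}

#' Read an MRtrix .tck file
#' @param file path
#' @return list of n x 3 matrices (world mm)
#' @export
read_tck <- function(file) {
  raw_all <- readBin(file, raw(), n = file.size(file))
  hdr_end <- grepRaw("END\n", raw_all)[1]
  if (is.na(hdr_end)) stop("not a tck file (no END marker)")
  hdr <- rawToChar(raw_all[1:(hdr_end + 3)])
  if (!startsWith(hdr, "mrtrix tracks")) stop("not a tck file")
  m <- regmatches(hdr, regexec("file: \\. ([0-9]+)", hdr))[[1]]
  off <- as.integer(m[2])
  vals <- readBin(raw_all[(off + 1):length(raw_all)], numeric(),
                  n = (length(raw_all) - off) / 4, size = 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  is_sep <- rowSums(is.na(pts)) > 0
  is_end <- rowSums(is.infinite(pts)) > 0
  out <- list()
  cur <- integer(0)
  for (i in seq_len(nrow(pts))) {
    if (is_end[i]) break
    if (is_sep[i]) {
      if (length(cur)) out[[length(out) + 1]] <- pts[cur, , drop = FALSE]
      cur <- integer(0)
    } else cur <- c(cur, i)
  }
  if (length(cur)) out[[length(out) + 1]] <- pts[cur, , drop = FALSE]
  out
}

#' Write FSL-style bvals/bvecs text files
#' @param scheme an [acquisition_scheme()]
#' @param bvals_file,bvecs_file output paths
#' @return invisibly, the two paths
#' @export
write_bvals_bvecs <- function(scheme, bvals_file, bvecs_file) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bvals_file)
  writeLines(apply(t(scheme$bvecs), 1, paste, collapse = " "), bvecs_file)
  invisible(c(bvals_file, bvecs_file))
}

#' Read FSL-style bvals/bvecs into an acquisition scheme
#' @param bvals_file,bvecs_file paths
#' @return an [acquisition_scheme()]
#' @export
read_bvals_bvecs <- function(bvals_file, bvecs_file) {
  bvals <- scan(bvals_file, quiet = TRUE)
  bv <- do.call(rbind, lapply(readLines(bvecs_file), function(l) scan(text = l, quiet = TRUE)))
  acquisition_scheme(bvals, t(bv))
}
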