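# Minimal NIfTI-1 I/O (single-file .nii, float32/float64, little-endian).
# No NIfTI package is available in this toolchain, so the 348-byte header is
# written directly; geometry is conveyed through pixdim and an axis-aligned
# sform.  Complex images are stored as paired magnitude/phase volumes by the
# callers.

#' Write a numeric array as a NIfTI-1 file
#'
#' @param data numeric array, 2 to 5 dimensions.
#' @param path output path (conventionally `.nii`).
#' @param pixdim voxel sizes per dimension, mm (recycled/padded as needed).
#' @param datatype `"float32"` or `"float64"`.
#' @param description free-text tag (max 79 characters).
#' @return the path, invisibly.
#' @export
nifti_write <- function(data, path, pixdim = c(1, 1, 1), datatype = "float32",
                        description = "") {
  nd <- length(dim(data))
  stopifnot(nd >= 2, nd <= 5)
  dims <- dim(data)
  dt_code <- switch(datatype, float32 = 16L, float64 = 64L,
                    stop("unsupported datatype", call. = FALSE))
  bitpix <- switch(datatype, float32 = 32L, float64 = 64L)
  pd <- rep(1, 7)
  pd[seq_along(pixdim)] <- pixdim

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s[seq_len(min(length(raw_s), len))],
               raw(max(0, len - length(raw_s)))), con)
  }
  wi(348, 4)                      # sizeof_hdr
  wc("", 10); wc("", 18)          # data_type, db_name
  wi(0, 4); wi(0, 2)              # extents, session_error
  wc("r", 1); wc("", 1)           # regular, dim_info
  wi(c(nd, dims, rep(1, 7 - nd)), 2)       # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)        # intent_p1..3, intent_code
  wi(dt_code, 2); wi(bitpix, 2); wi(0, 2)  # datatype, bitpix, slice_start
  wf(c(1, pd))                    # pixdim[8] (qfac = 1)
  wf(352)                         # vox_offset
  wf(1); wf(0)                    # scl_slope, scl_inter
  wi(0, 2); wc("", 1)             # slice_end, slice_code
  writeBin(as.raw(10L), con)      # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))               # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                  # glmax, glmin
  wc(substr(description, 1, 79), 80)
  wc("", 24)                      # aux_file
  wi(0, 2); wi(1, 2)              # qform_code, sform_code
  wf(rep(0, 6))                   # quatern b,c,d + qoffset x,y,z
  wf(c(pd[1], 0, 0, 0))           # srow_x
  wf(c(0, pd[2], 0, 0))           # srow_y
  wf(c(0, 0, pd[3], 0))           # srow_z
  wc("", 16)                      # intent_name
  wc("n+1", 4)                    # magic
  writeBin(raw(4), con)           # pad to vox_offset 352
  writeBin(as.numeric(data), con, size = bitpix / 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by [nifti_write()]
#'
#' Supports single-file little-endian float32/float64 volumes.
#'
#' @param path file path.
#' @return list: `data` (array), `pixdim`, `description`.
#' @export
nifti_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  sz <- readBin(hdr[1:4], "integer", 1, size = 4, endian = "little")
  if (sz != 348) stop("not a little-endian NIfTI-1 file", call. = FALSE)
  dims <- readBin(hdr[41:56], "integer", 8, size = 2, endian = "little")
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  dt <- readBin(hdr[71:72], "integer", 1, size = 2, endian = "little")
  pixdim <- readBin(hdr[77:108], "numeric", 8, size = 4, endian = "little")[2:(1 + nd)]
  vox_offset <- readBin(hdr[109:112], "numeric", 1, size = 4, endian = "little")
  descrip <- rawToChar(hdr[149:228][hdr[149:228] != as.raw(0)])
  size <- switch(as.character(dt), "16" = 4L, "64" = 8L,
                 stop("unsupported NIfTI datatype ", dt, call. = FALSE))
  seek(con, vox_offset)
  n <- prod(shape)
  data <- readBin(con, "numeric", n, size = size, endian = "little")
  list(data = array(data, shape), pixdim = pixdim, description = descrip)
}

#' Write a tagged image set as paired magnitude/phase NIfTI volumes
#'
#' One 4D file pair per encoding: `tag_<orientation>_<polarity>_{mag,phase}.nii`.
#'
#' @param set a `tagged_image_set`.
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_tagged_nifti <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- set$geometry
  pd <- c(geom$pixel_spacing, geom$pixel_spacing, geom$slice_thickness, 1)
  paths <- character(0)
  for (orient in names(set$images)) {
    for (pol in names(set$images[[orient]])) {
      img <- set$images[[orient]][[pol]]
      for (part in c("mag", "phase")) {
        arr <- if (part == "mag") Mod(img) else Arg(img)
        p <- file.path(dir, sprintf("tag_%s_%s_%s.nii", orient, pol, part))
        nifti_write(arr, p, pixdim = pd,
                    description = sprintf("%s %s %s", orient, pol, part))
        paths <- c(paths, p)
      }
    }
  }
  invisible(paths)
}
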