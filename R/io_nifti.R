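## Minimal single-file NIfTI-1 (.nii, uncompressed) reader/writer for mask,
## density and dose volumes. No NIfTI package is available in the target
## environment; the format is fixed (348-byte header, little-endian), so a
## small native implementation is used. The affine encodes the isotropic
## voxel size with the isocenter at the grid center.

.nifti_datatype <- function(x) {
  if (is.logical(x)) list(code = 2L, bitpix = 8L, what = "int", size = 1L)
  else list(code = 16L, bitpix = 32L, what = "double", size = 4L)
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param x numeric or logical 3-D array.
#' @param path output file (`.nii`).
#' @param voxel_mm isotropic voxel size in mm.
#' @export
write_nifti <- function(x, path, voxel_mm) {
  stopifnot(length(dim(x)) == 3)
  dt <- .nifti_datatype(x)
  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  dm <- dim(x)
  off <- c((dm - 1) / 2 * voxel_mm) # isocenter-centered affine offset

  w_i32(348)                         # sizeof_hdr
  w_raw(36)                          # data_type..dim_info (unused)
  w_i16(c(3L, dm, 1L, 1L, 1L, 1L))   # dim[8]
  w_f32(c(0, 0, 0))                  # intent_p1..p3
  w_i16(0L)                          # intent_code
  w_i16(dt$code)                     # datatype
  w_i16(dt$bitpix)                   # bitpix
  w_i16(0L)                          # slice_start
  w_f32(c(1, rep(voxel_mm, 3), 0, 0, 0, 0)) # pixdim[8]
  w_f32(352)                         # vox_offset
  w_f32(c(1, 0))                     # scl_slope, scl_inter
  w_i16(0L)                          # slice_end
  writeBin(as.raw(c(0L, 2L)), con)   # slice_code, xyzt_units (mm)
  w_f32(c(0, 0, 0, 0))               # cal_max..toffset
  w_i32(c(0L, 0L))                   # glmax, glmin
  w_raw(80 + 24)                     # descrip, aux_file
  w_i16(c(0L, 1L))                   # qform_code, sform_code
  w_f32(rep(0, 6))                   # quaternions, qoffsets
  w_f32(c(voxel_mm, 0, 0, -off[1],   # srow_x
          0, voxel_mm, 0, -off[2],   # srow_y
          0, 0, voxel_mm, -off[3]))  # srow_z
  w_raw(16)                          # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con) # magic
  w_raw(4)                           # extension indicator
  if (dt$what == "int") {
    writeBin(as.integer(x), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()] (or any uncompressed
#' single-file little-endian NIfTI-1 with datatype uint8/int16/float32/
#' float64)
#'
#' @param path `.nii` file.
#' @return list with `data` (array), `voxel_mm`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  r_i16 <- function(at) readBin(hdr[(at + 1):(at + 2)], "integer", size = 2,
                                endian = "little")
  r_f32 <- function(at, n = 1) readBin(hdr[(at + 1):(at + 4 * n)], "numeric",
                                       size = 4, n = n, endian = "little")
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = "little")
  if (sz != 348) stop("not a little-endian NIfTI-1 file")
  dm <- vapply(0:2, function(k) r_i16(42 + 2 * k), integer(1))
  datatype <- r_i16(70)
  pixdim <- r_f32(76, 8)
  vox_offset <- r_f32(108)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(dm)
  data <- switch(as.character(datatype),
                 "2" = readBin(con, "integer", n = n, size = 1, signed = FALSE,
                               endian = "little"),
                 "4" = readBin(con, "integer", n = n, size = 2,
                               endian = "little"),
                 "16" = readBin(con, "numeric", n = n, size = 4,
                                endian = "little"),
                 "64" = readBin(con, "numeric", n = n, size = 8,
                                endian = "little"),
                 stop("unsupported NIfTI datatype ", datatype))
  list(data = array(data, dm), voxel_mm = pixdim[2])
}

#' Write a patient model to a directory (one NIfTI per structure + density,
#' spec as YAML)
#' @param model a `patient_model`.
#' @param dir output directory (created if needed).
#' @export
write_patient <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- model$grid$voxel_mm
  for (nm in names(model$masks)) {
    write_nifti(model$masks[[nm]], file.path(dir, paste0(nm, ".nii")), v)
  }
  write_nifti(model$density, file.path(dir, "density.nii"), v)
  yaml::write_yaml(list(seed = model$seed, ptv_cc = model$ptv_cc,
                        grid = list(shape = model$grid$shape,
                                    voxel_mm = model$grid$voxel_mm),
                        flags = unclass(model$flags)),
                   file.path(dir, "patient.yaml"))
  invisible(dir)
}

#' Read a patient model written by [write_patient()]
#' @param dir the patient directory.
#' @export
read_patient <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "patient.yaml"))
  grid <- rt_grid(unlist(meta$grid$shape), meta$grid$voxel_mm)
  masks <- list()
  for (nm in c("PTV", "lung_L", "lung_R", "heart", "breast_L", "breast_R",
               "patient")) {
    masks[[nm]] <- array(read_nifti(file.path(dir, paste0(nm, ".nii")))$data > 0,
                         grid$shape)
  }
  density <- array(read_nifti(file.path(dir, "density.nii"))$data, grid$shape)
  fl <- meta$flags
  spec <- anatomy_spec(fl$ptv_target_volume_cc, fl$superior_extent,
                       fl$inferior_extent, unlist(fl$supraclavicular),
                       unlist(fl$axillary), fl$bulky, fl$lateral_offset_mm)
  structure(list(grid = grid, masks = masks, density = density, flags = spec,
                 ptv_cc = meta$ptv_cc, seed = meta$seed),
            class = "patient_model")
}
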