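# Volume IO: NIfTI (via RNifti) and MetaImage (MHD + RAW) with mm spacing.

#' Write a voxel grid to NIfTI
#' @param grid a [voxel_grid].
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume into a voxel grid
#' @param path NIfTI file path.
#' @param origin optional mm origin; default centres the grid.
#' @return a [voxel_grid].
#' @export
read_volume_nifti <- function(path, origin = NULL) {
  img <- RNifti::readNifti(path)
  voxel_grid(array(as.array(img), dim = dim(img)),
             RNifti::pixdim(img)[seq_len(3)], origin = origin)
}

#' Write a voxel grid as MetaImage (MHD header + RAW data)
#' @param grid a [voxel_grid].
#' @param path output path ending in .mhd; the .raw sits beside it.
#' @return the header path, invisibly.
#' @export
write_volume_mhd <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"), grepl("\\.mhd$", path))
  raw_path <- sub("\\.mhd$", ".raw", path)
  d <- dim(grid$values)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(grid$voxel_size, collapse = " ")),
           paste("Offset =", paste(grid$origin + grid$voxel_size / 2,
                                   collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.vector(grid$values), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a MetaImage volume into a voxel grid
#' @param path .mhd header path.
#' @return a [voxel_grid].
#' @export
read_volume_mhd <- function(path) {
  lines <- readLines(path)
  field <- function(key) {
    ln <- grep(paste0("^", key, " *="), lines, value = TRUE)[1]
    trimws(sub("^[^=]*=", "", ln))
  }
  d <- as.integer(strsplit(field("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(field("ElementSpacing"), " +")[[1]])
  off <- as.numeric(strsplit(field("Offset"), " +")[[1]])
  raw_path <- file.path(dirname(path), field("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  voxel_grid(array(vals, d), sp, origin = off - sp / 2)
}
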