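#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around RNifti preserving data, affine and voxel size.
#' Integer label volumes keep their integer storage mode on a round trip.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume`: the image array with a `voxel_size` attribute.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- tryCatch(
    suppressWarnings(RNifti::readNifti(path)),
    error = function(e) {
      stop(sprintf("failed to read NIfTI file '%s': %s", path,
                   conditionMessage(e)))
    }
  )
  arr <- as.array(img)
  attr(arr, "voxel_size") <- RNifti::pixdim(img)
  arr
}

#' @rdname read_volume
#' @param volume numeric or integer array.
#' @param voxel_size mm per axis, stored in the NIfTI header.
#' @export
write_volume <- function(volume, path, voxel_size = c(3, 3, 3)) {
  attr(volume, "voxel_size") <- NULL
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_size, length.out = length(dim(volume)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# TAC tables as plain text: time_min, duration_min, value (and suv if set).
write_tac <- function(x, path) {
  df <- data.frame(time_min = x$time_min, duration_min = x$duration_min,
                   value = x$value)
  if (!is.null(x$suv)) df$suv <- x$suv
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_tac <- function(path, schedule) {
  df <- read.table(path, header = TRUE, sep = "\t")
  tac(df$value, schedule, suv = df$suv)
}
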