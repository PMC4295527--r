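#' Per-voxel scalar maps over a masked grid
#'
#' A `stat_volume` couples a 3-D grid of per-voxel values with the binary
#' mask of voxels where the quantity is defined, plus a quantity tag.
#'
#' @param values 3-D numeric array (NA outside the mask is fine).
#' @param mask binary 3-D array of the same shape.
#' @param quantity free-form tag (e.g. `"r2_unique_a"`, `"p_full"`).
#' @return Object of class `stat_volume`.
#' @export
stat_volume <- function(values, mask, quantity = "") {
  values <- as.array(values); mask <- as.array(mask)
  if (!identical(dim(values), dim(mask)))
    stop("values and mask shapes differ")
  if (any(!is.finite(values[mask > 0])))
    stop("non-finite values inside the mask")
  structure(list(values = values, mask = mask, quantity = quantity),
            class = "stat_volume")
}

#' @export
print.stat_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("stat_volume [%s]: %dx%dx%d, %d masked voxels\n",
              x$quantity, d[1], d[2], d[3], sum(x$mask > 0)))
  invisible(x)
}

#' Export stat volumes as NIfTI and a tidy voxel table
#'
#' `write_stat_volumes()` writes one NIfTI file per quantity plus a CSV
#' with one row per masked voxel (x, y, z and all quantities).
#'
#' @param vols named list of [stat_volume]s sharing a mask.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return The CSV path, invisibly.
#' @export
write_stat_volumes <- function(vols, dir, prefix = "stat") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask <- vols[[1]]$mask
  for (nm in names(vols)) {
    v <- vols[[nm]]$values
    v[is.na(v)] <- 0
    RNifti::writeNifti(RNifti::asNifti(v),
                       file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm)))
  }
  idx <- which(mask > 0, arr.ind = TRUE)
  tab <- data.frame(x = idx[, 1], y = idx[, 2], z = idx[, 3])
  for (nm in names(vols)) tab[[nm]] <- vols[[nm]]$values[idx]
  csv <- file.path(dir, sprintf("%s_voxels.csv", prefix))
  utils::write.csv(tab, csv, row.names = FALSE)
  invisible(csv)
}
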