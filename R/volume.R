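#' Voxel volume of CT intensities
#'
#' A minimal calibrated CT container: a 3-D array of Hounsfield units plus the
#' geometric metadata needed to place voxels in the mesh's world coordinates.
#' Axis order is (x, y, z); indexing is 1-based in R; the centre of voxel
#' (i, j, k) sits at `origin + (c(i, j, k) - 0.5) * spacing` mm, i.e. the
#' volume corner (not the first voxel centre) is at `origin`.
#'
#' @param values 3-D numeric array of HU.
#' @param spacing voxel edge lengths in mm, length 3, all > 0.
#' @param origin world coordinates (mm) of the volume corner, length 3.
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3-D array")
  spacing <- as.double(spacing); origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite coordinates in mm")
  structure(list(values = values, spacing = spacing, origin = origin,
                 shape = dim(values)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, HU range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

# Voxel-centre world coordinates along one axis.
voxel_centers <- function(vol, axis) {
  vol$origin[axis] + (seq_len(vol$shape[axis]) - 0.5) * vol$spacing[axis]
}
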