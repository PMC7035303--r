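#' Write a 4D velocity field as NIfTI components with a JSON sidecar
#'
#' One NIfTI file per velocity component (`vx.nii.gz`, `vy.nii.gz`,
#' `vz.nii.gz`; the 4th dimension is cardiac phase, values cm/s) plus
#' `field.json` carrying VENC, phase times, the R-R interval and voxel size.
#'
#' @param field A `velocity_field_4d`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_velocity_field <- function(field, dir) {
  stopifnot(inherits(field, "velocity_field_4d"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- rep(field$voxel_size, 3)
  for (k in c("vx", "vy", "vz")) {
    img <- RNifti::asNifti(field[[k]], pixdim = pd)
    RNifti::writeNifti(img, file.path(dir, paste0(k, ".nii.gz")))
  }
  side <- list(venc = field$venc, voxel_size = field$voxel_size,
               n_phases = field$n_phases, phase_times = field$phase_times,
               rr_interval = field$rr_interval,
               grid_shape = field$grid_shape)
  jsonlite::write_json(side, file.path(dir, "field.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a 4D velocity field written by [write_velocity_field()]
#'
#' @param dir Directory containing `vx/vy/vz.nii.gz` and `field.json`.
#' @return A `velocity_field_4d`.
#' @export
read_velocity_field <- function(dir) {
  sidecar <- file.path(dir, "field.json")
  if (!file.exists(sidecar)) stopf("missing sidecar %s", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  comp <- lapply(c("vx", "vy", "vz"), function(k) {
    f <- file.path(dir, paste0(k, ".nii.gz"))
    if (!file.exists(f)) stopf("missing velocity component %s", f)
    arr <- as.array(RNifti::readNifti(f))
    attributes(arr) <- list(dim = dim(arr))
    arr
  })
  structure(list(vx = comp[[1]], vy = comp[[2]], vz = comp[[3]],
                 n_phases = as.integer(side$n_phases),
                 venc = side$venc,
                 voxel_size = side$voxel_size,
                 grid_shape = as.integer(side$grid_shape),
                 phase_times = as.numeric(side$phase_times),
                 rr_interval = side$rr_interval),
            class = "velocity_field_4d")
}
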