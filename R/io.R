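# Volume I/O: NIfTI (lossless, voxel size in the header) and multi-page
# TIFF (float32; voxel size carried by a JSON sidecar or supplied
# explicitly). A JSON sidecar also carries phantom ground truth.

sidecar_path <- function(path) paste0(path, ".json")

truth_to_json <- function(truth) {
  if (is.null(truth)) return(NULL)
  ex <- truth$extra
  # large arrays are not serialized; keep scalar ground truth only
  ex <- ex[!vapply(ex, function(v) is.array(v) || length(v) > 16, logical(1))]
  list(true_bvtv = truth$true_bvtv,
       principal_axis = truth$principal_axis,
       betti1 = truth$betti1,
       component_count = truth$component_count,
       extra = ex)
}

#' Write a density volume to disk
#'
#' NIfTI (`.nii` / `.nii.gz`) stores densities as doubles with the voxel
#' size in the header (bit-identical round trip). Multi-page TIFF stores
#' 32-bit samples on a fixed 0..65536 mgHA/cm^3 scale (round trip exact to
#' ~1.5e-5 mgHA/cm^3, the sample quantum); the voxel size and any phantom
#' ground truth go to a `<path>.json` sidecar.
#'
#' @param vol A [density_volume].
#' @param path Output path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @param truth Optional [phantom_truth] recorded in the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, truth = NULL) {
  stopifnot(inherits(vol, "density_volume"))
  lower <- tolower(path)
  side <- list(voxel_size_um = vol$voxel_size)
  if (!is.null(truth)) side$truth <- truth_to_json(truth)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- rep(vol$voxel_size / 1000, 3)  # header is in mm
    RNifti::writeNifti(img, path, datatype = "double")
    if (!is.null(truth))
      jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                           digits = NA, null = "null")
  } else if (grepl("\\.tiff?$", lower)) {
    d <- dim(vol$values)
    # fixed full-scale of 65536 mgHA/cm^3; 32-bit samples quantize to ~1.5e-5
    slices <- lapply(seq_len(d[1]), function(i)
      matrix(vol$values[i, , ] / 65536, d[2], d[3]))
    tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    stop("unrecognized volume format (use .nii, .nii.gz, .tif or .tiff)",
         call. = FALSE)
  }
  invisible(path)
}

#' Read a density volume from disk
#'
#' Accepts NIfTI and multi-page TIFF. The voxel size comes from the NIfTI
#' header (rounded to nanometres to absorb float32 header storage) or the
#' JSON sidecar; with neither available, `voxel_size` must be supplied.
#' Anisotropic voxels are rejected: the analysis assumes an isotropic grid.
#'
#' @param path Volume file path.
#' @param voxel_size Optional override in micrometres.
#' @return A [density_volume]; any ground truth found in the sidecar is
#'   attached as attribute `truth_sidecar`.
#' @export
read_volume <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lower <- tolower(path)
  side <- NULL
  if (file.exists(sidecar_path(path)))
    side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3] * 1000            # mm -> um
    pd <- round(pd, 3)                               # absorb float32 header
    if (is.null(voxel_size)) {
      if (any(pd <= 0)) stop("missing voxel size in NIfTI header; supply `voxel_size`",
                             call. = FALSE)
      if (max(pd) - min(pd) > 1e-6 * max(pd))
        stop("anisotropic voxels are not supported", call. = FALSE)
      voxel_size <- pd[1]
    }
    vals <- as.array(img)
    attributes(vals) <- list(dim = dim(img))
  } else if (grepl("\\.tiff?$", lower)) {
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    if (is.null(voxel_size)) {
      if (!is.null(side$voxel_size_um)) voxel_size <- side$voxel_size_um
      else stop("TIFF carries no voxel size and no override was supplied",
                call. = FALSE)
    }
    d2 <- dim(slices[[1]])
    vals <- array(0, c(length(slices), d2[1], d2[2]))
    for (i in seq_along(slices)) vals[i, , ] <- slices[[i]] * 65536
  } else {
    stop("unrecognized volume format (use .nii, .nii.gz, .tif or .tiff)",
         call. = FALSE)
  }
  out <- density_volume(vals, voxel_size)
  if (!is.null(side$truth)) attr(out, "truth_sidecar") <- side$truth
  out
}
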