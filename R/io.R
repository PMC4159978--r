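#' Read one contrast's multi-echo volumes plus its echo-time sidecar
#'
#' Accepts either a single 4D NIfTI file (echo as the fourth dimension) or a
#' vector of 3D NIfTI files, one per echo. Echo times always come from the
#' JSON sidecar (key `EchoTime_ms`, a list of milliseconds), never from
#' filenames. Volumes are reordered so echoes are ascending in TE.
#'
#' @param volume_paths Character vector: one 4D NIfTI path, or one 3D NIfTI
#'   path per echo (order corresponding to the sidecar's echo-time order).
#' @param sidecar_path Path to the JSON sidecar `{"EchoTime_ms": [...]}`.
#' @param label Contrast label; defaults to the sidecar's `Label` entry if
#'   present, else the sidecar file stem.
#' @return A validated [multi_echo_contrast].
#' @export
read_contrast <- function(volume_paths, sidecar_path, label = NULL) {
  for (p in c(volume_paths, sidecar_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  side <- jsonlite::fromJSON(sidecar_path)
  if (is.null(side$EchoTime_ms))
    stop("sidecar ", sidecar_path, " lacks required key 'EchoTime_ms'", call. = FALSE)
  te <- as.numeric(side$EchoTime_ms)
  if (is.null(label))
    label <- if (!is.null(side$Label)) as.character(side$Label) else
      sub("\\.json$", "", basename(sidecar_path))

  if (length(volume_paths) == 1L) {
    img <- RNifti::readNifti(volume_paths[1])
    arr <- as.array(img)
    if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 4L)
      stop("expected a 3D or 4D NIfTI: ", volume_paths[1], call. = FALSE)
    vox <- RNifti::pixdim(img)[1:3]
  } else {
    vols <- lapply(volume_paths, function(p) {
      a <- as.array(RNifti::readNifti(p))
      if (length(dim(a)) != 3L) stop("expected 3D volumes: ", p, call. = FALSE)
      a
    })
    d <- dim(vols[[1]])
    if (!all(vapply(vols, function(a) all(dim(a) == d), logical(1))))
      stop("echo volumes have inconsistent grid dimensions", call. = FALSE)
    arr <- array(unlist(vols, use.names = FALSE), dim = c(d, length(vols)))
    vox <- RNifti::pixdim(RNifti::readNifti(volume_paths[1]))[1:3]
  }
  if (length(te) != dim(arr)[4L])
    stop(sprintf("sidecar %s lists %d echo times but %d volumes were read",
                 sidecar_path, length(te), dim(arr)[4L]), call. = FALSE)
  if (any(arr < 0, na.rm = TRUE))
    stop("negative intensities in ", paste(volume_paths, collapse = ", "),
         ": magnitude data expected", call. = FALSE)
  ct <- multi_echo_contrast(label, arr, te)
  attr(ct, "voxel_size_mm") <- vox
  ct
}

write_nifti_map <- function(arr, path, voxel_size_mm, descrip = "") {
  img <- RNifti::asNifti(array(as.numeric(arr), dim = dim(arr)))
  RNifti::pixdim(img) <- voxel_size_mm
  img <- RNifti::updateNifti(img, template = list(descrip = descrip))
  RNifti::writeNifti(img, path, datatype = "double")
  path
}

#' Write a fit result to disk as NIfTI maps plus a provenance record
#'
#' Writes the R2* map (s^-1), one intercept map per contrast, the final
#' outlier-weight volumes when present, the validity mask, and a JSON
#' provenance file recording the method, parameters and software version.
#'
#' @param result A [fit_result][fit_ols] object.
#' @param out_dir Output directory (created if missing).
#' @param voxel_size_mm Voxel size recorded in the NIfTI headers.
#' @param overwrite Overwrite existing files? Defaults to `FALSE`, in which
#'   case any collision aborts before anything is written.
#' @param extra_provenance Named list merged into the provenance JSON
#'   (e.g. seeds, input paths).
#' @return Invisibly, a character vector of the files written (the manifest).
#' @export
write_fit_result <- function(result, out_dir, voxel_size_mm = c(1, 1, 1),
                             overwrite = FALSE, extra_provenance = list()) {
  stopifnot(inherits(result, "fit_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(file.path(out_dir, "r2s.nii.gz"),
             file.path(out_dir, sprintf("intercept_%s.nii.gz", names(result$intercepts))),
             file.path(out_dir, "valid.nii.gz"),
             file.path(out_dir, "provenance.json"))
  if (!is.null(result$weights))
    files <- c(files, file.path(out_dir, sprintf("weights_%s.nii.gz",
                                                 names(result$weights))))
  existing <- files[file.exists(files)]
  if (length(existing) && !overwrite)
    stop("refusing to overwrite existing files (use overwrite = TRUE): ",
         paste(basename(existing), collapse = ", "), call. = FALSE)

  manifest <- character(0)
  manifest <- c(manifest, write_nifti_map(result$r2s, files[1], voxel_size_mm,
                                          "R2* map [1/s]"))
  for (lab in names(result$intercepts))
    manifest <- c(manifest,
                  write_nifti_map(result$intercepts[[lab]],
                                  file.path(out_dir, sprintf("intercept_%s.nii.gz", lab)),
                                  voxel_size_mm, sprintf("I0 intercept (%s)", lab)))
  manifest <- c(manifest, write_nifti_map(result$valid + 0,
                                          file.path(out_dir, "valid.nii.gz"),
                                          voxel_size_mm, "fit validity mask"))
  if (!is.null(result$weights))
    for (lab in names(result$weights))
      manifest <- c(manifest,
                    write_nifti_map(result$weights[[lab]],
                                    file.path(out_dir, sprintf("weights_%s.nii.gz", lab)),
                                    voxel_size_mm, sprintf("outlier weights (%s)", lab)))
  prov <- c(list(method = result$method,
                 package = "estatics",
                 version = as.character(utils::packageVersion("estatics")),
                 n_valid_voxels = sum(result$valid),
                 diagnostics = result$diagnostics),
            extra_provenance)
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- c(manifest, prov_path)
  invisible(manifest)
}

#' Write a single 3D map as NIfTI
#'
#' Convenience wrapper used for ground-truth maps and masks.
#' @param arr 3D numeric/logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size for the header.
#' @param descrip Header description string.
#' @return The path, invisibly.
#' @export
write_map <- function(arr, path, voxel_size_mm = c(1, 1, 1), descrip = "") {
  invisible(write_nifti_map(arr, path, voxel_size_mm, descrip))
}

#' Read a single 3D map from NIfTI
#' @param path NIfTI path.
#' @return A 3D numeric array.
#' @export
read_map <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) == 4L && dim(a)[4L] == 1L) dim(a) <- dim(a)[1:3]
  a
}
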