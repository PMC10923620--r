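#' Read a 3D volume from NIfTI
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A list of class `mri_volume` with `voxels` (3D array), `spacing`
#'   (x, y, z in mm) and `origin`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("volume file does not exist: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("cannot read NIfTI %s: %s",
                                            path, conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3)
    stopf("expected a 3D volume in %s, got %dD data", path, length(d))
  sp <- RNifti::pixdim(img)
  org <- tryCatch(as.numeric(RNifti::origin(img)), error = function(e) c(0, 0, 0))
  structure(list(voxels = array(as.numeric(img), d),
                 spacing = as.numeric(sp[1:3]),
                 origin = org),
            class = "mri_volume")
}

#' Write a 3D volume or mask to NIfTI
#'
#' @param v an `mri_volume` or a plain 3D array.
#' @param path output path (`.nii` or `.nii.gz`); the parent directory is
#'   created if needed.
#' @param dtype_policy `"float32"` for images, `"uint8"` for binary masks.
#'   Under `"uint8"` the values must already be in \{0, 1\}.
#' @param spacing voxel spacing in mm, used when `v` is a plain array.
#' @return Invisibly, the path.
#' @export
write_volume <- function(v, path, dtype_policy = c("float32", "uint8"),
                         spacing = c(1, 1, 1)) {
  dtype_policy <- match.arg(dtype_policy)
  if (inherits(v, "mri_volume")) {
    arr <- v$voxels; spacing <- v$spacing
  } else arr <- v
  if (length(dim(arr)) != 3) stopf("write_volume expects a 3D array")
  if (dtype_policy == "uint8" && !is_binary(arr))
    stopf("uint8 policy requires a binary mask with values in {0, 1}")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  arr <- array(as.numeric(arr), dim(arr))
  RNifti::pixdim(arr) <- spacing
  img <- RNifti::asNifti(arr, datatype = if (dtype_policy == "uint8") "uint8"
                                         else "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

MANIFEST_VERSION <- "1.0"

#' Save / load a dataset manifest
#'
#' A manifest records, per case: `id`, `phase1`, `phase2`, `mask`, optional
#' `roi`, and `seed`. Paths are stored relative to the manifest location if
#' given that way. Duplicate ids are rejected.
#'
#' @param m data.frame with at least columns `id`, `phase1`, `phase2`, `mask`.
#' @param path JSON file path.
#' @name manifest_io
#' @export
save_manifest <- function(m, path) {
  check_manifest(m)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(format_version = MANIFEST_VERSION, cases = m),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname manifest_io
#' @param check_paths verify on load that the referenced files resolve
#'   (relative to the manifest's directory).
#' @export
load_manifest <- function(path, check_paths = FALSE) {
  if (!file.exists(path)) stopf("manifest does not exist: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$format_version) || is.null(j$cases))
    stopf("manifest %s violates the schema (format_version/cases missing)", path)
  m <- as.data.frame(j$cases)
  check_manifest(m)
  if (check_paths) {
    base <- dirname(path)
    for (col in intersect(c("phase1", "phase2", "mask"), names(m))) {
      p <- m[[col]]
      abs <- ifelse(file.exists(p), TRUE, file.exists(file.path(base, p)))
      if (!all(abs))
        stopf("manifest %s references missing file(s): %s", path,
              paste(p[!abs], collapse = ", "))
    }
  }
  m
}

check_manifest <- function(m) {
  need <- c("id", "phase1", "phase2", "mask")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stopf("manifest is missing required column(s): %s",
          paste(miss, collapse = ", "))
  if (anyDuplicated(m$id))
    stopf("manifest has duplicate case id(s): %s",
          paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  invisible(TRUE)
}

#' Export a phantom dataset to NIfTI + manifest
#'
#' Writes each case's two phases (float32) and mask (uint8) plus a JSON
#' manifest; the layout matches what [load_manifest()] expects.
#'
#' @param ds result of [generate_dataset()].
#' @param dir output directory.
#' @return The manifest data.frame, invisibly.
#' @export
export_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(ds$cases, function(cs) {
    p1 <- file.path(dir, paste0(cs$id, "_phase1.nii.gz"))
    p2 <- file.path(dir, paste0(cs$id, "_phase2.nii.gz"))
    mk <- file.path(dir, paste0(cs$id, "_mask.nii.gz"))
    write_volume(cs$phase1, p1, "float32")
    write_volume(cs$phase2, p2, "float32")
    write_volume(cs$gt_mask, mk, "uint8")
    data.frame(id = cs$id, phase1 = basename(p1), phase2 = basename(p2),
               mask = basename(mk), seed = cs$seed)
  })
  m <- do.call(rbind, rows)
  save_manifest(m, file.path(dir, "manifest.json"))
  invisible(m)
}
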