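#' Export component maps to neuroimaging formats
#'
#' Writes each grey-matter map as per-vertex GIFTI functional data
#' (`*.func.gii`) when all seeds are surface vertices, or as a NIfTI volume
#' when all seeds are volume voxels (using the seed space's grid and affine);
#' white-matter maps are always reconstituted onto the target grid and written
#' as NIfTI volumes. An optional hard parcellation is written as a GIFTI label
#' file (surface) or integer NIfTI volume.
#'
#' @param components A complete [decompose_group()] result (`wm_maps` present).
#' @param seed_space,target_space The spaces the maps live on.
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @param parcellation Optional [hard_parcellation()] result to export.
#' @return Invisibly, a character vector of the files written.
#' @export
export_maps <- function(components, seed_space, target_space, out_dir,
                        prefix = "tractica", parcellation = NULL) {
  stopifnot(inherits(components, "tractica_components"))
  if (is.null(components$wm_maps))
    stop("components incomplete: wm_maps absent (run backproject first)")
  kinds <- unique(seed_space$kind)
  if (length(kinds) > 1L)
    stop("seeds of mixed kind: configure a split rule before export")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  K <- components$K

  for (k in seq_len(K)) {
    if (kinds == "surface-vertex") {
      f <- file.path(out_dir, sprintf("%s_gm_ic%03d.func.gii", prefix, k))
      write_gifti(f, list(components$gm_maps[k, ]),
                  intent = "NIFTI_INTENT_NONE")
    } else {
      if (is.null(seed_space$grid_shape) || is.null(seed_space$affine))
        stop("volume-voxel seed export needs seed_space grid_shape/affine")
      f <- file.path(out_dir, sprintf("%s_gm_ic%03d.nii.gz", prefix, k))
      vol <- map_to_volume(components$gm_maps[k, ], seed_space$coordinates,
                           seed_space$grid_shape, seed_space$affine)
      RNifti::writeNifti(RNifti::asNifti(vol, pixdim = affine_pixdim(seed_space$affine)), f)
    }
    files <- c(files, f)
  }
  for (k in seq_len(K)) {
    f <- file.path(out_dir, sprintf("%s_wm_ic%03d.nii.gz", prefix, k))
    vol <- map_to_volume(components$wm_maps[k, ], target_space$coordinates,
                         target_space$grid_shape, target_space$affine)
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = affine_pixdim(target_space$affine)), f)
    files <- c(files, f)
  }
  if (!is.null(parcellation)) {
    stopifnot(inherits(parcellation, "tractica_parcellation"))
    if (kinds == "surface-vertex") {
      f <- file.path(out_dir, sprintf("%s_parcellation.label.gii", prefix))
      write_gifti(f, list(parcellation$labels),
                  intent = "NIFTI_INTENT_LABEL",
                  datatype = "NIFTI_TYPE_INT32",
                  labels = sprintf("parcel_%d", seq_len(parcellation$K)))
    } else {
      f <- file.path(out_dir, sprintf("%s_parcellation.nii.gz", prefix))
      vol <- map_to_volume(parcellation$labels, seed_space$coordinates,
                           seed_space$grid_shape, seed_space$affine)
      RNifti::writeNifti(RNifti::asNifti(vol, pixdim = affine_pixdim(seed_space$affine)), f)
    }
    files <- c(files, f)
  }
  invisible(files)
}

affine_pixdim <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# scatter a per-location vector into a 3-D array via mm coordinates + affine
map_to_volume <- function(values, coordinates, grid_shape, affine) {
  if (is.null(coordinates))
    stop("no coordinates available to place values on the grid")
  vox <- round(solve(affine) %*% rbind(t(coordinates), 1))[1:3, , drop = FALSE]
  vox <- t(vox) + 1  # to 1-based indices
  if (any(vox < 1) || any(vox > matrix(grid_shape, nrow(vox), 3, byrow = TRUE)))
    stop("coordinate maps outside the volume grid")
  vol <- array(0, dim = grid_shape)
  vol[cbind(vox[, 1L], vox[, 2L], vox[, 3L])] <- values
  vol
}

# inverse of map_to_volume for round-trip checks: sample a volume at
# coordinates
volume_to_map <- function(vol, coordinates, affine) {
  vox <- round(solve(affine) %*% rbind(t(coordinates), 1))[1:3, , drop = FALSE]
  vox <- t(vox) + 1
  vol[cbind(vox[, 1L], vox[, 2L], vox[, 3L])]
}
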