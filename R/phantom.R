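#' Build a block parcellation layout on a small voxel grid
#'
#' Assigns each region a disjoint slab of voxels along the third axis
#' of a regular grid (background label 0). This is deliberately
#' schematic: the phantom module exercises the volumetric arithmetic
#' (density integration, lesion masking, NIfTI geometry), not anatomy.
#'
#' @param regions Character vector of region names.
#' @param dim Grid dimensions, default `c(32, 32, 32)`.
#' @param tissue_class Optional named character vector region -> class
#'   (`"grey"`/`"white"`); defaults to `"grey"` for all.
#' @return A `parcellation_layout`: list with `parcellation` (integer
#'   array), `labels` (named integer vector) and `tissue_class`.
#' @examples
#' lay <- parcellation_layout(c("genu_cc", "pcg"), dim = c(8, 8, 8))
#' table(lay$parcellation)
#' @export
parcellation_layout <- function(regions, dim = c(32L, 32L, 32L),
                                tissue_class = NULL) {
  if (length(regions) == 0 || anyDuplicated(regions)) {
    abort("`regions` must be a non-empty set of unique names.")
  }
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) abort("`dim` must be three positive integers.")
  if (length(regions) > dim[3]) {
    abort("more regions than z-slices: some regions would get zero voxels.")
  }
  if (is.null(tissue_class)) {
    tissue_class <- setNames(rep("grey", length(regions)), regions)
  }
  if (!all(regions %in% names(tissue_class))) {
    abort("`tissue_class` must name every region.")
  }
  parc <- array(0L, dim)
  # split z-slices into contiguous slabs, one per region
  breaks <- floor(seq(0, dim[3], length.out = length(regions) + 1))
  for (i in seq_along(regions)) {
    parc[, , (breaks[i] + 1):breaks[i + 1]] <- i
  }
  structure(
    list(parcellation = parc,
         labels = setNames(seq_along(regions), regions),
         tissue_class = tissue_class[regions]),
    class = "parcellation_layout"
  )
}

#' Build a spherical binary lesion mask
#'
#' @param dim Grid dimensions.
#' @param centre Voxel coordinates of the sphere centre (1-based).
#' @param radius Radius in voxels.
#' @return 0/1 integer array of dimension `dim`.
#' @export
make_spherical_lesion <- function(dim, centre, radius) {
  dim <- as.integer(dim)
  if (length(centre) != 3L || radius < 0) {
    abort("`centre` must be length 3 and `radius` non-negative.")
  }
  if (any(centre - radius < 1) || any(centre + radius > dim)) {
    abort("lesion sphere extends outside the brain grid.")
  }
  idx <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  d2 <- (idx$x - centre[1])^2 + (idx$y - centre[2])^2 + (idx$z - centre[3])^2
  array(as.integer(d2 <= radius^2), dim)
}

#' Construct a voxel phantom reproducing a subject's tabular volumes
#'
#' Builds a tissue-density phantom on the layout's grid: within each
#' region the density is uniform and scaled so that unmasked integration
#' (`voxel_volume * sum(density)`) reproduces the subject's tabular
#' volume exactly. An optional lesion mask is stored alongside on the
#' same grid.
#'
#' @param subject One-row wide volume tibble (needs `<region>_mm3`
#'   columns for every layout region; `subject_id`, `age_years`,
#'   `ticv_mm3` are carried as metadata when present).
#' @param layout A [parcellation_layout()].
#' @param lesion Optional binary array of the layout's dimensions, or a
#'   list with `centre`/`radius` passed to [make_spherical_lesion()].
#' @param voxel_volume Voxel volume in mm^3 (default 1, i.e. 1 mm
#'   isotropic).
#' @return A `phantom` object: list with `tissue`, `parcellation`,
#'   `labels`, `tissue_class`, `lesion`, `voxel_volume` and subject
#'   metadata.
#' @export
generate_phantom <- function(subject, layout, lesion = NULL, voxel_volume = 1) {
  stopifnot(inherits(layout, "parcellation_layout"))
  if (nrow(subject) != 1L) abort("`subject` must be a single row.")
  if (voxel_volume <= 0) abort("`voxel_volume` must be positive.")
  dims <- dim(layout$parcellation)
  if (is.list(lesion) && !is.array(lesion)) {
    lesion <- make_spherical_lesion(dims, lesion$centre, lesion$radius)
  }
  if (!is.null(lesion)) {
    if (!identical(dim(lesion), dims)) abort("lesion grid does not match layout grid.")
    if (!all(lesion %in% c(0L, 1L))) abort("lesion mask must be binary.")
  }
  tissue <- array(0, dims)
  for (r in names(layout$labels)) {
    col <- paste0(r, "_mm3")
    if (!col %in% names(subject)) {
      abort(paste0("subject table has no column `", col, "`."))
    }
    vox <- layout$parcellation == layout$labels[[r]]
    n_vox <- sum(vox)
    if (n_vox == 0) abort(paste0("region `", r, "` has zero voxels in the layout."))
    tissue[vox] <- subject[[col]] / (n_vox * voxel_volume)
  }
  structure(
    list(tissue = tissue, parcellation = layout$parcellation,
         labels = layout$labels, tissue_class = layout$tissue_class,
         lesion = lesion, voxel_volume = voxel_volume,
         subject_id = subject$subject_id %||% NA_character_,
         age_years = subject$age_years %||% NA_real_,
         ticv_mm3 = subject$ticv_mm3 %||% NA_real_),
    class = "phantom"
  )
}

#' Extract (optionally lesion-masked) ROI volumes from a phantom
#'
#' For each region j, `volume_j = voxel_volume * sum(tissue[v])` over
#' voxels v with parcellation label j and (under the `"mask"` policy)
#' lesion value 0. `masked_fraction` is the proportion of the region's
#' voxels under the lesion.
#'
#' @param phantom A [generate_phantom()] object.
#' @param regions Regions to extract; default all layout regions.
#' @param lesion_policy `"mask"` (exclude lesioned voxels, default) or
#'   `"ignore"` (unmasked extraction).
#' @param lesion Optional lesion array overriding the phantom's own
#'   (used when re-extracting controls under a patient's lesion).
#' @return Tibble with columns `region`, `volume_mm3`,
#'   `masked_fraction`.
#' @export
extract_roi_volumes <- function(phantom, regions = NULL,
                                lesion_policy = c("mask", "ignore"),
                                lesion = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  lesion_policy <- match.arg(lesion_policy)
  regions <- regions %||% names(phantom$labels)
  missing <- setdiff(regions, names(phantom$labels))
  if (length(missing) > 0) {
    abort(paste0("region label(s) absent from parcellation: ",
                 paste(missing, collapse = ", ")))
  }
  lesion <- lesion %||% phantom$lesion
  if (!is.null(lesion) && !identical(dim(lesion), dim(phantom$tissue))) {
    abort("lesion grid geometry does not match the phantom grid.")
  }
  use_mask <- lesion_policy == "mask" && !is.null(lesion)
  purrr::map_dfr(regions, function(r) {
    vox <- phantom$parcellation == phantom$labels[[r]]
    if (use_mask) {
      hit <- vox & lesion == 1L
      mf <- sum(hit) / sum(vox)
      vol <- phantom$voxel_volume * sum(phantom$tissue[vox & !hit])
    } else {
      mf <- 0
      vol <- phantom$voxel_volume * sum(phantom$tissue[vox])
    }
    tibble(region = r, volume_mm3 = vol, masked_fraction = mf)
  })
}

#' Total tissue-class volume of a phantom
#'
#' Sums the (lesion-masked) volumes of all voxels whose region belongs
#' to the requested tissue class, under the same masking policy as
#' [extract_roi_volumes()].
#'
#' @inheritParams extract_roi_volumes
#' @param tissue_class `"grey"` or `"white"`.
#' @return Volume in mm^3 (0 for an empty class).
#' @export
total_tissue_volume <- function(phantom, tissue_class,
                                lesion_policy = c("mask", "ignore"),
                                lesion = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  if (!tissue_class %in% c("grey", "white")) {
    abort(paste0("unknown tissue class `", tissue_class, "`."))
  }
  members <- names(phantom$tissue_class)[phantom$tissue_class == tissue_class]
  if (length(members) == 0) return(0)
  vols <- extract_roi_volumes(phantom, members, lesion_policy, lesion)
  sum(vols$volume_mm3)
}

#' Write / read a phantom as NIfTI-1 images
#'
#' `write_phantom()` writes `<prefix>_tissue.nii.gz` (float densities),
#' `<prefix>_parcellation.nii.gz` (integer labels),
#' `<prefix>_lesion.nii.gz` (binary, if present) and a
#' `<prefix>_meta.json` sidecar holding labels, tissue classes, voxel
#' volume and subject metadata. `read_phantom()` reverses it.
#'
#' @param phantom A phantom object.
#' @param prefix Path prefix for the output files.
#' @return `write_phantom()` the prefix, invisibly; `read_phantom()` a
#'   phantom object.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "phantom"))
  pd <- phantom$voxel_volume^(1 / 3)
  as_nii <- function(x, datatype) {
    RNifti::asNifti(x, datatype = datatype, pixdim = rep(pd, 3))
  }
  RNifti::writeNifti(as_nii(phantom$tissue, "float"),
                     paste0(prefix, "_tissue.nii.gz"))
  RNifti::writeNifti(as_nii(phantom$parcellation, "int16"),
                     paste0(prefix, "_parcellation.nii.gz"))
  if (!is.null(phantom$lesion)) {
    RNifti::writeNifti(as_nii(phantom$lesion, "uint8"),
                       paste0(prefix, "_lesion.nii.gz"))
  }
  meta <- list(labels = as.list(phantom$labels),
               tissue_class = as.list(phantom$tissue_class),
               voxel_volume = phantom$voxel_volume,
               subject_id = phantom$subject_id,
               age_years = phantom$age_years,
               ticv_mm3 = phantom$ticv_mm3)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  tissue <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_tissue.nii.gz"))),
                  dim = dim(RNifti::readNifti(paste0(prefix, "_tissue.nii.gz"))))
  parc_img <- RNifti::readNifti(paste0(prefix, "_parcellation.nii.gz"))
  parc <- array(as.integer(parc_img), dim = dim(parc_img))
  lesion_path <- paste0(prefix, "_lesion.nii.gz")
  lesion <- NULL
  if (file.exists(lesion_path)) {
    img <- RNifti::readNifti(lesion_path)
    lesion <- array(as.integer(img), dim = dim(img))
  }
  structure(
    list(tissue = tissue, parcellation = parc,
         labels = unlist(meta$labels),
         tissue_class = unlist(meta$tissue_class),
         lesion = lesion, voxel_volume = meta$voxel_volume,
         subject_id = meta$subject_id, age_years = meta$age_years,
         ticv_mm3 = meta$ticv_mm3),
    class = "phantom"
  )
}
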