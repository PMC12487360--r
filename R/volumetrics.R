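#' Template tissue label codes
#'
#' Integer label codes used in the fetal macaque atlas segmentations.
#'
#' @return Named integer vector mapping code to tissue name.
#' @export
tissue_labels <- function() {
  c(csf = 1L, cortical_plate = 2L, subplate = 3L, ventricles = 4L,
    gmat = 5L, thalamus = 6L, cerebellum = 7L, brainstem = 8L,
    corpus_callosum = 9L, striatum = 10L, lentiform = 101L, caudate = 102L,
    hippocampus = 103L, globus_pallidus = 104L, amygdala = 106L,
    hypothalamus = 107L)
}

#' Construct a label volume
#'
#' @param labels 3-D integer array of tissue codes (0 = outside the head).
#' @param voxel_dims Voxel edge lengths in mm (length 3, positive).
#' @param label_map Named integer vector of known codes
#'   (default \code{\link{tissue_labels}}).
#' @return A \code{label_volume} list.
#' @export
label_volume <- function(labels, voxel_dims, label_map = tissue_labels()) {
  stopifnot(length(dim(labels)) == 3L, length(voxel_dims) == 3L)
  if (any(!is.finite(voxel_dims)) || any(voxel_dims <= 0)) {
    stop("voxel dimensions must be positive", call. = FALSE)
  }
  present <- setdiff(unique(as.integer(labels)), 0L)
  unknown <- setdiff(present, unname(label_map))
  if (length(unknown)) {
    warning("labels not in label map: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  structure(list(labels = labels, voxel_dims = as.numeric(voxel_dims),
                 label_map = label_map), class = "label_volume")
}

#' Read a label volume from a NIfTI file
#'
#' Voxel dimensions are taken from the header pixdim.
#'
#' @param path NIfTI file (.nii or .nii.gz) of integer tissue labels.
#' @inheritParams label_volume
#' @return A \code{label_volume}.
#' @export
read_label_volume <- function(path, label_map = tissue_labels()) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(as.array(img))), dim = dim(img))
  label_volume(arr, RNifti::pixdim(img)[1:3], label_map)
}

#' Compartment aggregation scheme
#'
#' Maps each reported compartment to the set of label codes it aggregates.
#' The default "atlas" scheme combines regions identifiable at all fetal
#' ages: whole brain (parenchyma plus ventricles, excluding extra-axial
#' CSF), extra-axial CSF, cortical plate, nascent white matter (subplate,
#' germinal matrix, corpus callosum), subcortical gray matter, brainstem,
#' cerebellum, and ventricles; intracranial volume (ICV) is everything
#' including the CSF. Striatal subdivisions that appear at later ages
#' (lentiform/putamen, caudate, globus pallidus) all map into subcortical
#' gray so every age aggregates identically.
#'
#' @param name Scheme name (only "atlas" is built in).
#' @return Named list: compartment -> integer label codes.
#' @export
compartment_scheme <- function(name = "atlas") {
  if (!identical(name, "atlas")) {
    stop("unknown compartment scheme: ", name, call. = FALSE)
  }
  all_codes <- unname(tissue_labels())
  list(
    icv = all_codes,
    whole_brain = setdiff(all_codes, 1L),
    extra_axial_csf = 1L,
    cortical_plate = 2L,
    nascent_white_matter = c(3L, 5L, 9L),
    subcortical_gray = c(6L, 10L, 101L, 102L, 103L, 104L, 106L, 107L),
    brainstem = 8L,
    cerebellum = 7L,
    ventricles = 4L
  )
}

#' Compartment volumes in mL
#'
#' Counts labeled voxels per compartment and multiplies by the voxel volume
#' (mm^3 converted to mL by /1000). Labels listed in the scheme but absent
#' from the volume contribute zero.
#'
#' @param vol A \code{label_volume}.
#' @param scheme A scheme list from \code{\link{compartment_scheme}}.
#' @return Named numeric vector of volumes in mL.
#' @export
compartment_volumes <- function(vol, scheme = compartment_scheme()) {
  stopifnot(inherits(vol, "label_volume"))
  voxel_ml <- prod(vol$voxel_dims) / 1000
  lab <- as.integer(vol$labels)
  counts <- table(lab[lab != 0L])
  codes_present <- as.integer(names(counts))
  vapply(scheme, function(codes) {
    sum(counts[codes_present %in% codes]) * voxel_ml
  }, numeric(1))
}

#' The standard volumetric analysis family
#'
#' The seven compartments analyzed (and Bonferroni-corrected) together:
#' whole brain, cortical plate, nascent white matter, subcortical gray
#' matter, brainstem, cerebellum, and ventricles.
#'
#' @return Character vector of region names.
#' @export
volume_regions <- function() {
  c("whole_brain", "cortical_plate", "nascent_white_matter",
    "subcortical_gray", "brainstem", "cerebellum", "ventricles")
}

#' Fetal volume as percent of the adult value
#'
#' @param fetal_ml,adult_ml Volumes in mL; \code{adult_ml} must be positive.
#' @return 100 * fetal / adult (unrounded).
#' @export
percent_of_adult <- function(fetal_ml, adult_ml) {
  if (any(adult_ml <= 0)) stop("adult volume must be positive", call. = FALSE)
  100 * fetal_ml / adult_ml
}

#' Mean daily growth rate
#'
#' @param v_start,v_end Volumes in mL at \code{t_start} and \code{t_end}.
#' @param t_start,t_end Ages in days; \code{t_end > t_start}.
#' @return (v_end - v_start) / (t_end - t_start), in mL/day.
#' @export
mean_daily_growth <- function(v_start, t_start, v_end, t_end) {
  if (any(t_end <= t_start)) {
    stop("t_end must exceed t_start", call. = FALSE)
  }
  (v_end - v_start) / (t_end - t_start)
}

#' Fold change
#'
#' @param v_start,v_end Start and end values; \code{v_start > 0}.
#' @return v_end / v_start.
#' @export
fold_change <- function(v_start, v_end) {
  if (any(v_start <= 0)) stop("start value must be positive", call. = FALSE)
  v_end / v_start
}
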