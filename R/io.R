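#' Volume input/output (NIfTI)
#'
#' Thin wrappers around RNifti carrying the voxel spacing. Output maps
#' are written on the input grid.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a list with `data` (3-D array) and
#'   `spacing` (mm); `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param data 3-D array.
#' @param spacing Voxel spacing in mm.
#' @export
write_volume <- function(data, spacing, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a dual-energy volume pair
#'
#' @param path_low,path_high NIfTI paths for the two beams.
#' @return A [dect_volume()].
#' @export
read_dect_volume <- function(path_low, path_high) {
  lo <- read_volume(path_low)
  hi <- read_volume(path_high)
  dect_volume(lo$data, hi$data, lo$spacing)
}

#' Stoichiometric parameter JSON I/O
#'
#' Fitted per-beam parameters are stored as a JSON object keyed by
#' `beam_label`, each entry holding `k1` and `k2`.
#'
#' @param params_list Named list of [stoich_params()] (names are beam
#'   labels) or a single [stoich_params()].
#' @param path JSON file path.
#' @return `read_stoich_params()` returns a named list of
#'   [stoich_params()].
#' @export
write_stoich_params <- function(params_list, path) {
  if (inherits(params_list, "stoich_params"))
    params_list <- stats::setNames(list(params_list),
                                   params_list$beam_label)
  obj <- lapply(params_list, function(p) list(k1 = p$k1, k2 = p$k2))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stoich_params
#' @export
read_stoich_params <- function(path) {
  obj <- jsonlite::fromJSON(path)
  out <- lapply(names(obj), function(lab)
    stoich_params(obj[[lab]]$k1, obj[[lab]]$k2, beam_label = lab))
  stats::setNames(out, names(obj))
}

#' SPR conversion-model JSON I/O
#'
#' @param model An [spr_model()].
#' @param path JSON file path.
#' @return `read_spr_model()` returns an [spr_model()].
#' @export
write_spr_model <- function(model, path) {
  stopifnot(inherits(model, "spr_model"))
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spr_model
#' @export
read_spr_model <- function(path) {
  o <- jsonlite::fromJSON(path)
  if (!is.null(o$i_map$zeff)) o$i_map$zeff <- as.numeric(o$i_map$zeff)
  if (!is.null(o$i_map$ln_i)) o$i_map$ln_i <- as.numeric(o$i_map$ln_i)
  spr_model(o$a, o$alpha, o$b, o$c, o$d, n = o$n, i_map = o$i_map,
            beta = o$beta, I_w = o$I_w, rho_e_floor = o$rho_e_floor)
}

#' Calibration-measurement CSV I/O
#'
#' CSV layout: `insert_name`, `beam_label`, `mean_hu`, `hu_std`. Insert
#' compositions come from a tissue table (see [read_tissue_table()]).
#'
#' @param path Measurement CSV path.
#' @param basis A [tissue_basis()] resolving `insert_name`.
#' @return Named list (one element per beam label) of lists of
#'   [calibration_measurement()].
#' @export
read_calibration_csv <- function(path, basis) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("insert_name", "beam_label", "mean_hu") %in% names(df)))
  if (is.null(df$hu_std)) df$hu_std <- NA_real_
  nm <- basis_names(basis)
  lapply(split(df, df$beam_label), function(part)
    lapply(seq_len(nrow(part)), function(i) {
      j <- match(part$insert_name[i], nm)
      if (is.na(j)) stop("unknown insert '", part$insert_name[i], "'",
                         call. = FALSE)
      calibration_measurement(basis$tissues[[j]], part$mean_hu[i],
                              part$hu_std[i])
    }))
}

#' ROI-specification JSON I/O
#'
#' JSON mirror of [roi_cylinder()] / [roi_box()] fields, with a `kind`
#' discriminator.
#'
#' @param path JSON file path.
#' @return An `roi_spec`.
#' @export
read_roi_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  if (identical(o$kind, "cylinder"))
    roi_cylinder(o$axis, as.numeric(o$center), o$diameter, o$length)
  else if (identical(o$kind, "box"))
    roi_box(as.numeric(o$corner), as.numeric(o$extents))
  else stop("unknown ROI kind: ", o$kind, call. = FALSE)
}

#' @rdname read_roi_json
#' @param roi An `roi_spec`.
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "roi_spec"))
  jsonlite::write_json(unclass(roi), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a depth-dose CSV
#'
#' Two columns: `depth_mm`, `dose`.
#'
#' @param path CSV path.
#' @return A [depth_dose()].
#' @export
read_depth_dose <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("depth_mm", "dose") %in% names(df)))
  depth_dose(df$depth_mm, df$dose)
}
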