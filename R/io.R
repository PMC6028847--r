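# NIfTI image carrying the grid geometry: diagonal affine with the voxel-1
# centre at origin + spacing/2, stored in both qform and sform.
nifti_with_grid <- function(arr, grid) {
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin + grid$spacing / 2
  img <- RNifti::asNifti(
    arr, reference = list(pixdim = c(-1, grid$spacing, rep(1, 4))),
    datatype = "double")
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

#' Write a DWI series as NIfTI-1 plus FSL-style .bval
#'
#' The 4-D signal array is written as `<prefix>.nii.gz` with an axial
#' diagonal affine built from the grid (voxel 1 centre at
#' `origin + spacing/2`), and the b-values as a single-line
#' whitespace-separated `<prefix>.bval` text file.
#'
#' @param series a [dwi_series()].
#' @param prefix output path prefix (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_dwi_series <- function(series, prefix) {
  stopifnot(inherits(series, "dwi_series"))
  nii <- paste0(prefix, ".nii.gz")
  bval <- paste0(prefix, ".bval")
  RNifti::writeNifti(nifti_with_grid(series$signal, series$grid), nii,
                     datatype = "double")
  writeLines(paste(format(series$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval)
  invisible(c(nifti = nii, bval = bval))
}

#' Read a DWI series from NIfTI-1 plus .bval
#'
#' Grid geometry is taken from the NIfTI transform: spacing from the
#' diagonal, origin from the offset minus half a voxel. The `.bval` file is
#' a single line of whitespace-separated b-values whose count must match
#' the 4th image dimension.
#'
#' @param nifti_path path to the `.nii`/`.nii.gz` volume.
#' @param bval_path path to the `.bval` sidecar.
#' @return A [dwi_series()].
#' @export
read_dwi_series <- function(nifti_path, bval_path) {
  if (!file.exists(nifti_path)) stop("NIfTI file not found: ", nifti_path)
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path)
  img <- RNifti::readNifti(nifti_path)
  arr <- structure(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L) stop("expected a 4-D DWI volume")
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  if (length(bvals) != dim(arr)[4])
    stop(sprintf("dimension mismatch: %d b-values for %d volumes",
                 length(bvals), dim(arr)[4]))
  if (any(diff(bvals) <= 0))
    stop("b-values must be strictly increasing without duplicates")
  aff <- RNifti::xform(img)
  spacing <- abs(diag(aff)[1:3])
  origin <- aff[1:3, 4] - spacing / 2
  grid <- grid_spec(dim(arr)[1:3], spacing, origin)
  dwi_series(arr, bvals, grid)
}

#' Write / read an ADC map as NIfTI
#'
#' The map is written as `<prefix>_adc.nii.gz` (invalid voxels as `NaN`)
#' and the validity mask as `<prefix>_mask.nii.gz` (0/1).
#'
#' @param map an [adc_map()].
#' @param prefix output path prefix.
#' @return Invisibly, the file paths.
#' @export
write_adc_map <- function(map, prefix) {
  stopifnot(inherits(map, "adc_map"))
  vals <- map$values
  vals[!map$mask] <- NaN
  paths <- c(adc = paste0(prefix, "_adc.nii.gz"),
             mask = paste0(prefix, "_mask.nii.gz"))
  for (nm in names(paths)) {
    arr <- if (nm == "adc") vals else array(as.numeric(map$mask),
                                            dim = dim(map$mask))
    RNifti::writeNifti(nifti_with_grid(arr, map$grid), paths[[nm]],
                       datatype = "double")
  }
  invisible(paths)
}

#' ROI specifications from YAML
#'
#' YAML schema: a list of entries with fields `shape` (`circle`|`sphere`),
#' `center_mm` (3 numbers) and `diameter_mm`.
#'
#' @param path YAML file.
#' @return List of [roi_spec][roi_circle] objects.
#' @export
read_roi_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  lapply(spec, function(e) {
    for (f in c("shape", "center_mm", "diameter_mm"))
      if (is.null(e[[f]])) stop("ROI entry missing field: ", f)
    if (!e$shape %in% c("circle", "sphere"))
      stop("ROI shape must be 'circle' or 'sphere'")
    new_roi(e$shape, unlist(e$center_mm), e$diameter_mm)
  })
}

#' Sphere layout from/to YAML
#'
#' YAML schema: `spheres:` list of `{id, center_mm, diameter_mm}`.
#'
#' @param path YAML file.
#' @return A [sphere_layout()].
#' @export
read_layout_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$spheres)) stop("layout YAML missing 'spheres' list")
  df <- do.call(rbind, lapply(spec$spheres, function(e) {
    ctr <- unlist(e$center_mm)
    data.frame(id = as.character(e$id), cx = ctr[1], cy = ctr[2], cz = ctr[3],
               diameter_mm = e$diameter_mm, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(df$diameter_mm)) stop("sphere diameters must be unique")
  attr(df, "reference_id") <- df$id[which.max(df$diameter_mm)]
  class(df) <- c("sphere_layout", "data.frame")
  df
}

#' @rdname read_layout_yaml
#' @param layout a [sphere_layout()].
#' @export
write_layout_yaml <- function(layout, path) {
  spheres <- lapply(seq_len(nrow(layout)), function(i) {
    list(id = layout$id[i],
         center_mm = c(layout$cx[i], layout$cy[i], layout$cz[i]),
         diameter_mm = layout$diameter_mm[i])
  })
  yaml::write_yaml(list(spheres = spheres), path)
  invisible(path)
}

#' QC thresholds from YAML
#'
#' YAML fields: `cv_max`, `rc_max`, `bias_max`, `noise_max`, `bdep_max`,
#' `snr_min`, `dc_true`; missing fields take the published claim defaults.
#'
#' @param path YAML file.
#' @return A [qiba_thresholds()].
#' @export
read_thresholds_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  allowed <- c("cv_max", "rc_max", "bias_max", "noise_max", "bdep_max",
               "snr_min", "dc_true")
  bad <- setdiff(names(spec), allowed)
  if (length(bad)) stop("unknown threshold field(s): ",
                        paste(bad, collapse = ", "))
  do.call(qiba_thresholds, spec)
}

#' Reader-measurement CSV I/O
#'
#' Standard schema `subject,node,reader,session,volume_cm3,mean_adc,sd_adc`
#' (RFC-4180, header row, decimal points) — the same schema accepts real
#' reader exports.
#'
#' @param table reader-measurement data.frame.
#' @param path CSV file path.
#' @name reader-csv
#' @export
write_reader_csv <- function(table, path) {
  cols <- c("subject", "node", "reader", "session", "volume_cm3",
            "mean_adc", "sd_adc")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname reader-csv
#' @export
read_reader_csv <- function(path) {
  tab <- utils::read.csv(path)
  cols <- c("subject", "node", "reader", "session", "volume_cm3",
            "mean_adc", "sd_adc")
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols))
    stop("reader CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(tab$volume_cm3 <= 0) || any(tab$mean_adc <= 0))
    stop("volumes and mean ADC values must be positive")
  tab
}

#' Write a JSON analysis report
#'
#' Serialises a result list to JSON with full numeric precision, embedding
#' the package version and the seed for reproducibility.
#'
#' @param results named list of results (scalars, vectors, data frames).
#' @param path output path.
#' @param seed the seed used to produce the results (recorded, may be NULL).
#' @return Invisibly, the path.
#' @export
write_report_json <- function(results, path, seed = NULL) {
  payload <- c(list(tool = "dwiqc",
                    version = as.character(utils::packageVersion("dwiqc")),
                    seed = seed),
               results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}
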