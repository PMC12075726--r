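#' Read a b-value table
#'
#' Reads a b-value file — either whitespace-separated plain text or a JSON
#' array — and converts to the canonical ms/um^2 unit.
#'
#' @param path File path.
#' @param units Units of the stored values: `"s/mm2"` (scanner convention,
#'   default) or `"ms/um2"`.
#' @return Numeric vector of b-values in ms/um^2.
#' @export
read_bvals <- function(path, units = c("s/mm2", "ms/um2")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("b-value file not found: ", path, call. = FALSE)
  b <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.numeric(unlist(jsonlite::read_json(path)))
  } else {
    scan(path, what = numeric(), quiet = TRUE)
  }
  if (units == "s/mm2") b <- b / 1000
  b
}

#' Fit parameter maps from files
#'
#' File-level front end of [fit_parameter_maps()]: reads a 4-D multi-b-value
#' NIfTI volume, a b-value table and one or more ROI masks (a single NIfTI
#' whose positive integer labels define the ROIs), fits the nine parameter
#' maps, writes each map as a NIfTI preserving the input geometry, and
#' writes the per-ROI means as a CSV plus a JSON manifest. Inputs are
#' validated before anything is written, so a failing call leaves no partial
#' outputs.
#'
#' @param dwi_path 4-D NIfTI path.
#' @param bval_path b-value table path (see [read_bvals()]).
#' @param mask_path NIfTI path of integer ROI labels (0 = background).
#' @param out_dir Output directory (created if needed).
#' @param config A [fit_config()].
#' @param bval_units Units of the b-value file.
#' @param delta,Delta Gradient timing for the FROC model, ms.
#' @return Invisibly, the manifest list. Outputs: `<parameter>.nii.gz` for
#'   the nine maps, `roi_means.csv`, `manifest.json`.
#' @export
run_fit <- function(dwi_path, bval_path, mask_path, out_dir,
                    config = fit_config(), bval_units = "s/mm2",
                    delta = 15, Delta = 35) {
  for (p in c(dwi_path, bval_path, mask_path)) {
    if (!file.exists(p)) stop("input not found: ", p, call. = FALSE)
  }
  img <- RNifti::readNifti(dwi_path)
  b <- read_bvals(bval_path, bval_units)
  if (length(dim(img)) != 4L) stop("DWI volume must be 4-D", call. = FALSE)
  if (dim(img)[4] != length(b)) {
    stop("b-value count (", length(b), ") does not match the 4th image axis (",
         dim(img)[4], ")", call. = FALSE)
  }
  protocol <- bvalue_protocol(b, delta = delta, Delta = Delta)
  labels <- RNifti::readNifti(mask_path)
  dl <- dim(labels)
  if (length(dl) < 3) dl <- c(dl, rep(1L, 3 - length(dl)))  # dropped singletons
  if (length(dl) != 3 || !all(dl == dim(img)[1:3])) {
    stop("mask grid does not match the DWI grid", call. = FALSE)
  }
  labels <- array(as.integer(round(labels)), dim(img)[1:3])

  maps <- fit_parameter_maps(img, protocol, mask = labels > 0, config = config)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref3d <- RNifti::asNifti(array(img[, , , 1], dim(img)[1:3]), reference = img)
  outputs <- character(0)
  for (p in names(maps$maps)) {
    path <- file.path(out_dir, paste0(p, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(maps$maps[[p]], reference = ref3d),
                       path, datatype = "float")
    outputs <- c(outputs, path)
  }
  roi_ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  roi_means <- purrr::map_dfr(roi_ids, function(id) {
    dplyr::mutate(extract_roi_means(maps, labels == id),
                  node_id = sprintf("roi_%02d", id), .before = 1)
  })
  csv_path <- file.path(out_dir, "roi_means.csv")
  utils::write.csv(roi_means, csv_path, row.names = FALSE)
  manifest <- list(
    command = "fit",
    inputs = list(dwi = dwi_path, bvals = bval_path, mask = mask_path),
    config_hash = rlang::hash(config),
    n_b = length(b),
    outputs = basename(c(outputs, csv_path)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a phantom to files
#'
#' Runs [generate_phantom()] and writes the 4-D image, the per-node label
#' mask and the b-value table as NIfTI/text, the ground-truth parameter
#' table as JSON, and a manifest.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(spec = phantom_spec(), out_dir) {
  ph <- generate_phantom(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(out_dir, "phantom.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(ph$image), img_path, datatype = "float")
  labels <- array(0L, spec$grid)
  for (i in seq_along(ph$masks)) labels[ph$masks[[i]]] <- i
  mask_path <- file.path(out_dir, "nodes.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(labels), mask_path, datatype = "int16")
  bval_path <- file.path(out_dir, "bvals.txt")
  writeLines(paste(ph$protocol$b * 1000, collapse = " "), bval_path)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(ph$truth, truth_path, digits = NA, dataframe = "rows")
  manifest <- list(
    command = "simulate", seed = spec$seed, snr = spec$snr,
    grid = spec$grid, config_hash = rlang::hash(spec[c("grid", "snr", "seed")]),
    outputs = basename(c(img_path, mask_path, bval_path, truth_path)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
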