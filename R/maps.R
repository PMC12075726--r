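#' Voxel-wise parameter mapping
#'
#' Fits the four decay models independently at every in-mask voxel of a 4-D
#' multi-b-value image and assembles the nine parameter maps
#' (`r paste(diffusion_parameter_names(), collapse = ", ")`).
#'
#' Voxels outside the mask, voxels whose b = 0 signal is non-positive, and
#' voxels with any non-positive normalized signal are marked invalid (`NA` in
#' every map, `FALSE` in the validity mask). Non-converged fits leave `NA` in
#' that model's maps only. Voxels are fitted independently with a
#' deterministic optimizer, so the result does not depend on iteration order.
#'
#' @param image 4-D numeric array, last axis matching the protocol length.
#' @param protocol A [bvalue_protocol()].
#' @param mask 3-D logical/0-1 array on the image grid; default all voxels.
#' @param config A [fit_config()].
#' @param models Models to fit; all four by default (all four are required
#'   to produce the full nine-map set).
#' @return A `dwi_map_set`: list with `maps` (named list of 3-D arrays),
#'   `valid` (3-D logical), `converged` (named list of 3-D logicals),
#'   `protocol`, `dim`.
#' @export
fit_parameter_maps <- function(image, protocol = bvalue_protocol(),
                               mask = NULL, config = fit_config(),
                               models = dwi_models()) {
  dm <- dim(image)
  if (length(dm) != 4L) stop("image must be a 4-D array", call. = FALSE)
  if (dm[4] != length(protocol$b)) {
    stop("4th image axis (", dm[4], ") does not match the protocol (",
         length(protocol$b), " b-values)", call. = FALSE)
  }
  models <- match.arg(models, dwi_models(), several.ok = TRUE)
  grid <- dm[1:3]
  if (is.null(mask)) mask <- array(TRUE, grid)
  if (!all(dim(mask) == grid)) stop("mask does not match the image grid",
                                    call. = FALSE)
  mask <- array(as.logical(mask), grid)

  par_names <- unlist(lapply(models, model_parameters))
  maps <- lapply(par_names, function(p) array(NA_real_, grid))
  names(maps) <- par_names
  conv <- lapply(models, function(m) array(FALSE, grid))
  names(conv) <- models
  valid <- array(FALSE, grid)

  flat <- matrix(image, prod(grid), dm[4])
  idx <- which(mask)
  for (v in idx) {
    raw <- flat[v, ]
    decay <- tryCatch(normalize_signal(raw, protocol), error = function(e) NULL)
    if (is.null(decay) || any(decay$signal <= 0)) next
    valid[v] <- TRUE
    for (m in models) {
      fit <- fit_decay(decay, m, config, protocol)
      conv[[m]][v] <- fit$converged
      if (fit$converged) {
        for (p in model_parameters(m)) maps[[p]][v] <- fit$params[[p]]
      }
    }
  }
  structure(list(maps = maps, valid = valid, converged = conv,
                 protocol = protocol, dim = grid),
            class = "dwi_map_set")
}

#' @export
print.dwi_map_set <- function(x, ...) {
  cat("<dwi_map_set> ", paste(x$dim, collapse = " x "), " grid, ",
      sum(x$valid), " valid voxels, maps: ",
      paste(names(x$maps), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Long-format view of a map set
#'
#' @param x A `dwi_map_set`.
#' @param ... Unused.
#' @return Tibble with `x`, `y`, `z`, one column per parameter, and `valid`.
#' @export
as_tibble.dwi_map_set <- function(x, ...) {
  grid <- expand.grid(x = seq_len(x$dim[1]), y = seq_len(x$dim[2]),
                      z = seq_len(x$dim[3]))
  out <- tibble::as_tibble(grid)
  for (p in names(x$maps)) out[[p]] <- as.vector(x$maps[[p]])
  out$valid <- as.vector(x$valid)
  out
}

#' ROI means across the nine parameter maps
#'
#' Propagates one region of interest across every parameter map and returns
#' the arithmetic mean over included voxels — the per-node measurement used
#' by the cohort statistics. Voxels in the exclusion sub-mask (necrotic or
#' cystic areas) and invalid voxels are dropped first.
#'
#' @param map_set A [fit_parameter_maps()] result.
#' @param roi 3-D logical/0-1 array on the map grid.
#' @param exclusion Optional 3-D logical array of voxels to drop (e.g. a
#'   necrosis mask).
#' @return One-row tibble: one column per parameter plus `voxel_count`.
#' @export
extract_roi_means <- function(map_set, roi, exclusion = NULL) {
  stopifnot(inherits(map_set, "dwi_map_set"))
  if (!all(dim(roi) == map_set$dim)) {
    stop("ROI does not match the map grid", call. = FALSE)
  }
  inc <- array(as.logical(roi), map_set$dim) & map_set$valid
  if (!is.null(exclusion)) {
    if (!all(dim(exclusion) == map_set$dim)) {
      stop("exclusion mask does not match the map grid", call. = FALSE)
    }
    inc <- inc & !array(as.logical(exclusion), map_set$dim)
  }
  if (!any(inc)) stop("effective ROI is empty after exclusions",
                      call. = FALSE)
  means <- lapply(map_set$maps, function(m) mean(m[inc], na.rm = TRUE))
  tibble::as_tibble(means) |>
    dplyr::mutate(voxel_count = sum(inc))
}
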