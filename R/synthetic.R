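#' Published reference summaries for benign and metastatic nodes
#'
#' Per-group mean and SD of the nine diffusion parameters in benign versus
#' metastatic retropharyngeal lymph nodes, as reported for the 23/45-node
#' reference cohort this package emulates. These are the default generating
#' distributions of [sample_cohort()] and the inputs of the summary-level
#' statistics (pooled-t recomputation, binormal AUC consistency checks).
#'
#' @return Tibble with columns `parameter`, `unit`, `benign_mean`,
#'   `benign_sd`, `metastatic_mean`, `metastatic_sd`, and `higher_in` (which
#'   group has the larger reported mean).
#' @export
reference_parameter_summaries <- function() {
  tibble::tribble(
    ~parameter,   ~unit,     ~benign_mean, ~benign_sd, ~metastatic_mean, ~metastatic_sd,
    "adc",        "um2/ms",  0.655, 0.063, 0.615, 0.068,
    "ddc",        "um2/ms",  0.721, 0.073, 0.622, 0.077,
    "alpha_sem",  "",        0.685, 0.047, 0.748, 0.044,
    "d_froc",     "um2/ms",  0.631, 0.065, 0.559, 0.061,
    "beta_froc",  "",        0.714, 0.071, 0.789, 0.040,
    "mu_froc",    "um",      3.235, 0.291, 3.461, 0.278,
    "d_ctrw",     "um2/ms",  0.782, 0.084, 0.688, 0.074,
    "alpha_ctrw", "",        0.694, 0.110, 0.649, 0.082,
    "beta_ctrw",  "",        0.821, 0.027, 0.889, 0.040
  ) |>
    dplyr::mutate(higher_in = ifelse(benign_mean > metastatic_mean,
                                     "benign", "metastatic"))
}

#' Reference t statistics for the normally distributed parameters
#'
#' The pooled two-sample t statistics reported for the reference cohort's
#' normally distributed parameters (the two skewed shape parameters were
#' compared by Mann-Whitney and are not recomputable from mean +/- SD).
#'
#' @return Tibble with `parameter` and `t_reported`.
#' @export
reference_t_statistics <- function() {
  tibble::tribble(
    ~parameter, ~t_reported,
    "adc", 2.343, "ddc", 5.077, "alpha_sem", -5.456,
    "d_froc", 4.473, "mu_froc", -3.148, "alpha_ctrw", 1.908
  )
}

#' Group specification for the cohort sampler
#'
#' Defines one diagnostic group: its size, the normal generating
#' distribution of each diffusion parameter, and the categorical morphology
#' frequencies. Defaults reproduce the reference cohort: 23 benign / 45
#' metastatic nodes, parameter means and SDs from
#' [reference_parameter_summaries()], minimal-axial-diameter (MiAD) category
#' frequencies 13/9/1 (benign) and 21/8/16 (metastatic) over
#' \[6,8), \[8,10), >=10 mm, plus maximum-axial-diameter, signal-homogeneity
#' and border frequencies from the same cohort description.
#'
#' @param label `"benign"` or `"metastatic"`.
#' @param n Number of nodes.
#' @param parameters Tibble with `parameter`, `mean`, `sd` for the nine
#'   diffusion parameters; defaults to the group's columns of
#'   [reference_parameter_summaries()].
#' @param miad_probs Probabilities of the MiAD categories
#'   `[6,8)`, `[8,10)`, `>=10` mm (sum to 1).
#' @param maxad_probs Probabilities of the maximum-axial-diameter categories
#'   `[6,10)`, `[10,20)`, `>=20` mm.
#' @param homogeneous_prob Probability a node has homogeneous T2 signal.
#' @param well_defined_prob Probability a node has a well-defined border.
#' @return A `group_spec` list.
#' @export
group_spec <- function(label = c("benign", "metastatic"), n = NULL,
                       parameters = NULL, miad_probs = NULL,
                       maxad_probs = NULL, homogeneous_prob = NULL,
                       well_defined_prob = NULL) {
  label <- match.arg(label)
  ref <- reference_parameter_summaries()
  defaults <- if (label == "benign") {
    list(n = 23L, miad = c(13, 9, 1) / 23, maxad = c(6, 17, 0) / 23,
         homog = 16 / 23, border = 20 / 23,
         parameters = tibble::tibble(parameter = ref$parameter,
                                     mean = ref$benign_mean,
                                     sd = ref$benign_sd))
  } else {
    list(n = 45L, miad = c(21, 8, 16) / 45, maxad = c(20, 24, 1) / 45,
         homog = 29 / 45, border = 35 / 45,
         parameters = tibble::tibble(parameter = ref$parameter,
                                     mean = ref$metastatic_mean,
                                     sd = ref$metastatic_sd))
  }
  n <- if (is.null(n)) defaults$n else as.integer(n)
  parameters <- if (is.null(parameters)) defaults$parameters else parameters
  miad_probs <- if (is.null(miad_probs)) defaults$miad else miad_probs
  maxad_probs <- if (is.null(maxad_probs)) defaults$maxad else maxad_probs
  homogeneous_prob <- if (is.null(homogeneous_prob)) defaults$homog else homogeneous_prob
  well_defined_prob <- if (is.null(well_defined_prob)) defaults$border else well_defined_prob

  if (n <= 0) stop("group size must be positive", call. = FALSE)
  if (any(parameters$sd <= 0)) stop("parameter SDs must be positive", call. = FALSE)
  if (abs(sum(miad_probs) - 1) > 1e-8 || abs(sum(maxad_probs) - 1) > 1e-8) {
    stop("category probabilities must sum to 1", call. = FALSE)
  }
  structure(list(label = label, n = n, parameters = parameters,
                 miad_probs = miad_probs, maxad_probs = maxad_probs,
                 homogeneous_prob = homogeneous_prob,
                 well_defined_prob = well_defined_prob),
            class = "group_spec")
}

# physical truncation bounds for cohort sampling (far in the tails of the
# reference distributions: moment shift < 0.5%)
parameter_truncation <- function(parameter) {
  if (parameter %in% c("alpha_sem", "beta_froc", "alpha_ctrw", "beta_ctrw")) {
    c(0.01, 1)
  } else if (parameter == "mu_froc") {
    c(0.1, 50)
  } else {
    c(1e-4, 5)
  }
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

miad_breaks <- c(6, 8, 10, 20)
maxad_breaks <- c(6, 10, 20, 30)

sample_group <- function(spec, corr_ddc_adc = 0) {
  n <- spec$n
  pars <- spec$parameters
  draws <- lapply(seq_len(nrow(pars)), function(i) {
    tr <- parameter_truncation(pars$parameter[i])
    rnorm_trunc(n, pars$mean[i], pars$sd[i], tr[1], tr[2])
  })
  names(draws) <- pars$parameter
  if (corr_ddc_adc != 0) {
    # Gaussian-copula coupling of ddc to adc (reported correlation ~ 0.8)
    ia <- match("adc", pars$parameter); id <- match("ddc", pars$parameter)
    za <- (draws$adc - pars$mean[ia]) / pars$sd[ia]
    zd <- corr_ddc_adc * za +
      sqrt(1 - corr_ddc_adc^2) * stats::rnorm(n)
    tr <- parameter_truncation("ddc")
    draws$ddc <- pmin(pmax(pars$mean[id] + pars$sd[id] * zd, tr[1]), tr[2])
  }

  miad_cat <- sample.int(3, n, replace = TRUE, prob = spec$miad_probs)
  miad <- miad_breaks[miad_cat] +
    stats::runif(n) * (miad_breaks[miad_cat + 1] - miad_breaks[miad_cat])
  maxad_cat <- sample.int(3, n, replace = TRUE, prob = spec$maxad_probs)

  tibble::tibble(
    group = spec$label, !!!draws,
    miad_mm = miad,
    miad_category = c("[6,8)", "[8,10)", ">=10")[miad_cat],
    maxad_category = c("[6,10)", "[10,20)", ">=20")[maxad_cat],
    homogeneity = ifelse(stats::runif(n) < spec$homogeneous_prob,
                         "homogeneous", "heterogeneous"),
    border = ifelse(stats::runif(n) < spec$well_defined_prob,
                    "well_defined", "ill_defined")
  )
}

#' Sample a synthetic two-group cohort
#'
#' Draws a node-level cohort with the statistical structure the downstream
#' analysis assumes: per group, each of the nine diffusion parameters from an
#' independent normal distribution truncated to its physical bounds, MiAD by
#' category then uniformly within the category (the open-ended top category
#' is capped at 20 mm), and morphology labels from the group frequencies.
#'
#' @param benign,metastatic [group_spec()] objects.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param corr_ddc_adc Optional within-group correlation between `ddc` and
#'   `adc` (default 0: parameters independent). The reference cohort reports
#'   a DDC-ADC correlation of about 0.8; enable this when studying the
#'   multivariable model.
#' @return A tibble with one row per node: `node_id`, `group`, the nine
#'   parameters, `miad_mm`, `miad_category`, `maxad_category`,
#'   `homogeneity`, `border`.
#' @examples
#' cohort <- sample_cohort(seed = 1)
#' dplyr::count(cohort, group)
#' @export
sample_cohort <- function(benign = group_spec("benign"),
                          metastatic = group_spec("metastatic"),
                          seed = 1L, corr_ddc_adc = 0) {
  stopifnot(inherits(benign, "group_spec"), inherits(metastatic, "group_spec"))
  out <- with_seed(seed, {
    dplyr::bind_rows(sample_group(benign, corr_ddc_adc),
                     sample_group(metastatic, corr_ddc_adc))
  })
  out |>
    dplyr::mutate(node_id = sprintf("node_%03d", dplyr::row_number()),
                  group = factor(.data$group, c("benign", "metastatic"))) |>
    dplyr::relocate("node_id")
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Phantom specification
#'
#' Geometry and noise description of a synthetic 4-D multi-b-value phantom:
#' elliptical "nodes" on a background of zero true signal, each decaying
#' according to one of the four models, with optional concentric necrotic
#' core and Rician measurement noise.
#'
#' @param grid Integer triple, image grid size.
#' @param nodes Tibble with one row per node: `node_id`, center `cx`, `cy`,
#'   slice `z`, radii `rx`, `ry` (voxels), `necrosis_r` (core radius,
#'   voxels, 0 for none), `model`, and a list-column `params` of named
#'   parameter vectors. Defaults: two CTRW nodes with the benign and
#'   metastatic reference means.
#' @param snr Signal-to-noise ratio at the b = 0 signal (`Inf` = noiseless);
#'   the Rician sigma is `1 / snr`.
#' @param protocol A [bvalue_protocol()].
#' @param seed Integer seed for the noise draws.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(24L, 24L, 1L), nodes = default_phantom_nodes(),
                         snr = Inf, protocol = bvalue_protocol(), seed = 1L) {
  stopifnot(length(grid) == 3L, all(grid >= 1), snr > 0)
  needed <- c("node_id", "cx", "cy", "z", "rx", "ry", "necrosis_r",
              "model", "params")
  if (!all(needed %in% names(nodes))) {
    stop("nodes table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  structure(list(grid = as.integer(grid), nodes = nodes, snr = snr,
                 protocol = protocol, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_phantom_nodes <- function() {
  tibble::tibble(
    node_id = c("benign_node", "metastatic_node"),
    cx = c(7, 17), cy = c(12, 12), z = c(1, 1),
    rx = c(4, 4), ry = c(5, 5), necrosis_r = c(0, 0),
    model = c("ctrw", "ctrw"),
    params = list(c(d_ctrw = 0.782, alpha_ctrw = 0.694, beta_ctrw = 0.821),
                  c(d_ctrw = 0.688, alpha_ctrw = 0.649, beta_ctrw = 0.889))
  )
}

#' Generate a multi-b-value image phantom
#'
#' Builds the noiseless decay of every node voxel from the forward models,
#' then (for finite SNR) applies Rician corruption
#' `S_obs = sqrt((S + sigma * e1)^2 + (sigma * e2)^2)` with independent
#' standard-normal `e1`, `e2` and `sigma = 1/snr` relative to the unit b = 0
#' signal. Voxels inside a node's necrotic core decay as free fluid
#' (mono-exponential, ADC 2.5 um^2/ms) and are recorded in the necrosis mask.
#' Node ellipses must not overlap, so the ground truth stays unambiguous.
#'
#' @param spec A [phantom_spec()].
#' @return List: `image` (4-D array), `masks` (named list of 3-D logicals,
#'   one per node, necrotic core included), `necrosis` (3-D logical),
#'   `truth` (tibble of generating parameters), `protocol`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  b <- spec$protocol$b
  nb <- length(b)
  img <- array(0, c(grid, nb))
  masks <- list()
  necrosis <- array(FALSE, grid)
  occupied <- array(FALSE, grid)

  xs <- seq_len(grid[1]); ys <- seq_len(grid[2])
  for (i in seq_len(nrow(spec$nodes))) {
    nd <- spec$nodes[i, ]
    inside2d <- outer((xs - nd$cx)^2 / nd$rx^2, (ys - nd$cy)^2 / nd$ry^2, "+") <= 1
    if (nd$z < 1 || nd$z > grid[3] ||
        any(inside2d[c(1, grid[1]), ]) || any(inside2d[, c(1, grid[2])])) {
      stop("node ", nd$node_id, " extends outside the grid", call. = FALSE)
    }
    m <- array(FALSE, grid)
    m[, , nd$z] <- inside2d
    if (any(m & occupied)) {
      stop("nodes overlap; phantom truth would be ambiguous", call. = FALSE)
    }
    occupied <- occupied | m
    core <- array(FALSE, grid)
    if (nd$necrosis_r > 0) {
      core2d <- outer((xs - nd$cx)^2, (ys - nd$cy)^2, "+") <= nd$necrosis_r^2
      core[, , nd$z] <- core2d & inside2d
    }
    necrosis <- necrosis | core
    sig_node <- signal_model(nd$model, b, nd$params[[1]], spec$protocol)
    sig_core <- signal_monoexp(b, 2.5)
    vox <- which(m)
    for (k in seq_len(nb)) {
      slab <- img[, , , k, drop = FALSE]
      slab[vox] <- ifelse(core[vox], sig_core[k], sig_node[k])
      img[, , , k] <- slab
    }
    masks[[nd$node_id]] <- m
  }

  if (is.finite(spec$snr)) {
    sigma <- 1 / spec$snr
    img <- with_seed(spec$seed, {
      e1 <- array(stats::rnorm(length(img)), dim(img))
      e2 <- array(stats::rnorm(length(img)), dim(img))
      sqrt((img + sigma * e1)^2 + (sigma * e2)^2)
    })
  }

  truth <- spec$nodes |>
    dplyr::mutate(param_table = purrr::map(.data$params, function(p) {
      tibble::as_tibble(as.list(p))
    })) |>
    tidyr::unnest("param_table") |>
    dplyr::select(-"params")

  list(image = img, masks = masks, necrosis = necrosis, truth = truth,
       protocol = spec$protocol, spec = spec)
}

#' Read group specifications from a YAML config
#'
#' Loads the cohort-generator configuration from a YAML file with `benign`
#' and `metastatic` sections (group size, per-parameter mean/sd, category
#' counts). The packaged default,
#' `system.file("extdata", "reference_groups.yaml", package = "ngdwi")`,
#' carries the reference-cohort values that [group_spec()] also uses.
#'
#' @param path YAML file path; defaults to the packaged reference config.
#' @return Named list of two [group_spec()] objects, `benign` and
#'   `metastatic`.
#' @export
read_group_specs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_groups.yaml", package = "ngdwi")
  }
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (g in c("benign", "metastatic")) {
    if (is.null(cfg[[g]])) stop("config lacks a '", g, "' section",
                                call. = FALSE)
  }
  known <- c("n_nodes", "parameters", "miad_counts", "maxad_counts",
             "homogeneous_count", "well_defined_count")
  lapply(stats::setNames(c("benign", "metastatic"), c("benign", "metastatic")),
         function(g) {
    s <- cfg[[g]]
    extra <- setdiff(names(s), known)
    if (length(extra)) stop("unknown key(s) in '", g, "' section: ",
                            paste(extra, collapse = ", "), call. = FALSE)
    pars <- tibble::tibble(
      parameter = names(s$parameters),
      mean = unname(vapply(s$parameters, function(p) p$mean, numeric(1))),
      sd = unname(vapply(s$parameters, function(p) p$sd, numeric(1))))
    group_spec(g, n = s$n_nodes, parameters = pars,
               miad_probs = s$miad_counts / sum(s$miad_counts),
               maxad_probs = s$maxad_counts / sum(s$maxad_counts),
               homogeneous_prob = s$homogeneous_count / s$n_nodes,
               well_defined_prob = s$well_defined_count / s$n_nodes)
  })
}
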