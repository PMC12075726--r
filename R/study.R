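#' Group comparison of the nine diffusion parameters
#'
#' Per-parameter comparison of the two diagnostic groups. Each parameter is
#' gated by Shapiro-Wilk normality in both groups (at `normality_alpha`):
#' normal parameters are compared by the pooled two-sample t test, skewed
#' ones by Mann-Whitney. Group means and SDs are always reported.
#'
#' @param cohort A cohort tibble from [sample_cohort()] (columns `group` and
#'   the nine parameters).
#' @param parameters Parameter columns to compare.
#' @param normality_alpha Shapiro-Wilk threshold below which a parameter is
#'   treated as non-normal in that group.
#' @return Tibble: `parameter`, group means/SDs, `method`, `statistic`,
#'   `p_value`.
#' @export
compare_groups <- function(cohort, parameters = diffusion_parameter_names(),
                           normality_alpha = 0.05) {
  stopifnot("group" %in% names(cohort),
            all(parameters %in% names(cohort)))
  g1 <- cohort[cohort$group == "benign", ]
  g2 <- cohort[cohort$group == "metastatic", ]
  purrr::map_dfr(parameters, function(p) {
    x <- g1[[p]]; y <- g2[[p]]
    normal <- stats::shapiro.test(x)$p.value > normality_alpha &&
      stats::shapiro.test(y)$p.value > normality_alpha
    res <- if (normal) student_t(x, y) else mann_whitney(x, y)
    tibble::tibble(parameter = p,
                   benign_mean = mean(x), benign_sd = stats::sd(x),
                   metastatic_mean = mean(y), metastatic_sd = stats::sd(y),
                   method = res$method, statistic = res$statistic,
                   p_value = res$p_value)
  })
}

#' Morphology/characteristics comparison table
#'
#' Category counts per group with Pearson chi-square p-values for the
#' categorical node characteristics (MiAD category, maximum-axial-diameter
#' category, signal homogeneity, border). Levels absent from both groups are
#' dropped before testing.
#'
#' @param cohort A cohort tibble.
#' @return Tibble: `characteristic`, `level`, `benign_n`, `metastatic_n`,
#'   `p_value` (repeated across the characteristic's levels).
#' @export
characteristics_table <- function(cohort) {
  chars <- c("miad_category", "maxad_category", "homogeneity", "border")
  purrr::map_dfr(chars, function(ch) {
    tab <- table(cohort[[ch]], cohort$group)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    p <- if (nrow(tab) >= 2) chi_square_test(tab)$p_value else NA_real_
    tibble::tibble(characteristic = ch, level = rownames(tab),
                   benign_n = as.integer(tab[, "benign"]),
                   metastatic_n = as.integer(tab[, "metastatic"]),
                   p_value = p)
  })
}

#' Diagnostic-performance (ROC) table
#'
#' Empirical ROC of every diffusion parameter, of MiAD, and of the combined
#' logistic model (`beta_ctrw` + MiAD), against the metastatic/benign label.
#' Parameters whose reference mean is higher in the benign group are
#' negated internally so that larger oriented scores always indicate
#' metastasis; cutoffs are reported on the original parameter scale.
#'
#' @param cohort A cohort tibble.
#' @param combined Include the combined `beta_ctrw` + MiAD logistic model row.
#' @return Tibble: `variable`, `auc`, `cutoff`, `youden`, `sensitivity`,
#'   `specificity`, and a list-column `roc` of `dwi_roc` objects (dropped on
#'   CSV export).
#' @export
roc_table <- function(cohort, combined = TRUE) {
  ref <- reference_parameter_summaries()
  vars <- tibble::tibble(
    variable = c(ref$parameter, "miad_mm"),
    higher_is_positive = c(ref$higher_in == "metastatic", TRUE)
  )
  rows <- purrr::pmap_dfr(vars, function(variable, higher_is_positive) {
    r <- empirical_roc(cohort[[variable]], cohort$group,
                       higher_is_positive = higher_is_positive)
    dplyr::bind_cols(tibble::tibble(variable = variable), glance(r),
                     tibble::tibble(roc = list(r)))
  })
  if (combined) {
    fit <- fit_logistic(cohort, "group", c("beta_ctrw", "miad_mm"))
    r <- empirical_roc(predict(fit), cohort$group)
    rows <- dplyr::bind_rows(
      rows,
      dplyr::bind_cols(tibble::tibble(variable = "combined"), glance(r),
                       tibble::tibble(roc = list(r))))
  }
  rows
}

#' DeLong comparison matrix against a reference variable
#'
#' Pairwise DeLong tests of one ROC row (default: the combined model)
#' against every other row of a [roc_table()] result.
#'
#' @param roc_tbl A [roc_table()] result (with its `roc` list-column).
#' @param reference Variable name to compare everything against.
#' @return Tibble: `variable_a`, `variable_b`, `auc_a`, `auc_b`,
#'   `statistic`, `p_value`.
#' @export
delong_matrix <- function(roc_tbl, reference = "combined") {
  stopifnot(reference %in% roc_tbl$variable)
  ra <- roc_tbl$roc[[match(reference, roc_tbl$variable)]]
  others <- setdiff(roc_tbl$variable, reference)
  purrr::map_dfr(others, function(v) {
    rb <- roc_tbl$roc[[match(v, roc_tbl$variable)]]
    res <- delong_compare(ra$scores, rb$scores, ra$labels)
    tibble::tibble(variable_a = reference, variable_b = v,
                   auc_a = res$auc_a, auc_b = res$auc_b,
                   statistic = res$statistic, p_value = res$p_value)
  })
}

#' Logistic-regression table (univariable + multivariable)
#'
#' Univariable logistic regression of the outcome on each diffusion
#' parameter (odds ratios per 0.001 units), plus a forward-stepwise
#' multivariable model over the parameters that are univariably significant.
#'
#' @param cohort A cohort tibble.
#' @param entry_p Significance threshold for univariable inclusion and
#'   stepwise entry.
#' @return Tibble with `analysis` (`"univariable"`/`"multivariable"`) and
#'   the OR table columns of [fit_logistic()].
#' @export
logistic_table <- function(cohort, entry_p = 0.05) {
  pars <- diffusion_parameter_names()
  uni <- purrr::map_dfr(pars, function(p) {
    fit <- fit_logistic(cohort, "group", p)
    dplyr::mutate(tidy(fit), analysis = "univariable", .before = 1)
  })
  sig <- uni$term[uni$p_value < entry_p]
  multi <- NULL
  if (length(sig)) {
    fit <- tryCatch(
      fit_logistic(cohort, "group", sig, selection = "forward_stepwise",
                   entry_p = entry_p),
      error = function(e) NULL)
    if (!is.null(fit)) {
      multi <- dplyr::mutate(tidy(fit), analysis = "multivariable",
                             .before = 1)
    }
  }
  dplyr::bind_rows(uni, multi)
}

#' Run the full synthetic study
#'
#' End-to-end rehearsal of the node-classification analysis on a synthetic
#' cohort: sample the cohort, compare characteristics and the nine
#' parameters between groups, compute the per-variable and combined-model
#' ROC table, the DeLong comparison matrix against the combined model, and
#' the logistic-regression table. Optionally writes the report bundle
#' (CSV tables + JSON report + manifest with seed and config hash) to
#' `out_dir`.
#'
#' @param seed Integer seed; the same seed reproduces the study exactly.
#' @param benign,metastatic [group_spec()] objects.
#' @param corr_ddc_adc Passed to [sample_cohort()].
#' @param out_dir Optional output directory.
#' @return A `dwi_study` list: `cohort`, `characteristics`, `comparison`,
#'   `roc`, `delong`, `logistic`, `seed`.
#' @examples
#' study <- run_study(seed = 1)
#' study$comparison
#' @export
run_study <- function(seed = 1L, benign = group_spec("benign"),
                      metastatic = group_spec("metastatic"),
                      corr_ddc_adc = 0, out_dir = NULL) {
  cohort <- sample_cohort(benign, metastatic, seed = seed,
                          corr_ddc_adc = corr_ddc_adc)
  roc <- roc_table(cohort)
  study <- structure(
    list(cohort = cohort,
         characteristics = characteristics_table(cohort),
         comparison = compare_groups(cohort),
         roc = roc,
         delong = delong_matrix(roc),
         logistic = logistic_table(cohort),
         seed = as.integer(seed)),
    class = "dwi_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.dwi_study <- function(x, ...) {
  cat("<dwi_study> seed", x$seed, "|", nrow(x$cohort), "nodes\n")
  cat("top AUC:",
      x$roc$variable[which.max(x$roc$auc)],
      sprintf("(%.3f)\n", max(x$roc$auc)))
  invisible(x)
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(cohort = study$cohort,
                 characteristics = study$characteristics,
                 comparison = study$comparison,
                 roc = dplyr::select(study$roc, -"roc"),
                 delong = study$delong,
                 logistic = study$logistic)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(tables, report_path, digits = NA, dataframe = "rows")
  manifest <- list(
    command = "study", seed = study$seed,
    config_hash = rlang::hash(list(seed = study$seed,
                                   n = nrow(study$cohort))),
    outputs = basename(c(paths, report_path)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Significance frequencies over replicated synthetic cohorts
#'
#' Repeats [sample_cohort()] + [compare_groups()] over `n_replicates`
#' seeded cohorts and reports, per parameter, how often the group difference
#' reaches `alpha` and how often its sign matches the reference direction.
#'
#' @param n_replicates Number of replicate cohorts.
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param benign,metastatic [group_spec()] objects.
#' @param alpha Significance level.
#' @return Tibble: `parameter`, `sig_rate`, `direction_rate`, `n_replicates`.
#' @export
replicate_significance <- function(n_replicates = 200L, seed = 1L,
                                   benign = group_spec("benign"),
                                   metastatic = group_spec("metastatic"),
                                   alpha = 0.05) {
  ref <- reference_parameter_summaries()
  res <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cohort <- sample_cohort(benign, metastatic, seed = seed + r - 1L)
    cmp <- compare_groups(cohort)
    dplyr::mutate(cmp, replicate = r)
  })
  res |>
    dplyr::left_join(dplyr::select(ref, "parameter", "higher_in"),
                     by = "parameter") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      sig_rate = mean(.data$p_value < alpha),
      direction_rate = mean(
        ifelse(.data$higher_in == "benign",
               .data$benign_mean > .data$metastatic_mean,
               .data$metastatic_mean > .data$benign_mean)),
      n_replicates = n_replicates) |>
    dplyr::arrange(match(.data$parameter, ref$parameter))
}
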