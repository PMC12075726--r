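test_that("cohort sampling is reproducible and respects group sizes", {
  c1 <- sample_cohort(seed = 7)
  c2 <- sample_cohort(seed = 7)
  expect_identical(c1, c2)
  expect_false(identical(sample_cohort(seed = 8), c1))
  counts <- table(c1$group)
  expect_equal(unname(counts[["benign"]]), 23)
  expect_equal(unname(counts[["metastatic"]]), 45)
  expect_true(all(diffusion_parameter_names() %in% names(c1)))
})

test_that("large-sample cohorts reproduce the generating moments", {
  big_b <- group_spec("benign", n = 100000)
  big_m <- group_spec("metastatic", n = 100000)
  co <- sample_cohort(big_b, big_m, seed = 1)
  ref <- reference_parameter_summaries()
  for (i in seq_len(nrow(ref))) {
    p <- ref$parameter[i]
    x <- co[[p]][co$group == "benign"]
    expect_lt(abs(mean(x) - ref$benign_mean[i]) / ref$benign_mean[i], 0.01)
    expect_lt(abs(stats::sd(x) - ref$benign_sd[i]) / ref$benign_sd[i], 0.02)
  }
  # MiAD category frequencies follow the reference counts
  f <- prop.table(table(co$miad_category[co$group == "benign"]))
  expect_equal(unname(f[["[6,8)"]]), 13 / 23, tolerance = 0.02)
  expect_equal(unname(f[["[8,10)"]]), 9 / 23, tolerance = 0.03)
  expect_equal(unname(f[[">=10"]]), 1 / 23, tolerance = 0.1)
  expect_true(all(co$miad_mm >= 6 & co$miad_mm <= 20))
})

test_that("group differences point the reported way at n = 10,000", {
  co <- sample_cohort(group_spec("benign", n = 10000),
                      group_spec("metastatic", n = 10000), seed = 2)
  ref <- reference_parameter_summaries()
  for (i in seq_len(nrow(ref))) {
    d <- mean(co[[ref$parameter[i]]][co$group == "benign"]) -
      mean(co[[ref$parameter[i]]][co$group == "metastatic"])
    expect_true((d > 0) == (ref$higher_in[i] == "benign"),
                info = ref$parameter[i])
  }
})

test_that("optional DDC-ADC coupling induces the requested correlation", {
  co <- sample_cohort(group_spec("benign", n = 20000),
                      group_spec("metastatic", n = 20000),
                      seed = 3, corr_ddc_adc = 0.797)
  r <- stats::cor(co$adc[co$group == "benign"], co$ddc[co$group == "benign"])
  expect_equal(r, 0.797, tolerance = 0.02)
  co0 <- sample_cohort(seed = 3)
  expect_lt(abs(stats::cor(co0$adc, co0$ddc)), 0.5)
})

test_that("phantom generation is seeded and Rician noise behaves", {
  spec <- phantom_spec(snr = 50, seed = 9)
  ph1 <- generate_phantom(spec)
  ph2 <- generate_phantom(spec)
  expect_identical(ph1$image, ph2$image)

  # background has zero true signal: Rayleigh mean sigma * sqrt(pi/2)
  bg <- !(Reduce(`|`, ph1$masks))
  sigma <- 1 / 50
  expect_equal(mean(ph1$image[, , , 1][bg]), sigma * sqrt(pi / 2),
               tolerance = 0.03)

  # noiseless phantom is exactly the forward model
  ph0 <- generate_phantom(phantom_spec(snr = Inf))
  vox <- which(ph0$masks$benign_node)[1]
  flat <- matrix(ph0$image, prod(dim(ph0$image)[1:3]), 12)
  expect_equal(flat[vox, ],
               signal_ctrw(ph0$protocol$b, 0.782, 0.694, 0.821),
               tolerance = 1e-12)
})

test_that("phantom geometry is validated", {
  bad <- phantom_spec(nodes = tibble::tibble(
    node_id = c("a", "b"), cx = c(10, 12), cy = c(12, 12), z = c(1, 1),
    rx = c(4, 4), ry = c(4, 4), necrosis_r = c(0, 0),
    model = "ctrw",
    params = list(c(d_ctrw = 0.7, alpha_ctrw = 0.7, beta_ctrw = 0.8),
                  c(d_ctrw = 0.7, alpha_ctrw = 0.7, beta_ctrw = 0.8))))
  expect_error(generate_phantom(bad), "overlap")
  outside <- phantom_spec(nodes = tibble::tibble(
    node_id = "a", cx = 2, cy = 12, z = 1, rx = 4, ry = 4, necrosis_r = 0,
    model = "ctrw",
    params = list(c(d_ctrw = 0.7, alpha_ctrw = 0.7, beta_ctrw = 0.8))))
  expect_error(generate_phantom(outside), "outside the grid")
})

test_that("a noiseless phantom round-trips through map fitting", {
  spec <- phantom_spec(
    grid = c(12, 12, 1),
    nodes = tibble::tibble(
      node_id = "n", cx = 6, cy = 6, z = 1, rx = 3, ry = 3, necrosis_r = 0,
      model = "ctrw",
      params = list(c(d_ctrw = 0.70, alpha_ctrw = 0.65, beta_ctrw = 0.85))),
    snr = Inf)
  ph <- generate_phantom(spec)
  maps <- fit_parameter_maps(ph$image, ph$protocol, mask = ph$masks$n,
                             config = fit_config(refit_d = TRUE),
                             models = "ctrw")
  means <- extract_roi_means(maps, ph$masks$n)
  expect_equal(means$d_ctrw, 0.70, tolerance = 1e-3)
  expect_equal(means$alpha_ctrw, 0.65, tolerance = 1e-3)
  expect_equal(means$beta_ctrw, 0.85, tolerance = 1e-3)
})

test_that("necrotic cores are recorded and decay like free fluid", {
  spec <- phantom_spec(
    grid = c(14, 14, 1),
    nodes = tibble::tibble(
      node_id = "n", cx = 7, cy = 7, z = 1, rx = 4, ry = 4, necrosis_r = 1.5,
      model = "monoexp", params = list(c(adc = 0.6))),
    snr = Inf)
  ph <- generate_phantom(spec)
  expect_true(any(ph$necrosis))
  core_vox <- which(ph$necrosis)[1]
  flat <- matrix(ph$image, prod(dim(ph$image)[1:3]), 12)
  expect_equal(flat[core_vox, ], signal_monoexp(ph$protocol$b, 2.5),
               tolerance = 1e-12)
})

test_that("the packaged YAML config reproduces the default group specs", {
  specs <- read_group_specs()
  expect_named(specs, c("benign", "metastatic"))
  defaults <- group_spec("metastatic")
  expect_equal(specs$metastatic$n, defaults$n)
  expect_equal(specs$metastatic$parameters$mean, defaults$parameters$mean)
  expect_equal(specs$benign$miad_probs, group_spec("benign")$miad_probs)
  # identical cohorts from either construction route
  expect_identical(sample_cohort(specs$benign, specs$metastatic, seed = 5),
                   sample_cohort(seed = 5))
  # unknown keys are rejected
  bad <- withr::local_tempfile(fileext = ".yaml")
  cfg <- yaml::read_yaml(system.file("extdata", "reference_groups.yaml",
                                     package = "ngdwi"))
  cfg$benign$typo_key <- 1
  yaml::write_yaml(cfg, bad)
  expect_error(read_group_specs(bad), "unknown key")
})
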