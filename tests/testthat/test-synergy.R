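test_that("the Webb CI identities and direction hold", {
  expect_equal(webb_ci(0.5, 0.5, 0.25), 1.0)
  expect_equal(webb_ci(0.5, 0.5, 0.125), 0.5)
  expect_equal(webb_ci(0.9, 0.9, 0.9), 0.9 / 0.81)

  expect_error(webb_ci(0, 0.5, 0.2), "undefined")
  expect_error(webb_ci(0.5, 0.5, -0.1), "negative")
  expect_warning(ci <- webb_ci(1.05, 0.5, 0.4), "clipped")
  expect_equal(ci, 0.8)

  # an ineffective monotherapy contributes nothing
  s <- c(0.2, 0.5, 0.9)
  expect_equal(webb_ci(s, 1, s * 0.7) / 0.7, rep(1, 3))

  # percent-vs-fraction input scale consistency
  path <- tempfile(fileext = ".csv")
  writeLines(c("cell_line,treatment,survival",
               "A,TMZ,50", "A,TRAIL,40", "A,TMZ+TRAIL,10"), path)
  pct <- read_viability(path, dialect = "percent")
  frac <- response_table(data.frame(cell_line = "A",
                                    treatment = c("TMZ", "TRAIL",
                                                  "TMZ+TRAIL"),
                                    survival = c(0.5, 0.4, 0.1)))
  expect_equal(combination_index_table(pct)$ci,
               combination_index_table(frac)$ci)
})

test_that("synergy classes bin half-open with upper-inclusive edges", {
  cls <- assign_synergy_class(c(0.3, 0.5, 0.7, 0.9, 1.2))
  expect_equal(as.character(cls),
               c("SYNERGY_HIGH", "SYNERGY_HIGH", "SYNERGY_MODERATE",
                 "SYNERGY_MODERATE", "NON_SYNERGISTIC"))
  expect_error(assign_synergy_class(0), "positive")
  expect_error(assign_synergy_class(0.5, bins = c(0.9, 0.5)),
               "strictly increasing")

  # class is nonincreasing in responsiveness order as CI grows
  ci <- sort(stats::runif(100, 0.05, 2))
  idx <- as.integer(assign_synergy_class(ci))
  expect_true(all(diff(idx) >= 0))
})

test_that("noiseless generated combinations round-trip the true CI", {
  cfg <- simulation_config(n_lines = 10, seed = 41, noise_sd = 0,
                           ci_noise_sd = 0, true_ci = 0.4)
  panel <- generate_panel(cfg)
  resp <- generate_responses(panel, cfg)$responses
  combo <- generate_combination(resp, cfg)
  tab <- combination_index_table(combo$responses, mono_floor = 0)
  expect_equal(tab$ci, rep(0.4, 10), tolerance = 1e-12)

  cfg1 <- simulation_config(n_lines = 6, seed = 42, noise_sd = 0,
                            ci_noise_sd = 0, true_ci = 1)
  combo1 <- generate_combination(
    generate_responses(generate_panel(cfg1), cfg1)$responses, cfg1)
  expect_equal(combination_index_table(combo1$responses, mono_floor = 0)$ci,
               rep(1, 6), tolerance = 1e-12)
})

test_that("the CI estimator's noise floor matches a Monte-Carlo bound", {
  # with survival noise SD 0.02 and monotherapy survival >= 0.5, the
  # median absolute CI error stays within 0.08
  set.seed(43)
  errs <- replicate(100, {
    s_a <- stats::runif(1, 0.5, 1)
    s_b <- stats::runif(1, 0.5, 1)
    ci <- stats::runif(1, 0.4, 1.2)
    s_ab <- pmin(pmax(ci * s_a * s_b + stats::rnorm(1, 0, 0.02), 0), 1)
    abs(webb_ci(s_a, s_b, s_ab) - ci)
  })
  expect_lte(stats::median(errs), 0.08)
})

test_that("synergy LOOCV predicts CI classes planted in the FG structure", {
  # a well-separated FG cluster structure determines the true CI: lines
  # with a competent death machinery respond synergistically
  accs <- vapply(1:5, function(s) {
    cfg <- simulation_config(n_lines = 24, seed = 500 + s, noise_sd = 0,
                             ci_noise_sd = 0, class_means = c(5, 0, -5))
    panel <- generate_panel(cfg)
    cfg$true_ci <- c(0.3, 0.7, 1.0)[as.integer(attr(panel, "class_true"))]
    resp <- generate_responses(panel, cfg)$responses
    combo <- generate_combination(resp, cfg)
    fg <- compute_fg_matrix(aggregate_replicates(panel))
    tab <- combination_index_table(combo$responses, mono_floor = 0)
    tab <- tab[match(rownames(fg), tab$cell_line), ]
    expect_equal(tab$ci, cfg$true_ci, tolerance = 1e-10)  # round trip
    labels <- assign_synergy_class(tab$ci, bins = c(0.5, 0.9))
    loocv_accuracy(synergy_loocv(fg, labels, fixed_k = 4))
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})
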