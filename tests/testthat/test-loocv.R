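test_that("LOOCV is deterministic and leaks nothing from the held-out line", {
  cfg <- simulation_config(n_lines = 12, seed = 31, class_means = c(5, 0, -5))
  fg <- compute_fg_matrix(aggregate_replicates(generate_panel(cfg)))
  lab <- attr(generate_panel(cfg), "class_true")

  r1 <- loocv_predict(fg, lab, fixed_k = 4, return_models = TRUE)
  r2 <- loocv_predict(fg, lab, fixed_k = 4, return_models = TRUE)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "fold_models"), attr(r2, "fold_models"))

  # mutating a held-out line leaves that fold's fitted models bit-exact
  for (i in c(1, 7, 12)) {
    fg_mut <- fg
    fg_mut[i, ] <- fg[i, ] * 1000 + 5
    r_mut <- loocv_predict(fg_mut, lab, fixed_k = 4, return_models = TRUE)
    expect_identical(attr(r_mut, "fold_models")[[i]],
                     attr(r1, "fold_models")[[i]])
  }
})

test_that("LOOCV recovers well-separated synthetic class structure", {
  accs <- vapply(1:5, function(s) {
    cfg <- simulation_config(n_lines = 24, seed = 300 + s,
                             class_means = c(6, 0, -6))
    panel <- generate_panel(cfg)
    fg <- compute_fg_matrix(aggregate_replicates(panel))
    loocv_accuracy(loocv_predict(fg, attr(panel, "class_true"),
                                 fixed_k = 4))
  }, numeric(1))
  expect_gte(mean(accs), 0.85)
})

test_that("folds record per-fold Kaiser k or the fixed override", {
  fg <- rand_fg_matrix(12, 11, seed = 33)
  lab <- factor(rep(c("LOW", "RESISTANT"), each = 6),
                levels = response_levels())
  fixed <- loocv_predict(fg, lab, fixed_k = 4)
  expect_true(all(fixed$k == 4L))
  kaiser <- loocv_predict(fg, lab)
  expect_true(all(kaiser$k >= 1L & kaiser$k <= 11L))
})

test_that("held-out labels are mapped through the fold's pooling", {
  # one HIGH line: every fold that drops a non-HIGH line pools HIGH->LOW
  fg <- rand_fg_matrix(8, 11, seed = 34)
  lab <- factor(rep(c("HIGH", "LOW", "RESISTANT"), c(1, 4, 3)),
                levels = response_levels())
  res <- loocv_predict(fg, lab, fixed_k = 3)
  expect_equal(res$observed[1], "LOW")
  expect_false(any(res$predicted == "HIGH", na.rm = TRUE))
})

test_that("degenerate folds are reported, not silently dropped", {
  fg <- rand_fg_matrix(6, 11, seed = 35)
  # leaving out line 6 makes training all-LOW after pooling
  lab <- factor(c(rep("LOW", 5), "RESISTANT"), levels = response_levels())
  res <- loocv_predict(fg, lab, fixed_k = 3)
  expect_true(is.na(res$predicted[6]))
  expect_false(res$correct[6])
  skipped <- loocv_predict(fg, lab, fixed_k = 3, skip_degenerate = TRUE)
  expect_equal(loocv_accuracy(skipped),
               mean(res$correct[!is.na(res$predicted)]))
})

test_that("treatment recommendation follows the more responsive prediction", {
  expect_equal(recommend_treatment(
    c("RESISTANT", "LOW", "HIGH", NA),
    c("LOW", "LOW", "RESISTANT", "LOW")),
    c("TRAIL", "either", "TMZ", "unavailable"))
})

test_that("recommendation scoring uses observed survival and a similarity margin", {
  # recommended arm kills more: correct
  ev <- evaluate_recommendations("TMZ", 0.20, 0.90)
  expect_true(ev$correct)
  # recommended arm kills less but within tolerance: correct
  ev <- evaluate_recommendations("TMZ", 0.55, 0.50, similar_tol = 0.10)
  expect_true(ev$correct)
  # recommended arm clearly worse: incorrect
  ev <- evaluate_recommendations("TMZ", 0.90, 0.20)
  expect_false(ev$correct)
  # symmetric under arm relabeling
  ev1 <- evaluate_recommendations(c("TMZ", "TRAIL"), c(0.2, 0.9),
                                  c(0.9, 0.2))
  ev2 <- evaluate_recommendations(c("TRAIL", "TMZ"), c(0.9, 0.2),
                                  c(0.2, 0.9))
  expect_equal(ev1$correct, ev2$correct)
  # "either" is acceptable; "unavailable" never is
  expect_true(evaluate_recommendations("either", 0.5, 0.52)$correct)
  expect_false(evaluate_recommendations("unavailable", 0.2, 0.9)$correct)
})
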