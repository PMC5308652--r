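test_that("target depletion zeroes exactly the requested proteins", {
  x <- stats::setNames(seq_len(19), canonical_proteins())
  x[c("Bcl-2", "Bcl-xL", "Mcl-1")] <- c(40, 25, 10)
  d <- deplete_targets(x)
  expect_equal(unname(d[c("Bcl-2", "Bcl-xL")]), c(0, 0))
  expect_equal(d[setdiff(names(x), c("Bcl-2", "Bcl-xL"))],
               x[setdiff(names(x), c("Bcl-2", "Bcl-xL"))])
  expect_equal(unname(compute_fg_row(d)["Bcl-2+Bcl-xL+Mcl-1"]), 10)

  # idempotent on already-zero targets; generalizes to other targets
  expect_equal(deplete_targets(d), d)
  dm <- deplete_targets(x, targets = "Mcl-1")
  expect_equal(unname(dm["Mcl-1"]), 0)
  expect_equal(dm[setdiff(names(x), "Mcl-1")],
               x[setdiff(names(x), "Mcl-1")])
  expect_error(deplete_targets(x, targets = "NotAProtein"), "unknown")

  # fractional depletion scales linearly
  half <- deplete_targets(x, fraction = 0.5)
  expect_equal(unname(half[c("Bcl-2", "Bcl-xL")]), c(20, 12.5))

  # panel form perturbs every line
  panel <- aggregate_replicates(generate_panel(simulation_config(seed = 61)))
  dp <- deplete_targets(panel)
  expect_true(all(panel_matrix(dp)[, c("Bcl-2", "Bcl-xL")] == 0))
})

test_that("repositioning displacement follows the projection's linearity", {
  cfg <- simulation_config(seed = 62)
  panel <- aggregate_replicates(generate_panel(cfg))
  fg <- compute_fg_matrix(panel)
  pc <- fit_pc_model(fg, n_components = 4)
  X <- panel_matrix(panel)
  row <- X[4, ]
  fg_pre <- compute_fg_row(row)

  # a perturbation that changes no FG gives zero displacement
  rp0 <- reposition(pc, fg_pre, fg_pre)
  expect_equal(unname(rp0$displacement), rep(0, 4))

  # zeroing Bcl-2/Bcl-xL changes only the anti-apoptotic FG, so the
  # displacement is collinear with that FG's loading row
  fg_post <- compute_fg_row(deplete_targets(row))
  rp <- reposition(pc, fg_pre, fg_post)
  load_row <- pc$loadings["Bcl-2+Bcl-xL+Mcl-1", 1:4]
  cross <- rp$displacement / load_row
  expect_lt(max(abs(cross - mean(cross))), 1e-10)

  # |displacement| has the closed form (dFG/SD) * |loading row|
  dz <- (fg_pre - fg_post)["Bcl-2+Bcl-xL+Mcl-1"] /
    pc$scale["Bcl-2+Bcl-xL+Mcl-1"]
  expect_equal(sqrt(sum(rp$displacement^2)),
               unname(dz * sqrt(sum(load_row^2))), tolerance = 1e-12)
})

test_that("movement vectors are linear in the standardized change", {
  pc <- fit_pc_model(rand_fg_matrix(10, 11, seed = 63), n_components = 4)
  expect_equal(unname(movement_vector(pc, "FG2", 0)), rep(0, 4))
  expect_equal(movement_vector(pc, "FG2", 2.4),
               2 * movement_vector(pc, "FG2", 1.2))
  expect_error(movement_vector(pc, "FG99", 1), "unknown FG")
  expect_error(movement_vector(pc, "FG2", -1), ">= 0")
})

test_that("movement-vector and reprojection formulations agree to 1e-10", {
  cfg <- simulation_config(seed = 64)
  panel <- aggregate_replicates(generate_panel(cfg))
  pc <- fit_pc_model(compute_fg_matrix(panel), n_components = 4)
  X <- panel_matrix(panel)
  for (i in seq_len(nrow(X))) {
    row <- X[i, ]
    fg_pre <- compute_fg_row(row)
    fg_post <- compute_fg_row(deplete_targets(row))
    rp <- reposition(pc, fg_pre, fg_post)
    dz <- unname((fg_pre - fg_post)["Bcl-2+Bcl-xL+Mcl-1"] /
                   pc$scale["Bcl-2+Bcl-xL+Mcl-1"])
    mv <- movement_vector(pc, "Bcl-2+Bcl-xL+Mcl-1", dz)
    expect_lt(max(abs(mv - rp$displacement)), 1e-10)
  }
})

test_that("displacement grows with the lines' target content", {
  pc <- fit_pc_model(rand_fg_matrix(12, 11, seed = 65), n_components = 4)
  norms <- vapply(seq(0, 3, by = 0.5), function(dz) {
    sqrt(sum(movement_vector(pc, "FG1", dz)^2))
  }, numeric(1))
  expect_true(all(diff(norms) >= 0))
})

test_that("verdicts: class improvement, zero-target lines, sign flips", {
  cfg <- simulation_config(n_lines = 12, seed = 66, class_means = c(5, 0, -5))
  panel <- aggregate_replicates(generate_panel(cfg))
  fg <- compute_fg_matrix(panel)
  pc <- fit_pc_model(fg, n_components = 4)
  coords <- project(pc, fg)
  labels <- pool_singleton_classes(attr(generate_panel(cfg), "class_true"))
  lda <- fit_class_regions(coords, labels)
  X <- panel_matrix(panel)

  # a line with no target expression is never predicted sensitized
  row0 <- X[1, ]
  row0[c("Bcl-2", "Bcl-xL")] <- 0
  p0 <- predict_sensitization(pc, lda, row0, cell_line = "zero")
  expect_equal(p0$verdict, "NOT_SENSITIZED")
  expect_equal(unname(p0$displacement), rep(0, 4))

  # verdict requires a strictly more responsive post class
  tab <- sensitization_table(pc, lda, panel, arm = "TRAIL")
  expect_true(all(tab$verdict %in% c("SENSITIZED", "NOT_SENSITIZED")))
  better <- match(tab$post_class, lda$classes) <
    match(tab$pre_class, lda$classes)
  expect_equal(tab$verdict == "SENSITIZED", better)

  # flipping a loading column flips coordinates and vectors consistently
  pc_flip <- pc
  pc_flip$loadings[, 2] <- -pc_flip$loadings[, 2]
  lda_flip <- fit_class_regions(project(pc_flip, fg), labels)
  tab_flip <- sensitization_table(pc_flip, lda_flip, panel, arm = "TRAIL")
  expect_equal(tab_flip$verdict, tab$verdict)
})
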