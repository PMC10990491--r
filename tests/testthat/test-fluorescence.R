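make_traces <- function(values, times = 0, nucleus = NULL) {
  # values: matrix cells x times of whole-cell mean fluorescence
  values <- as.matrix(values)
  df <- expand.grid(cell = seq_len(nrow(values)), t = seq_along(times))
  out <- data.frame(
    fov = "f1",
    object_id = paste0("c", df$cell),
    frame = df$t - 1,
    time = times[df$t],
    cell_mean_fluor = values[cbind(df$cell, df$t)],
    cell_area = 400,
    stringsAsFactors = FALSE
  )
  if (!is.null(nucleus)) {
    nucleus <- as.matrix(nucleus)
    out$nucleus_mean_fluor <- nucleus[cbind(df$cell, df$t)]
    out$nucleus_area <- 60
  }
  cell_traces(out)
}

test_that("fold change follows the stated baseline-population formula", {
  tr <- make_traces(cbind(c(80, 120, 100), c(380, 200, 100)),
                    times = c(0, 6))
  fc <- fold_change(tr, baseline_frame = 0)
  expect_equal(fc$baseline_mean, 100)
  at6 <- fc$per_cell[fc$per_cell$time == 6, ]
  expect_equal(at6$fold_change[at6$object_id == "c1"], 2.8)
  expect_equal(at6$fold_change[at6$object_id == "c2"], 1.0)
  expect_equal(at6$fold_change[at6$object_id == "c3"], 0.0)
  # the across-cell mean at the baseline frame is exactly zero
  expect_equal(fc$population$mean[fc$population$time == 0], 0)
  # all cells at the baseline mean at all times: identically zero
  tr0 <- make_traces(matrix(100, 3, 4), times = c(0, 6, 12, 18))
  expect_true(all(fold_change(tr0, 0)$per_cell$fold_change == 0))
})

test_that("fold change rejects a degenerate baseline", {
  tr <- make_traces(cbind(c(0, 0), c(10, 20)), times = c(0, 6))
  expect_error(fold_change(tr, baseline_frame = 0), "positive")
  tr2 <- make_traces(matrix(c(10, 20), 2, 1), times = 0)
  expect_error(fold_change(tr2, baseline_frame = 99), "baseline")
})

test_that("nuclear enrichment is the nucleus/cell ratio, scale invariant", {
  cellv <- cbind(c(100, 50), c(120, 60))
  nucv <- cbind(c(300, 50), c(120, 90))
  tr <- make_traces(cellv, times = c(0, 6), nucleus = nucv)
  enr <- nuclear_enrichment(tr)
  e0 <- enr$per_cell[enr$per_cell$time == 0, ]
  expect_equal(e0$enrichment[e0$object_id == "c1"], 3.0)
  expect_equal(e0$enrichment[e0$object_id == "c2"], 1.0)  # uniform cell
  # global intensity rescaling leaves enrichment unchanged
  tr2 <- make_traces(cellv * 37.5, times = c(0, 6), nucleus = nucv * 37.5)
  expect_equal(nuclear_enrichment(tr2)$per_cell$enrichment,
               enr$per_cell$enrichment)
  # missing nuclear channel is an error
  expect_error(nuclear_enrichment(make_traces(cellv, times = c(0, 6))),
               "nucleus")
})

test_that("relative fluorescence interpolates between calibration windows", {
  tt <- seq(0, 80, by = 5)
  base <- ifelse(tt >= 10 & tt <= 20 | tt >= 50 & tt <= 60, 300,
                 ifelse(tt >= 30 & tt <= 40 | tt >= 70 & tt <= 80, 100, 200))
  rf <- relative_fluorescence(data.frame(time = tt, fluor = base))
  expect_equal(attr(rf, "f_min")[["all"]], 100)
  expect_equal(attr(rf, "f_max")[["all"]], 300)
  expect_equal(rf$rf[tt == 15], 1)
  expect_equal(rf$rf[tt == 35], 0)
  expect_equal(rf$rf[tt == 25], 0.5)
  expect_false(any(rf$out_of_range))
  # affine invariance: F -> aF + b leaves RF unchanged
  rf2 <- relative_fluorescence(data.frame(time = tt, fluor = 3.7 * base + 55))
  expect_equal(rf2$rf, rf$rf)
  # out-of-range values are flagged, not clipped
  spik <- base; spik[tt == 45] <- 500
  rf3 <- relative_fluorescence(data.frame(time = tt, fluor = spik))
  expect_gt(rf3$rf[tt == 45], 1)
  expect_true(rf3$out_of_range[tt == 45])
  # F_max <= F_min is an error
  expect_error(relative_fluorescence(data.frame(time = tt, fluor = rep(5, length(tt)))),
               "exceed")
})

test_that("population curves average only the cells present at each time", {
  per_cell <- data.frame(object_id = c("a", "b", "a"),
                         time = c(0, 0, 6), v = c(1, 3, 5))
  pc <- population_curve(per_cell, "v")
  expect_equal(pc$mean, c(2, 5))
  expect_equal(pc$n, c(2, 1))
  expect_true(is.na(pc$ci95_low[2]))  # single cell: CI undefined
  expect_error(population_curve(per_cell, "v", times = 99), "no cells")
})
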