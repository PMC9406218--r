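# evaluation metrics: confusion counts, pixel metrics, connected
# components, aggregated Jaccard index (against a brute-force oracle),
# cell counting and report aggregation

test_that("confusion counts enumerate pixels and conserve the total", {
  c1 <- confusion_counts(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_equal(unclass(c1)[c("tp", "fp", "fn", "tn")],
               list(tp = 4L, fp = 0L, fn = 0L, tn = 0L))
  c2 <- confusion_counts(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(c2$tn, 9L)
  g <- matrix(c(1, 1, 0, 0), 1, 4)
  p <- matrix(c(0, 1, 1, 0), 1, 4)
  c3 <- confusion_counts(g, p)
  expect_equal(unclass(c3)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  set.seed(1)
  gg <- matrix(rbinom(64, 1, 0.4), 8, 8)
  pp <- matrix(rbinom(64, 1, 0.5), 8, 8)
  cc <- confusion_counts(gg, pp)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 64L)
})

test_that("pixel metrics match the defining formulas and conventions", {
  m <- pixel_metrics(list(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(unname(m), c(0.5, 0.5, 0.5))
  m2 <- pixel_metrics(list(tp = 3, fp = 1, fn = 1, tn = 9))
  expect_equal(m2[["sensitivity"]], 0.75)
  expect_equal(m2[["specificity"]], 0.9)
  m3 <- pixel_metrics(confusion_counts(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_equal(m3[["dice"]], 1)
  expect_equal(m3[["sensitivity"]], 1)
  # absent class scores as perfect agreement
  m4 <- pixel_metrics(list(tp = 0, fp = 0, fn = 0, tn = 4))
  expect_equal(unname(m4), c(1, 1, 1))
})

test_that("connected components honour connectivity and raster order", {
  m <- matrix(0L, 7, 7)
  m[1:2, 1:2] <- 1L
  m[1, 6:7] <- 1L
  m[6:7, 3:4] <- 1L
  lab <- connected_components(m, 8)
  expect_equal(max(lab), 3L)
  # raster order of first pixels: top-left block, top-right, bottom
  expect_equal(lab[1, 1], 1L)
  expect_equal(lab[1, 6], 2L)
  expect_equal(lab[6, 3], 3L)

  d <- matrix(0L, 2, 2); d[1, 1] <- 1L; d[2, 2] <- 1L
  expect_equal(max(connected_components(d, 8)), 1L)
  expect_equal(max(connected_components(d, 4)), 2L)

  expect_equal(max(connected_components(matrix(0L, 4, 4), 8)), 0L)
  expect_error(connected_components(m, 6), "connectivity")
})

test_that("aggregated Jaccard matches hand-worked examples", {
  a <- matrix(0L, 6, 6); a[2:3, 2:3] <- 1L
  expect_equal(aggregated_jaccard(a, a), 1.0)
  expect_equal(aggregated_jaccard(a, matrix(0L, 6, 6)), 0.0)
  expect_equal(aggregated_jaccard(matrix(0L, 6, 6), matrix(0L, 6, 6)), 1.0)

  # exact match plus a disjoint 2-px spurious component: 4 / (4 + 2)
  pr <- a
  pr[6, 5:6] <- 2L
  expect_equal(aggregated_jaccard(a, pr), 4 / 6, tolerance = 1e-12)

  # instances A (4 px) matched exactly, B (3 px) missed: 4 / (4 + 3)
  g2 <- a
  g2[5, 1:3] <- 2L
  p2 <- a
  expect_equal(aggregated_jaccard(g2, p2), 4 / 7, tolerance = 1e-12)
})

test_that("aggregated Jaccard agrees with the brute-force oracle", {
  for (s in 1:40) {
    gt <- rand_instance_map(10, 10, 4, seed = 1000 + s)
    pred <- rand_instance_map(10, 10, 4, seed = 2000 + s)
    expect_equal(aggregated_jaccard(gt, pred), aji_oracle(gt, pred),
                 tolerance = 1e-12)
  }
})

test_that("AJI <= pixel Jaccard <= Dice on random instance maps", {
  for (s in 1:25) {
    gt <- rand_instance_map(12, 12, 4, seed = 3000 + s)
    pred <- rand_instance_map(12, 12, 4, seed = 4000 + s)
    cc <- confusion_counts((gt > 0) * 1L, (pred > 0) * 1L)
    jac <- if (cc$tp + cc$fp + cc$fn == 0) 1
           else cc$tp / (cc$tp + cc$fp + cc$fn)
    dice <- pixel_metrics(cc)[["dice"]]
    aji <- aggregated_jaccard(gt, pred)
    expect_lte(aji, jac + 1e-12)
    expect_lte(jac, dice + 1e-12)
  }
})

test_that("cell counting filters components below the area threshold", {
  m <- matrix(0L, 20, 20)
  m[2:5, 2:5] <- 1L      # 16 px
  m[10:13, 10:12] <- 1L  # 12 px
  m[18, 18:19] <- 1L     # 2 px speck
  expect_equal(count_cells(m, min_area = 5), 2L)
  expect_equal(count_cells(m, min_area = 1), 3L)
  expect_equal(count_cells(matrix(0L, 5, 5)), 0L)
})

test_that("evaluate_pairs aggregates per-patch metrics correctly", {
  g <- matrix(0L, 8, 8); g[2:4, 2:4] <- 1L
  full <- list(gt = g, pred = g)                      # dice 1
  half <- list(gt = g, pred = {h <- g; h[2, ] <- 0L; h[5:6, 6:8] <- 1L; h})
  none <- list(gt = g, pred = matrix(0L, 8, 8))       # dice 0
  rep3 <- evaluate_pairs(list(full, none))
  dm <- rep3$aggregate$mean[rep3$aggregate$metric == "dice"]
  ds <- rep3$aggregate$sd[rep3$aggregate$metric == "dice"]
  expect_equal(dm, 0.5)
  expect_equal(ds, stats::sd(c(1, 0)))

  one <- evaluate_pairs(list(full))
  expect_true(all(one$aggregate$sd == 0))
  expect_true(all(one$aggregate$mean == 1))

  r <- evaluate_pairs(list(full, half, none), min_area = 4)
  expect_equal(nrow(r$per_patch), 3L)
  expect_equal(unname(r$totals["gt_cells"]),
               sum(r$per_patch$gt_cell_count))
  expect_equal(unname(r$totals["pred_cells"]),
               sum(r$per_patch$pred_cell_count))
  # aggregates recomputable from the per-patch rows
  expect_equal(r$aggregate$mean[r$aggregate$metric == "aji"],
               mean(r$per_patch$aji))
  expect_error(evaluate_pairs(list()), "empty")
})

test_that("metric reports serialize to CSV and JSON", {
  g <- matrix(0L, 8, 8); g[2:4, 2:4] <- 1L
  r <- evaluate_pairs(list(list(gt = g, pred = g, id = "p1")), min_area = 4)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_metrics_report(r, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$patch_id, "p1")
  expect_equal(back$dice, 1)
  agg <- jsonlite::read_json(js)
  expect_equal(agg$totals$gt_cells, 1L)
})
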