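test_that("scenario 1 worked examples classify as published", {
  sc <- scenario_definition(1, x = 0.5)
  expect_equal(ddgbind:::classify_pair(1.2, 1.5, sc), "tp")
  expect_equal(ddgbind:::classify_pair(0.3, 0.2, sc), "tn")
  expect_equal(ddgbind:::classify_pair(1.2, 0.3, sc), "fp")
  expect_equal(ddgbind:::classify_pair(0.3, 1.2, sc), "fn")
  # large magnitudes of opposite sign: a confident wrong-direction call
  expect_equal(ddgbind:::classify_pair(1.2, -1.3, sc), "fp")
})

test_that("scenario 2 gray zone excludes intermediate pairs from counts", {
  sc <- scenario_definition(2, x = 0.5, y = 1)
  pairs <- data.frame(calc = c(0.7, 1.5, 0.2), exp = c(0.7, 1.5, 0.2))
  cc <- confusion_counts(pairs, sc)
  expect_equal(cc$tp, 1)
  expect_equal(cc$tn, 1)
  expect_equal(cc$fp + cc$fn, 0)
  expect_equal(cc$n_total, 3)   # gray pair still counted in the database size
})

test_that("scenario definitions validate their parameters", {
  expect_error(scenario_definition(2, x = 0.5), "requires cut-off y")
  expect_error(scenario_definition(4, x = 0.5, y = 1), "requires cut-off z")
  expect_error(scenario_definition(3, x = 2, y = 1), "x <= y")
  expect_error(scenario_definition(9, x = 1), "1..5")
})

test_that("all five scenario predicate sets match the brute-force oracle", {
  vals <- c(-2.2, -1.4, -0.9, -0.4, 0, 0.3, 0.7, 1.1, 1.6, 2.4)
  grid <- expand.grid(calc = vals, exp = vals)
  settings <- list(list(id = 1, x = 0.5),
                   list(id = 2, x = 0.5, y = 1),
                   list(id = 3, x = 0.5, y = 1.5),
                   list(id = 3, x = 1, y = 2),
                   list(id = 4, x = 0.5, y = 1, z = 1.5),
                   list(id = 5, x = 0.5, y = 1, z = 1.5))
  for (s in settings) {
    sc <- scenario_definition(s$id, x = s$x, y = s$y, z = s$z)
    mine <- confusion_counts(grid, sc)
    ref <- counts_oracle(grid, s$id, s$x, s$y, s$z)
    expect_equal(mine$tp, ref$tp, info = paste("scenario", s$id))
    expect_equal(mine$tn, ref$tn, info = paste("scenario", s$id))
    expect_equal(mine$fp, ref$fp, info = paste("scenario", s$id))
    expect_equal(mine$fn, ref$fn, info = paste("scenario", s$id))
    # and per-pair agreement, not just totals
    cls_mine <- vapply(seq_len(nrow(grid)), function(i) {
      ddgbind:::classify_pair(grid$calc[i], grid$exp[i], sc)
    }, character(1))
    cls_ref <- mapply(scenario_oracle, grid$calc, grid$exp,
                      MoreArgs = list(id = s$id, x = s$x, y = s$y, z = s$z))
    expect_identical(cls_mine, unname(cls_ref))
  }
})

test_that("metrics match a hand computation from the defining formulas", {
  m <- confusion_metrics(list(tp = 3, tn = 4, fp = 1, fn = 2, n_total = 12))
  expect_equal(unname(m["tpr"]), 0.6)
  expect_equal(unname(m["fnr"]), 0.4)
  expect_equal(unname(m["tnr"]), 0.8)
  expect_equal(unname(m["ppv"]), 0.75)
  expect_equal(unname(m["npv"]), 2 / 3)
  expect_equal(unname(m["acc"]), 0.7)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_equal(unname(m["mcc"]), 10 / sqrt(600))
  expect_equal(unname(m["coverage"]), 10 / 12)
  expect_length(attr(m, "flagged"), 0)
})

test_that("zero-denominator metrics flag instead of failing", {
  m <- confusion_metrics(list(tp = 7, tn = 0, fp = 0, fn = 0, n_total = 7))
  expect_equal(unname(m[c("tpr", "ppv", "acc", "f1")]), rep(1, 4))
  expect_equal(unname(m["mcc"]), 0)
  expect_true(all(c("tnr", "npv", "mcc") %in% attr(m, "flagged")))

  m0 <- confusion_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0, n_total = 5))
  expect_true(all(m0 == 0))
  expect_equal(unname(m0["coverage"]), 0)
})

test_that("TPR + FNR = 1 and MCC is swap-symmetric on random counts", {
  set.seed(11)
  for (k in 1:50) {
    cts <- as.list(rpois(4, 6)); names(cts) <- c("tp", "tn", "fp", "fn")
    cts$n_total <- sum(unlist(cts)) + rpois(1, 2)
    m <- confusion_metrics(cts)
    if (cts$tp + cts$fn > 0) {
      expect_equal(unname(m["tpr"] + m["fnr"]), 1)
    }
    swapped <- list(tp = cts$tn, tn = cts$tp, fp = cts$fn, fn = cts$fp,
                    n_total = cts$n_total)
    expect_equal(unname(confusion_metrics(swapped)["mcc"]),
                 unname(m["mcc"]))
  }
})

test_that("cut-off scans produce one row per grid point", {
  pairs <- make_prediction_pairs(300, correlation = 0.6, seed = 3)
  tab <- scan_cutoffs(pairs, 1, c(0.5, 1, 1.5, 2))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$x, c(0.5, 1, 1.5, 2))
  # scenario 1 has no gray zone: full coverage at every cut-off
  expect_true(all(tab$coverage == 1))
  expect_error(scan_cutoffs(pairs, 3, c(0.5, 1)), "data frame")
  expect_error(scan_cutoffs(pairs, 1, numeric(0)), "empty")
})

test_that("coverage shrinks as the scenario-2 gray zone widens", {
  pairs <- make_prediction_pairs(400, correlation = 0.6, seed = 5)
  widths <- data.frame(x = rep(0.5, 4), y = c(0.5, 1, 1.5, 2))
  tab <- scan_cutoffs(pairs, 2, widths)
  expect_true(all(diff(tab$coverage) <= 1e-12))
})

test_that("scenario 3 scan equals brute-force predicate evaluation", {
  pairs <- make_prediction_pairs(200, correlation = 0.55, seed = 9)
  tab <- scan_cutoffs(pairs, 3, data.frame(x = 1, y = 2))
  ref <- counts_oracle(pairs, 3, x = 1, y = 2)
  expect_equal(tab$tp, ref$tp)
  expect_equal(tab$tn, ref$tn)
  expect_equal(tab$fp, ref$fp)
  expect_equal(tab$fn, ref$fn)
})

test_that("regression summary recovers exact linear relations", {
  pairs <- data.frame(calc = seq(-2, 2, by = 0.25))
  pairs$exp <- 2 * pairs$calc + 1
  rs <- regression_summary(pairs)
  expect_equal(rs$pearson_r, 1)
  expect_equal(rs$slope, 2)
  expect_equal(rs$intercept, 1)

  anti <- data.frame(calc = pairs$calc, exp = -pairs$calc)
  expect_equal(regression_summary(anti)$pearson_r, -1)

  expect_error(regression_summary(data.frame(calc = 1, exp = 1)), "at least 2")
  expect_error(regression_summary(data.frame(calc = c(1, 1), exp = c(1, 2))),
               "zero variance")
})

test_that("2-SD trimming removes a gross outlier and raises the correlation", {
  set.seed(21)
  pairs <- data.frame(calc = seq(-2, 2.75, by = 0.25))
  pairs$exp <- pairs$calc + rnorm(nrow(pairs), 0, 0.15)
  pairs$exp[10] <- pairs$calc[10] + 8    # gross outlier
  rs <- regression_summary(pairs, trim_sd = 2)
  expect_gte(rs$trimmed_r, rs$pearson_r)
  expect_equal(rs$n_trimmed, rs$n - 1)
  # direct recomputation on the cleaned set
  clean <- pairs[-10, ]
  expect_equal(rs$trimmed_r, cor(clean$calc, clean$exp), tolerance = 1e-12)
})
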