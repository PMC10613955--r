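test_that("abs_deviations is an elementwise, symmetric absolute difference", {
  pred <- tibble::tibble(group_id = c("a", "b"), delta_cal_ppm = c(22.0, 10))
  exp_ <- tibble::tibble(group_id = c("a", "b"), delta_exp_ppm = c(21.8, 10))
  out <- abs_deviations(pred, exp_)
  expect_equal(out$abs_dev_ppm, c(0.2, 0))

  # swapping the roles of the two maps leaves |ddelta| unchanged
  swapped <- abs_deviations(
    dplyr::rename(exp_, delta_cal_ppm = "delta_exp_ppm"),
    dplyr::rename(pred, delta_exp_ppm = "delta_cal_ppm")
  )
  expect_equal(swapped$abs_dev_ppm, out$abs_dev_ppm)

  expect_error(
    abs_deviations(pred, dplyr::mutate(exp_, group_id = c("a", "zz"))),
    "assignment inconsistency"
  )
})

test_that("summarize_errors computes MAE, RMSE, max and range forms", {
  d <- tibble::tibble(group_id = c("a", "b", "c"),
                      delta_exp_ppm = c(0, 5, 10),
                      delta_cal_ppm = c(1, 6, 11))
  m <- summarize_errors(abs_deviations(d))
  expect_equal(m$mae_ppm, 1)
  expect_equal(m$rmse_ppm, 1)

  d2 <- tibble::tibble(group_id = c("a", "b"),
                       delta_exp_ppm = c(0, 100),
                       delta_cal_ppm = c(3, 104))
  m2 <- summarize_errors(abs_deviations(d2))
  expect_equal(m2$mae_ppm, 3.5)
  expect_equal(m2$rmse_ppm, sqrt(12.5))      # 3.53553
  expect_equal(m2$max_abs_dev_ppm, 4)

  expect_error(summarize_errors(abs_deviations(d2)[0, ]), "empty metrics")
})

test_that("percentage-of-range forms reproduce the published ppm/percent pairs", {
  c13_range <- diff(range(oxime_assignments("13C")$delta_exp_ppm))
  h1_range <- diff(range(oxime_assignments("1H")$delta_exp_ppm))
  expect_equal(c13_range, 151.81)
  expect_equal(h1_range, 4.26)

  # every published (ppm, %) pair rounds to the printed percentage
  pct <- function(ppm, range) round(100 * ppm / range, 2)
  expect_equal(pct(0.84, c13_range), 0.55)   # best ensemble 13C RMSE
  expect_equal(pct(1.14, c13_range), 0.75)
  expect_equal(pct(0.62, c13_range), 0.41)   # best ensemble 13C MAE
  expect_equal(pct(0.89, c13_range), 0.59)
  expect_equal(pct(1.03, c13_range), 0.68)   # best screening 13C RMSE
  expect_equal(pct(1.41, c13_range), 0.93)
  expect_equal(pct(5.15, c13_range), 3.39)
  expect_equal(pct(3.61, c13_range), 2.38)
  expect_equal(pct(1.96, c13_range), 1.29)
  expect_equal(pct(0.0617, h1_range), 1.45)  # best ensemble 1H RMSE
  expect_equal(pct(0.0870, h1_range), 2.04)
  expect_equal(pct(0.0554, h1_range), 1.30)  # best ensemble 1H MAE
  expect_equal(pct(0.0765, h1_range), 1.80)
  expect_equal(pct(0.098, h1_range), 2.30)   # best screening 1H RMSE
  expect_equal(pct(0.108, h1_range), 2.54)

  # and summarize_errors itself produces the range-based form
  devs <- tibble::tibble(group_id = "x", delta_exp_ppm = 100,
                         delta_cal_ppm = 100.84, abs_dev_ppm = 0.84)
  m <- summarize_errors(
    dplyr::bind_rows(
      devs,
      tibble::tibble(group_id = c("lo", "hi"),
                     delta_exp_ppm = c(15.40, 167.21),
                     delta_cal_ppm = c(15.40 + 0.84, 167.21 - 0.84),
                     abs_dev_ppm = 0.84)
    )
  )
  expect_equal(m$rmse_pct, 100 * 0.84 / 151.81)
  expect_equal(round(m$rmse_pct, 2), 0.55)
})

test_that("mae <= rmse <= max holds on arbitrary deviation sets", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    d <- tibble::tibble(
      group_id = as.character(seq_len(n)),
      delta_exp_ppm = runif(n, 0, 170)
    )
    d$delta_cal_ppm <- d$delta_exp_ppm + rnorm(n, 0, 3)
    m <- summarize_errors(abs_deviations(d))
    expect_lte(m$mae_ppm, m$rmse_ppm + 1e-12)
    expect_lte(m$rmse_ppm, m$max_abs_dev_ppm + 1e-12)
    # permutation invariance
    m2 <- summarize_errors(abs_deviations(d[sample(n), ]))
    expect_equal(m2[-1], m[-1], tolerance = 1e-12)
  }
})

test_that("per_atom_summary averages across methods and flags strictly above threshold", {
  one <- tibble::tibble(group_id = c("C14", "C15"),
                        abs_dev_ppm = c(1.2, 0.4))
  six <- dplyr::bind_rows(lapply(1:6, function(i) {
    dplyr::mutate(one, functional = paste0("F", i), basis_set = "B")
  }))
  s <- per_atom_summary(six, nucleus = "13C")
  expect_equal(s$mean_abs_dev_ppm, one$abs_dev_ppm)
  expect_equal(s$n_methods, c(6, 6))
  expect_false(any(s$flagged))

  two <- tibble::tibble(
    functional = rep(c("F1", "F2"), each = 1),
    basis_set = "B",
    group_id = "g",
    abs_dev_ppm = c(1.0, 2.0)
  )
  expect_equal(per_atom_summary(two, threshold_ppm = 1.5)$mean_abs_dev_ppm,
               1.5)

  # a 13C group averaging 1.83 ppm across methods is flagged at 1.50
  flagged <- dplyr::mutate(six,
                           abs_dev_ppm = ifelse(group_id == "C14", 1.83, 0.4))
  sf <- per_atom_summary(flagged, nucleus = "13C")
  expect_equal(sf$flagged, c(TRUE, FALSE))
  # strict inequality: exactly at threshold is not flagged
  at <- dplyr::mutate(six, abs_dev_ppm = 1.50)
  expect_false(any(per_atom_summary(at, nucleus = "13C")$flagged))

  ragged <- six[-1, ]
  expect_error(per_atom_summary(ragged, nucleus = "13C"),
               "assignment inconsistency")
})
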