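branch_df <- function(k_app, mechanism = "FHT", state = "HA",
                      site = paste0("S", seq_along(k_app)),
                      compound = "X", f = NULL) {
  df <- data.frame(compound = compound, site = site, mechanism = mechanism,
                   protonation_state = state, k_app = k_app,
                   stringsAsFactors = FALSE)
  if (!is.null(f)) df$mole_fraction <- f
  df
}

test_that("weighted rate is the exact population product", {
  expect_equal(weighted_rate(0.009, 7.80e9), 7.02e7)
  expect_equal(weighted_rate(1, 123.4), 123.4)
  expect_equal(weighted_rate(0, 7.8e9), 0)
  expect_error(weighted_rate(1.2, 1), "\\[0, 1\\]")
})

test_that("overall rate reproduces the gas-phase sums and ratios", {
  gas <- medium("gas")
  res <- overall_rate(branch_df(c(7.29e2, 2.30e1)), gas)
  expect_equal(res$k_overall, 7.52e2)
  expect_equal(res$branches$gamma, c(96.9, 3.1), tolerance = 1e-3)

  res1 <- overall_rate(branch_df(5e3), gas)
  expect_equal(res1$k_overall, 5e3)
  expect_equal(res1$branches$gamma, 100)

  cmc <- overall_rate(branch_df(c(6.28e4, 1.04e1)), gas)
  expect_equal(cmc$k_overall, 6.28e4, tolerance = 5e-3)
})

test_that("the channel-admission rule tracks medium polarity", {
  chans <- rbind(branch_df(1e3, "FHT", "HA", "O14-H"),
                 branch_df(1e-30, "SET", "HA", "-"),
                 branch_df(7.8e9, "SET", "A_minus", "O14-H"))
  chans$mole_fraction <- c(0.991, 0.991, 0.009)
  water <- default_media()$water
  res_w <- overall_rate(chans, water)
  expect_true(all(res_w$branches$admitted))
  expect_equal(res_w$k_overall, 0.991 * 1e3 + 0.991 * 1e-30 + 7.02e7)

  gas <- medium("gas")
  res_g <- overall_rate(chans, gas)
  expect_identical(res_g$branches$admitted, c(TRUE, FALSE, FALSE))
  expect_match(res_g$branches$reason[3], "not admitted")
  expect_equal(res_g$k_overall, 0.991 * 1e3)
})

test_that("branching ratios sum to 100 and survive branch reordering", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    b <- branch_df(10^runif(n, -2, 9))
    res <- overall_rate(b, medium("gas"))
    expect_equal(sum(res$branches$gamma), 100, tolerance = 1e-12)
    perm <- sample(n)
    res2 <- overall_rate(b[perm, ], medium("gas"))
    expect_equal(res2$k_overall, res$k_overall, tolerance = 1e-15)
  }
  expect_error(overall_rate(branch_df(1)[0, ], medium("gas")), "empty")
})

test_that("scenario comparison divides overall rates with guards", {
  a <- overall_rate(branch_df(7.02e7), default_media()$water,
                    scenario = "default")
  b <- overall_rate(branch_df(2.16e7), default_media()$water,
                    scenario = "explicit_water")
  expect_equal(compare_scenarios(a, b), 3.25)
  expect_equal(compare_scenarios(a, a), 1)
  expect_equal(compare_scenarios(6.44e4, 1.06e3, digits = 0), 61)
  expect_error(compare_scenarios(1, 0), "denominator")
})

test_that("activity report orders results and computes reference folds", {
  res <- list(overall_rate(branch_df(7.02e7, compound = "CMA"),
                           default_media()$water),
              overall_rate(branch_df(8.66e7, compound = "CMB"),
                           default_media()$water))
  refs <- data.frame(name = c("trolox", "ascorbic_acid"),
                     k = c(1.30e5, 9.97e7))
  rep <- activity_report(res, refs)
  expect_identical(rep$overall$compound, c("CMA", "CMB"))
  fold_trolox <- rep$comparison$fold[rep$comparison$compound == "CMA" &
                                       rep$comparison$reference == "trolox"]
  expect_equal(fold_trolox, 5.4e2, tolerance = 1e-2)
  fold_asc <- rep$comparison$fold[rep$comparison$compound == "CMB" &
                                    rep$comparison$reference == "ascorbic_acid"]
  expect_equal(round(fold_asc, 2), 0.87)
  expect_null(activity_report(res, NULL)$comparison)
  expect_null(activity_report(res, refs[0, ])$comparison)
})
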