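neutral_at <- function(logp) {
  compound_descriptor("x", "OPO", log_p = logp, molecular_weight = 300,
                      charge_class = "neutral")
}

test_that("fraction unbound: hand evaluation, monotonicity, limits", {
  # hand evaluation of the implemented logistic form at (logP 2, neutral):
  # coefficients a = -0.51, b = 0.50 -> fup = 1 / (1 + 10^(-0.51 + 0.5*2))
  expect_equal(predict_fraction_unbound(neutral_at(2)),
               1 / (1 + 10^(-0.51 + 0.50 * 2)), tolerance = 1e-9)

  # acid: logD correction at pH 7.4 enters the same form
  acid <- compound_descriptor("a", "urinary_metabolite", log_p = 1.5,
                              molecular_weight = 200, charge_class = "acid",
                              pka = 4)
  logd <- 1.5 - log10(1 + 10^(7.4 - 4))
  expect_equal(predict_fraction_unbound(acid),
               1 / (1 + 10^(0.06 + 0.43 * logd)), tolerance = 1e-9)

  # monotone non-increasing in logP within a class
  expect_lt(predict_fraction_unbound(neutral_at(5)),
            predict_fraction_unbound(neutral_at(2)))
  fups <- vapply(seq(-2, 6, 0.5),
                 function(lp) predict_fraction_unbound(neutral_at(lp)),
                 numeric(1))
  expect_true(all(diff(fups) < 0))
  expect_true(all(fups > 0 & fups <= 1))

  # limiting behaviour: vanishing lipophilicity -> fully unbound
  expect_equal(predict_fraction_unbound(neutral_at(-30)), 1,
               tolerance = 1e-9)
})

test_that("BPR defaults by charge class with positive override", {
  acid <- compound_descriptor("a", "urinary_metabolite", log_p = 1,
                              molecular_weight = 200,
                              charge_class = "acid", pka = 4)
  base <- compound_descriptor("b", "urinary_metabolite", log_p = 1,
                              molecular_weight = 200,
                              charge_class = "base", pka = 9)
  expect_identical(predict_bpr(neutral_at(3)), 1.0)
  expect_identical(predict_bpr(acid), 0.55)
  expect_identical(predict_bpr(base), 1.0)
  expect_identical(predict_bpr(acid, override = 0.8), 0.8)
  expect_error(predict_bpr(acid, override = -1), "positive")
})

test_that("Berezhkovskiy Kp: hand evaluation and lipophilicity behaviour", {
  # hand evaluation at logP 0, fup 0.5 with the documented composition:
  # P = 1; fut = 1/(1 + ((1-0.5)/0.5)/2) = 2/3 (fat: fut = 1)
  denom <- 1 * (0.00147 + 0.3 * 0.00083) + (0.960 + 0.7 * 0.00083) / 0.5
  liver_num <- 1 * (0.0138 + 0.3 * 0.0303) + (0.705 + 0.7 * 0.0303) / (2 / 3)
  fat_num <- 1 * (0.853 + 0.3 * 0.002) + (0.120 + 0.7 * 0.002) / 1
  kp <- predict_partition_coefficients(neutral_at(0), fup = 0.5,
                                       method = "berezhkovskiy")
  expect_equal(kp[["liver"]], liver_num / denom, tolerance = 1e-9)
  expect_equal(kp[["fat"]], fat_num / denom, tolerance = 1e-9)

  # water-partitioning regime: all tissues within [0.1, 10]
  expect_true(all(kp > 0.1 & kp < 10))

  # adipose Kp strictly increasing in logP at fixed fup
  fat_kp <- vapply(seq(0, 6, 0.5), function(lp)
    predict_partition_coefficients(neutral_at(lp), fup = 0.1)[["fat"]],
    numeric(1))
  expect_true(all(diff(fat_kp) > 0))
})

test_that("Rodgers-Rowland Kp: hand evaluation for neutral and acid", {
  # neutral, logP 0, fup 0.5: X = Y = 1
  lip_p <- 0.0023 + 1 * 0.0013
  ka_pr <- 1 / 0.5 - 1 - lip_p
  liver_kpu <- 0.161 + 0.573 + (0.0135 + 1 * 0.0238) + 0.086 * ka_pr
  kp <- predict_partition_coefficients(neutral_at(0), fup = 0.5,
                                       method = "rodgers_rowland")
  expect_equal(kp[["liver"]], liver_kpu * 0.5, tolerance = 1e-9)

  # acid, logP 1.5, pKa 3, fup 0.3 -- ionization shifts intracellular water
  acid <- compound_descriptor("a", "urinary_metabolite", log_p = 1.5,
                              molecular_weight = 200, charge_class = "acid",
                              pka = 3)
  X <- 1 + 10^(7.0 - 3)
  Y <- 1 + 10^(7.4 - 3)
  P <- 10^1.5
  lip_pa <- (P * 0.0023 + (0.3 * P + 0.7) * 0.0013) / Y
  ka_pra <- 1 / 0.3 - 1 - lip_pa
  kid_kpu <- 0.273 + (X / Y) * 0.483 +
    (P * 0.0121 + (0.3 * P + 0.7) * 0.0240) / Y + 0.130 * ka_pra
  kpa <- predict_partition_coefficients(acid, fup = 0.3,
                                        method = "rodgers_rowland")
  expect_equal(kpa[["kidney"]], kid_kpu * 0.3, tolerance = 1e-9)
  expect_true(all(kpa > 0))

  # charge information is required
  noka <- compound_descriptor("m", "urinary_metabolite", log_p = 1,
                              molecular_weight = 200, charge_class = "acid")
  expect_error(predict_partition_coefficients(noka, fup = 0.5,
                                              method = "rodgers_rowland"),
               "pKa")
})

test_that("the two Kp methods agree within 10-fold for a neutral compound", {
  d <- neutral_at(1)
  fup <- predict_fraction_unbound(d)
  kb <- predict_partition_coefficients(d, fup, "berezhkovskiy")
  kr <- predict_partition_coefficients(d, fup, "rodgers_rowland")
  expect_true(all(kb / kr < 10 & kb / kr > 0.1))
})
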