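test_that("Savitzky-Golay smoothing reproduces low-degree polynomials", {
  expect_equal(smooth_signal(rep(3.5, 120)), rep(3.5, 120))

  t <- seq(0, 1, length.out = 120)
  cubic <- 2 + t - 3 * t^2 + 0.5 * t^3
  expect_equal(smooth_signal(cubic), cubic, tolerance = 1e-9)

  expect_message(out <- smooth_signal(cubic, window = 50), "rounding up to 51")
  expect_equal(out, cubic, tolerance = 1e-9)

  expect_error(smooth_signal(rnorm(40)), "longer than")
  expect_error(smooth_signal(cubic, window = 51, degree = 60), "degree")
})

test_that("smoothing reduces noise on logistic traces", {
  set.seed(21)
  t <- seq(0.25, 48, by = 0.25)
  worse <- 0
  for (i in 1:50) {
    truth <- 150 / (1 + exp(-0.35 * (t - 18)))
    noisy <- truth + rnorm(length(t), sd = 3)
    sm <- smooth_signal(noisy)
    if (sd(sm - truth) >= sd(noisy - truth)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("smoothed maximum commutes with time reversal", {
  set.seed(22)
  x <- cumsum(rnorm(120))
  expect_equal(max_signal(smooth_signal(x)),
               max_signal(smooth_signal(rev(x))), tolerance = 1e-9)
  expect_equal(max_signal(1:10), 10)
  expect_equal(max_signal(rep(2, 5)), 2)
})

test_that("growth calls standardize against negative controls", {
  ctrl <- c(1, 2, 3, 4)
  plate <- constant_plate(c(ctrl, mean(ctrl), mean(ctrl) + 10 * sd(ctrl)),
                          n_control = 4)
  calls <- growth_calls(plate)
  expect_true(all(is.na(calls$call[calls$is_control])))
  at_mean <- calls[5, ]
  expect_equal(at_mean$z, 0)
  expect_equal(at_mean$p, 0.5)
  expect_equal(at_mean$call, 0L)
  expect_equal(calls$call[6], 1L)

  # the published z-test variant: normal upper tail, Bonferroni over 94
  big <- constant_plate(c(ctrl, rep(mean(ctrl), 93),
                          mean(ctrl) + 10 * sd(ctrl)), n_control = 4)
  zcalls <- growth_calls(big, reference = "normal")
  hot <- zcalls[nrow(zcalls), ]
  expect_equal(hot$p_adj, pnorm(10, lower.tail = FALSE) * 94)
  expect_lt(hot$p_adj, 0.05)
  expect_equal(hot$call, 1L)

  expect_error(growth_calls(constant_plate(c(2, 2, 5), n_control = 2)),
               "zero variance")
  one_ctrl <- constant_plate(c(2, 5, 6), n_control = 1)
  expect_error(growth_calls(one_ctrl), "at least 2")
})

test_that("growth calls are invariant to rescaling the signal", {
  plate <- simulate_plate(plate_spec(n_wells = 40, n_control_wells = 8,
                                     n_timepoints = 96), seed = 31L)
  c1 <- growth_calls(plate)
  plate$signal <- plate$signal * 7.3
  c2 <- growth_calls(plate)
  expect_equal(c1$call, c2$call)
  expect_equal(c1$z, c2$z, tolerance = 1e-9)
})

test_that("call comparison tallies gains, losses and category percentages", {
  a <- setNames(c(1, 1, 1, 1, 1, 0), paste0("c", 1:6))
  b <- setNames(c(1, 0, 0, 0, 1, 1), paste0("c", 1:6))
  cats <- setNames(c("N", "N", "N", "N", "C", "C"), paste0("c", 1:6))
  res <- compare_calls(a, b, cats)
  expect_setequal(res$gained, "c6")
  expect_setequal(res$lost, c("c2", "c3", "c4"))
  expect_equal(unname(res$loss_percent["N"]), 75)
  expect_equal(unname(res$loss_percent["C"]), 0)

  same <- compare_calls(a, a, cats)
  expect_length(same$lost, 0)
  expect_true(all(same$loss_percent == 0))
  expect_error(compare_calls(a, setNames(1, "zz")), "no shared")
})

test_that("binary PCA separates strains and partitions variance", {
  calls <- rbind(s1 = c(1, 1, 0, 0, 1),
                 s2 = c(1, 1, 0, 0, 1),
                 s3 = c(0, 0, 1, 1, 0))
  colnames(calls) <- paste0("c", 1:5)
  pc <- pca_binary(calls)
  expect_equal(pc$variance_fraction[1], 1)
  expect_equal(sum(pc$variance_fraction), 1)
  expect_gt(abs(pc$scores["s3", 1] - pc$scores["s1", 1]), 1)
  expect_equal(pc$scores["s1", 1], pc$scores["s2", 1])

  with_flat <- cbind(calls, c0 = c(1, 1, 1))
  expect_warning(pc2 <- pca_binary(with_flat), "zero-variance")
  expect_equal(sum(pc2$variance_fraction), 1)
  expect_error(pca_binary(calls[1:2, ]), "3 strains")
  expect_error(suppressWarnings(pca_binary(with_flat[, 6, drop = FALSE] * 0 + 1)),
               "variance")
})
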