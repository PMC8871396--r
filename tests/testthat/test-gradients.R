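test_that("balance constants reproduce the analytic values", {
  b <- fx$const
  expect_equal(b$zeta, 6.15 / 4.738, tolerance = 1e-6)
  expect_lt(abs(b$J0 - 0.2112), 1e-4)
  expect_lt(abs(b$beta - 0.01034), 1e-5)
  expect_lt(abs(b$Z - (-3.813 / -4.738)), 1e-4)
  expect_gt(b$zeta, 0)
  expect_gt(b$Z, 0)
})

test_that("balanced J_IE keeps the baseline circuit at its published value", {
  p <- fx$params
  b <- fx$const
  expect_equal(balance_jie(0.3213, b, p), 0.15, tolerance = 1e-3)
  expect_equal(balance_jie(b$J0 - p$J_c, b, p), 0, tolerance = 1e-10)
  expect_equal(balance_jie(0.42, b, p),
               (b$J0 - 0.42 - p$J_c) / (2 * p$J_EI * b$zeta),
               tolerance = 1e-10)
  expect_equal(balance_jie(0.42, b, p), 0.2728, tolerance = 1e-3)
  expect_error(balance_jie(0.15, b, p), "below validity")
})

test_that("spontaneous state is invariant along the balanced gradient", {
  # areas with different J_s but Eq-balanced J_IE share one fixed point
  h <- seq(0, 1, length.out = 6)
  Js <- build_js_gradient(h, 0.21, 0.42)
  rates <- vapply(Js, function(js) {
    p <- fx$params
    p$J_s <- js
    p$J_IE <- balance_jie(js, fx$const, fx$params)
    spontaneous_state(p)["r_A"]
  }, 0)
  expect_lt(max(rates) - min(rates), 0.1)
})

test_that("spine counts are age-corrected and missing stays missing", {
  tab <- macaque_spine_table()
  expect_equal(nrow(tab), 30)
  expect_equal(tab$corrected_count[tab$area == "V1"], 643)
  expect_equal(tab$corrected_count[tab$area == "8m"], 3200 * 1.30)
  expect_true(is.na(tab$corrected_count[tab$area == "DP"]))
  bad <- data.frame(area = "X", spine_count = -5, age_factor = 1)
  expect_error(correct_spine_counts(bad), "negative")
})

test_that("spine hierarchy fills missing areas from their rank", {
  sh <- spine_hierarchy()
  expect_equal(range(sh$h), c(0, 1))
  expect_equal(unname(sh$h["V1"]), 0)
  expect_equal(unname(sh$h["9/46d"]), 1)
  expect_equal(unname(sh$source["DP"]), "hierarchy-proxy")
  expect_equal(unname(sh$source["V1"]), "spine")
  # proxy-filled frontal areas land high on the gradient
  expect_gt(unname(sh$h["8B"]), 0.6)
})

test_that("J_s gradient interpolates linearly between its endpoints", {
  expect_equal(build_js_gradient(0), 0.21)
  expect_equal(build_js_gradient(1), 0.42)
  expect_equal(build_js_gradient(0.5), 0.315)
  expect_error(build_js_gradient(0.5, J_min = 0.4, J_max = 0.3), "J_max")
  expect_error(build_js_gradient(1.5), "0, 1")
})

test_that("hierarchy fit inverts the logistic link exactly on two areas", {
  SLN <- matrix(0.5, 2, 2)
  SLN[2, 1] <- 0.73       # A1 -> A2 feedforward
  SLN[1, 2] <- 0.27
  FLN <- matrix(c(0, 1e-3, 1e-3, 0), 2, 2, byrow = TRUE)
  fit <- fit_hierarchy_from_sln(SLN, FLN, areas = c("A1", "A2"))
  expect_equal(unname(fit$H["A2"] - fit$H["A1"]), qlogis(0.73),
               tolerance = 1e-6)
  expect_equal(unname(coef(fit)), c(0, 1))
})

test_that("hierarchy fit recovers a known hierarchy up to monotone transform", {
  set.seed(4)
  n <- 20
  H <- runif(n)
  SLN <- plogis(4 * outer(H, H, "-"))
  diag(SLN) <- 0.5
  FLN <- matrix(1e-3, n, n)
  diag(FLN) <- 0
  fit <- fit_hierarchy_from_sln(SLN, FLN)
  expect_equal(cor(fit$h, H, method = "spearman"), 1.0)
})

test_that("hierarchy fit is equivariant under area relabeling", {
  bun <- fx$bundle
  fit1 <- fit_hierarchy_from_sln(bun$SLN, bun$FLN, areas = bun$areas)
  perm <- sample(seq_along(bun$areas))
  fit2 <- fit_hierarchy_from_sln(bun$SLN[perm, perm], bun$FLN[perm, perm],
                                 areas = bun$areas[perm])
  expect_equal(unname(fit2$h[bun$areas]), unname(fit1$h),
               tolerance = 1e-6)
})

test_that("degenerate SLN yields a flat hierarchy with a warning", {
  SLN <- matrix(0.5, 4, 4)
  FLN <- matrix(1e-3, 4, 4)
  diag(FLN) <- 0
  expect_warning(fit <- fit_hierarchy_from_sln(SLN, FLN), "flat")
  expect_true(all(fit$h == fit$h[1]))
})
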