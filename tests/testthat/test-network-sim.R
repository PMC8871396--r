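test_that("G = 0 decouples the network into isolated areas", {
  bun <- toy_bundle()
  net <- build_network(bun, mode = "custom", J_max = 0.42, G = 0)
  ev <- stimulus_event("A1", onset = 0.2, duration = 0.2)
  s <- simulate(net, duration = 1.5, events = ev, deterministic = TRUE)
  # the un-stimulated area never leaves its spontaneous state
  expect_lt(max(abs(s$rA[, "A2"] - net$spont["A2", "r_A"])), 1e-6)
  # the stimulated area responds and decays back (monostable)
  expect_gt(max(s$rA[, "A1"]), 10)
  expect_lt(tail(s$rA[, "A1"], 1), net$spont["A1", "r_A"] + 1)
})

test_that("exchange symmetry: identical areas follow identical trajectories", {
  n <- 2
  FLN <- matrix(0.05, n, n); diag(FLN) <- 0
  SLN <- matrix(0.5, n, n)
  bun <- connectome_bundle(c("A1", "A2"), FLN, SLN,
                           hierarchy = c(A1 = 0.5, A2 = 0.5))
  net <- build_network(bun, mode = "custom", J_max = 0.42, G = 0.3)
  ev <- list(stimulus_event("A1", onset = 0.2, duration = 0.3),
             stimulus_event("A2", onset = 0.2, duration = 0.3))
  s <- simulate(net, duration = 1, events = ev, deterministic = TRUE)
  expect_equal(s$rA[, "A1"], s$rA[, "A2"], tolerance = 1e-12)
})

test_that("identical seeds give bit-identical stochastic trajectories", {
  net <- fx_network()
  s1 <- simulate(net, seed = 21, duration = 1)
  s2 <- simulate(net, seed = 21, duration = 1)
  expect_identical(s1$rA, s2$rA)
  s3 <- simulate(net, seed = 22, duration = 1)
  expect_false(identical(s1$rA, s3$rA))
  expect_error(simulate(net, duration = 1), "seed")
})

test_that("noise-free network stays at its coupled spontaneous state", {
  net <- fx_network()
  s <- simulate(net, duration = 10, deterministic = TRUE)
  drift <- abs(s$rA[length(s$time), ] - net$spont[, "r_A"])
  expect_lt(max(drift), 0.1)
})

test_that("a sensory cue evokes a selective distributed delay pattern", {
  net <- fx_network()
  tr <- run_wm_trial(net, seed = 1, duration = 10)
  act <- tr$summary$active
  expect_gte(length(act), 10)
  expect_false(any(c("V1", "V2", "V4") %in% act))
  expect_true(all(c("9/46v", "9/46d", "24c") %in% act))
  # selectivity: the anti-cued pool stays at its spontaneous level
  expect_lt(max(tr$summary$table$rate_anti), net$spont_rate_iso + 2)
  # ranked rates show a clear gap separating active from inactive areas
  expect_gt(tr$summary$gap, 5)
})

test_that("delay summary recovers a constructed plateau and flags windows", {
  net <- build_network(toy_bundle(4), mode = "custom", J_max = 0.42, G = 0.2)
  s <- simulate(net, duration = 2, deterministic = TRUE)
  # all-spontaneous trace: empty active set
  expect_equal(length(summarize_delay_activity(s, window = c(1, 2))$active), 0)
  s$rA[, "A2"] <- 25       # synthetic 25 Hz plateau
  su <- summarize_delay_activity(s, window = c(1, 2))
  expect_equal(su$table$rate_cued[su$table$area == "A2"], 25)
  expect_equal(su$active, "A2")
  ev_sim <- simulate(net, duration = 2, deterministic = TRUE,
                     events = stimulus_event("A1", onset = 1, duration = 0.8))
  expect_warning(summarize_delay_activity(ev_sim, window = c(1.2, 2)),
                 "offset")
  expect_error(summarize_delay_activity(s, window = c(1, 5)), "window")
})

test_that("silencing clamps areas and suppression is monotone in set size", {
  net <- fx_network()
  ev <- stimulus_event("V1")
  base <- summarize_delay_activity(
    simulate(net, seed = 1, duration = 8, events = ev))
  ord <- order(net$h, decreasing = TRUE)
  sets <- list(net$areas[ord[1:2]], net$areas[ord[1:5]], net$areas[ord[1:9]])
  res <- lapply(sets, function(set) {
    s <- simulate(net, seed = 1, duration = 8, events = ev,
                  silencing = silencing_spec(set))
    su <- summarize_delay_activity(s)
    # silenced areas are clamped to zero rate throughout
    expect_equal(max(s$rA[, set]), 0)
    su
  })
  n_active <- c(length(base$active),
                vapply(res, function(x) length(x$active), 0L))
  expect_true(all(diff(n_active) <= 0))
  mean_rate <- vapply(res, function(x) {
    keep <- x$table$active & !(x$table$area %in% unlist(sets))
    if (!any(keep)) 0 else mean(x$table$rate_cued[keep])
  }, 0)
  expect_true(all(is.finite(mean_rate)))
})

test_that("gating scales incoming projections onto open areas only", {
  net <- fx_network()
  same <- apply_gating(net, "LIP", g_s = 0)
  expect_equal(same$W_EE, net$W_EE)
  gated <- apply_gating(net, "LIP", g_s = 0.5)
  i <- match("LIP", net$areas)
  expect_equal(gated$W_EE[i, ], 1.5 * net$W_EE[i, ])
  expect_equal(gated$W_EE[-i, ], net$W_EE[-i, ])
  expect_equal(gated$Js, net$Js)  # local couplings untouched by default
  expect_error(apply_gating(net, "V99", 0.1), "V99")
  expect_error(apply_gating(net, "LIP", -1), "g_s")
  # opening the gate raises (or keeps) the gated area's delay rate
  tr0 <- run_wm_trial(net, seed = 1, duration = 8)
  tr1 <- run_wm_trial(gated, seed = 1, duration = 8)
  r0 <- tr0$summary$table$rate_cued[i]
  r1 <- tr1$summary$table$rate_cued[i]
  expect_gte(r1, r0 - 0.5)
})

test_that("zero-amplitude distractors never overwrite the cue", {
  netS <- fx_network(mode = "strongly-distributed")
  tr <- run_distractor_trial(netS, distractor_amplitude = 0, seed = 1,
                             tail_time = 2)
  expect_equal(tr$outcome, "retained-cue")
})

test_that("shutdown pulses target inhibitory populations mechanically", {
  netS <- fx_network(mode = "strongly-distributed")
  # inhibiting one low-hierarchy area leaves the attractor intact
  sd1 <- run_shutdown_protocol(netS, targets = "V2", seed = 1,
                               settle = 2, tail_time = 2)
  expect_gte(length(sd1$post$active), length(sd1$pre$active) - 1)
  expect_error(run_shutdown_protocol(netS, targets = "V99"), "V99")
})

test_that("instability detection aborts with a diagnostic", {
  net <- fx_network()
  ev <- stimulus_event("V1", onset = 0, duration = 0.5, amplitude = 3)
  expect_error(simulate(net, duration = 0.5, deterministic = TRUE, dt = 0.1,
                        events = ev),
               "unstable|reduce dt")
})
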