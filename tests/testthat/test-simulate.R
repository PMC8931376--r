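test_that("EMU decomposition of a linear 1-carbon chain is minimal", {
  net <- toy_chain_net()
  sys <- emu_decompose(net, "C")
  sim <- sys$emus[sys$emus$role == "balanced", ]
  expect_equal(nrow(sim), 3L)
  expect_true(all(sim$size == 1L))
  expect_error(emu_decompose(net, "ZZZ"), "not in network")
  expect_error(emu_decompose(net, "S"), "balanced")
})

test_that("EMU source sizes always sum to the target size", {
  sys <- emu_decompose(make_variant(cbc_network(), "V5"),
                       c("G6P.c", "SUC.v", "RUBP.p"))
  size_of <- stats::setNames(sys$emus$size, sys$emus$key)
  for (ch in sys$channels) {
    expect_equal(sum(size_of[ch$sources]), unname(size_of[[ch$target]]))
  }
  # all observed full-length EMUs present
  ncar <- stats::setNames(sys$network$metabolites$n_carbons,
                          sys$network$metabolites$id)
  for (m in sys$observed) {
    key <- paste0(m, "|", paste(seq_len(ncar[[m]]), collapse = ","))
    expect_true(key %in% sys$emus$key)
  }
})

test_that("a single labeled pool follows the one-compartment closed form", {
  net <- parse_network(c(
    "in: S -> A , a -> a ; irreversible",
    "out: A -> X , a -> a ; irreversible"
  ))
  f <- flux_state(net, c(`in` = 2, out = 2))
  sys <- emu_decompose(net, "A")
  tm <- c(0, 5, 15, 30, 60, 120)
  sim <- simulate_labeling(sys, f, c(A = 1), tm, source_enrichment = c(S = 1),
                           rtol = 1e-10, atol = 1e-12)
  m0 <- sim$fraction[sim$mass == 0]
  expect_equal(m0[1], 1)  # initial condition returned exactly at t = 0
  expect_lt(max(abs(m0 - exp(-2 * tm / 60))), 1e-8)
})

test_that("the EMU cascade matches the linear-chain closed form", {
  net <- toy_chain_net()
  v <- 5
  rates <- c(10, 1, 0.1)
  pools <- stats::setNames(v / rates, c("A", "B", "C"))
  f <- flux_state(net, c(r0 = v, r1 = v, r2 = v, r3 = v))
  sys <- emu_decompose(net, c("A", "B", "C"))
  sim <- simulate_labeling(sys, f, pools, sampling_grid,
                           source_enrichment = c(S = 1),
                           rtol = 1e-10, atol = 1e-12)
  cf <- linear_chain_closed_form(rates, sampling_grid)
  ser <- twelve_c_series(sim)
  for (j in 1:3) {
    a <- ser$pct_12c[ser$metabolite == c("A", "B", "C")[j]] / 100
    b <- cf$values$pct_12c[cf$values$pool == j] / 100
    expect_lt(max(abs(a - b)), 1e-8)
  }
})

test_that("closed-form chain solution has the stated structure", {
  expect_equal(linear_chain_closed_form(1, 60)$values$pct_12c / 100,
               exp(-1), tolerance = 1e-12)
  # coefficients of every pool sum to 1 at t = 0
  cf <- linear_chain_closed_form(c(10, 1, 0.1), c(0, 30))
  expect_equal(unname(rowSums(cf$coefficients)), rep(1, 3))
  # two-pool complement form u2 = 2 exp(-t) - exp(-2t) for k = (2, 1)
  cf2 <- linear_chain_closed_form(c(2, 1), 60)
  u2 <- cf2$values$pct_12c[cf2$values$pool == 2] / 100
  expect_equal(u2, 2 * exp(-1) - exp(-2), tolerance = 1e-12)
  expect_error(linear_chain_closed_form(c(1, 1), 10), "repeated")
})

test_that("closed form agrees with a matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  rates <- c(3, 0.7, 0.15)
  B <- matrix(0, 3, 3)
  diag(B) <- -rates
  B[2, 1] <- rates[2]
  B[3, 2] <- rates[3]
  t_h <- 1.25
  oracle <- as.numeric(Matrix::expm(B * t_h) %*% rep(1, 3))
  cf <- linear_chain_closed_form(rates, t_h * 60)
  expect_equal(cf$values$pct_12c / 100, oracle, tolerance = 1e-10)
})

test_that("percent-12C summaries follow the definition", {
  expect_equal(twelve_c_fraction(c(1, 0, 0, 0)), 100)
  expect_equal(twelve_c_fraction(c(0, 0, 0, 1)), 0)
  expect_equal(twelve_c_fraction(rep(0.25, 4)), 50)
})

test_that("aggregation weights metabolites by pool carbon", {
  mk <- function(met, mid, t) {
    tibble::tibble(metabolite = met, n_carbons = length(mid) - 1L,
                   time_min = t, mass = seq_along(mid) - 1L, fraction = mid)
  }
  # 3-carbon species at 40% and 60% 12C
  mids <- dplyr::bind_rows(
    mk("P", c(0.2, 0.2, 0.2, 0.4), 10),   # 40%
    mk("Q", c(0.4, 0.2, 0.2, 0.2), 10)    # 60%
  )
  agg <- aggregate_12c(mids, c("P", "Q"), pool_sizes = c(P = 1, Q = 1))
  expect_equal(agg$pct_12c, 50)
  # single metabolite aggregates to itself
  one <- aggregate_12c(mids, "P", pool_sizes = c(P = 1))
  expect_equal(one$pct_12c, 40)
  # permutation invariance
  agg2 <- aggregate_12c(mids, c("Q", "P"), pool_sizes = c(P = 1, Q = 1))
  expect_equal(agg, agg2)
  # pool weighting shifts toward the heavier pool
  agg3 <- aggregate_12c(mids, c("P", "Q"), pool_sizes = c(P = 3, Q = 1))
  expect_equal(agg3$pct_12c, 45)
  expect_equal(aggregate_12c(mids, c("P", "Q"), weighted = FALSE)$pct_12c, 50)
  expect_error(aggregate_12c(mids, c("P", "Z"), pool_sizes = c(P = 1, Z = 1)),
               "absent")
})

test_that("EMU simulation equals brute-force isotopomer simulation", {
  net <- toy_condense_net()
  f <- flux_solve(net, c(fix = 3, iA = 1, oC = 3))
  pools <- c(A2 = 0.5, B3 = 0.8, C1 = 0.2)
  se <- c(Cin = 0.99, A0 = 0)
  s_emu <- simulate_labeling(emu_decompose(net, c("A2", "B3", "C1")), f,
                             pools, sampling_grid, source_enrichment = se,
                             rtol = 1e-10, atol = 1e-12)
  s_iso <- simulate_isotopomers(net, f, pools, sampling_grid,
                                source_enrichment = se,
                                rtol = 1e-11, atol = 1e-13)
  j <- dplyr::inner_join(s_emu, s_iso,
                         by = c("metabolite", "time_min", "mass"))
  expect_equal(nrow(j), nrow(s_emu))
  expect_lt(max(abs(j$fraction.x - j$fraction.y)), 1e-8)
})

test_that("oracle equivalence also holds with reversible exchange", {
  net <- parse_network(c(
    "in: S2 -> A2 , ab -> ab ; irreversible",
    "iso: A2 -> B2 , ab -> ba ; reversible",
    "out: B2 -> X , ab -> ab ; irreversible"
  ))
  f <- flux_state(net, c(`in` = 2, iso = 2, out = 2), exch = c(iso = 3))
  pools <- c(A2 = 0.4, B2 = 0.7)
  se <- c(S2 = 0.95)
  s_emu <- simulate_labeling(emu_decompose(net, c("A2", "B2")), f, pools,
                             sampling_grid, source_enrichment = se,
                             rtol = 1e-10, atol = 1e-12)
  s_iso <- simulate_isotopomers(net, f, pools, sampling_grid,
                                source_enrichment = se,
                                rtol = 1e-11, atol = 1e-13)
  j <- dplyr::inner_join(s_emu, s_iso,
                         by = c("metabolite", "time_min", "mass"))
  expect_lt(max(abs(j$fraction.x - j$fraction.y)), 1e-8)
})

test_that("MIDs stay on the simplex and decay is monotone without reentry", {
  net <- toy_condense_net()
  f <- flux_solve(net, c(fix = 3, iA = 1, oC = 3))
  pools <- c(A2 = 0.5, B3 = 0.8, C1 = 0.2)
  sim <- simulate_labeling(emu_decompose(net, c("A2", "B3", "C1")), f, pools,
                           sampling_grid,
                           source_enrichment = c(Cin = 1, A0 = 1))
  sums <- sim |>
    dplyr::group_by(.data$metabolite, .data$time_min) |>
    dplyr::summarise(s = sum(.data$fraction), .groups = "drop")
  expect_lt(max(abs(sums$s - 1)), 1e-9)
  expect_true(all(sim$fraction >= 0))
  ser <- twelve_c_series(sim)
  for (m in unique(ser$metabolite)) {
    u <- ser$pct_12c[ser$metabolite == m]
    expect_true(all(diff(u) <= 1e-6))
  }
})

test_that("steady-state 12C equals the unlabeled share of carbon inflow", {
  # two-pool toy: P receives phi unlabeled and (Phi - phi) labeled carbon
  net <- parse_network(c(
    "lab: L -> P , a -> a ; irreversible",
    "unl: U -> P , a -> a ; irreversible",
    "out: P -> X , a -> a ; irreversible"
  ))
  phi <- 1.3
  Phi <- 5
  f <- flux_solve(net, c(lab = Phi - phi, unl = phi))
  sim <- simulate_labeling(emu_decompose(net, "P"), f, c(P = 0.05),
                           c(0, 600), source_enrichment = c(L = 1, U = 0))
  final <- sim$fraction[sim$mass == 0 & sim$time_min == 600]
  expect_equal(final, phi / Phi, tolerance = 1e-6)
})

test_that("rescaling fluxes and pools is equivalent to rescaling time", {
  net <- toy_chain_net()
  v <- 5
  pools <- c(A = 0.5, B = 5, C = 50)
  f1 <- flux_state(net, c(r0 = v, r1 = v, r2 = v, r3 = v))
  f2 <- flux_state(net, 3 * c(r0 = v, r1 = v, r2 = v, r3 = v))
  sys <- emu_decompose(net, c("A", "B", "C"))
  tm <- c(0, 6, 30, 90)
  s1 <- simulate_labeling(sys, f1, pools, tm * 3,
                          source_enrichment = c(S = 1))
  s2 <- simulate_labeling(sys, f2, pools, tm, source_enrichment = c(S = 1))
  expect_equal(s1$fraction, s2$fraction, tolerance = 1e-7)
})

test_that("inactive fractions dilute the observed MID toward the start", {
  net <- parse_network(c(
    "in: S -> A , a -> a ; irreversible",
    "out: A -> X , a -> a ; irreversible"
  ))
  f <- flux_state(net, c(`in` = 2, out = 2))
  sys <- emu_decompose(net, "A")
  tm <- c(0, 60)
  plain <- simulate_labeling(sys, f, c(A = 1), tm,
                             source_enrichment = c(S = 1))
  mixed <- simulate_labeling(sys, f, c(A = 1), tm,
                             source_enrichment = c(S = 1),
                             f_inactive = c(A = 0.25))
  m0_plain <- plain$fraction[plain$mass == 0 & plain$time_min == 60]
  m0_mixed <- mixed$fraction[mixed$mass == 0 & mixed$time_min == 60]
  expect_equal(m0_mixed, 0.75 * m0_plain + 0.25, tolerance = 1e-10)
})

test_that("simulation rejects inconsistent inputs", {
  net <- toy_chain_net()
  sys <- emu_decompose(net, "C")
  f_bad <- flux_state(net, c(r0 = 5, r1 = 4, r2 = 5, r3 = 5))
  pools <- c(A = 1, B = 1, C = 1)
  expect_error(simulate_labeling(sys, f_bad, pools, c(0, 10)),
               "steady state")
  f <- flux_state(net, c(r0 = 5, r1 = 5, r2 = 5, r3 = 5))
  expect_error(simulate_labeling(sys, f, c(A = 1, B = 1), c(0, 10)),
               "pool size missing")
  expect_error(simulate_labeling(sys, f, c(A = 1, B = -1, C = 1), c(0, 10)),
               "positive")
})
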