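test_that("the canonical network parses with the expected structure", {
  net <- cbc_network()
  expect_s3_class(net, "cbc_network")
  expect_length(net$reactions, 46)
  comps <- sort(unique(stats::na.omit(net$metabolites$compartment)))
  expect_equal(comps, c("c", "m", "p", "v"))
  # every balanced metabolite has producers and consumers by construction
  expect_true(all(net$metabolites$role %in% c("balanced", "source", "sink")))
})

test_that("parse errors are informative", {
  expect_error(parse_network("vX: A -> B , ab : a ; irreversible"),
               "atom count mismatch.*vX")
  expect_error(parse_network("# only a comment"), "empty network")
  expect_error(parse_network(c(
    "r: A -> B , ab -> ba ; irreversible",
    "r: B -> C , ab -> ab ; irreversible"
  )), "duplicated reaction id")
  expect_error(parse_network("r: A -> B , ab -> ab"), "';'")
  expect_error(parse_network("r: A -> B , aa -> aa ; reversible"),
               "letter appears more than once")
  # inconsistent carbon count across reactions
  expect_error(parse_network(c(
    "r1: A -> B , ab -> ab ; irreversible",
    "r2: B -> C2 , abc -> abc ; irreversible"
  )), "inconsistent carbon count")
})

test_that("atom maps conserve carbon in every canonical reaction", {
  net <- cbc_network()
  for (r in net$reactions) {
    sub_atoms <- unlist(lapply(r$subs, `[[`, "atoms"))
    prod_atoms <- unlist(lapply(r$prods, `[[`, "atoms"))
    expect_setequal(sub_atoms, prod_atoms)
    expect_equal(length(sub_atoms), length(prod_atoms))
  }
})

test_that("variants add exactly their entry reactions", {
  net <- cbc_network()
  v0 <- make_variant(net, "V0")
  expect_length(v0$reactions, 34)
  v3 <- make_variant(net, "V3")
  expect_equal(setdiff(names(v3$reactions), names(v0$reactions)), "e3_co2")
  v5 <- make_variant(net, "V5")
  # glucose entry + the seven sucrose-recycling / vacuole reactions
  expect_equal(length(v5$reactions) - length(v0$reactions), 8L)
  expect_error(make_variant(net, "V9"), "unknown variant")
  # V0 keeps the core reaction set of the input
  expect_true(all(names(v0$reactions) %in% names(net$reactions)))
})

test_that("steady-state checking flags exactly the perturbed balances", {
  net <- make_variant(cbc_network(), "V5")
  spec <- c(rubisco_c = 172, rubisco_o = 50, shunt = 7, e1_glc = 1.9,
            adpgs = 6, suc_export = 7.5, inv_c = 1, suc_tono = 2,
            co2_efflux = 0)
  f <- flux_solve(net, spec)
  bal <- check_steady_state(net, f)
  expect_true(all(bal$balanced))
  expect_lt(max(abs(bal$net_production)) / max(abs(f$net)), 1e-9)

  # all-zero fluxes balance trivially
  zero <- flux_state(net, stats::setNames(numeric(length(net$reactions)),
                                          names(net$reactions)))
  expect_true(all(check_steady_state(net, zero)$balanced))

  # perturbing one flux flags exactly its adjacent balanced metabolites
  v2 <- f$net
  v2[["prk"]] <- v2[["prk"]] + 1
  bal2 <- check_steady_state(net, v2)
  expect_setequal(bal2$metabolite[!bal2$balanced], c("RU5P.p", "RUBP.p"))
})

test_that("inconsistent flux specifications are rejected", {
  net <- make_variant(cbc_network(), "V0")
  # photorespired CO2 release is tied to oxygenation: gdc = rubisco_o / 2
  expect_error(
    flux_solve(net, c(rubisco_c = 172, rubisco_o = 50, gdc = 10,
                      shunt = 7, adpgs = 6, suc_export = 7.5,
                      co2_efflux = 0)),
    "inconsistent"
  )
  expect_error(flux_solve(net, c(nosuch = 1)), "unknown reaction")
})

test_that("carbon accounting reproduces the flux-map economy", {
  acc <- carbon_accounting(172, 25, 7, 25, 7, 7)
  expect_equal(acc$extra_carbons, 110)
  expect_equal(acc$carbons_photorespiration, 75)
  expect_equal(acc$carbons_shunt, 35)
  expect_equal(round(acc$photoresp_pct_net), 18)
  expect_equal(round(acc$shunt_pct_net), 5)
  expect_equal(acc$atp_per_net_co2, 3.15)

  # no oxygenation, no shunt: bare cost of three ATP per CO2
  acc0 <- carbon_accounting(100, 0, 0, 0, 0, 0)
  expect_equal(acc0$extra_carbons, 0)
  expect_equal(acc0$atp_per_net_co2, 3)

  acc2 <- carbon_accounting(100, 10, 2, 10, 2, 2)
  expect_equal(acc2$extra_carbons, 40)
  expect_equal(acc2$net_assimilation, 88)
  expect_equal(acc2$atp_per_net_co2, 3 + 6 / 88)

  expect_error(carbon_accounting(10, 0, 0, 8, 3, 0), "positive")
})

test_that("accounting identities hold for arbitrary flux values", {
  set.seed(7)
  for (i in 1:20) {
    vc <- runif(1, 50, 300)
    gr <- runif(1, 0, 40)
    pr <- runif(1, 0, 15)
    rel_p <- runif(1, 0, vc / 4)
    rel_s <- runif(1, 0, vc / 10)
    acc <- carbon_accounting(vc, gr, pr, rel_p, rel_s, rel_s)
    expect_equal(acc$extra_carbons, 3 * gr + 5 * pr)
    expect_equal(acc$net_assimilation + rel_p + rel_s, vc)
  }
})

test_that("photorespiratory atom trace returns three quarters of the carbon", {
  net <- cbc_network()
  expect_equal(photorespiration_return_fraction(net), 0.75)

  # hypothetical lossless decarboxylation-free path returns everything
  lossless <- parse_network(c(
    "src: PGAin -> PGA.p , abc -> abc ; irreversible",
    "ox: PGA.p -> 2PG.p + Cx , abc -> ab + c ; irreversible",
    "pg: 2PG.p -> GLY.m , ab -> ab ; irreversible",
    "ret: GLY.m + GLY.m -> S4 , ab + cd -> abcd ; irreversible",
    "back: S4 -> PGA.p + Cw , abcd -> abc + d ; irreversible",
    "snk2: Cw -> W , a -> a ; irreversible",
    "snk: Cx -> X , a -> a ; irreversible"
  ))
  # S4 keeps all four carbons; the trace ends where carbon reaches PGA
  expect_equal(
    photorespiration_return_fraction(lossless, target = "S4"), 1.0)

  # exporting two of three serine-derived carbons leaves one quarter
  quarter <- parse_network(c(
    "src: Sin -> 2PG.p , ab -> ab ; irreversible",
    "pg: 2PG.p -> GLY.m , ab -> ab ; irreversible",
    "gdc: GLY.m + GLY.m -> SER.m + CO2x , ab + cd -> cdb + a ; irreversible",
    "split: SER.m -> GA1 + EXPORT2 , abc -> a + bc ; irreversible",
    "ret: GA1 -> RET1 , a -> a ; irreversible"
  ))
  expect_equal(photorespiration_return_fraction(quarter, target = "RET1"),
               0.25)

  # absent path errors
  nopath <- toy_chain_net()
  expect_error(photorespiration_return_fraction(nopath), "absent")
})

test_that("the return fraction is invariant to lumping granularity", {
  # explicit glycolate/glyoxylate intermediates between 2PG and glycine
  explicit <- parse_network(c(
    "src: Sin -> 2PG.p , ab -> ab ; irreversible",
    "pgp: 2PG.p -> GLT.p , ab -> ab ; irreversible",
    "gox: GLT.p -> GLX.m , ab -> ab ; irreversible",
    "ggat: GLX.m -> GLY.m , ab -> ab ; irreversible",
    "gdc: GLY.m + GLY.m -> SER.m + CO2x , ab + cd -> cdb + a ; irreversible",
    "ser_ga: SER.m -> GA.c , abc -> abc ; irreversible",
    "ret: GA.c -> PGA.p , abc -> abc ; irreversible",
    "use: PGA.p -> OUT , abc -> abc ; irreversible"
  ))
  expect_equal(photorespiration_return_fraction(explicit), 0.75)
})

test_that("carbon accounting can be read off a fitted flux state", {
  net <- make_variant(cbc_network(), "V5")
  f <- flux_solve(net, c(rubisco_c = 172, rubisco_o = 50, shunt = 7,
                         e1_glc = 1.9, adpgs = 6, suc_export = 7.5,
                         inv_c = 1, suc_tono = 2, co2_efflux = 0))
  acc <- carbon_accounting_fluxes(net, f)
  expect_equal(acc$extra_carbons, 110)
  expect_equal(acc$atp_per_net_co2, 3.15)
  expect_equal(round(acc$photoresp_pct_net), 18)
})
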