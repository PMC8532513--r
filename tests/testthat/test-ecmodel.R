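## single-enzyme toy: EX -> R1 (enzyme E, kcat k, MW m) -> biomass
single_enzyme_toy <- function(kcat = 30, mw = 2, pool = 0.1) {
  mets <- data.frame(id = c("A_e", "A_c"), name = "a",
                     compartment = c("e", "c"))
  rxns <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -1000, ub = 1000,
         gpr = NULL, subsystem = "exchange"),
    list(id = "R1", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000,
         gpr = parse_gpr("E"), subsystem = ""),
    list(id = "BIOMASS", stoich = c(A_c = -1), lb = 0, ub = 1000,
         gpr = NULL, subsystem = "biomass"))
  m <- new_model(mets, rxns, "BIOMASS", id = "toy1")
  build_ec_model(m,
                 data.frame(enzyme_id = "E", reaction_id = "R1",
                            kcat = kcat),
                 data.frame(enzyme_id = "E", mw = mw), pool)
}

## three-step pooled linear pathway for the summation theorem
pooled_chain_toy <- function(kcats = c(30, 50, 20),
                            mws = c(1, 2, 1.5), pool = 0.1) {
  mets <- data.frame(id = c("A_e", "A_c", "B_c", "BIO"), name = "m",
                     compartment = c("e", "c", "c", "c"))
  rxns <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -1e5, ub = 1000,
         gpr = NULL, subsystem = "exchange"),
    list(id = "R1", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1e5,
         gpr = parse_gpr("E1"), subsystem = ""),
    list(id = "R2", stoich = c(A_c = -1, B_c = 1), lb = 0, ub = 1e5,
         gpr = parse_gpr("E2"), subsystem = ""),
    list(id = "R3", stoich = c(B_c = -1, BIO = 1), lb = 0, ub = 1e5,
         gpr = parse_gpr("E3"), subsystem = ""),
    list(id = "BIOMASS", stoich = c(BIO = -1), lb = 0, ub = 1e5,
         gpr = NULL, subsystem = "biomass"))
  m <- new_model(mets, rxns, "BIOMASS", id = "toy3")
  build_ec_model(m,
                 data.frame(enzyme_id = c("E1", "E2", "E3"),
                            reaction_id = c("R1", "R2", "R3"),
                            kcat = kcats),
                 data.frame(enzyme_id = c("E1", "E2", "E3"), mw = mws),
                 pool)
}

test_that("ec construction validates its tables", {
  m <- chain_model()
  expect_error(build_ec_model(m, data.frame(enzyme_id = "E",
                                            reaction_id = "CONV",
                                            kcat = -1),
                              data.frame(enzyme_id = "E", mw = 1), 1),
               "non-positive kcat")
  expect_error(build_ec_model(m, data.frame(enzyme_id = "E",
                                            reaction_id = "CONV",
                                            kcat = 10),
                              data.frame(enzyme_id = "other", mw = 1), 1),
               "missing molecular weight")
  expect_error(build_ec_model(m, data.frame(enzyme_id = "E",
                                            reaction_id = "NOPE",
                                            kcat = 10),
                              data.frame(enzyme_id = "E", mw = 1), 1),
               "unknown reaction")
})

test_that("single-enzyme flux has the closed form kcat * pool / MW", {
  ec <- single_enzyme_toy(kcat = 30, mw = 2, pool = 0.1)
  r <- solve_ec(ec)
  expect_equal(r$objective, 30 * 0.1 / 2, tolerance = 1e-9)
  ## infinite pool releases the constraint entirely
  ec2 <- single_enzyme_toy(pool = Inf)
  expect_equal(solve_ec(ec2)$objective,
               solve_fba(ec2$base)$objective)
})

test_that("isozyme pairs allocate the pool to the better enzyme", {
  mets <- data.frame(id = c("A_e", "A_c"), name = "a",
                     compartment = c("e", "c"))
  rxns <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -1000, ub = 1000,
         gpr = NULL, subsystem = "exchange"),
    list(id = "R1", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000,
         gpr = parse_gpr("E1 or E2"), subsystem = ""),
    list(id = "BIOMASS", stoich = c(A_c = -1), lb = 0, ub = 1000,
         gpr = NULL, subsystem = "biomass"))
  m <- new_model(mets, rxns, "BIOMASS", id = "iso")
  P <- 0.2; k1 <- 40; k2 <- 25; m1 <- 2; m2 <- 1
  ec <- build_ec_model(m,
    data.frame(enzyme_id = c("E1", "E2"), reaction_id = c("R1", "R1"),
               kcat = c(k1, k2)),
    data.frame(enzyme_id = c("E1", "E2"), mw = c(m1, m2)), P)
  expect_equal(solve_ec(ec)$objective, P * max(k1 / m1, k2 / m2),
               tolerance = 1e-9)
})

test_that("the sole limiting enzyme has flux control 1", {
  ec <- single_enzyme_toy()
  expect_equal(compute_fcc(ec, "E"), 1, tolerance = 1e-6)
  w <- world_fixture()
  full <- apply_media(w$models[[w$world$truth$complete_species]],
                      w$media)
  ec1 <- build_ec_model(full, w$world$ec_single$kcat,
                        w$world$ec_single$mw, w$world$ec_single$pool)
  expect_equal(compute_fcc(ec1, w$world$truth$limiting_enzyme), 1,
               tolerance = 1e-6)
})

test_that("an unused parallel branch has flux control 0", {
  ## add an idle bypass enzyme to the pooled chain
  ec <- pooled_chain_toy()
  ec$base$reactions$R2b <- list(id = "R2b",
                                stoich = c(A_c = -1, B_c = 1),
                                lb = 0, ub = 1e5,
                                gpr = parse_gpr("E4"), subsystem = "")
  ec$base$gene_ids <- c(ec$base$gene_ids, "E4")
  ec$kcat <- rbind(ec$kcat,
                   data.frame(enzyme_id = "E4", reaction_id = "R2b",
                              kcat = 1))      # far worse than E2
  ec$mw <- c(ec$mw, E4 = 10)
  expect_equal(compute_fcc(ec, "E4"), 0)
})

test_that("flux control coefficients over a pooled pathway sum to 1", {
  ec <- pooled_chain_toy()
  fccs <- vapply(c("E1", "E2", "E3"), function(e) compute_fcc(ec, e),
                 numeric(1))
  expect_equal(sum(fccs), 1, tolerance = 1e-2)
  ## analytic shares: m_i/k_i over the total
  mk <- c(1 / 30, 2 / 50, 1.5 / 20)
  expect_equal(unname(fccs), mk / sum(mk), tolerance = 1e-2)
  ## halving the perturbation changes smooth FCCs by < 1e-3
  fccs2 <- vapply(c("E1", "E2", "E3"), function(e)
    compute_fcc(ec, e, relative_perturbation = 5e-4), numeric(1))
  expect_lt(max(abs(fccs - fccs2)), 1e-3)
})

test_that("flux control errors at zero reference flux", {
  ec <- single_enzyme_toy()
  ec$base$reactions$EX_A$lb <- 0      # nothing to eat
  expect_error(compute_fcc(ec, "E"), "zero flux")
})

test_that("kcat scans report the overflow switch", {
  w <- world_fixture()
  full <- apply_media(w$models[[w$world$truth$complete_species]],
                      w$media)
  ec <- build_ec_model(full, w$world$ec$kcat, w$world$ec$mw,
                       w$world$ec$pool)
  sc <- kcat_scan(ec, c("OGI1", "OGI2"), c(1, 2, 3, 5, 10),
                  report_reactions = c("EX_ETH", "RESP"),
                  carbon_exchange = "EX_S1")
  ## fold-1 row equals the unperturbed ec-pFBA result
  base <- solve_ec(ec, parsimonious = TRUE)
  expect_equal(sc$growth[1], base$objective)
  expect_equal(sc$EX_ETH[1], unname(base$fluxes["EX_ETH"]))
  ## growth is non-decreasing in the scanned kcat
  expect_true(all(diff(sc$growth) >= -1e-9))
  ## fermentation-product export weakly increases with glycolytic kcat
  expect_true(all(diff(sc$EX_ETH) >= -1e-9))
  expect_gt(sc$EX_ETH[nrow(sc)], sc$EX_ETH[1])
  ## respiration is active before the switch
  expect_gt(sc$RESP[1], 0)
  expect_error(kcat_scan(ec, "OGI1", c(0.5, 1), "EX_ETH", "EX_S1"),
               "start at 1")
  expect_error(kcat_scan(ec, "OGI1", c(1, -2), "EX_ETH", "EX_S1"),
               "ascending|positive")
})
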