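# Brutto-equation composition, balance checking and CO partition.

test_that("composed equations reproduce the two published growth-phase reactions", {
  # phase 1: lactate + 30 CO + 31 H2O + 30 Fe3+ ->
  #          acetate + 31 CO2 + 30 Fe2+ + 30 H+ + 17 H2
  eq4 <- compose_brutto(phase_summary(1, 30, 17))
  expect_equal(unname(eq4["co"]), 30)
  expect_equal(unname(eq4["h2o"]), 31)
  expect_equal(unname(eq4["co2"]), 31)
  expect_equal(unname(eq4["h"]), 30)
  expect_equal(unname(eq4["h2"]), 17)

  # phase 2: 270 CO, only 10 Fe3+
  eq5 <- compose_brutto(phase_summary(1, 10, 267))
  expect_equal(unname(eq5["co"]), 270)
  expect_equal(unname(eq5["h2o"]), 271)
  expect_equal(unname(eq5["co2"]), 271)

  # pure hydrogenogenic carboxydotrophy: CO + H2O -> CO2 + H2
  eq3 <- compose_brutto(phase_summary(0, 0, 1))
  expect_equal(unname(eq3["co"]), 1)
  expect_equal(unname(eq3["h2o"]), 1)
  expect_equal(unname(eq3["co2"]), 1)
  expect_equal(unname(eq3["h2"]), 1)
})

test_that("check_balance recounts elements by hand and flags perturbations", {
  # hand element counts for the phase-1 equation, e.g. H: 5+62 = 3+30+34
  eq4 <- compose_brutto(phase_summary(1, 30, 17))
  expect_equal(unname(check_balance(eq4)), rep(0, 5))
  eq5 <- compose_brutto(phase_summary(1, 10, 267))
  expect_equal(unname(check_balance(eq5)), rep(0, 5))

  bad <- unclass(eq4)
  bad["h2"] <- 18
  r <- check_balance(bad)
  expect_true(r["H"] != 0)
  expect_equal(unname(r["C"]), 0)
  expect_equal(unname(r["Fe"]), 0)
})

test_that("co_partition reports 13:17 (~43%) and 3:267 (~1%) splits", {
  p4 <- co_partition(compose_brutto(phase_summary(1, 30, 17)))
  expect_equal(p4$co_to_fe, 13)
  expect_equal(p4$co_to_h2, 17)
  expect_equal(p4$fraction_fe, 13 / 30, tolerance = 1e-12)

  p5 <- co_partition(compose_brutto(phase_summary(1, 10, 267)))
  expect_equal(p5$co_to_fe, 3)
  expect_equal(p5$co_to_h2, 267)
  expect_equal(p5$fraction_fe, 3 / 270, tolerance = 1e-12)

  # iron-free case: no CO goes to Fe
  p3 <- co_partition(compose_brutto(phase_summary(0, 0, 1)))
  expect_equal(p3$co_to_fe, 0)
  expect_equal(p3$fraction_fe, 0)

  # no CO at all: flagged-empty partition
  p0 <- co_partition(compose_brutto(phase_summary(1, 4, 0)))
  expect_false(p0$defined)
  expect_true(is.na(p0$fraction_fe))
})

test_that("infeasible or invalid phase summaries are rejected", {
  expect_error(compose_brutto(phase_summary(1, 3, 5)), "donor electron excess")
  expect_error(phase_summary(-1, 3, 5), "non-negative")
  expect_error(phase_summary(0, 0, 0), "non-zero")
})

test_that("random feasible inputs always balance and partition into [0,1]", {
  set.seed(42)
  for (i in 1:1000) {
    ph <- random_phase()
    eq <- compose_brutto(ph)
    expect_true(max(abs(check_balance(eq))) < 1e-9)
    # electron ledger identity: 4L + 2 CO = F + 2 H2
    expect_equal(4 * eq[["lactate"]] + 2 * eq[["co"]],
                 eq[["fe3"]] + 2 * eq[["h2"]], tolerance = 1e-9)
    p <- co_partition(eq)
    if (p$defined)
      expect_true(p$fraction_fe >= 0 && p$fraction_fe <= 1)
  }
})

test_that("increasing H2 at fixed lactate and iron strictly dilutes the Fe share", {
  fr <- vapply(c(5, 10, 20, 40), function(H)
    co_partition(compose_brutto(phase_summary(1, 30, H)))$fraction_fe,
    numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("half-reaction registry is consistent", {
  hr <- half_reactions()
  expect_false(anyDuplicated(hr$id) > 0)
  expect_true(all(hr$electrons_per_mole > 0))
})
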