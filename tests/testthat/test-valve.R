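test_that("scaling_factor implements 2^FC and rejects up-regulation", {
  expect_identical(scaling_factor(-2), 0.25)
  expect_identical(scaling_factor(0), 1)
  expect_identical(scaling_factor(-1), 0.5)
  expect_equal(scaling_factor(c(-3, -0.5)), c(0.125, 2^-0.5))
  expect_error(scaling_factor(0.1), "up-regulated")
})

test_that("reference fluxes are the parsimonious optimum", {
  toy <- make_toy_model("linear")
  ref <- compute_reference_fluxes(toy$model)
  expect_equal(unname(ref$fluxes), c(10, 10, 10), tolerance = 1e-9)
  expect_equal(ref$objective, toy$optimum, tolerance = 1e-9)
  # steady state within tolerance
  expect_lt(max(abs(as.matrix(toy$model$S) %*% ref$fluxes)), 1e-6)

  par <- make_toy_model("parallel")
  refp <- compute_reference_fluxes(par$model)
  expect_equal(unname(refp$fluxes["EX_A"]), 10, tolerance = 1e-9)
  expect_equal(unname(refp$fluxes["R1"] + refp$fluxes["R2"]), 10,
               tolerance = 1e-9)
  expect_equal(refp$objective, 10, tolerance = 1e-9)

  # forced uptake into a dead-end metabolite is infeasible
  dead <- metabolic_model(
    "dead", data.frame(id = "D"),
    data.frame(id = c("IN", "OTHER"), lower_bound = c(1, 0),
               upper_bound = 10, objective_coefficient = c(0, 1)),
    list(IN = c(D = 1), OTHER = c(D = 0)))
  expect_error(compute_reference_fluxes(dead), "infeasible")
})

test_that("cap mode scales bounds from the reference flux", {
  toy <- make_toy_model("linear")
  ref <- compute_reference_fluxes(toy$model)
  cm <- apply_valve_constraints(toy$model, ref, c(R_AB = -1))
  i <- match("R_AB", cm$reactions$id)
  expect_equal(cm$reactions$lower_bound[i], 0)
  expect_equal(cm$reactions$upper_bound[i], 5, tolerance = 1e-9)
  expect_equal(fba(cm)$objective, 5, tolerance = 1e-9)
  expect_equal(nrow(cm$provenance), 1)
  expect_equal(cm$provenance$factor, 0.5)

  # untouched reactions keep their bounds exactly
  other <- setdiff(cm$reactions$id, "R_AB")
  j <- match(other, cm$reactions$id)
  expect_identical(cm$reactions$lower_bound[j],
                   toy$model$reactions$lower_bound[match(other, toy$model$reactions$id)])

  # empty map: bound-identical derived model (idempotent)
  cm0 <- apply_valve_constraints(toy$model, ref, setNames(numeric(0), character(0)))
  expect_identical(cm0$reactions$lower_bound, toy$model$reactions$lower_bound)
  expect_identical(cm0$reactions$upper_bound, toy$model$reactions$upper_bound)
  cm00 <- apply_valve_constraints(cm0, ref, setNames(numeric(0), character(0)))
  expect_identical(cm00$reactions$upper_bound, cm0$reactions$upper_bound)
})

test_that("zero-reference-flux reactions scale their original bounds", {
  m <- metabolic_model(
    "zr", data.frame(id = c("A", "B")),
    data.frame(id = c("EX", "R", "LOOP", "BIO"),
               lower_bound = c(0, 0, -1000, 0),
               upper_bound = c(10, 1000, 1000, 1000),
               objective_coefficient = c(0, 0, 0, 1)),
    list(EX = c(A = 1), R = c(A = -1, B = 1), LOOP = c(A = -1, B = 1),
         BIO = c(B = -1)))
  ref <- compute_reference_fluxes(m)
  # parsimony leaves at most one of R / LOOP active; constrain the idle one
  idle <- if (abs(ref$fluxes[["LOOP"]]) < 1e-9) "LOOP" else "R"
  cm <- apply_valve_constraints(m, ref, setNames(-2, idle))
  i <- match(idle, cm$reactions$id)
  expect_equal(cm$reactions$lower_bound[i],
               0.25 * m$reactions$lower_bound[i])
  expect_equal(cm$reactions$upper_bound[i],
               0.25 * m$reactions$upper_bound[i])
})

test_that("fixed mode pins both bounds at the scaled reference flux", {
  toy <- make_toy_model("linear")
  ref <- compute_reference_fluxes(toy$model)
  cm <- apply_valve_constraints(toy$model, ref, c(R_AB = -1), mode = "fixed")
  i <- match("R_AB", cm$reactions$id)
  expect_equal(cm$reactions$lower_bound[i], 5, tolerance = 1e-9)
  expect_equal(cm$reactions$upper_bound[i], 5, tolerance = 1e-9)
  expect_equal(fba(cm)$objective, 5, tolerance = 1e-9)
})

test_that("valve constraints reject invalid maps", {
  toy <- make_toy_model("linear")
  ref <- compute_reference_fluxes(toy$model)
  expect_error(apply_valve_constraints(toy$model, ref, c(R_AB = 1)),
               "positive fold change")
  expect_error(apply_valve_constraints(toy$model, ref, c(nope = -1)),
               "unknown reaction")
})

test_that("cap-mode constraints only shrink: growth never exceeds wild type", {
  for (topology in c("linear", "parallel", "shortlong", "classify")) {
    toy <- make_toy_model(topology)
    base <- fba(toy$model)$objective
    ref <- compute_reference_fluxes(toy$model)
    set.seed(17)
    for (rep in 1:5) {
      rxns <- sample(toy$model$reactions$id,
                     sample(seq_len(nrow(toy$model$reactions)), 1))
      fc <- setNames(-runif(length(rxns), 0, 3), rxns)
      cm <- apply_valve_constraints(toy$model, ref, fc)
      sol <- fba(cm)
      expect_equal(sol$status, "optimal")
      expect_lte(sol$objective, base + 1e-9)
      # every constrained interval is inside base interval & reference sign
      for (r in rxns) {
        i <- match(r, cm$reactions$id)
        expect_gte(cm$reactions$lower_bound[i],
                   toy$model$reactions$lower_bound[i] - 1e-12)
        expect_lte(cm$reactions$upper_bound[i],
                   toy$model$reactions$upper_bound[i] + 1e-12)
      }
    }
  }
})

test_that("ever more negative FC drives flux to the switch limit", {
  toy <- make_toy_model("linear")
  ref <- compute_reference_fluxes(toy$model)
  growths <- vapply(c(0, -1, -2, -5, -10, -20), function(fc) {
    fba(apply_valve_constraints(toy$model, ref, c(R_AB = fc)))$objective
  }, numeric(1))
  expect_true(all(diff(growths) < 1e-9))  # monotone in |FC|
  expect_equal(growths[1], 10, tolerance = 1e-9)
  expect_lt(growths[6], 1e-4)            # approaches the switch (zero) limit
})
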