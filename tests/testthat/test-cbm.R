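test_that("FBA reproduces hand-derived optima and reports failures", {
  toy <- make_toy_model("linear")
  sol <- fba(toy$model)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-9)
  # steady state and bounds at the solution
  expect_lt(max(abs(as.matrix(toy$model$S) %*% sol$fluxes)), 1e-6)

  # closing the uptake drives growth to zero
  closed <- set_bounds(toy$model, "EX_A", lower_bound = 0, upper_bound = 0)
  expect_equal(fba(closed)$objective, 0, tolerance = 1e-9)

  # parallel path compensates a tightened branch
  par <- make_toy_model("parallel")$model
  tight <- set_bounds(par, "R1", lower_bound = 0, upper_bound = 3)
  expect_equal(fba(tight)$objective, 10, tolerance = 1e-9)

  expect_error(fba(set_objective(toy$model, "BIO", 0)), "no objective")
})

test_that("carrying-flux counts split by sign with tolerance", {
  sol <- structure(list(objective = 1, status = "optimal",
                        fluxes = c(a = 10, b = 10, c = 10)),
                   class = "flux_solution")
  expect_equal(count_carrying_flux(sol), list(total = 3, positive = 3,
                                              negative = 0))
  sol$fluxes <- c(a = 10, b = -5, c = 10, d = 0)
  expect_equal(count_carrying_flux(sol), list(total = 3, positive = 2,
                                              negative = 1))
  sol$fluxes <- c(a = 1e-12, b = 2)
  expect_equal(count_carrying_flux(sol, tol = 1e-9)$total, 1)
  sol$status <- "infeasible"
  expect_error(count_carrying_flux(sol), "infeasible")
})

test_that("FVA brackets fluxes at the required optimum fraction", {
  par <- make_toy_model("parallel")$model
  res <- fva(par, fraction_of_optimum = 1.0)
  r1 <- res[res$reaction == "R1", ]
  expect_equal(c(r1$min, r1$max), c(0, 10), tolerance = 1e-9)
  r2 <- res[res$reaction == "R2", ]
  expect_equal(c(r2$min, r2$max), c(0, 10), tolerance = 1e-9)

  lin <- make_toy_model("linear")$model
  res_lin <- fva(lin, fraction_of_optimum = 1.0)
  expect_equal(res_lin$min, rep(10, 3), tolerance = 1e-9)
  expect_equal(res_lin$max, rep(10, 3), tolerance = 1e-9)

  res_half <- fva(lin, fraction_of_optimum = 0.5)
  bio <- res_half[res_half$reaction == "BIO", ]
  expect_equal(c(bio$min, bio$max), c(5, 10), tolerance = 1e-9)

  # infeasible model errors before per-reaction solves
  dead <- metabolic_model(
    "dead", data.frame(id = "D"),
    data.frame(id = c("IN", "OUT"), lower_bound = c(5, 0),
               upper_bound = c(10, 0), objective_coefficient = c(0, 1)),
    list(IN = c(D = 1), OUT = c(D = -1)))
  expect_error(fva(dead), "infeasible")
})

test_that("capacity comparison classifies subsystems, overlap allowed", {
  m <- metabolic_model(
    "cap", data.frame(id = "A"),
    data.frame(id = c("R1", "R2", "R3"), lower_bound = 0, upper_bound = 10,
               subsystem = c("s1", "s1", "s2"),
               objective_coefficient = c(0, 0, 1)),
    list(R1 = c(A = 1), R2 = c(A = 1), R3 = c(A = -1)))
  fake_fva <- function(caps) {
    data.frame(reaction = c("R1", "R2", "R3"), min = 0, max = caps,
               capacity = caps)
  }
  cmp <- compare_capacity(fake_fva(c(10, 10, 10)), fake_fva(c(12, 7, 10)), m)
  expect_equal(cmp$per_reaction$delta, c(2, -3, 0))
  expect_equal(cmp$increased_subsystems, "s1")
  expect_equal(cmp$decreased_subsystems, "s1")   # same subsystem, both lists

  cmp_id <- compare_capacity(fake_fva(c(1, 2, 3)), fake_fva(c(1, 2, 3)), m)
  expect_length(cmp_id$increased_subsystems, 0)
  expect_length(cmp_id$decreased_subsystems, 0)

  expect_error(
    compare_capacity(fake_fva(c(1, 2, 3)),
                     fake_fva(c(1, 2, 3))[1:2, ], m),
    "different reaction sets")
})

test_that("single-gene deletion honours GPR semantics", {
  lin <- make_toy_model("linear")$model
  del <- single_gene_deletion(lin)
  expect_equal(del$growth[del$gene == "gB"], 0, tolerance = 1e-9)
  expect_true(del$essential[del$gene == "gB"])

  par <- make_toy_model("parallel")$model
  delp <- single_gene_deletion(par)
  expect_equal(delp$growth[delp$gene == "g1"], 10, tolerance = 1e-9)
  expect_false(delp$essential[delp$gene == "g1"])

  # isozymes: deleting one partner of an OR rule keeps the reaction open
  iso <- metabolic_model(
    "iso", data.frame(id = c("A", "B")),
    data.frame(id = c("EX", "R", "BIO"), lower_bound = 0,
               upper_bound = c(10, 1000, 1000), gpr = c("", "g1 or g2", ""),
               objective_coefficient = c(0, 0, 1)),
    list(EX = c(A = 1), R = c(A = -1, B = 1), BIO = c(B = -1)))
  deli <- single_gene_deletion(iso)
  expect_equal(deli$growth, c(10, 10), tolerance = 1e-9)
  expect_true(all(deli$growth_ratio >= 0 & deli$growth_ratio <= 1))
})

test_that("pFBA suppresses the long path and preserves the optimum", {
  sl <- make_toy_model("shortlong")$model
  sol <- pfba(sl)
  expect_equal(unname(sol$fluxes[c("L1", "L2")]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["SHORT"]), sol$fluxes[["EX_A"]],
               tolerance = 1e-6)
  f_fba <- fba(sl)$objective
  expect_lt(abs(sol$objective - f_fba), 1e-6 * max(1, f_fba))

  # unique optimum: pFBA equals plain FBA on the linear chain
  lin <- make_toy_model("linear")$model
  expect_equal(unname(pfba(lin)$fluxes), unname(fba(lin)$fluxes),
               tolerance = 1e-6)
})

test_that("pFBA flux lies inside the FVA envelope at the optimum", {
  for (topology in c("linear", "parallel", "shortlong", "classify")) {
    m <- make_toy_model(topology)$model
    sol <- pfba(m)
    env <- fva(m, fraction_of_optimum = 1)
    # pFBA tolerates a 1e-6 relative slip of the objective, so widen by that
    slack <- 1e-5
    expect_true(all(sol$fluxes >= env$min - slack),
                label = paste(topology, "pFBA >= FVA min"))
    expect_true(all(sol$fluxes <= env$max + slack),
                label = paste(topology, "pFBA <= FVA max"))
  }
})

test_that("six-way classification recovers the designed categories", {
  cl <- make_toy_model("classify")$model
  cls <- classify_genes_pfba(cl)
  got <- setNames(as.character(cls$category), cls$gene)
  expect_equal(got[["gs"]], "pFBA optima")
  expect_equal(got[["gl1"]], "ELE")
  expect_equal(got[["gl2"]], "ELE")
  expect_equal(got[["gm"]], "MLE")
  expect_equal(got[["g_dead"]], "blocked")
  expect_equal(got[["gA"]], "essential")
  expect_equal(got[["gBIO"]], "essential")

  # categories partition the gene-associated genes
  expect_setequal(cls$gene, model_genes(cl))
  expect_false(any(is.na(cls$category)))

  # essential by deletion implies essential category
  del <- single_gene_deletion(cl)
  expect_true(all(got[del$gene[del$essential]] == "essential"))
})

test_that("objective swaps are pure and honour the zero lower bound", {
  lin <- make_toy_model("linear")$model
  sol <- maximize_reaction_objective(lin, "R_AB")
  expect_equal(sol$objective, 10, tolerance = 1e-9)
  # the input model is untouched
  expect_equal(lin$reactions$objective_coefficient, c(0, 0, 1))

  # a dead-end target yields zero
  cl <- make_toy_model("classify")$model
  expect_equal(maximize_reaction_objective(cl, "DEAD")$objective, 0,
               tolerance = 1e-9)

  # a reversible target is solved with its lower bound forced to zero
  rev <- metabolic_model(
    "rev", data.frame(id = c("A", "B")),
    data.frame(id = c("EX", "R", "BIO"), lower_bound = c(0, -1000, 0),
               upper_bound = c(10, 1000, 1000),
               objective_coefficient = c(0, 0, 1)),
    list(EX = c(A = 1), R = c(A = -1, B = 1), BIO = c(B = -1)))
  solr <- maximize_reaction_objective(rev, "R")
  prov <- attr(solr, "provenance")
  expect_equal(prov$old_lower, -1000)
  expect_gte(min(solr$fluxes["R"]), 0)
  expect_error(maximize_reaction_objective(rev, "missing"), "unknown reaction")
})
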