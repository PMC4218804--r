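test_that("SBML fbc round trip preserves the model", {
  for (topology in c("linear", "classify")) {
    m <- make_toy_model(topology)$model
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, path)
    m2 <- read_sbml(path)
    expect_equal(m2$metabolites$id, m$metabolites$id)
    expect_equal(m2$reactions$id, m$reactions$id)
    expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
    expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
    expect_equal(m2$reactions$subsystem, m$reactions$subsystem)
    expect_equal(m2$reactions$objective_coefficient,
                 m$reactions$objective_coefficient)
    expect_equal(as.matrix(m2$S), as.matrix(m$S))
    expect_equal(lapply(m2$gpr, gpr_to_string), lapply(m$gpr, gpr_to_string))
  }
})

test_that("COBRA notes dialect (kinetic-law bounds, GENE_ASSOCIATION) reads", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="notes_toy">
  <listOfSpecies>
   <species id="A" name="metA" compartment="c"/>
   <species id="B" name="metB" compartment="c"/>
   <species id="A_ext" name="external A" compartment="e" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="EX_A" reversible="false">
    <listOfReactants><speciesReference species="A_ext"/></listOfReactants>
    <listOfProducts><speciesReference species="A"/></listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="0"/>
      <parameter id="UPPER_BOUND" value="10"/>
      <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="R_AB" reversible="true">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: g1 or g2</p>
      <p>SUBSYSTEM: toy pathway</p>
    </body></notes>
    <listOfReactants><speciesReference species="A"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="-1000"/>
      <parameter id="UPPER_BOUND" value="1000"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="BIO" reversible="false">
    <listOfReactants><speciesReference species="B"/></listOfReactants>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="0"/>
      <parameter id="UPPER_BOUND" value="1000"/>
      <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', path)
  m <- read_sbml(path)
  # boundary species dropped from mass balance
  expect_equal(sort(m$metabolites$id), c("A", "B"))
  expect_equal(m$reactions$lower_bound, c(0, -1000, 0))
  expect_equal(gpr_to_string(m$gpr$R_AB), "g1 or g2")
  expect_equal(m$reactions$subsystem[2], "toy pathway")
  expect_equal(unname(m$S["B", "R_AB"]), 2)
  expect_equal(fba(m)$objective, 20)   # 10 A -> 20 B via the 1:2 reaction
})

test_that("SBML error and warning paths behave as contracted", {
  expect_error(read_sbml(tempfile()), "not found")

  # unparseable GPR string downgraded to empty with a warning, reaction kept
  path <- withr::local_tempfile(fileext = ".xml")
  m <- make_toy_model("linear")$model
  write_sbml(m, path)
  txt <- readLines(path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  # rewrite as notes-dialect GPR with broken parentheses on R_AB
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  gpa <- xml2::xml_find_first(rx[[2]],
                              "./*[local-name()='geneProductAssociation']")
  xml2::xml_remove(gpa)
  nt <- xml2::xml_add_child(rx[[2]], "notes")
  bd <- xml2::xml_add_child(nt, "body")
  xml2::xml_add_child(bd, "p", "GENE_ASSOCIATION: (gB")
  path2 <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc, path2)
  expect_warning(m2 <- read_sbml(path2), "unparseable GPR")
  expect_true("R_AB" %in% m2$reactions$id)
  expect_equal(gpr_to_string(m2$gpr$R_AB), "")

  # a model declaring no objective is a configuration error naming it
  doc2 <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc2)
  fo <- xml2::xml_find_all(doc2, ".//*[local-name()='fluxObjective']")
  xml2::xml_remove(fo)
  path3 <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc2, path3)
  expect_error(read_sbml(path3), "TOY_LIN.*no objective")
})

test_that("a model with reactions but no genes reads with an empty gene set", {
  m <- metabolic_model(
    "nogenes", data.frame(id = "A"),
    data.frame(id = c("IN", "OUT"), lower_bound = 0, upper_bound = 10,
               objective_coefficient = c(0, 1)),
    list(IN = c(A = 1), OUT = c(A = -1)))
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_equal(model_genes(m2), character(0))
  expect_equal(fba(m2)$objective, 10)
})

test_that("JSON model dump round trips", {
  m <- make_toy_model("classify")$model
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, path)
  m2 <- model_from_json(path)
  expect_equal(m2$reactions, m$reactions)
  expect_equal(as.matrix(m2$S), as.matrix(m$S))
})
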