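test_that("COBRA-JSON round-trips the toy model", {
  toy <- toy_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_cobra_json(toy$model, path)
  back <- read_cobra_json(path)
  expect_equal(back$reactions$id, toy$model$reactions$id)
  expect_equal(back$reactions$lb, toy$model$reactions$lb)
  expect_equal(back$reactions$ub, toy$model$reactions$ub)
  expect_equal(back$reactions$gpr, toy$model$reactions$gpr)
  expect_equal(back$S[rownames(toy$model$S), ], toy$model$S,
               tolerance = 1e-12)
  expect_setequal(back$genes, toy$model$genes)
})

sbml_text <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="mini" fbc:strict="true">
    <listOfParameters>
      <parameter id="lb_m10" value="-10" constant="true"/>
      <parameter id="ub_100" value="100" constant="true"/>
      <parameter id="zero" value="0" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="A" compartment="c" boundaryCondition="false"/>
      <species id="B" compartment="c" boundaryCondition="false"/>
      <species id="X" compartment="e" boundaryCondition="true"/>
    </listOfSpecies>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="g3" fbc:label="g3"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="UP" reversible="true" fbc:lowerFluxBound="lb_m10"
                fbc:upperFluxBound="ub_100">
        <listOfReactants>
          <speciesReference species="X" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="CONV" reversible="false" fbc:lowerFluxBound="zero"
                fbc:upperFluxBound="ub_100">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="2" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="g1"/>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="g2"/>
              <fbc:geneProductRef fbc:geneProduct="g3"/>
            </fbc:and>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'

test_that("the SBML reader extracts species, bounds and GPRs", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml_text, path)
  m <- read_sbml(path)
  expect_equal(m$id, "mini")
  # boundary species dropped
  expect_setequal(m$metabolites$id, c("A", "B"))
  expect_equal(m$reactions$lb[m$reactions$id == "UP"], -10)
  expect_equal(m$reactions$ub[m$reactions$id == "UP"], 100)
  expect_equal(m$S["A", "CONV"], -2)
  expect_equal(m$S["B", "CONV"], 1)
  gpr <- parse_gpr(m$reactions$gpr[m$reactions$id == "CONV"])
  expect_equal(gpr$type, "or")
  expect_setequal(gpr_genes(gpr), c("g1", "g2", "g3"))
  expect_setequal(m$genes, c("g1", "g2", "g3"))
})

test_that("elemental balance checking flags an unbalanced reaction", {
  mets <- tibble::tibble(id = c("a", "b"), formula = c("C2H4", "CH2"),
                         compartment = "c")
  rxns <- tibble::tibble(id = c("GOOD", "BAD", "EX_a"),
                         lb = 0, ub = 10, gpr = "", objective = 0)
  S <- matrix(c(-1, 2, -1, 1, -1, 0), nrow = 2,
              dimnames = list(c("a", "b"), rxns$id))
  m <- metabolic_model("t", mets, rxns, S)
  out <- check_mass_balance(m)
  expect_true(all(out$reaction == "BAD"))   # exchange exempt, GOOD balanced
  expect_gt(nrow(out), 0)
})

test_that("formula weights match hand values", {
  expect_equal(formula_weight("H2O"), 2 * 1.008 + 15.999)
  expect_equal(formula_weight("C6H12O6"),
               6 * 12.011 + 12 * 1.008 + 6 * 15.999)
  expect_error(formula_weight("Xx2"), "atomic weight")
})

test_that("FBA on a hand-solvable chain finds the bottleneck optimum", {
  mets <- tibble::tibble(id = c("a", "b"), formula = NA_character_,
                         compartment = "c")
  rxns <- tibble::tibble(id = c("IN", "CONV", "OUT"),
                         lb = 0, ub = c(7, 100, 100), gpr = "",
                         objective = c(0, 0, 1))
  S <- matrix(c(1, 0, -1, 1, 0, -1), nrow = 2,
              dimnames = list(c("a", "b"), rxns$id))
  m <- metabolic_model("chain", mets, rxns, S)
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 7)
  expect_equal(unname(sol$fluxes["IN"]), 7)
  # objective by reaction id and by named vector agree
  expect_equal(fba(m, objective = "OUT")$objective, 7)
  expect_equal(fba(m, objective = c(OUT = 2))$objective, 14)
})
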