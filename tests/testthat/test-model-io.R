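test_that("toy TSV dialect parses the packaged loop fixture", {
  path <- system.file("extdata", "loop3.tsv", package = "lpmgem")
  net <- read_model(path)
  expect_length(reactions(net), 5L)
  expect_length(metabolites(net), 3L)
  expect_equal(sum(net$is_exchange), 2L)
  expect_equal(unname(net$S["A", "R_AB"]), -1)
  expect_equal(unname(net$S["B", "R_AB"]), 1)
  expect_equal(unname(net$lb["EX_A"]), -10)
  # order-stable: a second read gives the same ordering
  expect_identical(reactions(read_model(path)), reactions(net))
})

test_that("model round-trips through the TSV dialect exactly", {
  net <- make_loop_network(3, attach_to_path = TRUE)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_model_tsv(net, tmp)
  back <- read_model(tmp)
  expect_identical(reactions(back), reactions(net))
  expect_equal(back$S, net$S)
  expect_equal(back$lb, net$lb)
  expect_equal(back$ub, net$ub)
  expect_identical(back$reversible, net$reversible)
  expect_identical(back$is_exchange, net$is_exchange)
  expect_identical(back$biomass, net$biomass)
})

test_that("stoichiometric equations with coefficients parse", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlb\tub\treversible\texchange",
               "R1\tA + 2 B -> C\t0\t10\tFALSE\tFALSE",
               "EX_A\tA ->\t-5\t0\tFALSE\tTRUE",
               "EX_B\tB ->\t-5\t0\tFALSE\tTRUE",
               "EX_C\tC ->\t0\t10\tFALSE\tTRUE"), tmp)
  net <- read_model(tmp)
  expect_equal(unname(net$S[, "R1"]), c(-1, -2, 1))
})

test_that("invalid bounds and malformed exchanges are rejected", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlb\tub\treversible\texchange",
               "R1\tA -> B\t5\t2\tFALSE\tFALSE"), tmp)
  expect_error(read_model(tmp), "lower bound exceeds upper bound.*R1")
  writeLines(c("id\tequation\tlb\tub\treversible\texchange",
               "EX\tA -> B\t0\t2\tFALSE\tTRUE"), tmp)
  expect_error(read_model(tmp), "exchange reaction")
})

test_that("BiGG-style JSON models are read", {
  tmp <- withr::local_tempfile(fileext = ".json")
  model <- list(
    metabolites = list(list(id = "a"), list(id = "b")),
    reactions = list(
      list(id = "EX_a", metabolites = list(a = -1),
           lower_bound = -10, upper_bound = 0),
      list(id = "R1", metabolites = list(a = -1, b = 1),
           lower_bound = 0, upper_bound = 1000,
           objective_coefficient = 0),
      list(id = "EX_b", metabolites = list(b = -1),
           lower_bound = 0, upper_bound = 1000,
           objective_coefficient = 1)
    )
  )
  jsonlite::write_json(model, tmp, auto_unbox = TRUE)
  net <- read_model(tmp)
  expect_identical(reactions(net), c("EX_a", "R1", "EX_b"))
  expect_equal(unname(net$lb), c(-10, 0, 0))
  expect_identical(net$biomass, "EX_b")
  expect_identical(reactions(net)[net$is_exchange], c("EX_a", "R1", "EX_b")[c(1, 3)])
  sol <- run_fba(net, "EX_b")
  expect_equal(sol$objective, 10, tolerance = 1e-8)
})

test_that("SBML L3 + FBC models are read", {
  tmp <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy">
    <listOfParameters>
      <parameter id="lb_m10" value="-10" constant="true"/>
      <parameter id="lb_0" value="0" constant="true"/>
      <parameter id="ub_1000" value="1000" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="a" boundaryCondition="false"/>
      <species id="b" boundaryCondition="false"/>
      <species id="ext" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_a" reversible="true" fbc:lowerFluxBound="lb_m10"
                fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="a" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="ext" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" reversible="false" fbc:lowerFluxBound="lb_0"
                fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="a" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="b" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_b" reversible="false" fbc:lowerFluxBound="lb_0"
                fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="b" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="EX_b" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>', tmp)
  net <- read_model(tmp, format = "sbml")
  expect_identical(reactions(net), c("EX_a", "R1", "EX_b"))
  expect_length(metabolites(net), 2L)   # boundary species excluded
  expect_equal(unname(net$lb["EX_a"]), -10)
  expect_identical(net$biomass, "EX_b")
  expect_equal(run_fba(net, "EX_b")$objective, 10, tolerance = 1e-8)
})

test_that("expression reading averages replicates and flags bad input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tA_1\tA_2\tB_1",
               "g1\t4.0\t6.0\t2.0",
               "g2\t1.0\t1.0\t3.0"), tmp)
  expr <- read_expression(tmp, replicate_map = list(A = c("A_1", "A_2"),
                                                    B = "B_1"))
  expect_equal(expr$A[expr$gene == "g1"], 5.0)
  expect_equal(expr$B[expr$gene == "g1"], 2.0)  # single replicate unchanged

  writeLines(c("gene\tA", "g1\t1", "g1\t2"), tmp)
  expect_error(read_expression(tmp), "duplicate gene.*g1")

  writeLines(c("gene\tA\tB", "g1\tNA\tNA", "g2\t1\t2"), tmp)
  expect_warning(expr <- read_expression(tmp), "no data.*g1")
  expect_identical(expr$gene, "g2")

  writeLines(c("gene\tA", "g1\tnot_a_number"), tmp)
  expect_error(suppressWarnings(read_expression(tmp)), "non-numeric")
})

test_that("GPR reading rejects empty gene lists and reports unresolved ids", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction\tgenes", "R1\tg1;g2", "R2\tg3"), tmp)
  gpr <- read_gpr(tmp)
  expect_identical(gpr$genes[[1]], c("g1", "g2"))
  net <- make_path_network(3)
  expect_warning(checked <- validate_gpr(gpr, net), "R1.*R2|R1, R2")
  expect_identical(attr(checked, "unresolved"), c("R1", "R2"))

  writeLines(c("reaction\tgenes", "R1\t;"), tmp)
  expect_error(read_gpr(tmp), "empty gene list")
})

test_that("flux tables round-trip at full precision", {
  fluxes <- tibble::tibble(
    reaction = rep(c("r1", "r2"), 2),
    condition = rep(c("A", "B"), each = 2),
    flux = c(1 / 3, -2.5e-7, pi, 0)
  )
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_fluxes(fluxes, tmp)
  back <- read_fluxes(tmp)
  merged <- dplyr::inner_join(fluxes, back, by = c("reaction", "condition"))
  expect_equal(merged$flux.x, merged$flux.y, tolerance = 1e-12)
  expect_error(write_fluxes(fluxes[0, ], tmp), "empty")
})
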