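test_that("support sets keep oriented internal reactions above threshold", {
  net <- make_loop_network(3, attach_to_path = TRUE)
  v <- stats::setNames(rep(0, length(reactions(net))), reactions(net))
  expect_identical(nrow(support_set(v, net)), 0L)

  v[c("C1", "C2", "EX_in")] <- c(0.5, -0.5, -10)
  supp <- support_set(v, net, threshold = 0.01)
  expect_identical(sort(supp$reaction), c("C1", "C2"))   # exchange excluded
  expect_equal(supp$sign[supp$reaction == "C1"], 1)
  expect_equal(supp$sign[supp$reaction == "C2"], -1)

  expect_identical(nrow(support_set(v, net, threshold = 0.6)), 0L)
  expect_error(support_set(v, net, threshold = 0), "positive")
})

test_that("the canonical 3-cycle is detected; acyclic supports are not", {
  net <- make_loop_network(3)
  v <- stats::setNames(rep(1, 3), reactions(net))
  cut <- detect_min_loop(net, support_set(v, net))
  expect_identical(sort(cut$members), c("C1", "C2", "C3"))
  expect_identical(cut$k, 3L)

  chain <- make_path_network(4)
  sol <- run_fba(chain, "EX_out")
  v2 <- stats::setNames(sol$fluxes$flux, sol$fluxes$reaction)
  expect_null(detect_min_loop(chain, support_set(v2, chain)))
})

test_that("the minimum loop is found when 2- and 3-cycles coexist", {
  net <- two_and_three_cycle_network()
  v <- stats::setNames(c(-1, 2, 1, 2, 2, 2, 1), reactions(net))
  validate_solution(net, v)
  supp <- support_set(v, net)
  expect_identical(nrow(supp), 5L)
  cut <- detect_min_loop(net, supp)
  expect_identical(sort(cut$members), c("F_AB", "R_BA"))
  expect_identical(cut$k, 2L)
  # cross-checked against exhaustive cycle enumeration: the support graph
  # holds exactly one 2-cycle and one 3-cycle
  cycles <- lpmgem:::.enumerate_balanced_cycles(net, supp)
  lens <- sort(vapply(cycles, length, integer(1)))
  expect_identical(lens, c(2L, 3L))
  expect_identical(min(lens), cut$k)
})

test_that("loop removal reaches the hand-derived loopless optimum", {
  fx <- redtil_fixture()
  init <- solve_fit(fx$net, fx$targets, fx$partition, fx$config)
  v0 <- flux_vector(init)
  # the initial optimum genuinely rides the 2-cycle toward the target of 8
  expect_gt(v0[["C1"]], 1)
  expect_false(loopless_check(v0, fx$net)$loopless)

  rt <- run_redtil(fx$net, fx$targets, fx$partition, fx$config)
  expect_gte(nrow(rt$cut_log), 1L)
  v <- flux_vector(rt$solution)
  # final cycle net flux below the threshold, pathway flux preserved
  expect_lt(abs(v[["C1"]]), rt$threshold)
  expect_lt(abs(v[["C2"]]), rt$threshold)
  expect_equal(unname(v[c("S1", "S2")]), c(5, 5), tolerance = 1e-6)
  expect_true(loopless_check(v, fx$net, rt$threshold)$loopless)

  # exhaustive direction enumeration agrees on objective and pathway flux
  best <- enumerate_loopless_optimum(fx$net, fx$targets, fx$partition,
                                     fx$config)
  expect_lt(abs(rt$solution$by_condition$objective[1] - best$objective),
            1e-6)
  expect_equal(unname(v[c("S1", "S2")]),
               unname(best$fluxes[c("S1", "S2")]), tolerance = 1e-6)
})

test_that("loop-free solutions are a fixpoint and high thresholds cut nothing", {
  net <- make_path_network(3)
  fitted <- c("S1", "S2")
  fva <- run_fva(net, fitted)
  part <- reaction_partition(net, core = fitted, fva = fva)
  cfg <- fit_config(compute_weights(fva, part), alpha = 0)
  targets <- tibble::tibble(reaction = fitted, condition = "c1",
                            vfit = c(4, 4))
  rt <- run_redtil(net, targets, part, cfg)
  expect_identical(nrow(rt$cut_log), 0L)
  expect_equal(flux_vector(rt$solution)[["S1"]], 4, tolerance = 1e-8)

  fx <- redtil_fixture()
  rt_hi <- run_redtil(fx$net, fx$targets, fx$partition, fx$config,
                      threshold = 100)
  expect_identical(nrow(rt_hi$cut_log), 0L)
})

test_that("cuts accumulate without repeating and degrade the objective weakly", {
  sc <- make_random_til_scenario(11)
  rt <- run_redtil(sc$net, sc$targets, sc$partition, sc$config)
  if (nrow(rt$cut_log) >= 2L) {
    expect_false(anyDuplicated(rt$cut_log$members) > 0)
    expect_true(all(diff(rt$cut_log$objective) >= -1e-9))
  }
  init <- solve_fit(sc$net, sc$targets, sc$partition, sc$config)
  expect_gte(rt$solution$by_condition$objective[1] + 1e-9,
             init$by_condition$objective[1])
})

test_that("the two loop oracles agree, including on planted loops", {
  net <- make_loop_network(3, attach_to_path = TRUE)
  v <- stats::setNames(rep(0, length(reactions(net))), reactions(net))
  v[c("C1", "C2", "C3")] <- 1     # planted unit 3-cycle
  chk <- loopless_check(v, net)
  expect_false(chk$loopless)
  expect_identical(sort(chk$certificate), c("C1", "C2", "C3"))
  expect_identical(chk$milp, chk$graph)

  # empty support is trivially loopless
  chk0 <- loopless_check(v * 0, net)
  expect_true(chk0$loopless)
})

test_that("the single-MILP loopless reference matches plain fits when loop-free", {
  net <- make_path_network(3)
  fitted <- c("S1", "S2")
  fva <- run_fva(net, fitted)
  part <- reaction_partition(net, core = fitted, fva = fva)
  cfg <- fit_config(compute_weights(fva, part), alpha = 0)
  targets <- tibble::tibble(reaction = fitted, condition = "c1",
                            vfit = c(6, 6))
  plain <- solve_fit(net, targets, part, cfg)
  ref <- full_loopless_reference(net, targets, part, cfg)
  expect_equal(ref$by_condition$objective, plain$by_condition$objective,
               tolerance = 1e-8)
  expect_equal(flux_vector(ref)[["S1"]], 6, tolerance = 1e-8)

  big <- make_multicarbon_scenario(n_conditions = 2, seed = 1)$net
  expect_error(
    full_loopless_reference(big, targets, part, cfg, max_rxns = 3),
    "guard")
})
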