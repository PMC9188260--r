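test_that("reaction expression is the mean over mapped genes", {
  expr <- tibble::tibble(gene = c("g1", "g2", "g3"),
                         A = c(4, 6, 1), B = c(2, 2, 9))
  gpr <- tibble::tibble(reaction = c("R1", "R2"),
                        genes = list(c("g1", "g2"), c("g3", "absent")))
  expect_warning(summ <- summarize_expression(expr, gpr, c("R1", "R2")),
                 "absent")
  expect_equal(summ$gbar[summ$reaction == "R1" & summ$condition == "A"], 5)
  expect_equal(summ$gbar[summ$reaction == "R2" & summ$condition == "B"], 9)
  expect_equal(unique(summ$gmin[summ$reaction == "R1"]), 2)
  expect_equal(unique(summ$gmax[summ$reaction == "R1"]), 5)

  # single condition: degenerate range gmin = gmax = gbar
  summ1 <- suppressWarnings(
    summarize_expression(expr[, c("gene", "A")], gpr, "R1"))
  expect_equal(summ1$gmin, summ1$gbar)
  expect_equal(summ1$gmax, summ1$gbar)

  # a reaction with no measured gene is excluded with a warning
  gpr2 <- tibble::tibble(reaction = "R9", genes = list("missing"))
  expect_error(suppressWarnings(summarize_expression(expr, gpr2, "R9")),
               "no reaction")
  expect_error(summarize_expression(expr, gpr, character()), "empty")
})

test_that("linear mapping hits range endpoints and interpolates", {
  summ <- tibble::tibble(
    reaction = rep("R1", 3), condition = c("lo", "mid", "hi"),
    gbar = c(2, 3, 4), gmin = 2, gmax = 4
  )
  fva <- tibble::tibble(reaction = "R1", vmin = 0, vmax = 10)
  tg <- map_expression_to_flux(summ, fva)
  expect_equal(tg$vfit, c(0, 5, 10), tolerance = 1e-12)

  # degenerate expression range maps to the flux-range midpoint
  degen <- tibble::tibble(reaction = "R1", condition = "only",
                          gbar = 3, gmin = 3, gmax = 3)
  expect_message(tg2 <- map_expression_to_flux(degen, fva), "midpoint")
  expect_equal(tg2$vfit, 5)

  # negative ranges work and results stay clamped
  fva2 <- tibble::tibble(reaction = "R1", vmin = -4, vmax = 6)
  tg3 <- map_expression_to_flux(summ, fva2)
  expect_equal(tg3$vfit, c(-4, 1, 6), tolerance = 1e-12)
  expect_true(all(tg3$vfit >= -4 & tg3$vfit <= 6))
})

test_that("mapping is affine and invertible on non-degenerate ranges", {
  set.seed(42)
  for (i in 1:20) {
    g <- sort(stats::runif(4, 0, 12))
    vr <- sort(stats::runif(2, -50, 50))
    summ <- tibble::tibble(reaction = "R", condition = paste0("c", 1:4),
                           gbar = g, gmin = min(g), gmax = max(g))
    fva <- tibble::tibble(reaction = "R", vmin = vr[1], vmax = vr[2])
    tg <- map_expression_to_flux(summ, fva)
    # invert the affine map and recover the expression values
    g_back <- min(g) + (tg$vfit - vr[1]) * (max(g) - min(g)) /
      (vr[2] - vr[1])
    expect_equal(g_back, g, tolerance = 1e-9)
  }
})

test_that("weights follow the reciprocal-range rule with the +100 AR constant", {
  net <- make_path_network(3)
  fva <- tibble::tibble(reaction = c("S1", "S2"),
                        vmin = c(-4, -4), vmax = c(6, 6))
  part <- reaction_partition(net, core = "S1", associated = "S2")
  w <- compute_weights(fva, part)
  expect_equal(w$w[w$reaction == "S1"], 1 / 6)
  expect_equal(w$w[w$reaction == "S2"], 1 / 106)

  fva0 <- tibble::tibble(reaction = c("S1", "S2"),
                         vmin = c(0, 0), vmax = c(0, 6))
  expect_error(compute_weights(fva0, part), "zero flux range.*S1")
  # and the partition constructor discards such reactions upstream
  expect_message(
    part0 <- reaction_partition(net, core = c("S1", "S2"), fva = fva0),
    "zero feasible range")
  expect_identical(part0$CR, "S2")
  expect_true("S1" %in% part0$RO)
})

test_that("feasible targets are reproduced exactly (zero discrepancy)", {
  net <- make_path_network(3)
  fitted <- c("S1", "S2")
  fva <- run_fva(net, fitted)
  part <- reaction_partition(net, core = fitted, fva = fva)
  cfg <- fit_config(compute_weights(fva, part), alpha = 0)
  targets <- tibble::tibble(reaction = fitted, condition = "c1",
                            vfit = c(7, 7))
  fit <- solve_fit(net, targets, part, cfg)
  expect_lt(fit$discrepancy, 1e-9)
  expect_equal(flux_vector(fit)[["S1"]], 7, tolerance = 1e-8)
})

test_that("a bound-infeasible target leaves exactly the clip distance", {
  # chain capacity 5, target 8: optimum clips to 5, residual 3
  net <- make_path_network(3, uptake_bound = 5)
  fva <- run_fva(net, "S1")
  part <- reaction_partition(net, core = "S1", fva = fva)
  cfg <- fit_config(compute_weights(fva, part), alpha = 0)
  targets <- tibble::tibble(reaction = "S1", condition = "c1", vfit = 8)
  fit <- solve_fit(net, targets, part, cfg)
  expect_equal(flux_vector(fit)[["S1"]], 5, tolerance = 1e-8)
  expect_equal(fit$discrepancy, 3, tolerance = 1e-8)
  expect_equal(fit$by_condition$objective, 3 * cfg$weights$w[1],
               tolerance = 1e-8)
})

test_that("a large flux penalty suppresses a free internal cycle", {
  fx <- loopy_fit_fixture(alpha = 10, cycle_fitted = FALSE)
  fit <- solve_fit(fx$net, fx$targets, fx$partition, fx$config)
  v <- flux_vector(fit)
  expect_lt(max(abs(v[c("C1", "C2", "C3")])), 1e-6)
})

test_that("per-condition problems are independent and sum in d", {
  net <- make_path_network(3)
  fva <- run_fva(net, c("S1", "S2"))
  part <- reaction_partition(net, core = c("S1", "S2"), fva = fva)
  cfg <- fit_config(compute_weights(fva, part), alpha = 0)
  targets <- tibble::tibble(
    reaction = rep(c("S1", "S2"), 2),
    condition = rep(c("A", "B"), each = 2),
    vfit = c(3, 3, 11, 11)   # B overshoots capacity by 1 on each reaction
  )
  both <- solve_fit(net, targets, part, cfg)
  single_a <- solve_fit(net, targets[targets$condition == "A", ], part, cfg)
  single_b <- solve_fit(net, targets[targets$condition == "B", ], part, cfg)
  expect_equal(both$discrepancy,
               single_a$discrepancy + single_b$discrepancy,
               tolerance = 1e-9)
  expect_equal(both$by_condition$discrepancy[both$by_condition$condition == "B"],
               2, tolerance = 1e-8)
})

test_that("total_discrepancy recomputes d from the returned solution", {
  fx <- loopy_fit_fixture()
  fit <- solve_fit(fx$net, fx$targets, fx$partition, fx$config)
  rep <- total_discrepancy(fit, fx$targets)
  expect_equal(rep$d, fit$discrepancy, tolerance = 1e-8)
  manual <- sum(abs(fit$residuals$flux - fit$residuals$vfit))
  expect_equal(rep$d, manual, tolerance = 1e-8)

  # additivity on a hand-made table
  targets <- tibble::tibble(reaction = c("r", "r"), condition = c("A", "B"),
                            vfit = c(5, 5))
  fluxes <- tibble::tibble(reaction = c("r", "r"), condition = c("A", "B"),
                           flux = c(4, 7))
  expect_equal(total_discrepancy(fluxes, targets)$d, 3)
  expect_error(total_discrepancy(fluxes[1, ], targets), "cover all")
})

test_that("alpha trades the fit term against the flux penalty monotonically", {
  fx <- loopy_fit_fixture(cycle_fitted = FALSE)
  alphas <- c(0, 0.01, 0.1, 1, 10)
  fits <- lapply(alphas, function(a) {
    solve_fit(fx$net, fx$targets, fx$partition,
              fit_config(fx$config$weights, alpha = a))
  })
  fit_terms <- vapply(fits, function(f) f$fit_term, numeric(1))
  penalties <- vapply(fits, function(f) f$penalty_sum, numeric(1))
  expect_true(all(diff(fit_terms) >= -1e-8))
  expect_true(all(diff(penalties) <= 1e-8))
})

test_that("differential-expression screening selects shifted genes", {
  make_expr <- function(mat, prefix) {
    tb <- tibble::tibble(gene = rownames(mat))
    for (j in seq_len(ncol(mat))) tb[[paste0(prefix, j)]] <- mat[, j]
    tb
  }
  gpr <- tibble::tibble(reaction = c("R_flat", "R_sep"),
                        genes = list("g_flat", "g_sep"))

  # identical distributions -> p = 1 -> not selected;
  # zero within-group variance with distinct means -> selected
  expr_mat <- rbind(g_flat = c(1, 1, 1), g_sep = c(9, 9, 9))
  ctrl_mat <- rbind(g_flat = c(1, 1, 1), g_sep = c(2, 2, 2))
  expr <- make_expr(expr_mat, "t")
  attr(expr, "replicates") <- list(condA = c("t1", "t2", "t3"))
  control <- make_expr(ctrl_mat, "c")
  sel <- select_associated(expr, control, c("R_flat", "R_sep"), gpr)
  expect_identical(as.character(sel), "R_sep")

  # fewer than 2 replicates per group errors with the condition named
  expr_bad <- expr
  attr(expr_bad, "replicates") <- list(condA = "t1")
  expect_error(select_associated(expr_bad, control, "R_sep", gpr), "condA")
})

test_that("a 5-SD planted shift is recovered and nulls stay unselected", {
  # Oracle: recompute the same screen independently (t.test + BH over all
  # genes) each repeat; the function's selections must match it exactly.
  # Aggregate over 200 repeats, the null reactions stay almost entirely
  # unselected while the shifted reaction is selected at a rate far above
  # the null rate (n = 3 gives the screen limited but real power).
  set.seed(101)
  n_rep <- 200L
  hits <- 0L
  null_hits <- 0L
  n_null <- 20L
  genes <- c("g_shift", paste0("g_null", seq_len(n_null)))
  gpr <- tibble::tibble(
    reaction = c("R_shift", paste0("R_null", seq_len(n_null))),
    genes = as.list(genes)
  )
  for (i in seq_len(n_rep)) {
    base <- matrix(stats::rnorm((n_null + 1) * 3), ncol = 3,
                   dimnames = list(genes, NULL))
    trt <- matrix(stats::rnorm((n_null + 1) * 3), ncol = 3,
                  dimnames = list(genes, NULL))
    trt["g_shift", ] <- trt["g_shift", ] + 5   # planted 5-SD shift
    expr <- tibble::tibble(gene = genes, t1 = trt[, 1], t2 = trt[, 2],
                           t3 = trt[, 3])
    attr(expr, "replicates") <- list(condA = c("t1", "t2", "t3"))
    control <- tibble::tibble(gene = genes, c1 = base[, 1], c2 = base[, 2],
                              c3 = base[, 3])
    sel <- select_associated(expr, control, gpr$reaction, gpr, fdr = 0.05)
    # independent oracle for this repeat
    p <- vapply(genes, function(g) {
      stats::t.test(trt[g, ], base[g, ])$p.value
    }, numeric(1))
    oracle <- gpr$reaction[stats::p.adjust(p, "BH") < 0.05]
    expect_identical(sort(as.character(sel)), sort(oracle))
    if ("R_shift" %in% sel) hits <- hits + 1L
    null_hits <- null_hits + sum(grepl("null", sel))
  }
  null_rate <- null_hits / (n_rep * n_null)
  expect_gte(1 - null_rate, 0.95)          # >= 95% of nulls not selected
  expect_gt(hits / n_rep, 0.1)             # shift detected at a real rate
  expect_gt(hits / n_rep, 20 * max(null_rate, 1e-4))
})
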