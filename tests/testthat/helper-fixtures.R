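# Shared fixtures, built in code at test time.

# Attached 3-cycle network with expression for all fitted reactions.
# Chain genes are exact affine images of a planted chain flux (2, 5, 8 across
# conditions); cycle genes follow arbitrary monotone patterns, so the linear
# mapping inflates their targets over the loop-inflated FVA ranges.
loopy_fit_fixture <- function(alpha = 0.01, cycle_fitted = TRUE) {
  net <- make_loop_network(3, attach_to_path = TRUE)
  expr <- tibble::tibble(
    gene = c("gS1", "gS2", "gC1", "gC2", "gC3"),
    A = c(2 + 0.5 * 2, 3 + 0.4 * 2, 4, 6, 5),
    B = c(2 + 0.5 * 5, 3 + 0.4 * 5, 5, 5, 4),
    C = c(2 + 0.5 * 8, 3 + 0.4 * 8, 6, 4, 6)
  )
  gpr <- tibble::tibble(
    reaction = c("S1", "S2", "C1", "C2", "C3"),
    genes = list("gS1", "gS2", "gC1", "gC2", "gC3")
  )
  fitted <- if (cycle_fitted) c("S1", "S2", "C1", "C2", "C3") else
    c("S1", "S2")
  fva <- run_fva(net, fitted)
  partition <- reaction_partition(net, core = fitted, fva = fva)
  config <- fit_config(compute_weights(fva, partition), alpha = alpha)
  summary <- summarize_expression(expr[expr$gene %in% paste0(
    "g", fitted), , drop = FALSE], gpr, fitted)
  targets <- map_expression_to_flux(summary, fva)
  list(net = net, expr = expr, gpr = gpr, fva = fva, partition = partition,
       config = config, summary = summary, targets = targets)
}

# Path + attached 2-cycle fixture for loop removal. The forward cycle member
# C1 is a core reaction (target 8), the return member C2 an associated one
# (target 0); the slightly higher core weight makes circulating at 8 the
# optimum, so the initial fit genuinely rides the loop.
redtil_fixture <- function(alpha = 0.01) {
  net <- make_loop_network(2, attach_to_path = TRUE)
  fitted <- c("S1", "S2", "C1", "C2")
  fva <- run_fva(net, fitted)
  partition <- reaction_partition(net, core = c("S1", "S2", "C1"),
                                  associated = "C2", fva = fva)
  config <- fit_config(compute_weights(fva, partition), alpha = alpha)
  targets <- tibble::tibble(
    reaction = fitted,
    condition = "c1",
    vfit = c(5, 5, 8, 0)
  )
  idx <- match(targets$reaction, fva$reaction)
  targets$vmin <- fva$vmin[idx]
  targets$vmax <- fva$vmax[idx]
  class(targets) <- c("fit_targets", class(targets))
  list(net = net, fva = fva, partition = partition, config = config,
       targets = targets)
}

# Network holding both a duplicated forward/reverse pair (2-cycle) and a
# 3-cycle, everything internal except the two exchanges keeping it fed.
two_and_three_cycle_network <- function() {
  mets <- c("A", "B", "C", "D")
  ids <- c("EX_A", "F_AB", "R_BA", "T_BC", "T_CD", "T_DB", "EX_B")
  S <- matrix(0, nrow = length(mets), ncol = length(ids),
              dimnames = list(mets, ids))
  S["A", "EX_A"] <- -1
  S["A", "F_AB"] <- -1; S["B", "F_AB"] <- 1
  S["B", "R_BA"] <- -1; S["A", "R_BA"] <- 1
  S["B", "T_BC"] <- -1; S["C", "T_BC"] <- 1
  S["C", "T_CD"] <- -1; S["D", "T_CD"] <- 1
  S["D", "T_DB"] <- -1; S["B", "T_DB"] <- 1
  S["B", "EX_B"] <- -1
  metabolic_network(
    S,
    lb = c(-10, 0, 0, 0, 0, 0, 0),
    ub = c(0, 1000, 1000, 1000, 1000, 1000, 1000),
    reversible = rep(FALSE, length(ids)),
    is_exchange = ids %in% c("EX_A", "EX_B")
  )
}

# All flux values of one condition as a named vector.
flux_vector <- function(fit, condition = fit$fluxes$condition[1]) {
  sub <- fit$fluxes[fit$fluxes$condition == condition, , drop = FALSE]
  stats::setNames(sub$flux, sub$reaction)
}

# Exhaustive-direction loopless oracle for small networks: enumerate every
# sign orthant of the internal reactions, solve the fit LP restricted to it,
# keep solutions whose support carries no balanced directed cycle, return the
# best. Independent of run_redtil and full_loopless_reference.
enumerate_loopless_optimum <- function(net, targets, partition, config,
                                       condition = targets$condition[1]) {
  internal <- internal_reactions(net)
  stopifnot(length(internal) <= 12)
  patterns <- expand.grid(rep(list(c(1, -1)), length(internal)))
  best <- NULL
  for (i in seq_len(nrow(patterns))) {
    signs <- as.numeric(patterns[i, ])
    net2 <- net
    for (k in seq_along(internal)) {
      j <- match(internal[k], reactions(net2))
      if (signs[k] > 0) {
        net2$lb[j] <- max(net2$lb[j], 0)
      } else {
        net2$ub[j] <- min(net2$ub[j], 0)
      }
    }
    fit <- tryCatch(
      solve_fit(net2, targets, partition, config, condition),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    v <- flux_vector(fit, condition)
    chk <- loopless_check(v, net, threshold = 1e-6)
    if (!chk$loopless) next
    obj <- fit$by_condition$objective[1]
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(objective = obj, fluxes = v)
    }
  }
  best
}
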