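#' Post-solve validator for flux vectors
#'
#' Asserts the steady-state mass balance `|S v| <= tol` per metabolite and
#' the bound constraints `lb - tol <= v <= ub + tol`. Every solution the
#' package returns passes through this check.
#'
#' @param net A `metabolic_network`.
#' @param v Named (or network-ordered) flux vector.
#' @param tol Feasibility tolerance (default `1e-6`).
#' @return Invisibly `TRUE`; errors with the offending metabolite/reaction
#'   otherwise.
#' @export
validate_solution <- function(net, v, tol = 1e-6) {
  v <- if (!is.null(names(v))) v[reactions(net)] else stats::setNames(v, reactions(net))
  if (anyNA(v)) stop("flux vector has missing values")
  imbalance <- abs(as.numeric(net$S %*% v))
  if (any(imbalance > tol)) {
    worst <- which.max(imbalance)
    stop("mass balance violated at metabolite '", metabolites(net)[worst],
         "' (|S v| = ", format(imbalance[worst]), ")")
  }
  low <- v - net$lb; high <- net$ub - v
  if (any(low < -tol) || any(high < -tol)) {
    bad <- reactions(net)[which.min(pmin(low, high))]
    stop("flux bound violated for reaction '", bad, "'")
  }
  invisible(TRUE)
}

.flux_solution <- function(net, v, condition, objective, status) {
  fluxes <- tibble::tibble(
    reaction = reactions(net),
    condition = condition,
    flux = if (is.null(v)) NA_real_ else as.numeric(v)[seq_along(reactions(net))]
  )
  structure(list(fluxes = fluxes, objective = objective, status = status,
                 condition = condition),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> condition '", x$condition, "', status ", x$status,
      ", objective ", format(x$objective), "\n", sep = "")
  invisible(x)
}

# Assemble the shared LP skeleton: variables are the n reaction fluxes plus,
# when an exchange cap is set, one nonnegative uptake-magnitude auxiliary per
# capped exchange reaction (u_j >= -v_j, sum u_j <= cap).
.base_lp <- function(net, condition = NULL) {
  n <- length(reactions(net))
  cap <- net$constraints$exchange_cap
  capped <- if (!is.null(cap)) {
    setdiff(reactions(net)[net$is_exchange], cap$designated)
  } else character()
  nu <- length(capped)
  ntot <- n + nu
  A_eq <- cbind(net$S, matrix(0, nrow = nrow(net$S), ncol = nu))
  b_eq <- rep(0, nrow(net$S))
  A_ub <- NULL; b_ub <- NULL
  if (nu > 0L) {
    rows <- matrix(0, nrow = nu + 1L, ncol = ntot)
    for (k in seq_len(nu)) {           # -v_j - u_j <= 0  (u_j >= uptake)
      j <- match(capped[k], reactions(net))
      rows[k, j] <- -1
      rows[k, n + k] <- -1
    }
    rows[nu + 1L, n + seq_len(nu)] <- 1   # sum u_j <= cap
    A_ub <- rows
    b_ub <- c(rep(0, nu), cap$cap)
  }
  floors <- net$constraints$biomass_floor
  if (!is.null(condition) && !is.null(floors) && condition %in% names(floors)) {
    if (is.null(net$biomass)) stop("biomass floor set but no biomass reaction")
    row <- rep(0, ntot)
    row[match(net$biomass, reactions(net))] <- -1   # -v_bio <= -B_c
    A_ub <- rbind(A_ub, row)
    b_ub <- c(b_ub, -floors[[condition]])
  }
  list(n = n, ntot = ntot, capped = capped,
       A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
       lb = c(net$lb, rep(0, nu)), ub = c(net$ub, rep(Inf, nu)))
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction subject to steady-state
#' mass balance, flux bounds, and any exchange cap / biomass floor attached
#' to the network.
#'
#' @param net A `metabolic_network`.
#' @param objective Reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @param condition Optional condition label (applies that condition's
#'   biomass floor, if any).
#' @return A `flux_solution`; `status` reports infeasibility or
#'   unboundedness rather than erroring.
#' @export
run_fba <- function(net, objective, sense = c("max", "min"),
                    condition = NULL) {
  sense <- match.arg(sense)
  j <- match(objective, reactions(net))
  if (is.na(j)) stop("objective reaction '", objective, "' not in network")
  base <- .base_lp(net, condition)
  obj <- rep(0, base$ntot); obj[j] <- 1
  res <- solve_lp(lp_problem(obj, base$lb, base$ub,
                             A_eq = base$A_eq, b_eq = base$b_eq,
                             A_ub = base$A_ub, b_ub = base$b_ub,
                             maximize = sense == "max"))
  v <- NULL
  if (identical(res$status, "optimal")) {
    v <- res$x[seq_len(base$n)]
    validate_solution(net, v)
  }
  .flux_solution(net, v, condition %||% "default", res$objective, res$status)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux over the
#' feasible polytope (two LPs per reaction, batched into one solver call).
#' Run on the globally-bounded network: condition-specific biomass floors are
#' deliberately not applied, so the ranges hold across all conditions.
#'
#' @param net A `metabolic_network`.
#' @param rxns Reaction ids (default: all reactions).
#' @return Tibble with columns `reaction`, `vmin`, `vmax`.
#' @export
run_fva <- function(net, rxns = reactions(net)) {
  missing_ids <- setdiff(rxns, reactions(net))
  if (length(missing_ids)) {
    stop("unknown reaction(s): ", paste(missing_ids, collapse = ", "))
  }
  base <- .base_lp(net)
  feas <- solve_lp(lp_problem(rep(0, base$ntot), base$lb, base$ub,
                              A_eq = base$A_eq, b_eq = base$b_eq,
                              A_ub = base$A_ub, b_ub = base$b_ub))
  if (!identical(feas$status, "optimal")) {
    stop("network infeasible before FVA (status ", feas$status, ")")
  }
  probs <- list()
  for (r in rxns) {
    j <- match(r, reactions(net))
    obj <- rep(0, base$ntot); obj[j] <- 1
    probs[[length(probs) + 1L]] <-
      lp_problem(obj, base$lb, base$ub, A_eq = base$A_eq, b_eq = base$b_eq,
                 A_ub = base$A_ub, b_ub = base$b_ub, maximize = FALSE)
    probs[[length(probs) + 1L]] <-
      lp_problem(obj, base$lb, base$ub, A_eq = base$A_eq, b_eq = base$b_eq,
                 A_ub = base$A_ub, b_ub = base$b_ub, maximize = TRUE)
  }
  res <- solve_lp_batch(probs)
  vmin <- vmax <- numeric(length(rxns))
  for (i in seq_along(rxns)) {
    lo <- res[[2L * i - 1L]]; hi <- res[[2L * i]]
    if (!identical(lo$status, "optimal") || !identical(hi$status, "optimal")) {
      stop("FVA solve failed for reaction '", rxns[i], "' (status ",
           lo$status, "/", hi$status, ")")
    }
    j <- match(rxns[i], reactions(net))
    vmin[i] <- min(max(lo$objective, net$lb[j]), net$ub[j])
    vmax[i] <- max(min(hi$objective, net$ub[j]), net$lb[j])
    if (vmin[i] > vmax[i]) vmin[i] <- vmax[i] <- (vmin[i] + vmax[i]) / 2
  }
  tibble::tibble(reaction = rxns, vmin = vmin, vmax = vmax)
}

#' Cap the summed uptake of non-designated exchange reactions
#'
#' Adds the linear constraint that the total uptake magnitude
#' `sum(max(0, -v))` over all exchange reactions *not* in `designated` stays
#' at or below `cap` (linearized with nonnegative auxiliaries). Designated
#' exchanges (the candidate carbon sources) are untouched. This mirrors
#' restricting the influx of all medium components other than the carbon
#' sources under study.
#'
#' @param net A `metabolic_network`.
#' @param designated Exchange reaction ids exempt from the cap.
#' @param cap Nonnegative total uptake budget; `Inf` removes the cap.
#' @return The network with the cap recorded (consumed by all solvers).
#' @export
add_exchange_cap <- function(net, designated = character(), cap) {
  if (cap < 0) stop("exchange cap must be nonnegative")
  not_exch <- setdiff(designated, reactions(net)[net$is_exchange])
  if (length(not_exch)) {
    stop("designated id(s) are not exchange reactions: ",
         paste(not_exch, collapse = ", "))
  }
  if (is.infinite(cap)) {
    net$constraints$exchange_cap <- NULL
  } else {
    net$constraints$exchange_cap <- list(designated = designated, cap = cap)
  }
  net
}

#' Open uptake bounds for designated carbon transporters
#'
#' Sets `lb` of each listed exchange reaction to `-rate` — simultaneously for
#' every listed transporter, in every condition — so the fit can pick any
#' candidate carbon source without prior knowledge of the true one.
#'
#' @param net A `metabolic_network`.
#' @param transporters Named numeric vector: exchange reaction id -> maximum
#'   uptake rate (nonnegative).
#' @return The modified network.
#' @export
configure_carbon_uptake_bounds <- function(net, transporters) {
  if (length(transporters) == 0L) return(net)
  if (is.null(names(transporters)) || any(!nzchar(names(transporters)))) {
    stop("'transporters' must be a named vector")
  }
  if (any(transporters < 0)) stop("uptake rates must be nonnegative")
  not_exch <- setdiff(names(transporters), reactions(net)[net$is_exchange])
  if (length(not_exch)) {
    stop("not exchange reaction(s): ", paste(not_exch, collapse = ", "))
  }
  net$lb[names(transporters)] <- -as.numeric(transporters)
  net
}

#' Add per-condition biomass production floors
#'
#' Records the constraint `v_biomass >= B_c` for each condition (a lower
#' limit on growth), applied whenever that condition's problem is solved.
#'
#' @param net A `metabolic_network` with a biomass reaction.
#' @param floors Named numeric vector: condition -> nonnegative floor.
#' @return The modified network.
#' @export
add_biomass_floor <- function(net, floors) {
  if (is.null(net$biomass)) stop("network has no biomass reaction")
  if (any(floors < 0)) stop("biomass floors must be nonnegative")
  if (is.null(names(floors))) stop("'floors' must be named by condition")
  net$constraints$biomass_floor <-
    utils::modifyList(as.list(net$constraints$biomass_floor %||% list()),
                      as.list(floors))
  net
}
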