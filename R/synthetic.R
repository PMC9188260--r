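# Synthetic networks and scenarios. These are first-class generators used by
# the test-suite and the command-line `synth` preset; every generator is
# deterministic given its seed and never touches the caller's RNG state.

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Linear-chain toy network
#'
#' `EX_in -> M1 -> ... -> Mn -> EX_out`, irreversible, with an optional
#' biomass sink on the terminal metabolite. Conservation pins the maximal
#' chain flux to `uptake_bound`, and FVA of every internal step is
#' `(0, uptake_bound)`.
#'
#' @param n_steps Number of chain metabolites (>= 1).
#' @param uptake_bound Maximal substrate uptake rate (mmol/gDW/h).
#' @param biomass Include a `BIOMASS` sink reaction (default `TRUE`).
#' @return A `metabolic_network`.
#' @export
make_path_network <- function(n_steps = 3, uptake_bound = 10,
                              biomass = TRUE) {
  stopifnot(n_steps >= 1, uptake_bound >= 0)
  mets <- paste0("M", seq_len(n_steps))
  rxn_ids <- c("EX_in",
               if (n_steps > 1) paste0("S", seq_len(n_steps - 1L)),
               "EX_out",
               if (biomass) "BIOMASS")
  S <- matrix(0, nrow = n_steps, ncol = length(rxn_ids),
              dimnames = list(mets, rxn_ids))
  S["M1", "EX_in"] <- -1
  if (n_steps > 1) {
    for (k in seq_len(n_steps - 1L)) {
      S[k, paste0("S", k)] <- -1
      S[k + 1L, paste0("S", k)] <- 1
    }
  }
  S[mets[n_steps], "EX_out"] <- -1
  if (biomass) S[mets[n_steps], "BIOMASS"] <- -1
  lb <- stats::setNames(rep(0, length(rxn_ids)), rxn_ids)
  ub <- stats::setNames(rep(1000, length(rxn_ids)), rxn_ids)
  lb["EX_in"] <- -uptake_bound
  ub["EX_in"] <- 0
  metabolic_network(S, lb, ub,
                    reversible = rep(FALSE, length(rxn_ids)),
                    is_exchange = rxn_ids %in% c("EX_in", "EX_out"),
                    biomass = if (biomass) "BIOMASS")
}

#' Toy network containing a thermodynamically infeasible loop
#'
#' A directed internal cycle `L1 -> L2 -> ... -> L1` of reversible reactions
#' with symmetric bounds. Detached, the cycle is a pure circulation (FVA
#' spans the full `c(-bound, bound)` on every member). Attached, the cycle
#' shares one metabolite with a linear chain, so loop members inflate FVA
#' ranges while real pathway flux stays small — the motivating fixture for
#' bound reduction and loop removal.
#'
#' @param cycle_len Number of cycle reactions (>= 2).
#' @param attach_to_path Attach the cycle to a [make_path_network()] chain.
#' @param bound Symmetric flux bound on cycle members.
#' @param n_steps,uptake_bound Passed to the chain when attaching.
#' @return A `metabolic_network`.
#' @export
make_loop_network <- function(cycle_len = 3, attach_to_path = FALSE,
                              bound = 1000, n_steps = 3, uptake_bound = 10) {
  stopifnot(cycle_len >= 2)
  if (!attach_to_path) {
    mets <- paste0("L", seq_len(cycle_len))
    ids <- paste0("C", seq_len(cycle_len))
    S <- matrix(0, nrow = cycle_len, ncol = cycle_len,
                dimnames = list(mets, ids))
    for (k in seq_len(cycle_len)) {
      S[k, k] <- -1
      S[if (k == cycle_len) 1L else k + 1L, k] <- 1
    }
    return(metabolic_network(S, rep(-bound, cycle_len), rep(bound, cycle_len),
                             reversible = rep(TRUE, cycle_len),
                             is_exchange = rep(FALSE, cycle_len)))
  }
  path <- make_path_network(n_steps, uptake_bound)
  hub <- "M2"
  loop_mets <- paste0("L", seq_len(cycle_len - 1L))
  ids <- paste0("C", seq_len(cycle_len))
  mets <- c(metabolites(path), loop_mets)
  S <- matrix(0, nrow = length(mets), ncol = length(reactions(path)) + cycle_len,
              dimnames = list(mets, c(reactions(path), ids)))
  S[metabolites(path), reactions(path)] <- path$S
  cyc_nodes <- c(hub, loop_mets, hub)   # hub -> L1 -> ... -> hub
  for (k in seq_len(cycle_len)) {
    S[cyc_nodes[k], ids[k]] <- S[cyc_nodes[k], ids[k]] - 1
    S[cyc_nodes[k + 1L], ids[k]] <- S[cyc_nodes[k + 1L], ids[k]] + 1
  }
  metabolic_network(
    S,
    lb = c(path$lb, rep(-bound, cycle_len)),
    ub = c(path$ub, rep(bound, cycle_len)),
    reversible = c(path$reversible, rep(TRUE, cycle_len)),
    is_exchange = c(path$is_exchange, rep(FALSE, cycle_len)),
    biomass = path$biomass
  )
}

#' Multi-carbon-source scenario with planted fluxes and expression
#'
#' Emulates a study design in which an organism grows on one designated
#' carbon source per condition: `n_transporters` parallel substrate routes
#' (`EX_C_i -> T_i -> EX_P_i`), each condition's planted flux state running
#' predominantly through its designated transporter at the full uptake
#' bound. Gene expression is generated from the planted fluxes by the
#' affine-plus-noise rule `g = a + b * v + eps`, `eps ~ Normal(0, noise_sd)`
#' on the log2 scale, with two genes per transporter reaction
#' (per-gene `a`, `b > 0`). Planted states satisfy mass balance and bounds
#' by construction, and each fitted reaction attains its feasible minimum
#' and maximum across conditions, so at `noise_sd = 0` the expression-to-flux
#' mapping inverts exactly to the planted fluxes.
#'
#' @param n_conditions Number of conditions (>= 2; z-scores need at least 2).
#' @param n_transporters Number of substrate routes (>= `n_conditions`);
#'   routes beyond `n_conditions` carry a small, condition-varying background
#'   uptake.
#' @param seed RNG seed (mandatory; regeneration is bit-identical).
#' @param noise_sd Expression noise SD in log2 units (default 0.1).
#' @param uptake_bound Designated-substrate uptake bound (default 10).
#' @return An `lpm_scenario` list: `net`, `expression`, `gpr`, `planted`
#'   (long tibble), `transporters` (exchange ids), `designated` (condition ->
#'   exchange id), `core` (fitted reaction ids), `conditions`, `seed`.
#' @export
make_multicarbon_scenario <- function(n_conditions = 8,
                                      n_transporters = n_conditions,
                                      seed = 1, noise_sd = 0.1,
                                      uptake_bound = 10) {
  if (n_conditions < 2) stop("need at least 2 conditions (z-scores undefined)")
  if (n_transporters < n_conditions) {
    stop("n_transporters must be >= n_conditions")
  }
  .with_seed(seed, {
    ti <- seq_len(n_transporters)
    mets <- c(paste0("C", ti), paste0("P", ti))
    ex_c <- paste0("EX_C", ti)
    trans <- paste0("T", ti)
    ex_p <- paste0("EX_P", ti)
    ids <- c(ex_c, trans, ex_p)
    S <- matrix(0, nrow = length(mets), ncol = length(ids),
                dimnames = list(mets, ids))
    for (i in ti) {
      S[paste0("C", i), ex_c[i]] <- -1
      S[paste0("C", i), trans[i]] <- -1
      S[paste0("P", i), trans[i]] <- 1
      S[paste0("P", i), ex_p[i]] <- -1
    }
    bg_bound <- 0.5
    max_up <- ifelse(ti <= n_conditions, uptake_bound, bg_bound)
    lb <- stats::setNames(c(-max_up, rep(0, 2L * n_transporters)), ids)
    ub <- stats::setNames(c(rep(0, n_transporters),
                            rep(1000, 2L * n_transporters)), ids)
    net <- metabolic_network(S, lb, ub,
                             reversible = rep(FALSE, length(ids)),
                             is_exchange = ids %in% c(ex_c, ex_p))
    conditions <- paste0("cond", seq_len(n_conditions))
    uptake <- matrix(0, nrow = n_transporters, ncol = n_conditions,
                     dimnames = list(trans, conditions))
    for (i in ti) {
      if (i <= n_conditions) {
        uptake[i, i] <- uptake_bound
      } else {
        # background route: varies across conditions, hits 0 and its bound
        frac <- ((seq_len(n_conditions) + i) %% n_conditions) /
          (n_conditions - 1L)
        uptake[i, ] <- bg_bound * pmin(frac, 1)
      }
    }
    planted <- dplyr::bind_rows(lapply(conditions, function(cond) {
      u <- uptake[, cond]
      v <- stats::setNames(numeric(length(ids)), ids)
      v[ex_c] <- -u; v[trans] <- u; v[ex_p] <- u
      validate_solution(net, v)
      tibble::tibble(reaction = ids, condition = cond, flux = as.numeric(v))
    }))
    genes <- as.vector(vapply(ti, function(i) paste0("g", i, "_", 1:2),
                              character(2)))
    a <- stats::runif(length(genes), 2, 6)
    b <- stats::runif(length(genes), 0.3, 0.7)
    expr <- tibble::tibble(gene = genes)
    for (ci in seq_along(conditions)) {
      vals <- numeric(length(genes))
      for (i in ti) {
        for (k in 1:2) {
          gi <- 2L * (i - 1L) + k
          vals[gi] <- a[gi] + b[gi] * uptake[i, ci] +
            stats::rnorm(1, 0, noise_sd)
        }
      }
      expr[[conditions[ci]]] <- vals
    }
    gpr <- tibble::tibble(
      reaction = trans,
      genes = lapply(ti, function(i) paste0("g", i, "_", 1:2))
    )
    structure(
      list(net = net, expression = expr, gpr = gpr, planted = planted,
           transporters = ex_c,
           designated = stats::setNames(ex_c[seq_len(n_conditions)],
                                        conditions),
           core = trans, conditions = conditions, seed = seed,
           noise_sd = noise_sd),
      class = "lpm_scenario"
    )
  })
}

#' @export
print.lpm_scenario <- function(x, ...) {
  cat("<lpm_scenario> ", length(x$conditions), " conditions, ",
      length(x$transporters), " transporters, noise_sd = ", x$noise_sd,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Random path-plus-cycles fixture for loop-removal testing
#'
#' Builds a small chain network with one or two attached reversible cycles
#' (lengths 2-4) and fit targets that deliberately tempt the optimizer into
#' running flux around the cycles: chain targets come from a random planted
#' throughput, cycle-member targets are drawn well above it. All internal
#' reactions convert one metabolite into one metabolite, which keeps the
#' directed-cycle oracle of [loopless_check()] exact.
#'
#' @param seed RNG seed.
#' @param alpha Penalty strength for the returned config (default 0: loops
#'   are suppressed only by explicit loop removal).
#' @return List: `net`, `targets`, `partition`, `config`, `seed`.
#' @export
make_random_til_scenario <- function(seed, alpha = 0) {
  .with_seed(seed, {
    n_steps <- sample(3:4, 1)
    uptake <- stats::runif(1, 5, 15)
    n_cycles <- sample(1:2, 1)
    lens <- sample(2:4, n_cycles, replace = TRUE)
    net <- make_loop_network(lens[1L], attach_to_path = TRUE,
                             bound = 1000, n_steps = n_steps,
                             uptake_bound = uptake)
    if (n_cycles == 2L) {
      # second cycle through M1, appended manually
      k <- lens[2L]
      loop_mets <- paste0("K", seq_len(k - 1L))
      ids <- paste0("D", seq_len(k))
      mets <- c(metabolites(net), loop_mets)
      S <- matrix(0, nrow = length(mets),
                  ncol = length(reactions(net)) + k,
                  dimnames = list(mets, c(reactions(net), ids)))
      S[metabolites(net), reactions(net)] <- net$S
      nodes <- c("M1", loop_mets, "M1")
      for (j in seq_len(k)) {
        S[nodes[j], ids[j]] <- S[nodes[j], ids[j]] - 1
        S[nodes[j + 1L], ids[j]] <- S[nodes[j + 1L], ids[j]] + 1
      }
      net <- metabolic_network(
        S, c(net$lb, rep(-1000, k)), c(net$ub, rep(1000, k)),
        reversible = c(net$reversible, rep(TRUE, k)),
        is_exchange = c(net$is_exchange, rep(FALSE, k)),
        biomass = net$biomass
      )
    }
    cyc <- grep("^[CD]", reactions(net), value = TRUE)
    chain <- grep("^S", reactions(net), value = TRUE)
    fitted <- c(chain, cyc)
    fva <- run_fva(net, fitted)
    partition <- reaction_partition(net, core = fitted, fva = fva)
    config <- fit_config(compute_weights(fva, partition), alpha = alpha)
    planted <- stats::runif(1, 1, uptake)
    targets <- tibble::tibble(
      reaction = fitted,
      condition = "c1",
      vfit = c(rep(planted, length(chain)),
               stats::runif(length(cyc), 5, 50))
    )
    fva_idx <- match(targets$reaction, fva$reaction)
    targets$vfit <- pmin(pmax(targets$vfit, fva$vmin[fva_idx]),
                         fva$vmax[fva_idx])
    targets$vmin <- fva$vmin[fva_idx]
    targets$vmax <- fva$vmax[fva_idx]
    class(targets) <- c("fit_targets", class(targets))
    list(net = net, targets = targets, partition = partition,
         config = config, fva = fva, seed = seed)
  })
}
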