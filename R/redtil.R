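# RED-TIL: iterative detection and exclusion of thermodynamically infeasible
# loops (TILs). A TIL is a closed internal cycle carrying nonzero net flux at
# steady state, which violates the loop law; exchange reactions are never
# part of one.

#' Oriented support of a flux solution
#'
#' Internal reactions whose flux magnitude reaches `threshold`, each tagged
#' with the sign of its flux so that stoichiometric columns can be oriented
#' along the solution's direction.
#'
#' @param v Named flux vector (or `flux_solution`/`lpm_fit` restricted to
#'   one condition via `condition`).
#' @param net A `metabolic_network`.
#' @param threshold Flux magnitude cutoff (default 0.01).
#' @param condition Condition label when `v` is a fit object.
#' @return Tibble `reaction`, `sign` (+1/-1).
#' @export
support_set <- function(v, net, threshold = 0.01, condition = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  if (!is.numeric(v)) {
    fluxes <- v$fluxes
    if (!is.null(condition)) {
      fluxes <- fluxes[fluxes$condition == condition, , drop = FALSE]
    }
    v <- stats::setNames(fluxes$flux, fluxes$reaction)
  }
  ids <- intersect(internal_reactions(net), names(v))
  vv <- v[ids]
  keep <- abs(vv) >= threshold
  tibble::tibble(reaction = ids[keep],
                 sign = as.numeric(ifelse(vv[keep] > 0, 1, -1)))
}

#' Detect a minimum-total-flux infeasible loop in a support set
#'
#' Solves the MILP: minimize `sum(lambda)` subject to
#' `S_oriented %*% lambda = 0`, `lambda_r >= inFC_r`, `sum(inFC) >= 2`,
#' `inFC` binary, `lambda >= 0`, over the support columns oriented along the
#' solution's flux directions. A feasible optimum is a circulation — a TIL;
#' its members are the reactions carrying positive cycle flux. Returns
#' `NULL` when the MILP is infeasible (no loop within the support).
#'
#' @param net A `metabolic_network`.
#' @param support Oriented support tibble from [support_set()].
#' @param threshold Flux threshold recorded on the returned cut.
#' @param lambda_cap Upper bound on the cycle-flux variables (any positive
#'   cap gives the same membership set up to scaling; default 1000).
#' @return A loop cut: list `members`, `sign`, `k`, `lambda`, `threshold`;
#'   or `NULL`.
#' @export
detect_min_loop <- function(net, support, threshold = 0.01,
                            lambda_cap = 1000) {
  ns <- nrow(support)
  if (ns == 0L) return(NULL)
  S_or <- net$S[, support$reaction, drop = FALSE] %*% diag(support$sign, ns)
  nm <- nrow(S_or)
  # variables: lambda (ns) then inFC (ns)
  A_eq <- cbind(S_or, matrix(0, nm, ns))
  A_ub <- rbind(
    cbind(-diag(ns), diag(ns)),            # inFC_r - lambda_r <= 0
    c(rep(0, ns), rep(-1, ns))             # -sum inFC <= -2
  )
  res <- solve_lp(lp_problem(
    obj = c(rep(1, ns), rep(0, ns)),
    lb = rep(0, 2L * ns), ub = c(rep(lambda_cap, ns), rep(1, ns)),
    A_eq = A_eq, b_eq = rep(0, nm),
    A_ub = A_ub, b_ub = c(rep(0, ns), -2),
    integrality = c(rep(0L, ns), rep(1L, ns))
  ))
  if (!identical(res$status, "optimal")) return(NULL)
  lambda <- res$x[seq_len(ns)]
  infc <- res$x[ns + seq_len(ns)] > 0.5
  members <- lambda > 1e-6 | infc
  if (sum(members) < 2L) return(NULL)
  list(members = support$reaction[members],
       sign = support$sign[members],
       k = sum(members),
       lambda = lambda[members],
       threshold = threshold)
}

#' Iteratively remove infeasible loops from the fit solution
#'
#' Alternates: solve the expression fit, assemble the oriented support of
#' each condition's solution, detect a minimum loop, and exclude it with a
#' cut before re-solving. Each cut introduces binary indicators linked to the
#' loop members' fluxes by big-M rows (flux at or above the threshold in the
#' loop's direction forces the indicator to 1) plus the cardinality
#' constraint `sum(inFC) <= k - 1`, so at least one member must drop below
#' the threshold. Cuts are condition-specific. The loop ends when no
#' above-threshold loop remains in any condition; the objective can only
#' degrade (weakly) as cuts accumulate, and a repeated cut is a hard error.
#'
#' @param net A `metabolic_network`.
#' @param targets `fit_targets` tibble.
#' @param partition A `reaction_partition`.
#' @param config A `fit_config`.
#' @param conditions Conditions to solve (default: all in `targets`).
#' @param threshold TIL flux threshold (default 0.01, a trade-off between
#'   CPU time and resolution).
#' @param max_iter Safety cap on detect/re-solve rounds.
#' @return An `lpm_redtil` object: final `solution` (an `lpm_fit`), `cuts`
#'   per condition, a `cut_log` tibble, `threshold`, `n_iter`.
#' @export
run_redtil <- function(net, targets, partition, config,
                       conditions = unique(targets$condition),
                       threshold = 0.01, max_iter = 100L) {
  cuts <- stats::setNames(vector("list", length(conditions)), conditions)
  cut_log <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("loop removal did not terminate within ",
                              max_iter, " rounds")
    fit <- solve_fit(net, targets, partition, config, conditions,
                     cuts = cuts)
    found <- FALSE
    for (cond in conditions) {
      v <- stats::setNames(
        fit$fluxes$flux[fit$fluxes$condition == cond],
        fit$fluxes$reaction[fit$fluxes$condition == cond]
      )
      supp <- support_set(v, net, threshold)
      cut <- detect_min_loop(net, supp, threshold)
      if (is.null(cut)) next
      key <- paste(cut$members, cut$sign, sep = ":", collapse = "|")
      seen <- vapply(cuts[[cond]], function(x) {
        paste(x$members, x$sign, sep = ":", collapse = "|")
      }, character(1))
      if (key %in% seen) {
        stop("repeated loop cut in condition '", cond, "': ", key)
      }
      cuts[[cond]] <- c(cuts[[cond]], list(cut))
      cut_log[[length(cut_log) + 1L]] <- tibble::tibble(
        iteration = iter, condition = cond,
        members = paste(cut$members, collapse = ";"),
        k = cut$k,
        objective = fit$by_condition$objective[
          fit$by_condition$condition == cond]
      )
      found <- TRUE
    }
    if (!found) break
  }
  structure(
    list(solution = fit, cuts = cuts,
         cut_log = if (length(cut_log)) dplyr::bind_rows(cut_log) else
           tibble::tibble(iteration = integer(), condition = character(),
                          members = character(), k = integer(),
                          objective = numeric()),
         threshold = threshold, n_iter = iter),
    class = "lpm_redtil"
  )
}

#' @export
print.lpm_redtil <- function(x, ...) {
  cat("<lpm_redtil> ", nrow(x$cut_log), " loop cut(s) over ", x$n_iter,
      " round(s), threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

# Simple-cycle enumeration on the oriented support graph. Nodes are
# metabolites; each support reaction contributes edges from every consumed
# to every produced metabolite (after orienting its column along the
# solution's flux). Exact for networks whose internal reactions convert one
# metabolite into one metabolite (all generated fixtures).
.enumerate_balanced_cycles <- function(net, support, max_cycles = 10000L) {
  if (nrow(support) == 0L) return(list())
  edges <- list()
  for (i in seq_len(nrow(support))) {
    col <- net$S[, support$reaction[i]] * support$sign[i]
    from <- names(col)[col < 0]; to <- names(col)[col > 0]
    for (f in from) for (t in to) {
      edges[[length(edges) + 1L]] <-
        list(from = f, to = t, reaction = support$reaction[i])
    }
  }
  if (length(edges) == 0L) return(list())
  nodes <- sort(unique(unlist(lapply(edges, function(e) c(e$from, e$to)))))
  out_edges <- lapply(stats::setNames(nodes, nodes), function(nd) {
    Filter(function(e) e$from == nd, edges)
  })
  cycles <- list()
  # rooted DFS restricted to nodes >= root (each cycle found once, at its
  # lexicographically smallest node)
  for (root in nodes) {
    stack_path <- character()
    stack_rxns <- character()
    dfs <- function(node) {
      if (length(cycles) >= max_cycles) return()
      for (e in out_edges[[node]]) {
        if (e$to < root) next
        if (e$to == root) {
          rxns <- c(stack_rxns, e$reaction)
          if (length(unique(rxns)) == length(rxns)) {
            cycles[[length(cycles) + 1L]] <<- rxns
          }
        } else if (!(e$to %in% stack_path)) {
          stack_path <<- c(stack_path, e$to)
          stack_rxns <<- c(stack_rxns, e$reaction)
          dfs(e$to)
          stack_path <<- stack_path[-length(stack_path)]
          stack_rxns <<- stack_rxns[-length(stack_rxns)]
        }
      }
    }
    stack_path <- root
    dfs(root)
  }
  # keep cycles that admit a strictly positive balanced circulation
  Filter(function(rxns) {
    idx <- match(rxns, support$reaction)
    S_or <- net$S[, support$reaction[idx], drop = FALSE] %*%
      diag(support$sign[idx], length(idx))
    ns <- .nullspace(S_or)
    if (ncol(ns) == 0L) return(FALSE)
    if (ncol(ns) == 1L) {
      v <- ns[, 1L]
      return(all(v > 1e-9) || all(v < -1e-9))
    }
    TRUE   # multi-dimensional circulation space: treat as balanced
  }, cycles)
}

.nullspace <- function(A, tol = 1e-9) {
  if (ncol(A) == 0L) return(matrix(0, 0, 0))
  sv <- svd(A, nu = 0, nv = ncol(A))
  d <- c(sv$d, rep(0, ncol(A) - length(sv$d)))
  keep <- d < tol * max(d[1], 1)
  sv$v[, keep, drop = FALSE]
}

#' Verify that a solution carries no infeasible loop
#'
#' Two independent oracles must agree: (a) the minimum-loop MILP over the
#' solution's oriented support is infeasible; (b) directed-cycle enumeration
#' on the support graph finds no stoichiometrically balanced cycle. Their
#' disagreement is a hard error (a signal to the test harness, not a user
#' condition).
#'
#' @param v Named flux vector (or a fit object plus `condition`).
#' @param net A `metabolic_network`.
#' @param threshold Support threshold (default 0.01).
#' @param condition Condition label when `v` is a fit object.
#' @return List `loopless` (logical), `certificate` (reaction ids of a
#'   balanced cycle, or `NULL`), `milp`, `graph`.
#' @export
loopless_check <- function(v, net, threshold = 0.01, condition = NULL) {
  supp <- support_set(v, net, threshold, condition)
  if (nrow(supp) == 0L) {
    return(list(loopless = TRUE, certificate = NULL,
                milp = TRUE, graph = TRUE))
  }
  milp_loop <- detect_min_loop(net, supp, threshold)
  cycles <- .enumerate_balanced_cycles(net, supp)
  milp_clean <- is.null(milp_loop)
  graph_clean <- length(cycles) == 0L
  if (milp_clean != graph_clean) {
    stop("loop oracle disagreement: MILP says ",
         if (milp_clean) "loopless" else "loop",
         ", cycle enumeration says ",
         if (graph_clean) "loopless" else "loop")
  }
  list(loopless = milp_clean,
       certificate = if (!graph_clean) cycles[[1L]] else NULL,
       milp = milp_clean, graph = graph_clean)
}

#' Single-MILP loopless reference fit
#'
#' Solves the expression fit with the classical loopless constraints in one
#' MILP per condition: a direction binary per internal reaction, a bounded
#' pseudo-energy variable with sign opposite to the flux, and the null-space
#' condition that energies are orthogonal to every internal circulation.
#' Used as the independent reference that the iterative loop removal is
#' validated against; guarded to small networks.
#'
#' @param net A `metabolic_network` (at most `max_rxns` reactions).
#' @param targets,partition,config As for [solve_fit()].
#' @param conditions Conditions to solve.
#' @param max_rxns Size guard (default 200).
#' @param K Energy-variable bound (default 1000).
#' @return An `lpm_fit` (fluxes validated; loop-law satisfied).
#' @export
full_loopless_reference <- function(net, targets, partition, config,
                                    conditions = unique(targets$condition),
                                    max_rxns = 200L, K = 1000) {
  if (length(reactions(net)) > max_rxns) {
    stop("network exceeds the ", max_rxns, "-reaction guard")
  }
  internal <- internal_reactions(net)
  n_int <- length(internal)
  N <- .nullspace(net$S[, internal, drop = FALSE])
  builds <- lapply(conditions, function(cond) {
    tc <- targets[targets$condition == cond, , drop = FALSE]
    built <- .build_fit_lp(net, tc, partition, config, cond)
    p <- built$problem
    n0 <- length(p$obj)
    ntot <- n0 + 2L * n_int                   # + [a (binary) | G] blocks
    pad <- function(A) if (is.null(A)) NULL else
      cbind(A, matrix(0, nrow(A), ntot - ncol(A)))
    A_eq <- pad(p$A_eq); b_eq <- p$b_eq
    if (ncol(N) > 0L) {
      rows <- matrix(0, ncol(N), ntot)
      rows[, n0 + n_int + seq_len(n_int)] <- t(N)   # N^T G = 0
      A_eq <- rbind(A_eq, rows); b_eq <- c(b_eq, rep(0, ncol(N)))
    }
    A_ub <- pad(p$A_ub); b_ub <- p$b_ub
    rows <- matrix(0, 4L * n_int, ntot); rhs <- numeric(4L * n_int)
    for (k in seq_len(n_int)) {
      j <- match(internal[k], reactions(net))
      M <- max(abs(net$lb[j]), abs(net$ub[j]), 1)
      a_col <- n0 + k; g_col <- n0 + n_int + k
      r0 <- 4L * (k - 1L)
      rows[r0 + 1L, j] <- 1;  rows[r0 + 1L, a_col] <- -M;      rhs[r0 + 1L] <- 0
      rows[r0 + 2L, j] <- -1; rows[r0 + 2L, a_col] <- M;       rhs[r0 + 2L] <- M
      rows[r0 + 3L, g_col] <- 1;  rows[r0 + 3L, a_col] <- 1 + K; rhs[r0 + 3L] <- K
      rows[r0 + 4L, g_col] <- -1; rows[r0 + 4L, a_col] <- -(1 + K); rhs[r0 + 4L] <- -1
    }
    A_ub <- rbind(A_ub, rows); b_ub <- c(b_ub, rhs)
    integrality <- c(p$integrality %||% rep(0L, n0),
                     rep(1L, n_int), rep(0L, n_int))
    problem <- lp_problem(
      obj = c(p$obj, rep(0, 2L * n_int)),
      lb = c(p$lb, rep(0, n_int), rep(-K, n_int)),
      ub = c(p$ub, rep(1, n_int), rep(K, n_int)),
      A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
      integrality = integrality
    )
    list(problem = problem, n = built$n)
  })
  res <- solve_lp_batch(lapply(builds, `[[`, "problem"))
  flux_rows <- list(); resid_rows <- list(); cond_rows <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[[i]]
    r <- res[[i]]
    if (!identical(r$status, "optimal")) {
      stop("loopless reference ", r$status, " for condition '", cond, "'")
    }
    v <- stats::setNames(r$x[seq_len(builds[[i]]$n)], reactions(net))
    validate_solution(net, v)
    tc <- targets[targets$condition == cond, , drop = FALSE]
    resid <- abs(v[tc$reaction] - tc$vfit)
    w <- config$weights$w[match(tc$reaction, config$weights$reaction)]
    flux_rows[[i]] <- tibble::tibble(reaction = reactions(net),
                                     condition = cond, flux = as.numeric(v))
    resid_rows[[i]] <- tibble::tibble(
      reaction = tc$reaction, condition = cond,
      flux = as.numeric(v[tc$reaction]), vfit = tc$vfit, w = w,
      residual = as.numeric(resid)
    )
    cond_rows[[i]] <- tibble::tibble(
      condition = cond, status = r$status, objective = r$objective,
      fit_term = sum(w * resid),
      penalty_sum = sum(abs(v[partition$RO])),
      discrepancy = sum(resid)
    )
  }
  by_condition <- dplyr::bind_rows(cond_rows)
  structure(
    list(fluxes = dplyr::bind_rows(flux_rows),
         residuals = dplyr::bind_rows(resid_rows),
         targets = targets, partition = partition, config = config,
         by_condition = by_condition,
         discrepancy = sum(by_condition$discrepancy),
         fit_term = sum(by_condition$fit_term),
         penalty_sum = sum(by_condition$penalty_sum)),
    class = "lpm_fit"
  )
}

#' Write the loop-cut log as TSV
#'
#' @param redtil An `lpm_redtil`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_cut_log <- function(redtil, path) {
  readr::write_tsv(redtil$cut_log, path, progress = FALSE)
  invisible(path)
}
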