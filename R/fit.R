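#' Partition reactions into core, associated and remaining sets
#'
#' Core reactions (CR) are fitted directly to expression-derived targets;
#' associated reactions (AR) are fitted with down-weighted residuals; all
#' remaining reactions (RO, internal and exchange) enter only the L1 flux
#' penalty. When FVA bounds are supplied, fitted reactions whose feasible
#' range is exactly `[0, 0]` are discarded from CR/AR (they cannot carry
#' flux) and moved to RO with a message.
#'
#' @param net A `metabolic_network`.
#' @param core,associated Character vectors of reaction ids (disjoint).
#' @param fva Optional FVA bounds tibble from [run_fva()].
#' @return A list with components `CR`, `AR`, `RO` (class
#'   `reaction_partition`).
#' @export
reaction_partition <- function(net, core, associated = character(),
                               fva = NULL) {
  all_r <- reactions(net)
  unknown <- setdiff(c(core, associated), all_r)
  if (length(unknown)) {
    stop("unknown reaction(s) in partition: ", paste(unknown, collapse = ", "))
  }
  if (length(intersect(core, associated))) {
    stop("core and associated sets overlap: ",
         paste(intersect(core, associated), collapse = ", "))
  }
  if (!is.null(fva)) {
    zero <- fva$reaction[fva$vmin == 0 & fva$vmax == 0]
    dropped <- intersect(c(core, associated), zero)
    if (length(dropped)) {
      message("discarding ", length(dropped),
              " fitted reaction(s) with zero feasible range: ",
              paste(dropped, collapse = ", "))
      core <- setdiff(core, dropped)
      associated <- setdiff(associated, dropped)
    }
  }
  structure(list(CR = core, AR = associated,
                 RO = setdiff(all_r, c(core, associated))),
            class = "reaction_partition")
}

#' Average expression onto reactions
#'
#' For each reaction, the per-condition reaction expression is the arithmetic
#' mean of its mapped genes' log2 values (GPR boolean structure is
#' deliberately not evaluated). Genes absent from the matrix are dropped with
#' a warning; a reaction left with no measured gene is excluded (warning) and
#' listed in the `excluded` attribute. Per-reaction minima and maxima are
#' taken across all supplied conditions.
#'
#' @param expr Expression tibble (`gene` + one column per condition).
#' @param gpr GPR tibble from [read_gpr()].
#' @param rxns Reaction ids to summarize (typically CR and AR).
#' @return Tibble with columns `reaction`, `condition`, `gbar`, `gmin`,
#'   `gmax` (class `expression_summary`).
#' @export
summarize_expression <- function(expr, gpr, rxns) {
  if (length(rxns) == 0L) stop("empty reaction set")
  conds <- setdiff(names(expr), "gene")
  gpr_use <- gpr[gpr$reaction %in% rxns, , drop = FALSE]
  missing_rxn <- setdiff(rxns, gpr_use$reaction)
  if (length(missing_rxn)) {
    stop("no GPR entry for reaction(s): ", paste(missing_rxn, collapse = ", "))
  }
  rows <- list(); excluded <- character(); missing_genes <- character()
  for (i in seq_len(nrow(gpr_use))) {
    rid <- gpr_use$reaction[i]
    genes <- gpr_use$genes[[i]]
    have <- intersect(genes, expr$gene)
    missing_genes <- c(missing_genes, setdiff(genes, expr$gene))
    if (length(have) == 0L) {
      excluded <- c(excluded, rid)
      next
    }
    sub <- as.matrix(expr[match(have, expr$gene), conds, drop = FALSE])
    gbar <- colMeans(sub, na.rm = TRUE)
    if (any(!is.finite(gbar))) {
      excluded <- c(excluded, rid)
      next
    }
    rows[[rid]] <- tibble::tibble(
      reaction = rid, condition = conds, gbar = as.numeric(gbar),
      gmin = min(gbar), gmax = max(gbar)
    )
  }
  if (length(missing_genes)) {
    warning("gene(s) without expression data ignored: ",
            paste(unique(missing_genes), collapse = ", "))
  }
  if (length(excluded)) {
    warning("reaction(s) with no measured gene excluded from the fit: ",
            paste(excluded, collapse = ", "))
  }
  if (length(rows) == 0L) stop("no reaction could be summarized")
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- excluded
  class(out) <- c("expression_summary", class(out))
  out
}

#' Map reaction expression linearly onto feasible flux ranges
#'
#' The expression-derived target flux interpolates the reaction's feasible
#' range: `vfit = Vmin + (gbar - gmin) * (Vmax - Vmin) / (gmax - gmin)`,
#' so the condition with the lowest expression maps to `Vmin` and the highest
#' to `Vmax`. Degenerate expression ranges (`gmax == gmin`) map to the range
#' midpoint (logged per reaction); results are clamped to `[Vmin, Vmax]`
#' against floating-point round-off.
#'
#' @param summary An `expression_summary` from [summarize_expression()].
#' @param fva FVA bounds tibble (`reaction`, `vmin`, `vmax`).
#' @return Tibble of fit targets: `reaction`, `condition`, `vfit`, `vmin`,
#'   `vmax` (class `fit_targets`).
#' @export
map_expression_to_flux <- function(summary, fva) {
  missing_b <- setdiff(unique(summary$reaction), fva$reaction)
  if (length(missing_b)) {
    stop("no FVA bounds for reaction(s): ", paste(missing_b, collapse = ", "))
  }
  tab <- dplyr::left_join(
    tibble::as_tibble(summary),
    fva[c("reaction", "vmin", "vmax")],
    by = "reaction"
  )
  degen <- tab$gmax == tab$gmin
  if (any(degen)) {
    message("degenerate expression range for reaction(s) ",
            paste(unique(tab$reaction[degen]), collapse = ", "),
            "; using flux-range midpoint")
  }
  vfit <- ifelse(
    degen,
    (tab$vmin + tab$vmax) / 2,
    tab$vmin + (tab$gbar - tab$gmin) * (tab$vmax - tab$vmin) /
      (tab$gmax - tab$gmin)
  )
  out <- tibble::tibble(
    reaction = tab$reaction, condition = tab$condition,
    vfit = pmin(pmax(vfit, tab$vmin), tab$vmax),
    vmin = tab$vmin, vmax = tab$vmax
  )
  class(out) <- c("fit_targets", class(out))
  out
}

#' Residual weights for fitted reactions
#'
#' `Vweight = max(|Vmax|, |Vmin|)` from FVA; core reactions get
#' `w = 1 / Vweight` (equalizing reactions with small and large flux
#' variance) and associated reactions are down-weighted by the constant
#' `+100` in the denominator: `w = 1 / (Vweight + 100)`.
#'
#' @param fva FVA bounds tibble.
#' @param partition A `reaction_partition`.
#' @return Tibble `reaction`, `set` (`"CR"`/`"AR"`), `vweight`, `w`.
#' @export
compute_weights <- function(fva, partition) {
  fitted <- c(partition$CR, partition$AR)
  missing_b <- setdiff(fitted, fva$reaction)
  if (length(missing_b)) {
    stop("no FVA bounds for fitted reaction(s): ",
         paste(missing_b, collapse = ", "))
  }
  idx <- match(fitted, fva$reaction)
  vweight <- pmax(abs(fva$vmax[idx]), abs(fva$vmin[idx]))
  zero <- fitted[vweight == 0]
  if (length(zero)) {
    stop("zero flux range for fitted reaction(s) (discard upstream): ",
         paste(zero, collapse = ", "))
  }
  set <- ifelse(fitted %in% partition$CR, "CR", "AR")
  tibble::tibble(
    reaction = fitted, set = set, vweight = vweight,
    w = ifelse(set == "CR", 1 / vweight, 1 / (vweight + 100))
  )
}

#' Fit configuration
#'
#' @param weights Weight tibble from [compute_weights()].
#' @param alpha Nonnegative penalty strength on the summed absolute fluxes of
#'   non-fitted (RO) reactions; default `0.01`, the trade-off between a low
#'   mapping discrepancy and suppressed loop-carrying fluxes.
#' @return A `fit_config` list.
#' @export
fit_config <- function(weights, alpha = 0.01) {
  if (alpha < 0) stop("alpha must be nonnegative")
  if (any(weights$w <= 0)) stop("weights must be positive")
  structure(list(alpha = alpha, weights = weights), class = "fit_config")
}

# Build the per-condition L1 fit problem. Variables:
#   [v (+ cap auxiliaries) | e+ e- per target | p+ p- per RO | binaries per cut]
# Residual splits: v_ri - e+ + e- = vfit;  penalty splits: v_ro - p+ + p- = 0.
# Loop cuts (RED-TIL) add big-M indicator rows and a cardinality row each.
.build_fit_lp <- function(net, targets_c, partition, config, condition,
                          cuts = NULL) {
  base <- .base_lp(net, condition)
  n <- base$n
  tgt_idx <- match(targets_c$reaction, reactions(net))
  if (anyNA(tgt_idx)) stop("target for unknown reaction")
  w <- config$weights$w[match(targets_c$reaction, config$weights$reaction)]
  if (anyNA(w)) {
    stop("missing weight for reaction(s): ",
         paste(targets_c$reaction[is.na(w)], collapse = ", "))
  }
  ro <- if (config$alpha > 0) partition$RO else character()
  ro_idx <- match(ro, reactions(net))
  nt <- nrow(targets_c); nr <- length(ro)
  cut_bins <- if (length(cuts)) {
    lapply(cuts, function(cut) seq_along(cut$members))
  } else list()
  nb <- sum(lengths(cut_bins))
  ntot <- base$ntot + 2L * nt + 2L * nr + nb

  pad <- function(A) cbind(A, matrix(0, nrow = nrow(A), ncol = ntot - ncol(A)))
  A_eq <- pad(base$A_eq); b_eq <- base$b_eq
  if (nt > 0L) {
    rows <- matrix(0, nrow = nt, ncol = ntot)
    for (k in seq_len(nt)) {
      rows[k, tgt_idx[k]] <- 1
      rows[k, base$ntot + 2L * k - 1L] <- -1
      rows[k, base$ntot + 2L * k] <- 1
    }
    A_eq <- rbind(A_eq, rows); b_eq <- c(b_eq, targets_c$vfit)
  }
  if (nr > 0L) {
    rows <- matrix(0, nrow = nr, ncol = ntot)
    off <- base$ntot + 2L * nt
    for (k in seq_len(nr)) {
      rows[k, ro_idx[k]] <- 1
      rows[k, off + 2L * k - 1L] <- -1
      rows[k, off + 2L * k] <- 1
    }
    A_eq <- rbind(A_eq, rows); b_eq <- c(b_eq, rep(0, nr))
  }
  A_ub <- if (!is.null(base$A_ub)) pad(base$A_ub) else NULL
  b_ub <- base$b_ub
  integrality <- NULL
  if (nb > 0L) {
    integrality <- rep(0L, ntot)
    boff <- base$ntot + 2L * nt + 2L * nr
    b_at <- boff
    for (ci in seq_along(cuts)) {
      cut <- cuts[[ci]]
      k <- length(cut$members)
      mem_idx <- match(cut$members, reactions(net))
      rows <- matrix(0, nrow = k + 1L, ncol = ntot)
      rhs <- numeric(k + 1L)
      for (m in seq_len(k)) {
        jm <- mem_idx[m]
        M <- max(abs(net$lb[jm]), abs(net$ub[jm])) + 1
        # sign * v_m - M * inFC_m <= threshold * (1 - 1e-6)
        rows[m, jm] <- cut$sign[m]
        rows[m, b_at + m] <- -M
        rhs[m] <- cut$threshold * (1 - 1e-6)
        integrality[b_at + m] <- 1L
      }
      rows[k + 1L, b_at + seq_len(k)] <- 1    # sum inFC <= k - 1
      rhs[k + 1L] <- k - 1
      A_ub <- rbind(A_ub, rows); b_ub <- c(b_ub, rhs)
      b_at <- b_at + k
    }
  }
  obj <- c(rep(0, base$ntot),
           rep(w, each = 2L),
           rep(config$alpha, 2L * nr),
           rep(0, nb))
  lb <- c(base$lb, rep(0, 2L * nt + 2L * nr), rep(0, nb))
  ub <- c(base$ub, rep(Inf, 2L * nt + 2L * nr), rep(1, nb))
  list(problem = lp_problem(obj, lb, ub, A_eq = A_eq, b_eq = b_eq,
                            A_ub = A_ub, b_ub = b_ub,
                            integrality = integrality),
       n = n)
}

#' Solve the weighted L1 expression-to-flux fit
#'
#' Minimizes `sum_ri w_ri |v_ri - vfit_ri| + alpha * sum_ro |v_ro|` subject
#' to steady-state mass balance, flux bounds, the exchange cap and the
#' per-condition biomass floor, with every absolute value linearized through
#' split nonnegative auxiliaries. Conditions share no variables, so each is
#' solved as an independent LP (batched into one solver call).
#'
#' @param net A `metabolic_network` (with any caps/floors attached).
#' @param targets `fit_targets` tibble from [map_expression_to_flux()] (or
#'   hand-built with columns `reaction`, `condition`, `vfit`).
#' @param partition A `reaction_partition`.
#' @param config A `fit_config`.
#' @param conditions Conditions to solve (default: all in `targets`).
#' @param cuts Optional per-condition list of loop cuts (used by
#'   [run_redtil()]); adds binary indicator variables, making the problem a
#'   MILP.
#' @return An `lpm_fit` object: `fluxes` (long tibble), `residuals`,
#'   `by_condition` (status, objective, fit term, penalty sum, discrepancy),
#'   and the total mapping discrepancy `discrepancy`.
#' @export
solve_fit <- function(net, targets, partition, config,
                      conditions = unique(targets$condition), cuts = NULL) {
  stopifnot(inherits(config, "fit_config"))
  builds <- lapply(conditions, function(cond) {
    tc <- targets[targets$condition == cond, , drop = FALSE]
    .build_fit_lp(net, tc, partition, config, cond, cuts = cuts[[cond]])
  })
  res <- solve_lp_batch(lapply(builds, `[[`, "problem"))
  flux_rows <- list(); resid_rows <- list(); cond_rows <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[[i]]
    r <- res[[i]]
    if (!identical(r$status, "optimal")) {
      stop("fit ", r$status, " for condition '", cond, "'")
    }
    v <- stats::setNames(r$x[seq_len(builds[[i]]$n)], reactions(net))
    validate_solution(net, v)
    tc <- targets[targets$condition == cond, , drop = FALSE]
    resid <- abs(v[tc$reaction] - tc$vfit)
    w <- config$weights$w[match(tc$reaction, config$weights$reaction)]
    penalty_sum <- sum(abs(v[partition$RO]))
    flux_rows[[i]] <- tibble::tibble(reaction = reactions(net),
                                     condition = cond, flux = as.numeric(v))
    resid_rows[[i]] <- tibble::tibble(
      reaction = tc$reaction, condition = cond,
      flux = as.numeric(v[tc$reaction]), vfit = tc$vfit,
      w = w, residual = as.numeric(resid)
    )
    cond_rows[[i]] <- tibble::tibble(
      condition = cond, status = r$status, objective = r$objective,
      fit_term = sum(w * resid), penalty_sum = penalty_sum,
      discrepancy = sum(resid)
    )
  }
  by_condition <- dplyr::bind_rows(cond_rows)
  structure(
    list(
      fluxes = dplyr::bind_rows(flux_rows),
      residuals = dplyr::bind_rows(resid_rows),
      targets = targets, partition = partition, config = config,
      by_condition = by_condition,
      discrepancy = sum(by_condition$discrepancy),
      fit_term = sum(by_condition$fit_term),
      penalty_sum = sum(by_condition$penalty_sum)
    ),
    class = "lpm_fit"
  )
}

#' @export
print.lpm_fit <- function(x, ...) {
  cat("<lpm_fit> ", nrow(x$by_condition), " condition(s), alpha = ",
      x$config$alpha, "\n  total mapping discrepancy d = ",
      format(x$discrepancy), "\n", sep = "")
  invisible(x)
}

#' Total model mapping discrepancy
#'
#' The unweighted deviation `d = sum over fitted reactions and conditions of
#' |v - vfit|`, recomputed directly from a flux table and targets (it does
#' not reuse any value stored in a fit object).
#'
#' @param solutions An `lpm_fit`, `flux_solution`, or long flux tibble.
#' @param targets `fit_targets` tibble.
#' @return A `discrepancy_report`: `residuals` tibble, `by_condition`
#'   summary, and total `d`.
#' @export
total_discrepancy <- function(solutions, targets) {
  fluxes <- if (is.data.frame(solutions)) solutions else solutions$fluxes
  joined <- dplyr::inner_join(
    targets[c("reaction", "condition", "vfit")],
    fluxes[c("reaction", "condition", "flux")],
    by = c("reaction", "condition")
  )
  if (nrow(joined) != nrow(targets)) {
    stop("flux table does not cover all target (reaction, condition) pairs")
  }
  joined$residual <- abs(joined$flux - joined$vfit)
  by_condition <- dplyr::summarise(
    dplyr::group_by(joined, .data$condition),
    discrepancy = sum(.data$residual), .groups = "drop"
  )
  structure(list(residuals = tibble::as_tibble(joined),
                 by_condition = by_condition,
                 d = sum(joined$residual)),
            class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat("<discrepancy_report> d =", format(x$d), "over",
      nrow(x$residuals), "reaction x condition pairs\n")
  invisible(x)
}

#' Select associated reactions by differential expression
#'
#' Candidate reactions (already filtered by the caller for network adjacency
#' to the core set and participation of key metabolites) are kept when at
#' least one mapped gene is differentially expressed in at least one
#' condition versus the control: per-gene two-sample t-tests (condition
#' replicates vs control replicates), Benjamini-Hochberg correction pooled
#' across all genes and conditions, adjusted p below `fdr`.
#'
#' @param expr Replicate-level expression tibble (from
#'   `read_expression(average = FALSE)`), with a `"replicates"` attribute
#'   mapping condition -> replicate columns.
#' @param control Replicate-level expression tibble for the control medium;
#'   all non-gene columns are treated as control replicates.
#' @param candidates Candidate reaction ids.
#' @param gpr GPR tibble.
#' @param fdr Adjusted-p cutoff (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Character vector of selected reaction ids, with attribute
#'   `"tests"` (tibble gene, condition, p, p_adj).
#' @export
select_associated <- function(expr, control, candidates, gpr, fdr = 0.05,
                              var_equal = FALSE) {
  groups <- attr(expr, "replicates")
  if (is.null(groups)) {
    stop("expr lacks a 'replicates' attribute; read with average = FALSE")
  }
  ctrl_cols <- setdiff(names(control), "gene")
  if (length(ctrl_cols) < 2L) stop("control group has fewer than 2 replicates")
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small)) {
    stop("fewer than 2 replicates in condition(s): ",
         paste(small, collapse = ", "))
  }
  gpr_use <- gpr[gpr$reaction %in% candidates, , drop = FALSE]
  genes <- intersect(unique(unlist(gpr_use$genes)),
                     intersect(expr$gene, control$gene))
  if (length(genes) == 0L) stop("no candidate gene has expression data")
  tests <- list()
  for (g in genes) {
    ctrl_vals <- as.numeric(control[match(g, control$gene), ctrl_cols])
    for (cond in names(groups)) {
      vals <- as.numeric(expr[match(g, expr$gene), groups[[cond]]])
      p <- if (stats::sd(vals) == 0 && stats::sd(ctrl_vals) == 0) {
        if (mean(vals) == mean(ctrl_vals)) 1 else 0   # complete separation
      } else {
        stats::t.test(vals, ctrl_vals, var.equal = var_equal)$p.value
      }
      tests[[length(tests) + 1L]] <-
        tibble::tibble(gene = g, condition = cond, p = p)
    }
  }
  tests <- dplyr::bind_rows(tests)
  tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  sig_genes <- unique(tests$gene[tests$p_adj < fdr])
  keep <- vapply(seq_len(nrow(gpr_use)), function(i) {
    any(gpr_use$genes[[i]] %in% sig_genes)
  }, logical(1))
  out <- gpr_use$reaction[keep]
  attr(out, "tests") <- tests
  out
}
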