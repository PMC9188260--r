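#' Rank reactions by representative maximal FVA bound
#'
#' Each reaction's representative bound is `max(|Vmax|, |Vmin|)`; reactions
#' are sorted descending (the reaction with the highest value first). Ties
#' break lexicographically on the reaction id for determinism.
#'
#' @param fva FVA bounds tibble (`reaction`, `vmin`, `vmax`).
#' @return Character vector of reaction ids, ranked.
#' @export
rank_reactions <- function(fva) {
  if (nrow(fva) == 0L) stop("empty FVA table")
  rep_bound <- pmax(abs(fva$vmax), abs(fva$vmin))
  fva$reaction[order(-rep_bound, fva$reaction)]
}

#' Halve a feasible flux range
#'
#' Opposite-sign ranges have both endpoints halved; a range entirely at or
#' above zero has only `vmax` halved, entirely at or below zero only `vmin`
#' — always shrinking the range toward zero. If halving the moving endpoint
#' would cross the fixed one, it clamps there (the range cannot invert), and
#' `moved = FALSE` signals that iteration should stop for this reaction.
#'
#' @param vmin,vmax Current range endpoints (`vmin <= vmax`).
#' @return List `vmin`, `vmax`, `moved`.
#' @export
halve_bounds <- function(vmin, vmax) {
  stopifnot(vmin <= vmax)
  new_min <- vmin; new_max <- vmax
  if (vmin < 0 && vmax > 0) {
    new_min <- vmin / 2
    new_max <- vmax / 2
  } else if (vmin >= 0) {
    new_max <- max(vmax / 2, vmin)
  } else {
    new_min <- min(vmin / 2, vmax)
  }
  list(vmin = new_min, vmax = new_max,
       moved = (new_min != vmin) || (new_max != vmax))
}

#' Iterative feasible flux space reduction
#'
#' Starting from FVA-derived ranges, reactions are processed in
#' [rank_reactions()] order. For each, the range is halved, the
#' expression-to-flux targets are rebuilt with the shrunken range, and the
#' fit is re-solved; the halving is accepted only while the total model
#' mapping discrepancy strictly decreases, otherwise the previous range is
#' restored and the next reaction is taken. The run terminates early once
#' the discrepancy is stable (relative spread below `stability` across a
#' sliding window of `window` outer steps), or when the ranked list is
#' exhausted, or after `max_outer` outer steps. The accepted-step
#' discrepancy sequence is non-increasing by construction. The procedure is
#' fully deterministic. Intended for the training phase: the reduced bounds
#' are then reused at prediction time.
#'
#' @param net A `metabolic_network`.
#' @param summary `expression_summary` for the fitted reactions.
#' @param partition A `reaction_partition`.
#' @param config A `fit_config`.
#' @param fva Initial FVA bounds (default: computed for fitted reactions).
#' @param conditions Conditions to fit (default: all in `summary`).
#' @param max_outer Cap on outer (per-reaction) steps.
#' @param stability Relative-stability tolerance (default `1e-4`).
#' @param window Sliding-window length for the stability check (default 10).
#' @return An `lpm_iffpr` object: final `bounds` (with initial ranges),
#'   per-step `history`, `initial_d`, `final_d`, final `solution` and
#'   `targets`, and `stopped_early`.
#' @export
run_iffpr <- function(net, summary, partition, config, fva = NULL,
                      conditions = unique(summary$condition),
                      max_outer = Inf, stability = 1e-4, window = 10L) {
  fitted <- c(partition$CR, partition$AR)
  if (is.null(fva)) fva <- run_fva(net, fitted)
  fva <- fva[fva$reaction %in% fitted, , drop = FALSE]
  bounds <- tibble::tibble(
    reaction = fva$reaction,
    vmin0 = fva$vmin, vmax0 = fva$vmax,
    vmin = fva$vmin, vmax = fva$vmax
  )
  current_bounds <- function() {
    tibble::tibble(reaction = bounds$reaction,
                   vmin = bounds$vmin, vmax = bounds$vmax)
  }
  targets <- map_expression_to_flux(summary, current_bounds())
  fit <- solve_fit(net, targets, partition, config, conditions)
  d_prev <- fit$discrepancy
  initial_d <- d_prev
  ranked <- rank_reactions(fva)
  history <- list()
  d_window <- d_prev
  step <- 0L
  stopped_early <- FALSE
  processed <- 0L
  for (rid in ranked) {
    if (processed >= max_outer) break
    i <- match(rid, bounds$reaction)
    repeat {
      prop <- halve_bounds(bounds$vmin[i], bounds$vmax[i])
      if (!prop$moved) break
      old <- c(bounds$vmin[i], bounds$vmax[i])
      bounds$vmin[i] <- prop$vmin; bounds$vmax[i] <- prop$vmax
      new_targets <- map_expression_to_flux(summary, current_bounds())
      new_fit <- solve_fit(net, new_targets, partition, config, conditions)
      step <- step + 1L
      accepted <- new_fit$discrepancy < d_prev
      history[[step]] <- tibble::tibble(
        step = step, reaction = rid,
        vmin = prop$vmin, vmax = prop$vmax,
        d = new_fit$discrepancy, accepted = accepted
      )
      if (accepted) {
        d_prev <- new_fit$discrepancy
        targets <- new_targets
        fit <- new_fit
      } else {
        bounds$vmin[i] <- old[1L]; bounds$vmax[i] <- old[2L]   # revert
        break
      }
    }
    processed <- processed + 1L
    d_window <- c(d_window, d_prev)
    if (length(d_window) > window) {
      d_window <- d_window[(length(d_window) - window + 1L):length(d_window)]
      spread <- max(d_window) - min(d_window)
      if (spread <= stability * max(max(abs(d_window)), .Machine$double.eps)) {
        stopped_early <- TRUE
        break
      }
    }
  }
  structure(
    list(bounds = bounds,
         history = if (length(history)) dplyr::bind_rows(history) else
           tibble::tibble(step = integer(), reaction = character(),
                          vmin = numeric(), vmax = numeric(),
                          d = numeric(), accepted = logical()),
         initial_d = initial_d, final_d = d_prev,
         solution = fit, targets = targets,
         processed = processed, stopped_early = stopped_early),
    class = "lpm_iffpr"
  )
}

#' @export
print.lpm_iffpr <- function(x, ...) {
  red <- if (x$initial_d > 0) 100 * (1 - x$final_d / x$initial_d) else 0
  cat("<lpm_iffpr> ", x$processed, " reaction(s) processed, d: ",
      format(x$initial_d), " -> ", format(x$final_d),
      " (", sprintf("%.2f", red), "% reduction)",
      if (x$stopped_early) ", stopped early on stability" else "",
      "\n", sep = "")
  invisible(x)
}

#' Write the bounds-reduction history as TSV
#'
#' One row per halving attempt: step, reaction, proposed range, resulting
#' discrepancy, and whether the step was accepted — the input for
#' discrepancy-vs-iteration plots.
#'
#' @param iffpr An `lpm_iffpr`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_bounds_history <- function(iffpr, path) {
  readr::write_tsv(iffpr$history, path, progress = FALSE)
  invisible(path)
}
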