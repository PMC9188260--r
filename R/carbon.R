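#' Cross-condition z-scores of transporter uptake
#'
#' For each designated transporter, its per-condition uptake magnitude
#' `u = max(0, -v)` (exchange convention: uptake is negative flux) is
#' standardized across conditions: `z = (u - mean(u)) / sd(u)` with the
#' sample (n-1) SD. Standardizing per transporter makes transporters with
#' small flux differences comparable to ones with large differences.
#' Transporters with zero SD carry no signal; they are flagged, excluded
#' from ranking, and reported in the `excluded` attribute. Set
#' `use = "flux"` to z-score the signed flux instead of uptake magnitude.
#'
#' @param fluxes An `lpm_fit` (or long flux tibble with `reaction`,
#'   `condition`, `flux`).
#' @param transporters Exchange reaction ids of the candidate carbon
#'   sources.
#' @param use `"uptake"` (default) or `"flux"`.
#' @return Tibble `transporter`, `condition`, `value`, `z` (class
#'   `carbon_z`), with attribute `excluded`.
#' @export
zscore_transporters <- function(fluxes, transporters,
                                use = c("uptake", "flux")) {
  use <- match.arg(use)
  tab <- if (is.data.frame(fluxes)) fluxes else fluxes$fluxes
  tab <- tab[tab$reaction %in% transporters, , drop = FALSE]
  missing_t <- setdiff(transporters, unique(tab$reaction))
  if (length(missing_t)) {
    stop("transporter(s) not in the flux table: ",
         paste(missing_t, collapse = ", "))
  }
  conds <- unique(tab$condition)
  if (length(conds) < 2L) {
    stop("z-scores need at least 2 conditions (got ", length(conds), ")")
  }
  tab$value <- if (use == "uptake") pmax(0, -tab$flux) else tab$flux
  out <- dplyr::mutate(
    dplyr::group_by(tab, .data$reaction),
    z = (.data$value - mean(.data$value)) / stats::sd(.data$value)
  )
  out <- dplyr::ungroup(out)
  sd0 <- unique(out$reaction[!is.finite(out$z)])
  if (length(sd0)) {
    warning("transporter(s) with zero SD excluded from ranking: ",
            paste(sd0, collapse = ", "))
    out <- out[!out$reaction %in% sd0, , drop = FALSE]
  }
  res <- tibble::tibble(transporter = out$reaction,
                        condition = out$condition,
                        value = out$value, z = out$z)
  attr(res, "excluded") <- sd0
  class(res) <- c("carbon_z", class(res))
  res
}

#' Call primary and secondary carbon sources per condition
#'
#' Within each condition, transporters are ranked by z-score descending; the
#' top transporter is called the primary carbon source and the runner-up the
#' secondary. Exact ties break lexicographically on the transporter id and
#' are flagged.
#'
#' @param z A `carbon_z` tibble from [zscore_transporters()].
#' @return Tibble `condition`, `transporter`, `z`, `rank`, `call`
#'   (`"primary"`, `"secondary"` or `NA`), `tie` (class `carbon_call`).
#' @export
call_carbon_sources <- function(z) {
  out <- dplyr::group_modify(
    dplyr::group_by(tibble::as_tibble(z), .data$condition),
    function(df, key) {
      df <- df[order(-df$z, df$transporter), , drop = FALSE]
      df$rank <- seq_len(nrow(df))
      df$call <- NA_character_
      if (nrow(df) >= 1L) df$call[1L] <- "primary"
      if (nrow(df) >= 2L) df$call[2L] <- "secondary"
      df$tie <- duplicated(df$z) | duplicated(df$z, fromLast = TRUE)
      df
    }
  )
  out <- dplyr::ungroup(out)
  out <- out[c("condition", "transporter", "z", "rank", "call", "tie")]
  class(out) <- c("carbon_call", class(out))
  out
}

#' Write carbon-source calls as a JSON report
#'
#' `{condition: {primary, secondary, zscores: {...}, ties: [...]}}`.
#'
#' @param calls A `carbon_call` tibble.
#' @param path Output JSON.
#' @return `path`, invisibly.
#' @export
write_carbon_calls <- function(calls, path) {
  report <- lapply(split(calls, calls$condition), function(df) {
    list(
      primary = df$transporter[df$call %in% "primary"][1],
      secondary = if (any(df$call %in% "secondary")) {
        df$transporter[df$call %in% "secondary"][1]
      },
      zscores = as.list(stats::setNames(df$z, df$transporter)),
      ties = df$transporter[df$tie]
    )
  })
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Normalized prediction error
#'
#' The Euclidean distance between predicted and reference flux vectors,
#' divided by the magnitude of the reference:
#' `||predicted - reference|| / ||reference||`.
#'
#' @param predicted,reference Numeric vectors over the same reaction index.
#' @return Scalar error (0 for a perfect prediction, 1 for an all-zero one).
#' @export
normalized_error <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference have different lengths")
  }
  ref_norm <- sqrt(sum(reference^2))
  if (ref_norm == 0) stop("reference flux vector has zero norm")
  sqrt(sum((predicted - reference)^2)) / ref_norm
}

#' Pearson correlation between predicted and reference fluxes
#'
#' Standard Pearson r over paired values. A constant side (zero variance —
#' e.g. a reaction predicted to be zero in every condition) makes r
#' undefined; this is reported via `undefined = TRUE`, never coerced to 0.
#'
#' @param predicted,reference Numeric vectors (>= 3 pairs).
#' @return List `r`, `n`, `undefined`.
#' @export
correlation_eval <- function(predicted, reference) {
  ok <- is.finite(predicted) & is.finite(reference)
  predicted <- predicted[ok]; reference <- reference[ok]
  if (length(predicted) < 3L) stop("need at least 3 paired values")
  if (stats::sd(predicted) == 0 || stats::sd(reference) == 0) {
    return(list(r = NA_real_, n = length(predicted), undefined = TRUE))
  }
  list(r = stats::cor(predicted, reference),
       n = length(predicted), undefined = FALSE)
}

#' Per-condition evaluation metrics against reference fluxes
#'
#' Joins predictions and reference on (reaction, condition) and reports, per
#' condition, the Pearson correlation and the normalized error.
#'
#' @param predicted,reference Long flux tibbles (`reaction`, `condition`,
#'   `flux`).
#' @return Tibble `condition`, `n`, `r`, `normalized_error`.
#' @export
evaluate_predictions <- function(predicted, reference) {
  joined <- dplyr::inner_join(
    predicted, reference, by = c("reaction", "condition"),
    suffix = c("_pred", "_ref")
  )
  if (nrow(joined) == 0L) stop("no overlapping (reaction, condition) pairs")
  dplyr::summarise(
    dplyr::group_by(joined, .data$condition),
    n = dplyr::n(),
    r = if (stats::sd(.data$flux_pred) == 0 ||
            stats::sd(.data$flux_ref) == 0) NA_real_ else
      stats::cor(.data$flux_pred, .data$flux_ref),
    normalized_error = normalized_error(.data$flux_pred, .data$flux_ref),
    .groups = "drop"
  )
}
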