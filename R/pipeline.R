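#' Export a synthetic scenario as plain-text pipeline inputs
#'
#' Writes the network (TSV model dialect), expression matrix, GPR table,
#' core-reaction list, designated-transporter list and a ground-truth JSON
#' (planted fluxes plus the designated source per condition) into a
#' directory, ready for [run_pipeline()] or the command-line interface.
#'
#' @param scenario An `lpm_scenario` from [make_multicarbon_scenario()].
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    model = file.path(dir, "model.tsv"),
    expression = file.path(dir, "expression.tsv"),
    gpr = file.path(dir, "gpr.tsv"),
    core = file.path(dir, "core.txt"),
    transporters = file.path(dir, "transporters.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_model_tsv(scenario$net, paths$model)
  readr::write_tsv(scenario$expression, paths$expression, progress = FALSE)
  gpr_flat <- data.frame(
    reaction = scenario$gpr$reaction,
    genes = vapply(scenario$gpr$genes, paste, character(1), collapse = ";")
  )
  utils::write.table(gpr_flat, paths$gpr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(scenario$core, paths$core)
  writeLines(scenario$transporters, paths$transporters)
  jsonlite::write_json(
    list(designated = as.list(scenario$designated),
         seed = scenario$seed, noise_sd = scenario$noise_sd,
         planted = scenario$planted),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON key-value config. Recognized keys: `model`, `expression`,
#' `gpr`, `core`, `associated` (file paths); `alpha`, `exchange_cap`,
#' `til_threshold`, `fdr`, `seed` (scalars); `designated` (file of exchange
#' ids exempt from the cap and used for carbon calling); `carbon_uptake`,
#' `biomass_floors` (named maps); `iffpr` (logical), `iffpr_max_outer`,
#' `iffpr_stability`; `replicate_map` (named map condition -> columns).
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  base <- dirname(normalizePath(path))
  for (key in c("model", "expression", "gpr", "core", "associated",
                "designated")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      candidate <- file.path(base, cfg[[key]])
      if (file.exists(candidate)) cfg[[key]] <- candidate
    }
  }
  cfg
}

.read_id_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}

#' Run the full train-reduce-deloop-predict workflow
#'
#' Stages: read inputs; apply carbon-uptake bounds, exchange cap and biomass
#' floors; FVA over the fitted reactions; expression summarization and
#' linear mapping; L1 fit; iterative bound reduction (optional); iterative
#' loop removal; carbon-source calling by transporter z-scores. Every stage
#' output is a plain file so any stage can be inspected or re-entered; a
#' manifest records the configuration hash, seed and versions.
#'
#' @param config Config list or path (see [read_pipeline_config()]).
#' @param out_dir Artifact directory (created if missing).
#' @return Invisibly, a list with the artifact paths and the fitted objects
#'   (`fit`, `iffpr`, `redtil`, `calls`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (key in c("model", "expression", "gpr", "core")) {
    if (is.null(config[[key]])) stop("config lacks required key '", key, "'")
    if (!file.exists(config[[key]])) {
      stop("stage input missing: ", key, " file '", config[[key]], "'")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  set.seed(seed)

  net <- read_model(config$model)
  replicate_map <- config$replicate_map
  expr <- read_expression(config$expression, replicate_map = replicate_map)
  gpr <- read_gpr(config$gpr, net = net)
  core <- .read_id_list(config$core)
  associated <- if (!is.null(config$associated)) {
    .read_id_list(config$associated)
  } else character()
  designated <- if (!is.null(config$designated)) {
    .read_id_list(config$designated)
  } else character()

  if (!is.null(config$carbon_uptake)) {
    net <- configure_carbon_uptake_bounds(net, unlist(config$carbon_uptake))
  }
  if (!is.null(config$exchange_cap)) {
    net <- add_exchange_cap(net, designated, config$exchange_cap)
  }
  if (!is.null(config$biomass_floors)) {
    net <- add_biomass_floor(net, unlist(config$biomass_floors))
  }

  fitted <- c(core, associated)
  fva <- run_fva(net, fitted)
  partition <- reaction_partition(net, core, associated, fva = fva)
  weights <- compute_weights(fva, partition)
  fcfg <- fit_config(weights, alpha = config$alpha %||% 0.01)
  summary <- summarize_expression(expr, gpr,
                                  c(partition$CR, partition$AR))

  targets <- map_expression_to_flux(
    summary, fva[fva$reaction %in% c(partition$CR, partition$AR), ])
  fit <- solve_fit(net, targets, partition, fcfg)

  iffpr <- NULL
  if (isTRUE(config$iffpr %||% TRUE)) {
    iffpr <- run_iffpr(net, summary, partition, fcfg, fva = fva,
                       max_outer = config$iffpr_max_outer %||% Inf,
                       stability = config$iffpr_stability %||% 1e-4)
    targets <- iffpr$targets
  }

  redtil <- run_redtil(net, targets, partition, fcfg,
                       threshold = config$til_threshold %||% 0.01)
  final <- redtil$solution

  calls <- NULL
  if (length(designated) >= 1L) {
    z <- zscore_transporters(final, designated)
    calls <- call_carbon_sources(z)
  }

  paths <- list(fluxes = file.path(out_dir, "fluxes.tsv"))
  write_fluxes(final, paths$fluxes)
  if (!is.null(iffpr)) {
    paths$bounds_history <- file.path(out_dir, "bounds_history.tsv")
    write_bounds_history(iffpr, paths$bounds_history)
  }
  paths$cut_log <- file.path(out_dir, "cut_log.tsv")
  write_cut_log(redtil, paths$cut_log)
  if (!is.null(calls)) {
    paths$carbon_calls <- file.path(out_dir, "carbon_calls.json")
    write_carbon_calls(calls, paths$carbon_calls)
  }
  metrics <- dplyr::mutate(glance(final), stage = "final")
  if (!is.null(iffpr)) {
    metrics <- dplyr::bind_rows(
      metrics,
      dplyr::mutate(glance(iffpr$solution), stage = "post_iffpr"),
      dplyr::mutate(glance(fit), stage = "initial")
    )
  }
  paths$metrics <- file.path(out_dir, "metrics.tsv")
  readr::write_tsv(metrics, paths$metrics, progress = FALSE)

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = seed,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("lpmgem")),
    n_cuts = nrow(redtil$cut_log),
    discrepancy = final$discrepancy
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(paths = paths, fit = fit, iffpr = iffpr, redtil = redtil,
                 calls = calls, net = net, partition = partition,
                 config = config))
}
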