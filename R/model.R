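#' Construct a metabolic network
#'
#' The central container: a stoichiometric matrix `S` (rows = metabolites,
#' columns = reactions) with per-reaction flux bounds, reversibility and
#' exchange flags. Fluxes are in mmol/gDW/h by convention; exchange reactions
#' follow the COBRA sign convention (negative flux = uptake, positive =
#' secretion).
#'
#' @param S Numeric matrix with metabolite rownames and reaction colnames.
#' @param lb,ub Per-reaction lower/upper flux bounds.
#' @param reversible Logical per reaction; defaults to `lb < 0`.
#' @param is_exchange Logical per reaction; defaults to columns with exactly
#'   one nonzero coefficient (boundary reactions).
#' @param biomass Optional biomass reaction id.
#' @return An object of class `metabolic_network`.
#' @export
#' @examples
#' net <- make_path_network(3)
#' net
metabolic_network <- function(S, lb, ub, reversible = NULL,
                              is_exchange = NULL, biomass = NULL) {
  S <- as.matrix(S)
  n <- ncol(S)
  if (is.null(colnames(S)) || is.null(rownames(S))) {
    stop("S needs metabolite rownames and reaction colnames")
  }
  if (length(lb) != n || length(ub) != n) {
    stop("lb/ub length must equal the number of reactions")
  }
  bad <- which(lb > ub)
  if (length(bad)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(colnames(S)[bad], collapse = ", "))
  }
  if (is.null(reversible)) reversible <- lb < 0
  if (is.null(is_exchange)) is_exchange <- colSums(S != 0) == 1L
  stopifnot(length(reversible) == n, length(is_exchange) == n)
  incons <- which(reversible & lb >= 0)
  if (length(incons)) {
    warning("reaction(s) flagged reversible but lb >= 0: ",
            paste(colnames(S)[incons], collapse = ", "))
  }
  if (!is.null(biomass) && !biomass %in% colnames(S)) {
    stop("biomass reaction '", biomass, "' not in the network")
  }
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  names(lb) <- names(ub) <- colnames(S)
  structure(
    list(S = S, lb = lb, ub = ub,
         reversible = as.logical(reversible),
         is_exchange = as.logical(is_exchange),
         biomass = biomass),
    class = "metabolic_network"
  )
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", length(reactions(x)), " reactions, ",
      length(metabolites(x)), " metabolites (",
      sum(x$is_exchange), " exchange)\n", sep = "")
  if (!is.null(x$biomass)) cat("  biomass: ", x$biomass, "\n", sep = "")
  invisible(x)
}

#' Reaction and metabolite identifiers of a network
#' @param net A `metabolic_network`.
#' @return Character vector of ids, in network (file) order.
#' @export
reactions <- function(net) colnames(net$S)

#' @rdname reactions
#' @export
metabolites <- function(net) rownames(net$S)

#' Internal (non-exchange) reaction ids
#' @param net A `metabolic_network`.
#' @return Character vector.
#' @export
internal_reactions <- function(net) reactions(net)[!net$is_exchange]

# ---- toy TSV dialect --------------------------------------------------------

.parse_equation <- function(eq, id) {
  eq <- trimws(eq)
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, "<->|->")[[1L]]
  if (length(sides) > 2L) {
    stop("cannot parse equation for reaction '", id, "': ", eq)
  }
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side) {
    side <- trimws(side)
    if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
    coefs <- vapply(terms, function(term) {
      m <- regmatches(term, regexec("^([0-9]*\\.?[0-9]+)\\s+(.+)$", term))[[1L]]
      if (length(m) == 3L) as.numeric(m[[2L]]) else 1
    }, numeric(1))
    mets <- vapply(terms, function(term) {
      m <- regmatches(term, regexec("^([0-9]*\\.?[0-9]+)\\s+(.+)$", term))[[1L]]
      if (length(m) == 3L) m[[3L]] else term
    }, character(1))
    if (any(!nzchar(mets))) {
      stop("empty metabolite name in equation for reaction '", id, "'")
    }
    stats::setNames(coefs, mets)
  }
  list(lhs = parse_side(sides[[1L]]), rhs = parse_side(sides[[2L]]),
       reversible = rev)
}

.format_equation <- function(coefs, reversible) {
  fmt <- function(v) {
    if (length(v) == 0L) return("")
    paste(ifelse(v == 1, names(v), paste(format(v, trim = TRUE), names(v))),
          collapse = " + ")
  }
  lhs <- -coefs[coefs < 0]
  rhs <- coefs[coefs > 0]
  arrow <- if (reversible) "<->" else "->"
  paste(fmt(lhs), arrow, fmt(rhs))
}

read_model_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  need <- c("id", "equation", "lb", "ub", "reversible", "exchange")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("model TSV '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  parsed <- lapply(seq_len(nrow(tab)),
                   function(i) .parse_equation(tab$equation[i], tab$id[i]))
  mets <- unique(unlist(lapply(parsed, function(p) c(names(p$lhs), names(p$rhs)))))
  S <- matrix(0, nrow = length(mets), ncol = nrow(tab),
              dimnames = list(mets, tab$id))
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    S[names(p$lhs), i] <- S[names(p$lhs), i] - p$lhs
    S[names(p$rhs), i] <- S[names(p$rhs), i] + p$rhs
  }
  exch <- as.logical(tab$exchange)
  bad_exch <- which(exch & colSums(S != 0) != 1L)
  if (length(bad_exch)) {
    stop("exchange reaction(s) with more than one metabolite: ",
         paste(tab$id[bad_exch], collapse = ", "))
  }
  biomass <- if ("biomass" %in% names(tab) && any(as.logical(tab$biomass))) {
    tab$id[which(as.logical(tab$biomass))[1L]]
  }
  metabolic_network(S, tab$lb, tab$ub, reversible = as.logical(tab$reversible),
                    is_exchange = exch, biomass = biomass)
}

#' Write a network in the plain TSV model dialect
#'
#' One row per reaction with columns `id`, `equation` (e.g. `"A + 2 B -> C"`,
#' `<->` marks reversible), `lb`, `ub`, `reversible`, `exchange`, `biomass`.
#' Round-trips exactly through [read_model()].
#'
#' @param net A `metabolic_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(net, path) {
  eqs <- vapply(seq_along(reactions(net)), function(j) {
    col <- net$S[, j]
    .format_equation(col[col != 0], net$reversible[j])
  }, character(1))
  tab <- data.frame(
    id = reactions(net), equation = eqs,
    lb = net$lb, ub = net$ub,
    reversible = net$reversible, exchange = net$is_exchange,
    biomass = reactions(net) %in% (net$biomass %||% ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- BiGG-style JSON --------------------------------------------------------

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$reactions) || is.null(doc$metabolites)) {
    stop("JSON model '", path, "' lacks 'reactions' or 'metabolites'")
  }
  mets <- vapply(doc$metabolites, function(m) m$id, character(1))
  rxns <- vapply(doc$reactions, function(r) r$id, character(1))
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  lb <- ub <- numeric(length(rxns))
  obj_coef <- numeric(length(rxns))
  for (j in seq_along(doc$reactions)) {
    r <- doc$reactions[[j]]
    st <- r$metabolites
    if (length(st)) {
      unknown <- setdiff(names(st), mets)
      if (length(unknown)) {
        stop("reaction '", r$id, "' references unknown metabolite(s): ",
             paste(unknown, collapse = ", "))
      }
      S[names(st), j] <- vapply(st, as.numeric, numeric(1))
    }
    lb[j] <- as.numeric(r$lower_bound %||% -1000)
    ub[j] <- as.numeric(r$upper_bound %||% 1000)
    obj_coef[j] <- as.numeric(r$objective_coefficient %||% 0)
  }
  biomass <- if (any(obj_coef != 0)) rxns[which(obj_coef != 0)[1L]]
  metabolic_network(S, lb, ub, biomass = biomass)
}

# ---- SBML Level 3 + FBC -----------------------------------------------------

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  if (length(sp_nodes) == 0L) stop("SBML '", path, "' contains no species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  mets <- sp_id[!boundary]

  par_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (length(rx_nodes) == 0L) stop("SBML '", path, "' contains no reactions")
  rxns <- xml2::xml_attr(rx_nodes, "id")
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  lb <- rep(-1000, length(rxns)); ub <- rep(1000, length(rxns))
  rev_flag <- xml2::xml_attr(rx_nodes, "reversible") %in% "true"
  lookup_bound <- function(ref, default) {
    if (is.na(ref)) return(default)
    if (!ref %in% names(par_val)) {
      stop("flux bound parameter '", ref, "' not defined")
    }
    par_val[[ref]]
  }
  for (j in seq_along(rx_nodes)) {
    node <- rx_nodes[[j]]
    add_side <- function(xpath, sign) {
      refs <- xml2::xml_find_all(node, xpath)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        if (sp %in% mets) S[sp, j] <<- S[sp, j] + sign * coef
      }
    }
    add_side(".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']", -1)
    add_side(".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']", +1)
    lb[j] <- lookup_bound(xml2::xml_attr(node, "lowerFluxBound"),
                          if (rev_flag[j]) -1000 else 0)
    ub[j] <- lookup_bound(xml2::xml_attr(node, "upperFluxBound"), 1000)
  }
  fobj <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  biomass <- if (!inherits(fobj, "xml_missing")) {
    xml2::xml_attr(fobj, "reaction")
  }
  if (!is.null(biomass) && !biomass %in% rxns) biomass <- NULL
  metabolic_network(S, lb, ub, reversible = rev_flag, biomass = biomass)
}

#' Read a metabolic model
#'
#' Supports SBML Level 3 with the FBC bounds extension, BiGG-style JSON
#' (`reactions[]`/`metabolites[]` with `lower_bound`/`upper_bound`), and the
#' package's plain TSV dialect (see [write_model_tsv()]). Reaction and
#' metabolite order is file order, so repeated reads are identical.
#'
#' @param path Model file.
#' @param format `"sbml"`, `"json"`, `"tsv"`, or `"auto"` (by extension).
#' @return A [metabolic_network()].
#' @export
read_model <- function(path, format = c("auto", "tsv", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      tsv = "tsv", txt = "tsv", json = "json",
      xml = "sbml", sbml = "sbml",
      stop("cannot guess model format from extension '.", ext, "'")
    )
  }
  switch(format,
    tsv = read_model_tsv(path),
    json = read_model_json(path),
    sbml = read_model_sbml(path)
  )
}

# ---- expression & GPR -------------------------------------------------------

#' Read a gene-expression matrix
#'
#' Expects a TSV whose first column holds gene symbols and whose remaining
#' columns are numeric log2 expression values. Replicate columns of the same
#' condition are collapsed by their arithmetic mean when `replicate_map` is
#' given (`list(condA = c("a1", "a2"), ...)`) or, with `average = FALSE`,
#' kept and recorded in the `"replicates"` attribute for use by
#' [select_associated()].
#'
#' @param path Expression TSV.
#' @param replicate_map Optional named list mapping condition labels to
#'   replicate column names.
#' @param average Collapse replicates by mean (default `TRUE`).
#' @return A tibble with column `gene` plus one numeric column per condition
#'   (or per replicate when `average = FALSE`).
#' @export
read_expression <- function(path, replicate_map = NULL, average = TRUE) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE, na = c("", "NA"))
  names(tab)[1L] <- "gene"
  value_cols <- names(tab)[-1L]
  bad <- value_cols[!vapply(tab[value_cols], is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric expression column(s): ", paste(bad, collapse = ", "))
  }
  dup <- unique(tab$gene[duplicated(tab$gene)])
  if (length(dup)) {
    stop("duplicate gene rows: ", paste(dup, collapse = ", "))
  }
  all_na <- apply(is.na(tab[value_cols]), 1L, all)
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " gene(s) with no data: ",
            paste(utils::head(tab$gene[all_na], 5L), collapse = ", "))
    tab <- tab[!all_na, , drop = FALSE]
  }
  if (is.null(replicate_map)) {
    attr(tab, "replicates") <- stats::setNames(as.list(value_cols), value_cols)
    return(tab)
  }
  unknown <- setdiff(unlist(replicate_map), value_cols)
  if (length(unknown)) {
    stop("replicate_map names missing column(s): ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(names(replicate_map))) {
    stop("condition labels must be unique after replicate averaging")
  }
  if (!average) {
    attr(tab, "replicates") <- replicate_map
    return(tab)
  }
  out <- tibble::tibble(gene = tab$gene)
  for (cond in names(replicate_map)) {
    cols <- replicate_map[[cond]]
    out[[cond]] <- rowMeans(tab[cols], na.rm = TRUE)
    out[[cond]][is.nan(out[[cond]])] <- NA_real_
  }
  attr(out, "replicates") <- stats::setNames(as.list(names(replicate_map)),
                                             names(replicate_map))
  out
}

#' Read a gene-protein-reaction (GPR) mapping
#'
#' TSV with two columns: reaction id and a semicolon-separated gene list.
#'
#' @param path GPR TSV.
#' @param net Optional network; ids absent from it are reported with a
#'   warning (never silently dropped) and kept in the table.
#' @return Tibble with columns `reaction` and `genes` (list column).
#' @export
read_gpr <- function(path, net = NULL) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           sep = "\t")
  names(tab)[1:2] <- c("reaction", "genes")
  genes <- strsplit(tab$genes, ";", fixed = TRUE)
  genes <- lapply(genes, function(g) trimws(g[nzchar(trimws(g))]))
  empty <- vapply(genes, length, integer(1)) == 0L
  if (any(empty)) {
    stop("empty gene list for reaction(s): ",
         paste(tab$reaction[empty], collapse = ", "))
  }
  out <- tibble::tibble(reaction = tab$reaction, genes = genes)
  if (!is.null(net)) out <- validate_gpr(out, net)
  out
}

#' Check a GPR table against a network
#'
#' @param gpr Tibble as from [read_gpr()].
#' @param net A `metabolic_network`.
#' @return `gpr` with an `unresolved` attribute listing reaction ids that do
#'   not resolve in the network (also emitted as a warning).
#' @export
validate_gpr <- function(gpr, net) {
  unresolved <- setdiff(gpr$reaction, reactions(net))
  if (length(unresolved)) {
    warning("GPR reaction id(s) not in the network: ",
            paste(unresolved, collapse = ", "))
  }
  attr(gpr, "unresolved") <- unresolved
  gpr
}

# ---- flux tables ------------------------------------------------------------

#' Write predicted fluxes as a reaction x condition TSV
#'
#' @param solution A fit/flux object with a `fluxes` tibble
#'   (`reaction`, `condition`, `flux`) or such a tibble directly.
#' @param path Output TSV; full double precision, rows in network order.
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(solution, path) {
  fluxes <- if (is.data.frame(solution)) solution else solution$fluxes
  if (is.null(fluxes) || nrow(fluxes) == 0L) {
    stop("empty flux solution; nothing to write")
  }
  wide <- tidyr::pivot_wider(fluxes[c("reaction", "condition", "flux")],
                             names_from = "condition", values_from = "flux")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a flux table written by [write_fluxes()]
#'
#' @param path Flux TSV.
#' @return Long tibble with columns `reaction`, `condition`, `flux`.
#' @export
read_fluxes <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(wide)[1L] <- "reaction"
  tidyr::pivot_longer(wide, -"reaction", names_to = "condition",
                      values_to = "flux")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
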