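#' Construct a constraint-based metabolic model
#'
#' The container used throughout the package: a set of metabolites, a set of
#' bounded reactions, a gene list and a designated objective reaction. Together
#' with the steady-state assumption \eqn{S v = 0} these define the flux
#' polytope that FBA, FVA and flux sampling interrogate.
#'
#' @param metabolites data frame with columns `id`, `name`, `compartment` and
#'   optionally `formula`, `charge`. Ids must be unique and compartments
#'   non-empty.
#' @param reactions list of reactions as returned by [reaction()].
#' @param genes character vector of gene identifiers.
#' @param objective_id id of the objective reaction (must exist).
#' @param annotations free-form named list.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [reaction()], [load_model()], [stoichiometric_matrix()],
#'   [model_report()]
#' @export
metabolic_model <- function(metabolites, reactions, genes = character(),
                            objective_id, annotations = list()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  for (col in c("formula", "charge")) {
    if (is.null(metabolites[[col]])) {
      metabolites[[col]] <- rep(NA, nrow(metabolites))
    }
  }
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         genes = as.character(genes), objective_id = objective_id,
         annotations = annotations),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Construct a reaction
#'
#' @param id unique reaction identifier. Exchange reactions conventionally use
#'   the `EX_` prefix; lumped multi-step pathways the `LMPD_` prefix.
#' @param stoichiometry named numeric vector, metabolite id to signed
#'   coefficient (negative = consumed).
#' @param lower_bound,upper_bound flux bounds in mmol gDCW^-1 h^-1 (the growth
#'   reaction is in h^-1). Default to the community convention of +/-1000.
#' @param name human-readable name.
#' @param subsystem pathway tag used by [prune()].
#' @param gene_rule boolean gene-association expression (free-form string).
#' @param is_exchange,is_lumped flags; see [detect_exchanges()] for how the
#'   exchange flag is reconciled with the id prefix.
#' @return A list of class `model_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -1000,
                     upper_bound = 1000, name = id, subsystem = "",
                     gene_rule = "", is_exchange = NA, is_lumped = NA) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound")
  }
  if (is.na(is_exchange)) {
    is_exchange <- startsWith(id, "EX_") || length(stoichiometry) == 1L
  }
  if (is.na(is_lumped)) is_lumped <- startsWith(id, "LMPD_")
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 subsystem = subsystem, gene_rule = gene_rule,
                 is_exchange = is_exchange, is_lumped = is_lumped),
            class = "model_reaction")
}

#' Validate model integrity
#'
#' Checks id uniqueness, non-empty compartments, bound ordering, that every
#' stoichiometry entry resolves to a model metabolite, that exchange-flagged
#' reactions touch exactly one metabolite, and that the objective exists.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly. Errors list every offending id.
#' @export
validate_model <- function(model) {
  met_ids <- model$metabolites$id
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  if (any(!nzchar(model$metabolites$compartment))) {
    stop("metabolites with empty compartment: ",
         paste(met_ids[!nzchar(model$metabolites$compartment)],
               collapse = ", "))
  }
  dangling <- character()
  for (rx in model$reactions) {
    if (rx$lower_bound > rx$upper_bound) {
      stop("reaction '", rx$id, "': lower_bound > upper_bound")
    }
    miss <- setdiff(names(rx$stoichiometry), met_ids)
    if (length(miss)) dangling <- c(dangling, paste0(rx$id, " -> ", miss))
    if (isTRUE(rx$is_exchange) && length(rx$stoichiometry) != 1L) {
      stop("exchange reaction '", rx$id,
           "' must touch exactly one metabolite")
    }
  }
  if (length(dangling)) {
    stop("reactions reference unknown metabolites: ",
         paste(dangling, collapse = ", "))
  }
  if (length(model$reactions) &&
      !model$objective_id %in% rxn_ids) {
    stop("objective reaction '", model$objective_id, "' not in model")
  }
  invisible(model)
}

#' Identify exchange reactions
#'
#' An exchange reaction crosses the system boundary and touches exactly one
#' metabolite (uptake is negative flux by convention). Detection combines the
#' structural test (single metabolite) with the `EX_` id prefix; when the two
#' disagree the prefix wins and a message is emitted.
#'
#' @param model a `metabolic_model`.
#' @return Character vector of exchange reaction ids.
#' @export
detect_exchanges <- function(model, quiet = FALSE) {
  ids <- character()
  for (rx in model$reactions) {
    by_prefix <- startsWith(rx$id, "EX_")
    by_struct <- length(rx$stoichiometry) == 1L
    if (!quiet && by_prefix && !isTRUE(rx$is_exchange)) {
      message("exchange flag disagreement for '", rx$id,
              "': id prefix wins")
    }
    if (by_prefix || by_struct) ids <- c(ids, rx$id)
  }
  ids
}

reaction_ids <- function(model) names(model$reactions)

#' Stoichiometric matrix of a model
#'
#' Rows follow metabolite order, columns reaction order; entry `S[i, j]` is
#' the signed coefficient of metabolite `i` in reaction `j`. Under the
#' pseudo-steady-state assumption the net production and consumption of every
#' metabolite is zero, i.e. feasible fluxes satisfy `S %*% v == 0`.
#'
#' @param model a `metabolic_model`.
#' @param sparse return a `Matrix::sparseMatrix` (default) or a dense matrix.
#' @return The (n_metabolites x n_reactions) matrix with dimnames.
#' @export
stoichiometric_matrix <- function(model, sparse = TRUE) {
  met_ids <- model$metabolites$id
  rxn_ids <- reaction_ids(model)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    ii <- c(ii, match(names(st), met_ids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  if (sparse) S else as.matrix(S)
}

lower_bounds <- function(model) {
  vapply(model$reactions, `[[`, 0, "lower_bound")
}
upper_bounds <- function(model) {
  vapply(model$reactions, `[[`, 0, "upper_bound")
}

#' Structural report of a model
#'
#' Counts of reactions, metabolites and genes, plus exchanges, lumped
#' reactions and a per-subsystem tally; the summary customarily quoted for a
#' reconstruction (e.g. "652 reactions, 1552 metabolites, 1284 genes").
#'
#' @param model a `metabolic_model`.
#' @return A list of class `model_report` with fields `n_reactions`,
#'   `n_metabolites`, `n_genes`, `n_exchanges`, `n_lumped`, `subsystems`
#'   (named table).
#' @export
model_report <- function(model) {
  subs <- vapply(model$reactions, `[[`, "", "subsystem")
  structure(list(
    n_reactions = length(model$reactions),
    n_metabolites = nrow(model$metabolites),
    n_genes = length(model$genes),
    n_exchanges = sum(vapply(model$reactions, `[[`, NA, "is_exchange")),
    n_lumped = sum(vapply(model$reactions, `[[`, NA, "is_lumped")),
    subsystems = table(subs[nzchar(subs)])
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("%d reactions, %d metabolites, %d genes\n",
              x$n_reactions, x$n_metabolites, x$n_genes))
  cat(sprintf("exchanges: %d, lumped: %d\n", x$n_exchanges, x$n_lumped))
  if (length(x$subsystems)) {
    cat("subsystems:\n")
    for (s in names(x$subsystems)) {
      cat(sprintf("  %-24s %d\n", s, x$subsystems[[s]]))
    }
  }
  invisible(x)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d reactions, %d metabolites, %d genes; objective: %s\n",
              length(x$reactions), nrow(x$metabolites), length(x$genes),
              x$objective_id))
  invisible(x)
}

#' Write a model report as TSV
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_model_report <- function(model, path) {
  rep <- model_report(model)
  df <- data.frame(
    key = c("reactions", "metabolites", "genes", "exchanges", "lumped",
            paste0("subsystem:", names(rep$subsystems))),
    value = c(rep$n_reactions, rep$n_metabolites, rep$n_genes,
              rep$n_exchanges, rep$n_lumped, as.integer(rep$subsystems)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
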