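#' Find dead-end metabolites
#'
#' A dead-end metabolite is only produced or only consumed across all
#' reactions (a reversible reaction counts as both producer and consumer),
#' so at steady state every reaction touching it is forced to zero flux.
#' Metabolites touched by no reaction are reported as dead ends too.
#'
#' @param model a `metabolic_model`.
#' @return Character vector of metabolite ids.
#' @export
find_dead_end_metabolites <- function(model) {
  met_ids <- model$metabolites$id
  produced <- stats::setNames(logical(length(met_ids)), met_ids)
  consumed <- produced
  for (rx in model$reactions) {
    fwd <- rx$upper_bound > 1e-12
    rev <- rx$lower_bound < -1e-12
    if (!fwd && !rev) next
    st <- rx$stoichiometry
    pos <- names(st)[st > 0]
    neg <- names(st)[st < 0]
    if (fwd) { produced[pos] <- TRUE; consumed[neg] <- TRUE }
    if (rev) { produced[neg] <- TRUE; consumed[pos] <- TRUE }
  }
  met_ids[produced != consumed | (!produced & !consumed)]
}

#' Find blocked reactions
#'
#' Reactions that cannot carry flux in any steady state with all exchange
#' reactions open: their attainable flux minimum and maximum are both within
#' `tol` of zero. This is the flux-variability reading of "zero-flux
#' reactions".
#'
#' @param model a `metabolic_model` (must be feasible).
#' @param tol flux threshold, default 1e-9.
#' @param open_bound magnitude to which exchange bounds are opened.
#' @return Character vector of reaction ids.
#' @export
find_blocked_reactions <- function(model, tol = 1e-9, open_bound = 1000) {
  for (id in detect_exchanges(model, quiet = TRUE)) {
    model$reactions[[id]]$lower_bound <- -open_bound
    model$reactions[[id]]$upper_bound <- open_bound
  }
  S <- stoichiometric_matrix(model, sparse = FALSE)
  ids <- reaction_ids(model)
  lb <- lower_bounds(model)
  ub <- upper_bounds(model)
  feas <- lp_solve(numeric(length(ids)), S, numeric(nrow(S)), lb = lb,
                   ub = ub)
  if (feas$status != "optimal") stop("find_blocked_reactions: model ",
                                     feas$status)
  blocked <- character()
  for (j in seq_along(ids)) {
    cvec <- as.numeric(seq_along(ids) == j)
    hi <- lp_solve(cvec, S, numeric(nrow(S)), lb = lb, ub = ub)
    if (hi$status == "optimal" && abs(hi$objective) > tol) next
    lo <- lp_solve(cvec, S, numeric(nrow(S)), lb = lb, ub = ub,
                   maximize = FALSE)
    if (lo$status == "optimal" && abs(lo$objective) > tol) next
    blocked <- c(blocked, ids[j])
  }
  blocked
}

new_reduction_log <- function() {
  structure(list(passes = list()), class = "reduction_log")
}

log_pass <- function(log, action, removed_reactions = character(),
                     removed_metabolites = character(),
                     added_reactions = list(),
                     added_metabolites = character(),
                     dropped_precursors = character()) {
  log$passes[[length(log$passes) + 1L]] <- list(
    action = action, removed_reactions = removed_reactions,
    removed_metabolites = removed_metabolites,
    added_reactions = added_reactions,
    added_metabolites = added_metabolites,
    dropped_precursors = dropped_precursors)
  log
}

#' @export
print.reduction_log <- function(x, ...) {
  cat(sprintf("<reduction_log> %d passes\n", length(x$passes)))
  for (p in x$passes) {
    cat(sprintf("  %s: -%d rxns, -%d mets, +%d rxns\n", p$action,
                length(p$removed_reactions), length(p$removed_metabolites),
                length(p$added_reactions)))
  }
  invisible(x)
}

#' Replay a reduction log
#'
#' Applies the recorded passes to a model; by construction
#' `replay_reduction_log(input, log)` reproduces the reduced output exactly.
#'
#' @param model the input `metabolic_model`.
#' @param log a `reduction_log`.
#' @return The transformed model.
#' @export
replay_reduction_log <- function(model, log) {
  for (p in log$passes) {
    model <- remove_reactions(model, p$removed_reactions)
    if (length(p$removed_metabolites)) {
      keep <- !model$metabolites$id %in% p$removed_metabolites
      model$metabolites <- model$metabolites[keep, , drop = FALSE]
    }
    if (length(p$added_metabolites)) {
      model$metabolites <- rbind(
        model$metabolites,
        data.frame(id = p$added_metabolites, name = p$added_metabolites,
                   compartment = "c", formula = NA, charge = NA))
    }
    for (rx in p$added_reactions) {
      model$reactions[[rx$id]] <- rx
    }
    if (length(p$dropped_precursors)) {
      bid <- attr(log, "biomass_id") %||% model$objective_id
      st <- model$reactions[[bid]]$stoichiometry
      model$reactions[[bid]]$stoichiometry <-
        st[!names(st) %in% p$dropped_precursors]
    }
  }
  validate_model(model)
  model
}

remove_reactions <- function(model, ids) {
  if (!length(ids)) return(model)
  model$reactions <- model$reactions[!names(model$reactions) %in% ids]
  model
}

#' Prune a model to selected subsystems
#'
#' Keeps only reactions whose subsystem is in `keep_subsystems` (plus
#' `protected` reactions and the objective), then iteratively removes
#' dead-end metabolites, the reactions touching them, and blocked reactions
#' until a fixed point is reached; finally drops metabolites no reaction
#' references. Pruning a feasible model leaves it feasible, and pruning is
#' idempotent.
#'
#' @param model a `metabolic_model`.
#' @param keep_subsystems character set of subsystem tags to keep; reactions
#'   with an empty subsystem tag are always kept.
#' @param protected reaction ids never removed (objective always protected).
#' @param remove_blocked also remove FVA-blocked reactions each pass (default
#'   TRUE).
#' @return A list with `model` and `log` (a `reduction_log`).
#' @export
prune <- function(model, keep_subsystems, protected = character(),
                  remove_blocked = TRUE) {
  stopifnot(length(keep_subsystems) > 0)
  log <- new_reduction_log()
  subs <- vapply(model$reactions, `[[`, "", "subsystem")
  drop <- names(model$reactions)[nzchar(subs) &
                                   !subs %in% keep_subsystems &
                                   !names(model$reactions) %in% protected]
  if (model$objective_id %in% drop) {
    stop("pruning would remove the objective reaction '",
         model$objective_id, "'; keep its subsystem or protect it")
  }
  # past the subsystem filter the objective is shielded from the iterative
  # dead-end / blocked sweeps
  protected <- union(protected, model$objective_id)
  if (length(drop)) {
    model <- remove_reactions(model, drop)
    log <- log_pass(log, "subsystem_filter", removed_reactions = drop)
  }
  repeat {
    changed <- FALSE
    de <- find_dead_end_metabolites(model)
    if (length(de)) {
      touching <- names(model$reactions)[vapply(model$reactions, function(r)
        any(names(r$stoichiometry) %in% de), NA)]
      touching <- setdiff(touching, protected)
      orphan_mets <- de[!vapply(de, function(m)
        any(vapply(model$reactions[setdiff(names(model$reactions), touching)],
                   function(r) m %in% names(r$stoichiometry), NA)), NA)]
      if (length(touching) || length(orphan_mets)) {
        model <- remove_reactions(model, touching)
        keep <- !model$metabolites$id %in% orphan_mets
        model$metabolites <- model$metabolites[keep, , drop = FALSE]
        log <- log_pass(log, "dead_end_removal",
                        removed_reactions = touching,
                        removed_metabolites = orphan_mets)
        changed <- length(touching) > 0 || length(orphan_mets) > 0
      }
    }
    if (!changed && remove_blocked) {
      bl <- setdiff(find_blocked_reactions(model), protected)
      if (length(bl)) {
        model <- remove_reactions(model, bl)
        log <- log_pass(log, "blocked_removal", removed_reactions = bl)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  used <- unique(unlist(lapply(model$reactions, function(r)
    names(r$stoichiometry))))
  unused <- setdiff(model$metabolites$id, used)
  if (length(unused)) {
    model$metabolites <- model$metabolites[
      !model$metabolites$id %in% unused, , drop = FALSE]
    log <- log_pass(log, "unused_metabolites",
                    removed_metabolites = unused)
  }
  validate_model(model)
  list(model = model, log = log)
}

#' Add a lumped reaction
#'
#' Adds a single reaction summarizing a multi-step pathway's net
#' stoichiometry. Metabolites not yet in the model are auto-created (with a
#' warning); a reaction whose net stoichiometry cancels to nothing is
#' rejected.
#'
#' @param model a `metabolic_model`.
#' @param id new unique reaction id (conventionally `LMPD_`-prefixed).
#' @param stoichiometry named numeric vector (duplicate names are summed).
#' @param lower_bound,upper_bound flux bounds.
#' @param genes character vector of associated genes (appended to the model
#'   gene list; joined with `and` into the gene rule).
#' @param subsystem subsystem tag.
#' @return The extended model.
#' @export
add_lumped_reaction <- function(model, id, stoichiometry, lower_bound = 0,
                                upper_bound = 1000, genes = character(),
                                subsystem = "lumped") {
  if (id %in% reaction_ids(model)) stop("duplicate reaction id '", id, "'")
  st <- tapply(unname(stoichiometry), names(stoichiometry), sum)
  st <- stats::setNames(as.numeric(st), names(st))
  st <- st[abs(st) > 1e-12]
  if (!length(st)) stop("lumped reaction '", id,
                        "' is a null reaction (stoichiometry cancels)")
  new_mets <- setdiff(names(st), model$metabolites$id)
  if (length(new_mets)) {
    warning("lumped reaction '", id, "' creates metabolites: ",
            paste(new_mets, collapse = ", "))
    model$metabolites <- rbind(
      model$metabolites,
      data.frame(id = new_mets, name = new_mets, compartment = "c",
                 formula = NA, charge = NA))
  }
  rx <- reaction(id, st, lower_bound, upper_bound,
                 subsystem = subsystem,
                 gene_rule = paste(genes, collapse = " and "),
                 is_lumped = TRUE)
  model$reactions[[id]] <- rx
  model$genes <- union(model$genes, genes)
  validate_model(model)
  model
}

# maximum flux through a temporary sink for `met`; the temporary reaction
# never persists (the model copy is discarded)
max_sink_flux <- function(model, met) {
  sink_id <- ".tmp_sink"
  st <- stats::setNames(-1, met)
  model$reactions[[sink_id]] <- reaction(sink_id, st, 0, 1000,
                                         is_exchange = FALSE)
  sol <- fba(model, sink_id)
  if (sol$status != "optimal") return(NA_real_)
  sol$objective_value
}

#' Check producibility of biomass precursors
#'
#' For each substrate of the biomass reaction a temporary sink is added and
#' maximized; the precursor is producible iff the attainable sink flux
#' exceeds `tol`. The model is left untouched.
#'
#' @param model a `metabolic_model` (must be feasible).
#' @param biomass_id id of the biomass reaction.
#' @param tol producibility threshold, default 1e-9.
#' @return Named logical vector over the biomass substrates.
#' @export
check_biomass_precursors <- function(model, biomass_id, tol = 1e-9) {
  if (!biomass_id %in% reaction_ids(model)) {
    stop("biomass reaction '", biomass_id, "' not in model")
  }
  st <- model$reactions[[biomass_id]]$stoichiometry
  precursors <- names(st)[st < 0]
  flags <- vapply(precursors, function(m) {
    fx <- max_sink_flux(model, m)
    !is.na(fx) && fx > tol
  }, NA)
  stats::setNames(flags, precursors)
}

#' Drop unproducible precursors from the biomass reaction
#'
#' Removes the flagged precursors from the biomass stoichiometry. Remaining
#' coefficients are deliberately not renormalized: the carbon contribution of
#' dropped precursors is assumed negligible, so rescaling would distort the
#' growth yield more than the removal does.
#'
#' @param model a `metabolic_model`.
#' @param biomass_id biomass reaction id.
#' @param flags named logical vector from [check_biomass_precursors()]
#'   (`TRUE` = producible).
#' @return The model with a slimmed biomass reaction.
#' @export
drop_unproducible_precursors <- function(model, biomass_id, flags) {
  bad <- names(flags)[!flags]
  if (length(bad) == length(flags)) {
    stop("all biomass precursors are unproducible")
  }
  if (!length(bad)) return(model)
  st <- model$reactions[[biomass_id]]$stoichiometry
  model$reactions[[biomass_id]]$stoichiometry <-
    st[!(names(st) %in% bad & st < 0)]
  model
}

#' Greedy gap filling from a candidate reaction pool
#'
#' Repeatedly adds the pool reaction that newly enables the largest number of
#' currently unproducible target metabolites (producibility via temporary
#' sink maximization), breaking ties by pool order, until every target is
#' producible or no candidate helps. A greedy heuristic rather than an exact
#' minimal-addition MILP; adequate for curation-scale gaps.
#'
#' @param model a `metabolic_model`.
#' @param pool list of candidate [reaction()]s (or a model whose reactions
#'   serve as the pool).
#' @param targets metabolite ids that must become producible.
#' @param tol producibility threshold.
#' @return A list with `model` (extended), `added` (reaction ids in addition
#'   order) and `unproducible` (targets that remain out of reach; a warning
#'   lists them).
#' @export
gap_fill <- function(model, pool, targets, tol = 1e-9) {
  if (inherits(pool, "metabolic_model")) pool <- pool$reactions
  producible <- function(mod, met) {
    if (!met %in% mod$metabolites$id) return(FALSE)
    fx <- max_sink_flux(mod, met)
    !is.na(fx) && fx > tol
  }
  unmet <- Filter(function(m) !producible(model, m), targets)
  added <- character()
  pool_left <- pool
  while (length(unmet) && length(pool_left)) {
    gains <- vapply(pool_left, function(rx) {
      mod2 <- try_add_pool_reaction(model, rx)
      sum(vapply(unmet, function(m) producible(mod2, m), NA))
    }, 0L)
    if (max(gains) == 0L) break
    k <- which.max(gains)              # first maximum = pool-order tie-break
    rx <- pool_left[[k]]
    model <- try_add_pool_reaction(model, rx)
    added <- c(added, rx$id)
    pool_left <- pool_left[-k]
    unmet <- Filter(function(m) !producible(model, m), unmet)
  }
  if (length(unmet)) {
    warning("gap_fill: targets remain unproducible: ",
            paste(unlist(unmet), collapse = ", "))
  }
  list(model = model, added = added, unproducible = unlist(unmet))
}

try_add_pool_reaction <- function(model, rx) {
  new_mets <- setdiff(names(rx$stoichiometry), model$metabolites$id)
  if (length(new_mets)) {
    model$metabolites <- rbind(
      model$metabolites,
      data.frame(id = new_mets, name = new_mets, compartment = "c",
                 formula = NA, charge = NA))
  }
  model$reactions[[rx$id]] <- rx
  model
}

#' Detect thermodynamically infeasible cycles
#'
#' Closes every exchange reaction (bounds 0, 0) and looks for reactions that
#' can still carry flux: with no exchange with the environment, any nonzero
#' steady-state flux is a closed internal circulation violating the loop law.
#' Loop membership is grouped by the connected supports of circulations found
#' by pushing flux through each implicated reaction in the closed system.
#'
#' @param model a `metabolic_model`.
#' @param tol flux threshold.
#' @return A list of class `tic_report`: `loops` (list of reaction-id sets),
#'   `corrected` (empty here; populated by [correct_tics()]), `unresolved`.
#' @export
detect_tics <- function(model, tol = 1e-6) {
  closed <- model
  for (id in detect_exchanges(closed, quiet = TRUE)) {
    closed$reactions[[id]]$lower_bound <- 0
    closed$reactions[[id]]$upper_bound <- 0
  }
  S <- stoichiometric_matrix(closed, sparse = FALSE)
  ids <- reaction_ids(closed)
  lb <- lower_bounds(closed)
  ub <- upper_bounds(closed)
  zero <- numeric(nrow(S))
  members <- character()
  supports <- list()
  for (j in seq_along(ids)) {
    cvec <- as.numeric(seq_along(ids) == j)
    for (mx in c(TRUE, FALSE)) {
      sol <- lp_solve(cvec, S, zero, lb = lb, ub = ub, maximize = mx)
      if (sol$status == "optimal" && abs(sol$objective) > tol) {
        members <- union(members, ids[j])
        supports[[length(supports) + 1L]] <- ids[abs(sol$x) > tol]
        break
      }
    }
  }
  # merge overlapping circulation supports into loops
  loops <- list()
  for (sup in supports) {
    hit <- which(vapply(loops, function(l) length(intersect(l, sup)) > 0, NA))
    if (length(hit)) {
      merged <- sort(unique(c(unlist(loops[hit]), sup)))
      loops <- loops[-hit]
      loops[[length(loops) + 1L]] <- merged
    } else {
      loops[[length(loops) + 1L]] <- sort(sup)
    }
  }
  structure(list(loops = loops,
                 corrected = data.frame(reaction_id = character(),
                                        old_lb = numeric(),
                                        old_ub = numeric(),
                                        new_lb = numeric(),
                                        new_ub = numeric()),
                 unresolved = character()),
            class = "tic_report")
}

#' @export
print.tic_report <- function(x, ...) {
  cat(sprintf("<tic_report> %d loop(s)\n", length(x$loops)))
  for (l in x$loops) cat("  loop:", paste(l, collapse = ", "), "\n")
  if (nrow(x$corrected)) {
    cat("corrected:", paste(x$corrected$reaction_id, collapse = ", "), "\n")
  }
  if (length(x$unresolved)) {
    cat("unresolved:", paste(x$unresolved, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a Gibbs-energy evidence table
#'
#' CSV with columns `reaction_id`, `dg_kj_mol` and optionally `uncertainty`
#' (kJ/mol), e.g. exported from a thermodynamic estimation database.
#'
#' @param path CSV file.
#' @return A data frame.
#' @export
read_evidence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "dg_kj_mol") %in% names(df)))
  if (any(!is.finite(df$dg_kj_mol))) stop("non-finite Gibbs energies")
  df
}

#' Correct TICs by Gibbs-energy directionality restriction
#'
#' Loop members whose estimated standard Gibbs energy change is decisively
#' negative (`dg < -dg_threshold` kJ/mol) are restricted to the forward
#' direction (lower bound raised to 0); decisively positive ones to the
#' reverse direction (upper bound lowered to 0). Members inside the dead band
#' `[-dg_threshold, dg_threshold]`, or without evidence, are left untouched
#' and listed as unresolved. A correction that would make the model
#' infeasible is reverted and its reaction marked unresolved. Detection is
#' re-run afterwards and residual loops recorded.
#'
#' @param model a `metabolic_model`.
#' @param report a `tic_report` from [detect_tics()].
#' @param evidence data frame `reaction_id`, `dg_kj_mol` (see
#'   [read_evidence()]) or a named numeric vector.
#' @param dg_threshold dead-band half-width in kJ/mol (default 5, on the
#'   order of typical estimation uncertainties).
#' @return A list with `model` (corrected) and `report` (updated
#'   `tic_report` with `corrected`, `unresolved` and residual `loops`).
#' @export
correct_tics <- function(model, report, evidence, dg_threshold = 5) {
  if (is.data.frame(evidence)) {
    dg <- stats::setNames(evidence$dg_kj_mol, evidence$reaction_id)
  } else {
    dg <- evidence
  }
  corrected <- report$corrected
  unresolved <- character()
  for (loop in report$loops) {
    for (rid in loop) {
      if (!rid %in% names(dg)) {
        unresolved <- union(unresolved, rid)
        next
      }
      g <- dg[[rid]]
      rx <- model$reactions[[rid]]
      old <- c(rx$lower_bound, rx$upper_bound)
      if (g < -dg_threshold && rx$lower_bound < 0) {
        model$reactions[[rid]]$lower_bound <- 0
      } else if (g > dg_threshold && rx$upper_bound > 0) {
        model$reactions[[rid]]$upper_bound <- 0
      } else {
        if (abs(g) <= dg_threshold) unresolved <- union(unresolved, rid)
        next
      }
      chk <- fba(model)
      if (chk$status != "optimal") {
        model$reactions[[rid]]$lower_bound <- old[1]
        model$reactions[[rid]]$upper_bound <- old[2]
        unresolved <- union(unresolved, rid)
        next
      }
      corrected <- rbind(corrected, data.frame(
        reaction_id = rid, old_lb = old[1], old_ub = old[2],
        new_lb = model$reactions[[rid]]$lower_bound,
        new_ub = model$reactions[[rid]]$upper_bound))
    }
  }
  post <- detect_tics(model)
  out <- structure(list(loops = post$loops, corrected = corrected,
                        unresolved = unresolved),
                   class = "tic_report")
  list(model = model, report = out)
}
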