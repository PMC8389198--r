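#' Flux balance analysis
#'
#' Solves the FBA linear program: optimize the flux through one reaction
#' subject to steady-state mass balance `S v = 0` and the flux bounds. The
#' returned solution carries the dual information: per-metabolite shadow
#' prices and per-reaction reduced costs.
#'
#' Shadow-price convention: the reported value is the sensitivity of the
#' optimum to relaxing the metabolite's mass balance, signed so that the
#' standard interpretation rules apply literally — (i) negative: the
#' metabolite limits the objective (a free external supply would raise it);
#' (ii) zero: the objective is insensitive to it; (iii) positive: the
#' metabolite is in surplus at the optimum. `raw_duals` carries the solver's
#' unmodified row duals (d objective / d rhs), which under this package's LP
#' core coincide with the reported convention; the field exists so that the
#' provenance of the sign is explicit when comparing with solvers that report
#' the opposite sign. Shadow prices at degenerate optima are
#' solver-dependent; interpret them only at non-degenerate solutions.
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction to optimize (default: the model objective).
#' @param sense `"max"` (default) or `"min"`.
#' @return A `flux_solution`: list with `status`, `objective_value`, `fluxes`
#'   (named), `shadow_prices` (named, by metabolite), `reduced_costs`
#'   (named), `raw_duals`, `dual_objective`.
#' @examples
#' toy <- generate_toy_network(toy_network_config())
#' sol <- fba(toy$model)
#' sol$objective_value
#' @export
fba <- function(model, objective_id = model$objective_id,
                sense = c("max", "min")) {
  sense <- match.arg(sense)
  S <- stoichiometric_matrix(model, sparse = FALSE)
  ids <- reaction_ids(model)
  cvec <- as.numeric(ids == objective_id)
  if (!any(cvec == 1)) stop("objective reaction '", objective_id,
                            "' not in model")
  res <- lp_solve(cvec, S, rhs = numeric(nrow(S)),
                  lb = lower_bounds(model), ub = upper_bounds(model),
                  maximize = sense == "max")
  as_flux_solution(res, ids, model$metabolites$id)
}

as_flux_solution <- function(res, rxn_ids, met_ids) {
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective_value = NA_real_,
                          fluxes = NULL, shadow_prices = NULL,
                          reduced_costs = NULL, raw_duals = NULL,
                          dual_objective = NA_real_),
                     class = "flux_solution"))
  }
  structure(list(
    status = "optimal",
    objective_value = res$objective,
    fluxes = stats::setNames(res$x[seq_along(rxn_ids)], rxn_ids),
    shadow_prices = stats::setNames(res$y, met_ids),
    reduced_costs = stats::setNames(res$reduced_costs[seq_along(rxn_ids)],
                                    rxn_ids),
    raw_duals = stats::setNames(res$y, met_ids),
    dual_objective = res$dual_objective),
    class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", objective: %.6g", x$objective_value))
  }
  cat("\n")
  invisible(x)
}

#' Two-step FBA: objective maximization then L1-norm minimization
#'
#' Step 1 maximizes the objective flux (plain [fba()]), giving the optimum
#' `Z*`. Step 2 fixes the objective at `Z*` and minimizes the Manhattan norm
#' `sum(|v|)` of the whole flux vector via the split-variable reformulation
#' `v = v+ - v-`, `v+, v- >= 0`, which removes thermodynamically implausible
#' futile flux and selects a parsimonious representative among the alternate
#' optima. The reported fluxes are the step-2 optimum; the reported shadow
#' prices are the step-1 duals, because the sensitivity of interest is that
#' of the production objective, not of the norm (`shadow_price_step` switches
#' this).
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction to maximize.
#' @param include_exchanges include exchange reactions in the norm (default
#'   TRUE: the norm covers the whole flux vector; exchanges are typically
#'   pinned by scenario bounds so their inclusion is harmless).
#' @param shadow_price_step `1` (default) or `2`: which LP's duals to report.
#' @return A `flux_solution` with extra fields `total_flux` (`sum(|v|)` of
#'   the returned fluxes) and `step1_objective`.
#' @export
two_step_fba <- function(model, objective_id = model$objective_id,
                         include_exchanges = TRUE, shadow_price_step = 1) {
  step1 <- fba(model, objective_id)
  if (step1$status != "optimal") return(step1)
  zstar <- step1$objective_value

  S <- stoichiometric_matrix(model, sparse = FALSE)
  ids <- reaction_ids(model)
  n <- length(ids)
  m <- nrow(S)
  lb <- lower_bounds(model)
  ub <- upper_bounds(model)
  cobj <- as.numeric(ids == objective_id)

  # split variables: columns 1..n are v+, n+1..2n are v-
  A2 <- rbind(cbind(S, -S), c(cobj, -cobj))
  lb2 <- c(pmax(0, lb), pmax(0, -ub))
  ub2 <- c(pmax(0, ub), pmax(0, -lb))
  cost <- rep(1, 2 * n)
  if (!include_exchanges) {
    ex <- ids %in% detect_exchanges(model, quiet = TRUE)
    cost[c(ex, ex)] <- 0
  }
  solve2 <- function(z) {
    lp_solve(cost, A2, rhs = c(numeric(m), z), lb = lb2, ub = ub2,
             maximize = FALSE)
  }
  res2 <- solve2(zstar)
  if (res2$status != "optimal") {
    message("step-2 LP infeasible at Z* = ", format(zstar),
            "; retrying with Z*(1 - 1e-9)")
    res2 <- solve2(zstar * (1 - 1e-9))
    if (res2$status != "optimal") {
      stop("two_step_fba: norm-minimization step ", res2$status)
    }
  }
  v <- res2$x[seq_len(n)] - res2$x[n + seq_len(n)]
  out <- step1
  out$fluxes <- stats::setNames(v, ids)
  out$total_flux <- sum(abs(v))
  out$step1_objective <- zstar
  if (shadow_price_step == 2) {
    y2 <- res2$y[seq_len(m)]
    out$shadow_prices <- stats::setNames(y2, model$metabolites$id)
    out$raw_duals <- out$shadow_prices
  }
  out
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' objective stays at or above `fraction_of_optimum` times its maximum: two
#' LPs per reaction. The spanned interval is the flux range drawn as whiskers
#' in flux-map figures.
#'
#' @param model a `metabolic_model`.
#' @param fraction_of_optimum required fraction of the FBA optimum in
#'   `[0, 1]`; default 1.
#' @param reactions reaction ids to analyse (default all).
#' @param objective_id objective reaction.
#' @param big_M value reported (with a warning) for an unbounded direction.
#' @return A data frame `reaction_id`, `min`, `max`.
#' @export
fva <- function(model, fraction_of_optimum = 1, reactions = NULL,
                objective_id = model$objective_id, big_M = 1000) {
  ids <- reaction_ids(model)
  if (is.null(reactions)) reactions <- ids
  stopifnot(all(reactions %in% ids))
  base <- fba(model, objective_id)
  if (base$status != "optimal") {
    stop("fva: base FBA ", base$status)
  }
  S <- stoichiometric_matrix(model, sparse = FALSE)
  cobj <- as.numeric(ids == objective_id)
  A <- rbind(S, cobj)
  rhs <- c(numeric(nrow(S)), fraction_of_optimum * base$objective_value)
  dir <- c(rep("=", nrow(S)), ">=")
  lb <- lower_bounds(model)
  ub <- upper_bounds(model)
  res <- lapply(reactions, function(rid) {
    cvec <- as.numeric(ids == rid)
    lo <- lp_solve(cvec, A, rhs, dir, lb, ub, maximize = FALSE)
    hi <- lp_solve(cvec, A, rhs, dir, lb, ub, maximize = TRUE)
    vmin <- lo$objective; vmax <- hi$objective
    if (lo$status == "unbounded") {
      warning("fva: '", rid, "' unbounded below; reporting -big_M")
      vmin <- -big_M
    }
    if (hi$status == "unbounded") {
      warning("fva: '", rid, "' unbounded above; reporting +big_M")
      vmax <- big_M
    }
    c(vmin, vmax)
  })
  out <- do.call(rbind, res)
  data.frame(reaction_id = reactions, min = out[, 1], max = out[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Define an experimental scenario
#'
#' A scenario is a set of measured rates applied to the model to emulate one
#' cultivation phase: the growth rate is a hard constraint (both bounds), each
#' measured uptake rate (negative by convention) becomes the lower bound of
#' its exchange reaction, and each measured secretion rate (non-negative) the
#' upper bound — the soft-constraint convention of chemostat/fed-batch flux
#' studies.
#'
#' @param name scenario label.
#' @param growth_rate measured growth rate in h^-1 (hard constraint); `NA`
#'   leaves growth unconstrained.
#' @param lower_bounded named list/vector: exchange id -> measured uptake
#'   (values must be <= 0).
#' @param upper_bounded named list/vector: exchange id -> measured secretion
#'   (values must be >= 0).
#' @param objective_id objective used when simulating the scenario.
#' @param growth_id id of the growth reaction.
#' @return A list of class `scenario`.
#' @export
scenario <- function(name, growth_rate = NA_real_, lower_bounded = list(),
                     upper_bounded = list(), objective_id = NULL,
                     growth_id = "GROWTH") {
  lower_bounded <- unlist(lower_bounded)
  upper_bounded <- unlist(upper_bounded)
  if (length(lower_bounded) && any(lower_bounded > 1e-12)) {
    stop("scenario '", name, "': uptake (lower_bounded) entries must be <= 0")
  }
  if (length(upper_bounded) && any(upper_bounded < -1e-12)) {
    stop("scenario '", name,
         "': secretion (upper_bounded) entries must be >= 0")
  }
  structure(list(name = name, growth_rate = growth_rate,
                 lower_bounded = lower_bounded, upper_bounded = upper_bounded,
                 objective_id = objective_id, growth_id = growth_id),
            class = "scenario")
}

#' Apply a scenario's constraints to a model
#'
#' Growth bounds are both set to the measured growth rate; measured uptakes
#' replace lower bounds (upper bounds untouched) and measured secretions
#' replace upper bounds (lower bounds untouched).
#'
#' @param model a `metabolic_model`.
#' @param sc a [scenario()].
#' @return The constrained model. Errors if a replacement would leave
#'   `lower_bound > upper_bound`, naming the reaction.
#' @export
apply_scenario <- function(model, sc) {
  stopifnot(inherits(sc, "scenario"))
  ids <- reaction_ids(model)
  need <- c(if (!is.na(sc$growth_rate)) sc$growth_id,
            names(sc$lower_bounded), names(sc$upper_bounded))
  miss <- setdiff(need, ids)
  if (length(miss)) stop("scenario references unknown reactions: ",
                         paste(miss, collapse = ", "))
  if (!is.na(sc$growth_rate)) {
    gr <- model$reactions[[sc$growth_id]]
    model$reactions[[sc$growth_id]]$lower_bound <- sc$growth_rate
    model$reactions[[sc$growth_id]]$upper_bound <- sc$growth_rate
  }
  for (id in names(sc$lower_bounded)) {
    model$reactions[[id]]$lower_bound <- unname(sc$lower_bounded[[id]])
  }
  for (id in names(sc$upper_bounded)) {
    model$reactions[[id]]$upper_bound <- unname(sc$upper_bounded[[id]])
  }
  for (id in need) {
    rx <- model$reactions[[id]]
    if (rx$lower_bound > rx$upper_bound + 1e-12) {
      stop("scenario '", sc$name, "' makes bounds contradictory for '", id,
           "' (", rx$lower_bound, " > ", rx$upper_bound, ")")
    }
  }
  if (!is.null(sc$objective_id)) model$objective_id <- sc$objective_id
  model
}

#' Read / write a scenario as CSV
#'
#' Columns: `reaction_id`, `value`, `role` with role one of `hard_growth`,
#' `lower`, `upper`.
#'
#' @param path CSV file.
#' @param name scenario label (default: file name).
#' @param objective_id,growth_id passed to [scenario()]; `growth_id` defaults
#'   to the `hard_growth` row's reaction.
#' @return A [scenario()].
#' @export
read_scenario <- function(path, name = basename(path), objective_id = NULL,
                          growth_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "value", "role") %in% names(df)))
  bad <- setdiff(df$role, c("hard_growth", "lower", "upper"))
  if (length(bad)) stop("unknown scenario roles: ", paste(bad, collapse = ", "))
  g <- df[df$role == "hard_growth", ]
  scenario(name = name,
           growth_rate = if (nrow(g)) g$value[1] else NA_real_,
           lower_bounded = stats::setNames(
             as.list(df$value[df$role == "lower"]),
             df$reaction_id[df$role == "lower"]),
           upper_bounded = stats::setNames(
             as.list(df$value[df$role == "upper"]),
             df$reaction_id[df$role == "upper"]),
           objective_id = objective_id,
           growth_id = growth_id %||% (if (nrow(g)) g$reaction_id[1]
                                       else "GROWTH"))
}

#' @rdname read_scenario
#' @param sc a [scenario()] to write.
#' @export
write_scenario <- function(sc, path) {
  df <- rbind(
    if (!is.na(sc$growth_rate))
      data.frame(reaction_id = sc$growth_id, value = sc$growth_rate,
                 role = "hard_growth"),
    if (length(sc$lower_bounded))
      data.frame(reaction_id = names(sc$lower_bounded),
                 value = unname(sc$lower_bounded), role = "lower"),
    if (length(sc$upper_bounded))
      data.frame(reaction_id = names(sc$upper_bounded),
                 value = unname(sc$upper_bounded), role = "upper"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a flux solution as TSV
#'
#' Two tables separated by a blank line: reaction fluxes with reduced costs,
#' then metabolite shadow prices.
#'
#' @param sol a `flux_solution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flux_solution <- function(sol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  rx <- data.frame(reaction = names(sol$fluxes), flux = unname(sol$fluxes),
                   reduced_cost = unname(sol$reduced_costs))
  utils::write.table(rx, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("", con)
  met <- data.frame(metabolite = names(sol$shadow_prices),
                    shadow_price = unname(sol$shadow_prices))
  utils::write.table(met, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
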