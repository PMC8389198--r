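#' Configuration for the synthetic toy network generator
#'
#' The generator emulates, at miniature scale, the topology of a reduced
#' central-carbon + secondary-metabolite network: a glycolysis-like linear
#' chain feeding a C3 node, a TCA-like cycle with a glyoxylate-shunt analog,
#' an anaplerotic carboxylation, and a two-precursor secondary-metabolite
#' branch in which a C3 intermediate condenses with a C5 amino acid to yield
#' the product while releasing a succinate analog (the arrangement of the
#' clavulanic-acid pathway, where glyceraldehyde-3-phosphate condenses with
#' arginine and clavaminate-synthase steps release succinate). Optional
#' injections with recorded ground truth: a thermodynamically infeasible
#' 2-reaction loop, dead-end metabolites, an unreachable 3-reaction branch,
#' extra parallel routes, and a prunable "minor" subsystem.
#'
#' @param include_tic add two parallel reversible reactions forming a closed
#'   loop that carries flux without any exchange (a TIC).
#' @param include_dead_ends number of injected dead-end metabolites.
#' @param include_unreachable_branch add a 3-reaction branch rooted in a
#'   metabolite nothing produces (all three are blocked).
#' @param include_minor_subsystem add a 4-reaction side pathway tagged
#'   `"minor"`, removable by [prune()].
#' @param n_parallel_routes number of routes from the carbon source to the C3
#'   node; routes beyond the first take two steps instead of one, so the
#'   L1-norm minimization of [two_step_fba()] prefers the direct route.
#' @param randomize_bounds draw random finite caps for the internal reactions
#'   and a random uptake bound (for oracle stress tests). The analytic optimum
#'   in the ground truth is only recorded when this is `FALSE`.
#' @param seed integer seed used when `randomize_bounds = TRUE`.
#' @param bound_scale multiplies the default carbon-source uptake bound of 10
#'   mmol gDCW^-1 h^-1.
#' @return A list of class `toy_network_config`.
#' @export
toy_network_config <- function(include_tic = FALSE, include_dead_ends = 0L,
                               include_unreachable_branch = FALSE,
                               include_minor_subsystem = FALSE,
                               n_parallel_routes = 1L,
                               randomize_bounds = FALSE, seed = 1L,
                               bound_scale = 1) {
  stopifnot(include_dead_ends >= 0, n_parallel_routes >= 1, bound_scale > 0)
  structure(list(include_tic = include_tic,
                 include_dead_ends = as.integer(include_dead_ends),
                 include_unreachable_branch = include_unreachable_branch,
                 include_minor_subsystem = include_minor_subsystem,
                 n_parallel_routes = as.integer(n_parallel_routes),
                 randomize_bounds = randomize_bounds,
                 seed = as.integer(seed), bound_scale = bound_scale),
            class = "toy_network_config")
}

#' Generate a toy metabolic network with known ground truth
#'
#' The core network has 14 reactions and 9 metabolites. Carbon source uptake
#' (`EX_glyc`, lower bound `-10 * bound_scale`) feeds `g3p`; `akg` is drained
#' into an amino-acid analog by the lumped reaction `LMPD_ARG`; the product
#' branch `CEAS` condenses `g3p + arg + akg` into `clav`, releasing `suc` and
#' `co2`. With all internal caps open, maximizing `EX_clav` has the
#' closed-form optimum `uptake / 4` (each product unit consumes four C3 units
#' of carbon source: one as g3p, three via pyruvate for the two akg and the
#' anaplerotic oxaloacetate, with the released succinate recycled).
#'
#' @param config a [toy_network_config()].
#' @return A list with elements `model` (a [metabolic_model()]) and
#'   `ground_truth`: `analytic_optimum` (NA when bounds are randomized),
#'   `tic_loop`, `dead_end_metabolites`, `unreachable_reactions`,
#'   `minor_subsystem_reactions`, `subsystems`, counts, and the `config`.
#' @examples
#' toy <- generate_toy_network(toy_network_config())
#' fba(toy$model)$objective  # equals toy$ground_truth$analytic_optimum
#' @export
generate_toy_network <- function(config = toy_network_config()) {
  bs <- config$bound_scale
  uptake <- 10 * bs
  M <- 1000 * bs
  mets <- c("glyc", "g3p", "pyr", "oaa", "akg", "suc", "arg", "clav", "co2")
  rxns <- list(
    reaction("EX_glyc", c(glyc = -1), -uptake, 0, name = "glycerol exchange",
             subsystem = "exchange"),
    reaction("GLYT", c(glyc = -1, g3p = 1), 0, M,
             name = "glycerol assimilation", subsystem = "glycolysis",
             gene_rule = "g_glyt"),
    reaction("PYK", c(g3p = -1, pyr = 1), 0, M, name = "lower glycolysis",
             subsystem = "glycolysis", gene_rule = "g_pyk"),
    reaction("PPC", c(pyr = -1, co2 = -1, oaa = 1), 0, M,
             name = "anaplerotic carboxylation", subsystem = "anaplerotic",
             gene_rule = "g_ppc"),
    reaction("CS", c(pyr = -1, oaa = -1, akg = 1, co2 = 2), 0, M,
             name = "citrate synthase + oxidative TCA (lumped)",
             subsystem = "tca", gene_rule = "g_cs"),
    reaction("AKGDH", c(akg = -1, suc = 1, co2 = 1), 0, M,
             name = "akg dehydrogenase", subsystem = "tca",
             gene_rule = "g_akgdh"),
    reaction("SOD", c(suc = -1, oaa = 1), 0, M,
             name = "lower TCA: succinate to oxaloacetate (lumped)",
             subsystem = "tca", gene_rule = "g_sod"),
    reaction("ICL", c(pyr = -1, oaa = -1, suc = 1, co2 = 3), 0, M,
             name = "glyoxylate shunt analog", subsystem = "glyoxylate_shunt",
             gene_rule = "g_icl"),
    reaction("LMPD_ARG", c(akg = -1, arg = 1), 0, M,
             name = "arginine synthesis (lumped)", subsystem = "amino_acids",
             gene_rule = "g_args"),
    reaction("CEAS", c(g3p = -1, arg = -1, akg = -1, clav = 1, suc = 1,
                       co2 = 1), 0, M,
             name = "clavam branch: C3+C5 condensation to product",
             subsystem = "clavam", gene_rule = "g_ceas"),
    reaction("GROWTH", c(g3p = -1, oaa = -1), 0, M, name = "biomass (lumped)",
             subsystem = "biomass"),
    reaction("EX_clav", c(clav = -1), 0, M, name = "product exchange",
             subsystem = "exchange"),
    reaction("EX_suc", c(suc = -1), 0, M, name = "succinate exchange",
             subsystem = "exchange"),
    reaction("EX_co2", c(co2 = -1), 0, M, name = "CO2 exchange",
             subsystem = "exchange"))

  gt <- list(analytic_optimum = uptake / 4, tic_loop = character(),
             dead_end_metabolites = character(),
             unreachable_reactions = character(),
             minor_subsystem_reactions = character())

  if (config$n_parallel_routes > 1L) {
    for (k in seq_len(config$n_parallel_routes - 1L)) {
      mid <- sprintf("route%d_int", k)
      mets <- c(mets, mid)
      st1 <- stats::setNames(c(-1, 1), c("glyc", mid))
      st2 <- stats::setNames(c(-1, 1), c(mid, "g3p"))
      rxns <- c(rxns, list(
        reaction(sprintf("GLYT_alt%d_a", k), st1, 0, M,
                 subsystem = "glycolysis"),
        reaction(sprintf("GLYT_alt%d_b", k), st2, 0, M,
                 subsystem = "glycolysis")))
    }
  }
  if (config$include_tic) {
    # two parallel routes between the same metabolites; TIC1 reversible, so
    # the pair supports a closed circulation (TIC2 forward, TIC1 backward)
    # that a single directionality restriction on TIC1 dissolves
    mets <- c(mets, "tic_a", "tic_b")
    rxns <- c(rxns, list(
      reaction("TIC1", c(tic_a = -1, tic_b = 1), -M, M, subsystem = "tic"),
      reaction("TIC2", c(tic_a = -1, tic_b = 1), 0, M, subsystem = "tic")))
    gt$tic_loop <- c("TIC1", "TIC2")
  }
  if (config$include_dead_ends > 0L) {
    for (k in seq_len(config$include_dead_ends)) {
      oid <- sprintf("orphan%d", k)
      mets <- c(mets, oid)
      st <- stats::setNames(c(-1, 1), c("g3p", oid))
      rxns <- c(rxns, list(reaction(sprintf("DEAD%d", k), st, 0, M,
                                    subsystem = "dead_end")))
      gt$dead_end_metabolites <- c(gt$dead_end_metabolites, oid)
    }
  }
  if (config$include_unreachable_branch) {
    mets <- c(mets, "unr_a", "unr_b", "unr_c")
    rxns <- c(rxns, list(
      reaction("UNR1", c(unr_a = -1, unr_b = 1), 0, M,
               subsystem = "unreachable"),
      reaction("UNR2", c(unr_b = -1, unr_c = 1), 0, M,
               subsystem = "unreachable"),
      reaction("UNR3", c(unr_c = -1, co2 = 1), 0, M,
               subsystem = "unreachable")))
    gt$unreachable_reactions <- c("UNR1", "UNR2", "UNR3")
  }
  if (config$include_minor_subsystem) {
    mets <- c(mets, "min_a", "min_b", "min_c")
    rxns <- c(rxns, list(
      reaction("MIN1", c(g3p = -1, min_a = 1), 0, M, subsystem = "minor"),
      reaction("MIN2", c(min_a = -1, min_b = 1), 0, M, subsystem = "minor"),
      reaction("MIN3", c(min_b = -1, min_c = 1), 0, M, subsystem = "minor"),
      reaction("EX_min", c(min_c = -1), 0, M, subsystem = "minor")))
    gt$minor_subsystem_reactions <- c("MIN1", "MIN2", "MIN3", "EX_min")
  }

  if (config$randomize_bounds) {
    rng <- local_seed(config$seed)
    on.exit(rng(), add = TRUE)
    uptake_r <- stats::runif(1, 5, 15) * bs
    rxns[[1]]$lower_bound <- -uptake_r
    internal <- c("GLYT", "PYK", "PPC", "CS", "AKGDH", "SOD", "ICL",
                  "LMPD_ARG", "CEAS")
    for (id in internal) {
      k <- which(vapply(rxns, `[[`, "", "id") == id)
      if (stats::runif(1) < 0.5) {
        rxns[[k]]$upper_bound <- stats::runif(1, 0.5, 8) * bs
      }
    }
    gt$analytic_optimum <- NA_real_
  }

  met_df <- data.frame(id = mets, name = mets, compartment = "c",
                       stringsAsFactors = FALSE)
  genes <- sort(unique(unlist(lapply(rxns, function(r)
    if (nzchar(r$gene_rule)) r$gene_rule))))
  model <- metabolic_model(met_df, rxns, genes = genes,
                           objective_id = "EX_clav")
  gt$subsystems <- vapply(model$reactions, `[[`, "", "subsystem")
  gt$n_reactions <- length(model$reactions)
  gt$n_metabolites <- nrow(model$metabolites)
  gt$n_genes <- length(genes)
  gt$config <- config
  list(model = model, ground_truth = gt)
}

# run code under a temporary seed, restoring the caller's RNG state
local_seed <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Generate an experimental scenario from a known flux distribution
#'
#' Emulates the structure of a measured cultivation scenario: the growth rate
#' is a hard constraint, measured uptakes (negative) become lower bounds and
#' measured secretions (non-negative) upper bounds. Gaussian measurement noise
#' with standard deviation `noise_sd` perturbs the *reported* experimental
#' exchange rates; the constraint values stay at the underlying true rates, so
#' the deviation of a validated prediction from the report reflects the
#' injected measurement error alone (with `noise_sd = 0` validation recovers
#' an exact fit, MSE = 0).
#'
#' @param model a `metabolic_model`.
#' @param true_fluxes named flux vector (e.g. from [fba()]) used as ground
#'   truth.
#' @param noise_sd standard deviation of the measurement noise
#'   (mmol gDCW^-1 h^-1).
#' @param seed integer seed.
#' @param growth_id id of the growth reaction (default `"GROWTH"`).
#' @return A list with `scenario` (a [scenario()]) and `experimental`
#'   (data frame `reaction_id`, `value`, `available`).
#' @export
generate_scenario <- function(model, true_fluxes, noise_sd = 0, seed = 1L,
                              growth_id = "GROWTH") {
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  ex_ids <- detect_exchanges(model, quiet = TRUE)
  truth <- true_fluxes[ex_ids]
  noisy <- truth + stats::rnorm(length(truth), 0, noise_sd)
  lower <- truth[truth < 0]
  upper <- truth[truth >= 0]
  sc <- scenario(name = "synthetic",
                 growth_rate = unname(true_fluxes[[growth_id]]),
                 lower_bounded = as.list(lower), upper_bounded = as.list(upper),
                 objective_id = model$objective_id, growth_id = growth_id)
  # the growth rate enters as the hard constraint, not as a validated flux,
  # so the report rows cover the exchanges only: every row then carries
  # measurement noise and the expected validation MSE equals noise_sd^2
  exp_rows <- data.frame(reaction_id = ex_ids, value = unname(noisy),
                         available = 1L, stringsAsFactors = FALSE)
  list(scenario = sc, experimental = exp_rows)
}

#' Brute-force FBA oracle by vertex enumeration
#'
#' Independent check of the LP core: enumerates every vertex of the flux
#' polytope `{S v = 0, lb <= v <= ub}` by fixing each choice of
#' `n - rank(S)` variables at a bound and solving for the rest, then returns
#' the best feasible objective. Exponential in the degrees of freedom, so it
#' is restricted to networks with at most `max_reactions` reactions.
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction to maximize (default: model objective).
#' @param max_reactions guard on problem size.
#' @return A list with `status` (`"optimal"` or `"infeasible"`), `objective`
#'   and `vertex` (the best vertex flux vector).
#' @export
brute_force_fba_oracle <- function(model, objective_id = model$objective_id,
                                   max_reactions = 14L) {
  n <- length(model$reactions)
  if (n > max_reactions) {
    stop("vertex enumeration limited to ", max_reactions, " reactions (got ",
         n, ")")
  }
  S <- stoichiometric_matrix(model, sparse = FALSE)
  lb <- lower_bounds(model)
  ub <- upper_bounds(model)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("vertex enumeration requires finite bounds")
  }
  r <- qr(S)$rank
  cvec <- as.numeric(reaction_ids(model) == objective_id)
  best <- -Inf
  best_v <- NULL
  nfree <- n - r
  nb_sets <- if (nfree == 0L) list(integer()) else
    utils::combn(n, nfree, simplify = FALSE)
  for (nbs in nb_sets) {
    bas <- setdiff(seq_len(n), nbs)
    B <- S[, bas, drop = FALSE]
    qrB <- qr(B)
    if (qrB$rank < r) next
    # all 2^k assignments of the nonbasic variables to their bounds at once
    k <- length(nbs)
    if (k > 0L) {
      grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
      vals <- matrix(ifelse(t(grid), ub[nbs], lb[nbs]), nrow = k)
      rhs <- -S[, nbs, drop = FALSE] %*% vals
    } else {
      vals <- matrix(0, 0, 1)
      rhs <- matrix(0, nrow(S), 1)
    }
    xb <- qr.coef(qrB, rhs)
    xb[is.na(xb)] <- 0
    resid <- S[, bas, drop = FALSE] %*% xb - rhs
    ok <- colSums(abs(resid)) < 1e-8
    inb <- colSums(xb < lb[bas] - 1e-9 | xb > ub[bas] + 1e-9) == 0
    for (col in which(ok & inb)) {
      v <- numeric(n)
      v[bas] <- xb[, col]
      if (ncol(vals)) v[nbs] <- vals[, col]
      obj <- sum(cvec * v)
      if (obj > best + 1e-12) {
        best <- obj
        best_v <- stats::setNames(v, reaction_ids(model))
      }
    }
  }
  if (is.null(best_v)) {
    return(list(status = "infeasible", objective = NA_real_, vertex = NULL))
  }
  list(status = "optimal", objective = best, vertex = best_v)
}
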