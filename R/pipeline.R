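#' Run the full two-condition analysis pipeline
#'
#' Reproduces the constraint-based workflow for comparing two metabolic
#' states end to end. For each scenario: apply the measured constraints, run
#' [two_step_fba()], [fva()] and [chrr_sample()]. Across scenarios: a
#' per-reaction Kruskal-Wallis comparison of the flux samples, the
#' shadow-price matrix with PCA and top-changing-metabolite ranking, and
#' squared-error validation against any supplied experimental rows. All
#' tables are written as TSV into `out_dir` together with a JSON manifest
#' (seed, configuration hash, per-stage status); a failing stage is recorded
#' in the manifest and earlier outputs are kept.
#'
#' @param model a `metabolic_model`.
#' @param scenarios named list of [scenario()]s (typically two, e.g. batch
#'   and fed-batch).
#' @param experimental optional named list of experimental-row data frames
#'   (names matching `scenarios`) for [validate_scenario()].
#' @param sampler a [sampler_config()]; its seed is re-derived from `seed`
#'   per scenario so conditions get independent chains.
#' @param fva_fraction fraction of optimum for [fva()].
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output.
#' @param seed master seed for the run.
#' @param alpha significance cutoff for the flux-distribution comparison.
#' @param top_k metabolites to keep in the shadow-price ranking.
#' @return A list with per-scenario results (`solutions`, `fva`, `samples`,
#'   `validation`), the cross-scenario `comparison`, `shadow_matrix`, `pca`,
#'   `top_metabolites`, and the `manifest`.
#' @export
run_pipeline <- function(model, scenarios, experimental = NULL,
                         sampler = sampler_config(n_points = 500L,
                                                  steps_per_point = 100L),
                         fva_fraction = 1, out_dir = NULL, seed = 1L,
                         alpha = 0.001, top_k = 70L) {
  stopifnot(length(scenarios) >= 1, !is.null(names(scenarios)))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(seed = seed,
                   sampler = unclass(sampler),
                   fva_fraction = fva_fraction,
                   scenarios = names(scenarios),
                   stages = list())
  results <- list(solutions = list(), fva = list(), samples = list(),
                  validation = list())
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(out))
      NULL
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      out
    }
  }
  for (i in seq_along(scenarios)) {
    nm <- names(scenarios)[i]
    sc <- scenarios[[i]]
    constrained <- stage(paste0("constrain:", nm),
                         apply_scenario(model, sc))
    if (is.null(constrained)) next
    sol <- stage(paste0("two_step_fba:", nm), two_step_fba(constrained))
    if (!is.null(sol)) {
      results$solutions[[nm]] <- sol
      if (!is.null(out_dir)) {
        write_flux_solution(sol, file.path(out_dir,
                                           paste0("fluxes_", nm, ".tsv")))
      }
    }
    fv <- stage(paste0("fva:", nm), fva(constrained, fva_fraction))
    if (!is.null(fv)) {
      results$fva[[nm]] <- fv
      if (!is.null(out_dir)) {
        utils::write.table(fv, file.path(out_dir, paste0("fva_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    cfg <- sampler
    cfg$seed <- as.integer((seed + 104729L * i) %% .Machine$integer.max)
    sm <- stage(paste0("sample:", nm), chrr_sample(constrained, cfg))
    if (!is.null(sm)) {
      results$samples[[nm]] <- sm
      if (!is.null(out_dir)) {
        write_flux_sample(sm, file.path(out_dir,
                                        paste0("samples_", nm, ".tsv")))
      }
    }
    if (!is.null(experimental) && nm %in% names(experimental)) {
      vr <- stage(paste0("validate:", nm),
                  validate_scenario(model, sc, experimental[[nm]]))
      if (!is.null(vr)) {
        results$validation[[nm]] <- vr
        if (!is.null(out_dir)) {
          write_validation_report(vr, file.path(out_dir,
                                                paste0("validation_", nm,
                                                       ".tsv")))
        }
      }
    }
  }
  if (length(results$samples) >= 2) {
    cmp <- stage("kruskal_wallis", compare_flux_distributions(
      results$samples[[1]], results$samples[[2]], alpha = alpha))
    results$comparison <- cmp
    if (!is.null(cmp) && !is.null(out_dir)) {
      utils::write.table(cmp, file.path(out_dir, "kw.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  if (length(results$solutions) >= 2) {
    spm <- stage("shadow_matrix",
                 shadow_price_matrix(results$solutions))
    results$shadow_matrix <- spm
    if (!is.null(spm)) {
      if (!is.null(out_dir)) {
        utils::write.table(
          data.frame(metabolite = rownames(spm), spm, check.names = FALSE),
          file.path(out_dir, "shadow_matrix.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
      }
      results$pca <- stage("pca", shadow_price_pca(spm))
      if (!is.null(results$pca) && !is.null(out_dir)) {
        utils::write.table(
          data.frame(metabolite = rownames(results$pca$scores),
                     results$pca$scores, check.names = FALSE),
          file.path(out_dir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        utils::write.table(
          data.frame(condition = rownames(results$pca$loadings),
                     results$pca$loadings, check.names = FALSE),
          file.path(out_dir, "pca_loadings.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
      }
      if (ncol(spm) == 2) {
        results$top_metabolites <- stage("top_changing",
                                         top_changing_metabolites(spm,
                                                                  top_k))
        if (!is.null(results$top_metabolites) && !is.null(out_dir)) {
          utils::write.table(results$top_metabolites,
                             file.path(out_dir, "top_metabolites.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
  }
  cfg_json <- jsonlite::toJSON(manifest[c("seed", "sampler",
                                          "fva_fraction", "scenarios")],
                               auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- config_hash(as.character(cfg_json))
  results$manifest <- manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}

# small stable polynomial rolling hash so the manifest can fingerprint its
# configuration without a cryptographic dependency
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
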