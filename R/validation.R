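#' Squared error between experimental and predicted flux
#'
#' \eqn{SE_i = (X_i - \hat X_i)^2}, the per-flux deviation measure used to
#' score constraint-based predictions against measured exchange rates.
#'
#' @param x experimental flux value(s), mmol gDCW^-1 h^-1.
#' @param xhat model-predicted flux value(s).
#' @return `(x - xhat)^2`, vectorized.
#' @examples
#' squared_error(-1.350, -0.512)  # 0.702 to 3 d.p.
#' @export
squared_error <- function(x, xhat) {
  (x - xhat)^2
}

#' Mean squared error over the quantified fluxes of a scenario
#'
#' \eqn{MSE = \frac1p \sum_{i=1}^p SE_i}, where `p` counts only the fluxes
#' with an experimental value: entries with `x = NA` (no experimental data
#' available) are excluded from both the sum and `p`.
#'
#' @param x experimental flux values (may contain `NA`).
#' @param xhat predicted flux values.
#' @return A list with `mse`, `sse` (the plain sum of SE, reported alongside
#'   because some published per-scenario aggregates are sums rather than
#'   means), `p`, and `se` (named per-flux squared errors).
#' @export
mean_squared_error <- function(x, xhat) {
  keep <- !is.na(x)
  p <- sum(keep)
  if (p == 0L) stop("mean_squared_error: no experimental values (p = 0)")
  se <- squared_error(x[keep], xhat[keep])
  list(mse = mean(se), sse = sum(se), p = p, se = se)
}

#' Validate a model against an experimental scenario
#'
#' Applies the scenario constraints, runs [two_step_fba()] on the constrained
#' model, and scores the predicted exchange fluxes against the experimental
#' rows with [squared_error()] / [mean_squared_error()]. Rows with no
#' experimental value (`available = 0` or `NA`) are excluded from `p`.
#'
#' @param model a `metabolic_model`.
#' @param sc a [scenario()].
#' @param experimental data frame with columns `reaction_id`, `value` and
#'   optionally `available` (1/0).
#' @param objective_id objective for the simulation (default: scenario's,
#'   falling back to the model's).
#' @return A `validation_report`: list with `status`, `rows` (data frame
#'   `reaction_id`, `x`, `xhat`, `se`), `p`, `mse`, `sse`, `scenario`. When
#'   the constrained model is infeasible, `status` records it and the error
#'   fields are `NA`.
#' @export
validate_scenario <- function(model, sc, experimental,
                              objective_id = NULL) {
  stopifnot(is.data.frame(experimental),
            all(c("reaction_id", "value") %in% names(experimental)))
  constrained <- apply_scenario(model, sc)
  obj <- objective_id %||% sc$objective_id %||% model$objective_id
  sol <- two_step_fba(constrained, obj)
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, rows = NULL, p = NA_integer_,
                          mse = NA_real_, sse = NA_real_,
                          scenario = sc$name),
                     class = "validation_report"))
  }
  avail <- if ("available" %in% names(experimental)) {
    !is.na(experimental$available) & experimental$available != 0
  } else rep(TRUE, nrow(experimental))
  avail <- avail & !is.na(experimental$value)
  rows <- data.frame(reaction_id = experimental$reaction_id,
                     x = ifelse(avail, experimental$value, NA_real_),
                     stringsAsFactors = FALSE)
  miss <- setdiff(rows$reaction_id, names(sol$fluxes))
  if (length(miss)) {
    stop("experimental rows reference unknown reactions: ",
         paste(miss, collapse = ", "))
  }
  rows$xhat <- unname(sol$fluxes[rows$reaction_id])
  rows$se <- squared_error(rows$x, rows$xhat)
  ms <- mean_squared_error(rows$x, rows$xhat)
  structure(list(status = "optimal", rows = rows, p = ms$p, mse = ms$mse,
                 sse = ms$sse, scenario = sc$name, solution = sol),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  cat(sprintf("<validation_report> scenario '%s': %s\n", x$scenario,
              x$status))
  if (x$status == "optimal") {
    df <- x$rows
    df$x <- round(df$x, digits); df$xhat <- round(df$xhat, digits)
    df$se <- round(df$se, digits)
    print(df, row.names = FALSE)
    cat(sprintf("p = %d, MSE = %.3f (SSE = %.3f)\n", x$p, x$mse, x$sse))
  }
  invisible(x)
}

#' Read experimental flux rows
#'
#' CSV with columns `reaction_id`, `value` and optionally `available`
#' (1 = measured, 0 = no experimental data).
#'
#' @param path CSV file.
#' @return A data frame.
#' @export
read_experimental_rows <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "value") %in% names(df)))
  df
}

#' Write a validation report as TSV
#'
#' @param report a `validation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  if (report$status != "optimal") {
    utils::write.table(data.frame(status = report$status), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  df <- report$rows
  df$mse <- c(report$mse, rep(NA, nrow(df) - 1L))
  df$sse <- c(report$sse, rep(NA, nrow(df) - 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled cultivation rate datasets for S. clavuligerus
#'
#' Comparison tables of FBA-predicted and experimentally measured exchange
#' rates compiled from published cultivation studies of *Streptomyces
#' clavuligerus*:
#' \describe{
#'   \item{`"chemostat"`}{continuous cultures at dilution rates 0.035, 0.045
#'     and 0.050 h^-1; columns `dilution_rate`, `reaction`, `fba`, `exp`
#'     (`NA` = no experimental data). Flux units mmol gDCW^-1 h^-1, growth
#'     h^-1.}
#'   \item{`"fedbatch"`}{batch (36 h) and fed-batch (48 h) phases of a
#'     2D-rocking-bioreactor cultivation; columns `phase`, `reaction`,
#'     `fba`, `exp`, `exp_sd` (reported uncertainty, growth only; carried as
#'     metadata, not used in SE).}
#'   \item{`"shadow_prices"`}{shadow prices of central-carbon metabolites
#'     under the batch and fed-batch conditions; columns `metabolite`,
#'     `batch`, `fedbatch`, `pathway`.}
#' }
#'
#' @param which dataset name.
#' @return A data frame.
#' @examples
#' head(sclav_rates("chemostat"))
#' @export
sclav_rates <- function(which = c("chemostat", "fedbatch",
                                  "shadow_prices")) {
  which <- match.arg(which)
  fname <- switch(which, chemostat = "sclav_chemostat_rates.csv",
                  fedbatch = "sclav_fedbatch_rates.csv",
                  shadow_prices = "sclav_shadow_prices.csv")
  f <- system.file("extdata", fname, package = "redgem", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
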