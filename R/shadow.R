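#' Classify shadow prices into limiting / insensitive / surplus
#'
#' Applies the standard interpretation of metabolite shadow prices at an FBA
#' optimum: (i) negative — the metabolite's availability limits the
#' objective; (ii) zero (within `tol`) — the objective is insensitive to it;
#' (iii) positive — the metabolite is in surplus (its forced net production
#' already exceeds what the objective can use). Only meaningful at
#' non-degenerate optima; at degenerate ones the dual solution, and hence the
#' classification, is solver-dependent.
#'
#' @param solution a `flux_solution` with duals (from [fba()] or
#'   [two_step_fba()]), or a named numeric vector of shadow prices.
#' @param tol zero band, default 1e-9.
#' @return Named character vector over metabolites with values `"limiting"`,
#'   `"insensitive"`, `"surplus"`.
#' @export
classify_shadow_prices <- function(solution, tol = 1e-9) {
  sp <- if (inherits(solution, "flux_solution")) solution$shadow_prices
        else solution
  if (is.null(sp)) stop("solution carries no shadow prices")
  out <- ifelse(abs(sp) <= tol, "insensitive",
                ifelse(sp < 0, "limiting", "surplus"))
  stats::setNames(out, names(sp))
}

#' Assemble a shadow-price matrix across conditions
#'
#' One column per condition (e.g. batch and fed-batch), one row per
#' metabolite. All solutions must cover the same metabolite set; the matrix
#' has no holes.
#'
#' @param solutions named list of `flux_solution` objects (names become
#'   condition labels).
#' @return A numeric matrix (metabolites x conditions) with a `provenance`
#'   attribute recording each column's solution status.
#' @export
shadow_price_matrix <- function(solutions) {
  stopifnot(length(solutions) >= 1, !is.null(names(solutions)))
  mets <- names(solutions[[1]]$shadow_prices)
  cols <- lapply(solutions, function(s) {
    if (is.null(s$shadow_prices)) stop("a solution carries no shadow prices")
    if (!identical(names(s$shadow_prices), mets)) {
      stop("solutions cover different metabolite sets")
    }
    unname(s$shadow_prices)
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(mets, names(solutions))
  attr(m, "provenance") <- vapply(solutions, `[[`, "", "status")
  m
}

#' PCA of a metabolite-by-condition shadow-price matrix
#'
#' Column-centered singular value decomposition: metabolite scores are
#' `U %*% D`, condition loadings are `V`, and the explained variance ratios
#' are the squared singular values normalized to sum to one. Condition
#' loadings pointing in opposite directions indicate shadow-price profiles
#' that differ between conditions. Sign convention: each component is
#' flipped, if needed, so its largest-magnitude loading is positive, making
#' the output deterministic. PCA on just two conditions is unusual but valid;
#' [top_changing_metabolites()] offers the equivalent direct ranking.
#'
#' @param m matrix from [shadow_price_matrix()] (>= 2 conditions).
#' @return A list with `scores` (metabolites x components), `loadings`
#'   (conditions x components), `explained_variance`.
#' @export
shadow_price_pca <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2)
  centered <- sweep(m, 2, colMeans(m))
  if (max(abs(centered)) < 1e-12) {
    stop("shadow_price_pca: matrix has zero variance after centering")
  }
  sv <- svd(centered)
  flip <- vapply(seq_along(sv$d), function(k) {
    l <- sv$v[, k]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  scores <- sv$u %*% diag(sv$d, length(sv$d)) %*% diag(flip, length(flip))
  loadings <- sv$v %*% diag(flip, length(flip))
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_along(sv$d)))
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_along(sv$d)))
  list(scores = scores, loadings = loadings,
       explained_variance = sv$d^2 / sum(sv$d^2))
}

#' Rank metabolites by shadow-price change between two conditions
#'
#' Descending absolute difference `|price_B - price_A|`; ties broken by
#' lexicographic metabolite id. The direct equivalent of reading the extreme
#' metabolites off a two-condition PCA biplot.
#'
#' @param m matrix from [shadow_price_matrix()] with exactly 2 columns.
#' @param k number of metabolites to return (default 70); `k > n` returns
#'   all.
#' @return A data frame `metabolite`, `price_a`, `price_b`, `delta`,
#'   `abs_delta`, ranked.
#' @export
top_changing_metabolites <- function(m, k = 70L) {
  stopifnot(is.matrix(m), ncol(m) == 2)
  delta <- m[, 2] - m[, 1]
  ord <- order(-abs(delta), rownames(m))
  ord <- ord[seq_len(min(k, nrow(m)))]
  data.frame(metabolite = rownames(m)[ord], price_a = m[ord, 1],
             price_b = m[ord, 2], delta = delta[ord],
             abs_delta = abs(delta[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalize metabolite compartment suffixes
#'
#' Converts bracket compartment notation (`"btn[c]"`) to the underscore
#' convention (`"btn_c"`) so ids from either style can be matched against a
#' model or shadow-price matrix.
#'
#' @param x character vector of metabolite ids.
#' @return Normalized ids.
#' @examples
#' normalize_met_ids(c("btn[c]", "glc__D_e"))
#' @export
normalize_met_ids <- function(x) {
  gsub("\\[([A-Za-z0-9]+)\\]$", "_\\1", x)
}
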