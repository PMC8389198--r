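#' Sampler configuration
#'
#' Defaults mirror common practice for characterizing metabolic flux spaces:
#' 5000 returned points with a thinning of 1848 steps per point. Tests and
#' examples run scaled down (e.g. 500 points, 100 steps) for speed.
#'
#' @param n_points number of returned sample points.
#' @param steps_per_point thinning: hit-and-run steps between kept points.
#' @param seed integer seed; the sample is bit-reproducible under a fixed
#'   seed.
#' @param warmup_points number of warm-up points used to estimate the
#'   rounding transform; `NA` (default) uses all FVA extreme points.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_points = 5000L, steps_per_point = 1848L,
                           seed = 1L, warmup_points = NA_integer_) {
  stopifnot(n_points > 0, steps_per_point > 0)
  structure(list(n_points = as.integer(n_points),
                 steps_per_point = as.integer(steps_per_point),
                 seed = as.integer(seed),
                 warmup_points = as.integer(warmup_points)),
            class = "sampler_config")
}

#' Coordinate hit-and-run sampling of the flux polytope (with rounding)
#'
#' Samples near-uniformly from `{v : S v = 0, lb <= v <= ub}`. Pipeline:
#' (1) the polytope is parameterized by an orthonormal basis of the null
#' space of `S`, so every sampled point satisfies the steady state exactly;
#' (2) a warm-up set of FVA extreme points spans the polytope; (3) a rounding
#' transform is taken as the symmetric eigenvalue factorization of the
#' warm-up covariance, stretching thin directions so coordinate moves mix
#' well (if the covariance is numerically rank deficient the transform falls
#' back to the identity with a warning); (4) coordinate hit-and-run walks in
#' the rounded space, keeping every `steps_per_point`-th state.
#'
#' @param model a `metabolic_model` (the polytope must be non-empty with
#'   nonzero volume inside the null space).
#' @param config a [sampler_config()].
#' @return An object of class `flux_sample`: list with `points` (matrix
#'   `n_points` x n_reactions, columns named by reaction), `config`, and
#'   `diagnostics` (degrees of freedom, mean chord length).
#' @export
chrr_sample <- function(model, config = sampler_config()) {
  restore <- local_seed(config$seed)
  on.exit(restore(), add = TRUE)

  S <- stoichiometric_matrix(model, sparse = FALSE)
  ids <- reaction_ids(model)
  n <- length(ids)
  lb <- lower_bounds(model)
  ub <- upper_bounds(model)

  qrt <- qr(t(S))
  rank <- qrt$rank
  k <- n - rank
  if (k <= 0L) stop("chrr_sample: polytope has no degrees of freedom")
  Q <- qr.Q(qrt, complete = TRUE)
  N <- Q[, seq(rank + 1L, n), drop = FALSE]      # orthonormal null basis

  # warm-up: FVA extreme points of the polytope itself
  warm <- matrix(NA_real_, 2L * n, n)
  zero <- numeric(nrow(S))
  for (j in seq_len(n)) {
    cvec <- as.numeric(seq_len(n) == j)
    lo <- lp_solve(cvec, S, zero, lb = lb, ub = ub, maximize = FALSE)
    hi <- lp_solve(cvec, S, zero, lb = lb, ub = ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("chrr_sample: polytope is empty (", lo$status, ")")
    }
    warm[2L * j - 1L, ] <- lo$x
    warm[2L * j, ] <- hi$x
  }
  if (!is.na(config$warmup_points) && config$warmup_points < nrow(warm)) {
    warm <- warm[sample.int(nrow(warm), config$warmup_points), ,
                 drop = FALSE]
  }
  U <- warm %*% N                                 # reduced coordinates
  u0 <- colMeans(U)
  C <- stats::cov(U)
  ev <- eigen(C, symmetric = TRUE)
  if (max(ev$values) <= 0) {
    warning("chrr_sample: warm-up covariance is rank deficient; ",
            "using identity rounding transform")
    Tm <- diag(1, k)
  } else {
    # equality-pinned reactions (e.g. a hard growth constraint) leave
    # zero-width directions inside the null space; the walk is restricted
    # to the eigen-directions the polytope actually spans
    keep <- ev$values > 1e-10 * max(ev$values)
    if (!all(keep)) {
      message("chrr_sample: dropping ", sum(!keep),
              " degenerate polytope direction(s)")
    }
    Tm <- ev$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(ev$values[keep]), sum(keep))
  }
  k <- ncol(Tm)
  G <- N %*% Tm                                   # v-space move directions

  v <- as.numeric(N %*% u0)
  w <- numeric(k)
  v0 <- v
  pts <- matrix(NA_real_, config$n_points, n,
                dimnames = list(NULL, ids))
  chord <- 0
  steps <- 0L
  eps <- 1e-11
  for (p in seq_len(config$n_points)) {
    for (s in seq_len(config$steps_per_point)) {
      i <- sample.int(k, 1L)
      g <- G[, i]
      dist_up <- ub - v
      dist_lo <- lb - v
      pos <- g > eps
      neg <- g < -eps
      tmax <- suppressWarnings(min(dist_up[pos] / g[pos],
                                   dist_lo[neg] / g[neg]))
      tmin <- suppressWarnings(max(dist_lo[pos] / g[pos],
                                   dist_up[neg] / g[neg]))
      if (!is.finite(tmax) || !is.finite(tmin) || tmax <= tmin) next
      tt <- stats::runif(1L, tmin, tmax)
      w[i] <- w[i] + tt
      v <- v + tt * g
      chord <- chord + (tmax - tmin)
      steps <- steps + 1L
      if (steps %% 1000L == 0L) v <- v0 + as.numeric(G %*% w)
    }
    pts[p, ] <- v
  }
  structure(list(points = pts, config = config,
                 diagnostics = list(dof = k,
                                    mean_chord = chord / max(steps, 1L))),
            class = "flux_sample")
}

#' @export
print.flux_sample <- function(x, ...) {
  cat(sprintf("<flux_sample> %d points x %d reactions (dof %d, seed %d)\n",
              nrow(x$points), ncol(x$points), x$diagnostics$dof,
              x$config$seed))
  invisible(x)
}

#' Compare two flux samples reaction by reaction
#'
#' Two-group Kruskal-Wallis rank test per reaction (tie-corrected H,
#' chi-square p-value with 1 degree of freedom), the standard test for
#' whether flux samples generated under two different condition sets stem
#' from the same distribution. Raw p-values are reported together with a
#' Benjamini-Hochberg adjusted column; the significance flag uses the raw
#' p-value against `alpha` (0.001 by default, the customary cutoff in flux
#' distribution figures).
#'
#' @param sample_a,sample_b `flux_sample` objects (or plain matrices with
#'   identical column order); at least 5 points each.
#' @param alpha significance level on the raw p-value.
#' @return A data frame `reaction_id`, `H`, `p`, `p_adj`, `significant`.
#' @examples
#' compare_flux_distributions(matrix(1:3, 3, 1, dimnames = list(NULL, "r")),
#'                            matrix(4:6, 3, 1, dimnames = list(NULL, "r")),
#'                            alpha = 0.05)
#' @export
compare_flux_distributions <- function(sample_a, sample_b, alpha = 0.001) {
  A <- if (inherits(sample_a, "flux_sample")) sample_a$points else sample_a
  B <- if (inherits(sample_b, "flux_sample")) sample_b$points else sample_b
  stopifnot(identical(colnames(A), colnames(B)))
  res <- lapply(seq_len(ncol(A)), function(j) {
    x <- A[, j]; y <- B[, j]
    if (max(c(x, y)) - min(c(x, y)) < .Machine$double.eps * 100) {
      return(c(H = 0, p = 1))                    # identical constant columns
    }
    kt <- stats::kruskal.test(list(x, y))
    c(H = unname(kt$statistic), p = kt$p.value)
  })
  out <- do.call(rbind, res)
  df <- data.frame(reaction_id = colnames(A), H = out[, "H"], p = out[, "p"],
                   stringsAsFactors = FALSE, row.names = NULL)
  df$p_adj <- stats::p.adjust(df$p, method = "BH")
  df$significant <- df$p < alpha
  df
}

#' Write a flux sample as TSV
#'
#' @param sample a `flux_sample`.
#' @param path output file; reactions as columns.
#' @return `path`, invisibly.
#' @export
write_flux_sample <- function(sample, path) {
  utils::write.table(sample$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
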