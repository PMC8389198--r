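test_that("classification follows the sign rules and finite differences", {
  toy <- default_toy()
  sol <- fba(toy$model)
  cls <- classify_shadow_prices(sol)
  # the imported carbon source limits the product objective
  expect_equal(unname(cls["glyc"]), "limiting")
  # the freely exportable byproduct CO2 does not constrain it
  expect_equal(unname(cls["co2"]), "insensitive")
  # sign agreement with finite-difference sensitivity
  S <- stoichiometric_matrix(toy$model, sparse = FALSE)
  lb <- vapply(toy$model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(toy$model$reactions, `[[`, 0, "upper_bound")
  cvec <- as.numeric(names(toy$model$reactions) == "EX_clav")
  eps <- 1e-4
  for (met in names(cls)) {
    rhs <- numeric(nrow(S)); rhs[match(met, rownames(S))] <- -eps
    dz <- lp_solve(cvec, S, rhs, lb = lb, ub = ub)$objective -
      sol$objective_value
    expected <- if (abs(dz) < 1e-10) "insensitive"
                else if (dz > 0) "limiting" else "surplus"
    expect_equal(unname(cls[met]), expected, label = met)
  }
  # a published fed-batch example: positive succinate price = surplus
  sp <- sclav_rates("shadow_prices")
  suc <- sp$fedbatch[sp$metabolite == "Succinate"]
  expect_equal(unname(classify_shadow_prices(c(suc_c = suc))), "surplus")
})

test_that("a metabolite off any active path is insensitive", {
  # a bystander metabolite with its own reversible exchange and no link to
  # the producing network (duals of dead-end rows are degenerate, so the
  # non-degenerate off-path case is the one asserted)
  toy <- default_toy()
  m <- toy$model
  m$metabolites <- rbind(m$metabolites,
                         data.frame(id = "bystander", name = "bystander",
                                    compartment = "c", formula = NA,
                                    charge = NA))
  m$reactions$EX_bys <- reaction("EX_bys", c(bystander = -1), -1, 1)
  cls <- classify_shadow_prices(fba(m))
  expect_equal(unname(cls["bystander"]), "insensitive")
})

test_that("shadow price matrices assemble completely across conditions", {
  toy <- default_toy()
  s1 <- fba(toy$model)
  m2 <- toy$model
  m2$reactions$EX_glyc$lower_bound <- -5
  s2 <- fba(m2)
  spm <- shadow_price_matrix(list(batch = s1, fedbatch = s2))
  expect_equal(dim(spm), c(nrow(toy$model$metabolites), 2))
  expect_false(any(is.na(spm)))
  expect_equal(colnames(spm), c("batch", "fedbatch"))
})

test_that("PCA is a column-centered SVD with deterministic signs", {
  m <- matrix(c(1, 0, 1, 0, 0, 1, 1, 0), 4, 2,
              dimnames = list(c("m1", "m2", "m3", "m4"), c("a", "b")))
  p <- shadow_price_pca(m)
  # independent oracle: prcomp performs the same centered decomposition
  ref <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  expect_equal(abs(unname(p$scores)), abs(unname(ref$x)), tolerance = 1e-9)
  expect_equal(p$explained_variance,
               ref$sdev^2 / sum(ref$sdev^2), tolerance = 1e-9)
  expect_equal(sum(p$explained_variance), 1)
  # reconstruction of the centered matrix
  centered <- sweep(m, 2, colMeans(m))
  expect_equal(p$scores %*% t(p$loadings), centered, tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (k in seq_len(ncol(p$loadings))) {
    l <- p$loadings[, k]
    expect_gte(l[which.max(abs(l))], 0)
  }
  # zero-variance matrix errors
  expect_error(shadow_price_pca(matrix(1, 3, 2)), "zero variance")
  # anti-correlated profiles load in opposite directions on PC1
  m2 <- matrix(c(1, -1, 2, -2, -1, 1, -2, 2), 4, 2,
               dimnames = list(paste0("m", 1:4), c("a", "b")))
  p2 <- shadow_price_pca(m2)
  expect_lt(prod(p2$loadings[, 1]), 0)
})

test_that("top-changing ranking is ordered, tie-broken, and shift-invariant", {
  m <- matrix(c(3.0, 0.1, 0.5, 0.28, 0.1, 0.9), 3, 2,
              dimnames = list(c("btn_c", "aaa_c", "zzz_c"),
                              c("batch", "fedbatch")))
  top <- top_changing_metabolites(m, k = 70)   # k > n returns all
  expect_equal(nrow(top), 3)
  # biotin-like row: |0.28 - 3.0| = 2.72 ranks first
  expect_equal(top$metabolite[1], "btn_c")
  expect_equal(top$abs_delta[1], 2.72)
  # ties broken lexicographically
  m_id <- matrix(c(1, 1, 1, 1), 2, 2,
                 dimnames = list(c("zz", "aa"), c("a", "b")))
  expect_equal(top_changing_metabolites(m_id)$metabolite, c("aa", "zz"))
  # adding a constant to both conditions changes nothing
  top_shift <- top_changing_metabolites(m + 5, k = 70)
  expect_equal(top_shift$metabolite, top$metabolite)
  expect_equal(top_shift$abs_delta, top$abs_delta)
  # a planted large change dominates
  m[2, 2] <- 100
  expect_equal(top_changing_metabolites(m)$metabolite[1], "aaa_c")
})

test_that("bracket compartment suffixes normalize to underscores", {
  expect_equal(normalize_met_ids(c("btn[c]", "glc__D[e]", "akg_c")),
               c("btn_c", "glc__D_e", "akg_c"))
})
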