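test_that("minimal and malformed models load as specified", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"metabolites":[{"id":"A","compartment":"c"}],',
                    '"reactions":[{"id":"EX_A","stoichiometry":{"A":-1},',
                    '"lower_bound":-5,"upper_bound":5}],',
                    '"objective":"EX_A"}'), p)
  m <- load_model(p)
  rep <- model_report(m)
  expect_equal(c(rep$n_reactions, rep$n_metabolites), c(1, 1))
  expect_equal(m$reactions$EX_A$lower_bound, -5)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"metabolites":[{"id":"A","compartment":"c"}],',
                    '"reactions":[{"id":"R1","stoichiometry":{"X":-1}}],',
                    '"objective":"R1"}'), bad)
  expect_error(load_model(bad), "X")
  notjson <- withr::local_tempfile(fileext = ".json")
  writeLines("{]", notjson)
  expect_error(load_model(notjson), "format error")
})

test_that("default bounds of +/-1000 apply when a JSON file omits them", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"metabolites":[{"id":"A","compartment":"c"}],',
                    '"reactions":[{"id":"EX_A","stoichiometry":{"A":-1}}],',
                    '"objective":"EX_A"}'), p)
  m <- load_model(p)
  expect_equal(m$reactions$EX_A$lower_bound, -1000)
  expect_equal(m$reactions$EX_A$upper_bound, 1000)
})

fields <- c("id", "name", "stoichiometry", "lower_bound", "upper_bound",
            "subsystem", "gene_rule", "is_exchange", "is_lumped")

roundtrip_identical <- function(model, format) {
  ext <- if (format == "sbml") ".xml" else ".json"
  p <- tempfile(fileext = ext)
  on.exit(unlink(p))
  save_model(model, p, format)
  m2 <- load_model(p, format)
  for (f in fields) {
    expect_identical(lapply(m2$reactions, `[[`, f),
                     lapply(model$reactions, `[[`, f),
                     label = paste(format, "field", f))
  }
  expect_identical(m2$metabolites$id, model$metabolites$id)
  expect_identical(m2$metabolites$compartment,
                   model$metabolites$compartment)
  expect_identical(sort(m2$genes), sort(model$genes))
  expect_identical(m2$objective_id, model$objective_id)
}

test_that("JSON and SBML round trips preserve every field", {
  cases <- list(default_toy(),
                default_toy(include_tic = TRUE),
                default_toy(include_dead_ends = 2))
  for (toy in cases) {
    roundtrip_identical(toy$model, "json")
    roundtrip_identical(toy$model, "sbml")
  }
  # fractional and irrational bounds survive to full double precision
  m <- chain_model(uptake = pi, internal_ub = 1 / 3)
  roundtrip_identical(m, "json")
  roundtrip_identical(m, "sbml")
})

test_that("stoichiometric matrix columns mirror reaction stoichiometries", {
  m <- chain_model()
  S <- stoichiometric_matrix(m, sparse = FALSE)
  expect_equal(S[, "TRANS"], c(A = -1, B = 1))
  expect_equal(S[, "EX_A"], c(A = -1, B = 0))
  # column-consistency: every reaction is recoverable from its column
  toy <- default_toy()
  St <- stoichiometric_matrix(toy$model, sparse = FALSE)
  for (rx in toy$model$reactions) {
    col <- St[, rx$id]
    expect_equal(col[col != 0][names(rx$stoichiometry)],
                 rx$stoichiometry[names(rx$stoichiometry)])
  }
  # steady state holds for an actual FBA solution
  sol <- fba(toy$model)
  expect_lt(max(abs(St %*% sol$fluxes)), 1e-6)
})

test_that("model report counts match the generator's ground truth", {
  toy <- default_toy(include_tic = TRUE, include_dead_ends = 1,
                     include_minor_subsystem = TRUE)
  rep <- model_report(toy$model)
  expect_equal(rep$n_reactions, toy$ground_truth$n_reactions)
  expect_equal(rep$n_metabolites, toy$ground_truth$n_metabolites)
  expect_equal(rep$n_genes, toy$ground_truth$n_genes)
  expect_equal(sum(rep$subsystems[c("tic", "minor", "dead_end")]),
               2 + 4 + 1)
  empty <- metabolic_model(
    data.frame(id = character(), name = character(),
               compartment = character()),
    list(), objective_id = "none")
  erep <- model_report(empty)
  expect_equal(c(erep$n_reactions, erep$n_metabolites, erep$n_genes),
               c(0, 0, 0))
})

test_that("model integrity violations are rejected with offender names", {
  mets <- data.frame(id = c("A", "A"), name = "A", compartment = "c")
  expect_error(metabolic_model(mets, list(reaction("EX_A", c(A = -1))),
                               objective_id = "EX_A"), "duplicate")
  expect_error(reaction("R", c(A = 1), lower_bound = 2, upper_bound = 1),
               "lower_bound")
  mets2 <- data.frame(id = "A", name = "A", compartment = "c")
  expect_error(
    metabolic_model(mets2, list(reaction("EX_A", c(A = -1))),
                    objective_id = "nope"), "nope")
  expect_error(
    metabolic_model(mets2,
                    list(reaction("EX_A", c(A = -1, B = 1),
                                  is_exchange = TRUE)),
                    objective_id = "EX_A"), "exactly one")
})

test_that("exchange detection combines structure and EX_ prefix", {
  toy <- default_toy()
  ex <- detect_exchanges(toy$model, quiet = TRUE)
  expect_setequal(ex, c("EX_glyc", "EX_clav", "EX_suc", "EX_co2"))
  # a mis-flagged EX_ reaction is reported, prefix winning
  m <- chain_model()
  m$reactions$EX_A$is_exchange <- FALSE
  expect_message(detect_exchanges(m), "prefix wins")
})
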