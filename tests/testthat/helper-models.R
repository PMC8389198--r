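# shared fixtures, all built in code

# linear chain: EX_A (uptake, lb -10) -> A -> B -> EX_B
chain_model <- function(uptake = 10, internal_ub = 1000) {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c")
  metabolic_model(mets, list(
    reaction("EX_A", c(A = -1), -uptake, 0),
    reaction("TRANS", c(A = -1, B = 1), 0, internal_ub),
    reaction("EX_B", c(B = -1), 0, 1000)),
    objective_id = "EX_B")
}

# k independent in/out pairs; each pair spans one uniform degree of freedom
box_model <- function(widths = c(1, 2)) {
  k <- length(widths)
  ids <- paste0("M", seq_len(k))
  mets <- data.frame(id = ids, name = ids, compartment = "c")
  rxns <- list()
  for (i in seq_len(k)) {
    st_in <- stats::setNames(1, ids[i])
    st_out <- stats::setNames(-1, ids[i])
    rxns <- c(rxns, list(
      reaction(paste0("IN", i), st_in, 0, widths[i], is_exchange = FALSE),
      reaction(paste0("EX_M", i), st_out, 0, widths[i])))
  }
  metabolic_model(mets, rxns, objective_id = "EX_M1")
}

# 3-reaction fully reversible cycle plus one exchange
cycle_model <- function() {
  mets <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                     compartment = "c")
  metabolic_model(mets, list(
    reaction("R1", c(A = -1, B = 1), -10, 10),
    reaction("R2", c(B = -1, C = 1), -10, 10),
    reaction("R3", c(C = -1, A = 1), -10, 10),
    reaction("EX_A", c(A = -1), -5, 5)),
    objective_id = "EX_A")
}

default_toy <- function(...) generate_toy_network(toy_network_config(...))

expect_feasible_rows <- function(points, model, tol = 1e-6) {
  S <- stoichiometric_matrix(model, sparse = FALSE)
  expect_lt(max(abs(S %*% t(points))), tol)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  expect_lt(max(sweep(points, 2, ub, "-")), tol)
  expect_lt(max(sweep(-points, 2, -lb, "-")), tol)
}
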