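# Fixtures built in code: the 3-reaction chain model used throughout, and a
# random small-model generator for the oracle comparisons.

# EX_A (A[e] exchange, uptake to -5) -> R1 (A[e] -> B[c], ub 3) -> EX_B
chain_model <- function(r1_ub = 3, ex_a_lb = -5) {
  metabolic_model(
    data.frame(id = c("A[e]", "B[c]"), name = c("A", "B"),
               compartment = c("e", "c")),
    data.frame(id = c("EX_A", "R1", "EX_B"),
               lb = c(ex_a_lb, 0, -1000), ub = c(1000, r1_ub, 1000),
               subsystem = c("Exchange", "Chain", "Exchange"),
               gpr = c("", "g1", "")),
    list(c("A[e]" = -1), c("A[e]" = -1, "B[c]" = 1), c("B[c]" = -1)))
}

# Random small stoichiometric model; v = 0 is always feasible because every
# bound interval straddles (or touches) zero.
random_toy_model <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  m <- sample(2:(n - 2), 1)
  S <- matrix(0, m, n)
  for (j in seq_len(n)) {
    k <- sample(1:min(2, m), 1)
    rows <- sample.int(m, k)
    S[rows, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
  }
  lb <- round(runif(n, -10, 0), 2)
  lb[runif(n) < 0.4] <- 0
  ub <- round(runif(n, 0, 10), 2)
  mets <- data.frame(id = sprintf("M%d[c]", seq_len(m)),
                     name = sprintf("M%d", seq_len(m)), compartment = "c")
  stoich <- lapply(seq_len(n), function(j) {
    s <- S[, j]
    stats::setNames(s[s != 0], mets$id[s != 0])
  })
  rxns <- data.frame(id = sprintf("R%d", seq_len(n)), lb = lb, ub = ub,
                     subsystem = "s", gpr = "")
  metabolic_model(mets, rxns, stoich)
}
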