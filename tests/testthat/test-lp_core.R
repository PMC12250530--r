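test_that("FBA solves the bottleneck chain and closed systems", {
  m <- chain_model()
  r <- fba(m, "EX_B", "max")
  expect_equal(r$status, "optimal")
  expect_equal(r$value, 3)                       # min(5, 3)
  expect_lt(max(abs(stoich_matrix(m) %*% r$flux)), 1e-6)

  closed <- apply_medium(model_bounds(m), m, medium_table(numeric(0)))
  expect_equal(fba(m, "R1", "max", bounds = closed)$value, 0)
  expect_error(fba(m, "NOPE", "max"), "unknown objective")
})

test_that("FVA brackets the chain and degenerate reactions", {
  m <- chain_model()
  r <- fva(m)
  expect_equal(r$min[r$reaction == "R1"], 0)
  expect_equal(r$max[r$reaction == "R1"], 3)
  expect_true(all(r$min <= r$max + 1e-9))

  m0 <- chain_model(r1_ub = 0)                   # lb = ub = 0
  r0 <- fva(m0, "R1")
  expect_equal(c(r0$min, r0$max), c(0, 0))
})

test_that("FBA matches the vertex-enumeration oracle on random toy models", {
  for (seed in 1:20) {
    m <- random_toy_model(seed)
    j <- sample(nrow(m$rxns), 1)
    for (sense in c("max", "min")) {
      got <- fba(m, m$rxns$id[j], sense)
      want <- oracle_fba(m, m$rxns$id[j], sense)
      expect_equal(got$value, want, tolerance = 1e-6,
                   label = sprintf("seed %d %s", seed, sense))
    }
  }
})

test_that("fba objective is reproducible to 1e-9 across runs", {
  m <- random_toy_model(99)
  v1 <- fba(m, m$rxns$id[2], "max")$value
  v2 <- fba(m, m$rxns$id[2], "max")$value
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("infeasible bounds are reported, naming an exchange", {
  m <- chain_model()
  b <- model_bounds(m)
  b$lb["EX_B"] <- 500                            # forced secretion beyond supply
  b$ub["EX_B"] <- 1000
  expect_error(fva(m, bounds = b), "infeasible")
})

test_that("metabolite knockout blocks consumption only", {
  m <- chain_model()
  b <- knockout_metabolite(m, model_bounds(m), "A[e]")
  expect_equal(unname(b$ub["R1"]), 0)            # sole consumer blocked
  expect_equal(unname(b$lb["EX_A"]), -5)         # exchange untouched

  # only-produced metabolite: bounds unchanged
  b2 <- knockout_metabolite(m, model_bounds(m), "B[c]")
  expect_equal(b2$lb, model_bounds(m)$lb)
  expect_equal(b2$ub, model_bounds(m)$ub)

  # reversible consumer in reverse direction: lb raised to 0, ub kept
  m3 <- metabolic_model(
    data.frame(id = c("A[c]", "B[c]"), name = c("A", "B"), compartment = "c"),
    data.frame(id = c("R3", "EX_A", "EX_B"), lb = c(-10, -10, -10),
               ub = c(10, 10, 10), subsystem = "s", gpr = ""),
    list(c("A[c]" = -1, "B[c]" = 1), c("A[c]" = -1), c("B[c]" = -1)))
  b3 <- knockout_metabolite(m3, model_bounds(m3), "B[c]")
  expect_equal(unname(b3$lb["R3"]), 0)           # reverse consumes B
  expect_equal(unname(b3$ub["R3"]), 10)
  expect_error(knockout_metabolite(m, model_bounds(m), "Z[c]"), "unknown")
})

test_that("ko_effect_matrix has the documented structure on the chain", {
  m <- chain_model()
  M <- ko_effect_matrix(m)
  expect_true(all(M %in% c(-1L, 0L, 1L)))
  expect_equal(unname(M["A[e]", ]), c(0L, -1L, -1L))  # downstream all lose flux
  expect_equal(unname(M["B[c]", ]), c(0L, 0L, 0L))    # never consumed internally
})

test_that("knockouts only shrink the feasible region", {
  for (seed in c(4, 17)) {
    m <- random_toy_model(seed)
    wt <- fva(m)
    for (met in m$mets$id) {
      b <- knockout_metabolite(m, model_bounds(m), met)
      ko <- tryCatch(fva(m, bounds = b), error = function(e) NULL)
      if (is.null(ko)) next
      expect_true(all(ko$max <= wt$max + 1e-6), label = paste(seed, met))
    }
  }
})

test_that("flux_matrix summarises per-sample FVA deterministically", {
  net <- make_toy_network(2, 3, seed = 8)
  expr <- simulate_expression(net$model, net$truth, 3, 3, seed = 8)
  bs <- compute_vmax_bounds(net$model, expr, toy_kinetome(net$model))
  bs <- lapply(bs, apply_medium, model = net$model, medium = toy_medium(net$model))
  fm <- flux_matrix(net$model, bs)
  expect_equal(dim(fm), c(nrow(net$model$rxns), 6))
  expect_equal(attr(fm, "provenance"), "fva_max")
  fm2 <- flux_matrix(net$model, bs)
  expect_identical(fm, fm2)
  # mid summary is the FVA midpoint
  fmid <- flux_matrix(net$model, bs[1], summary = "mid")
  r <- fva(net$model, bounds = bs[[1]])
  expect_equal(unname(fmid[, 1]), (r$min + r$max) / 2, tolerance = 1e-9)
})
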