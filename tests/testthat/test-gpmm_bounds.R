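test_that("GPR evaluation: AND = min, OR = sum, empty = unbounded", {
  lv <- c(g1 = 4, g2 = 1, g3 = 2)
  expect_equal(evaluate_gpr("(g1 and g2)", lv), 1)
  expect_equal(evaluate_gpr("(g1 or g2)", lv), 5)
  expect_equal(evaluate_gpr("((g1 and g2) or g3)", lv), 3)
  expect_equal(evaluate_gpr("", lv), Inf)
  expect_equal(evaluate_gpr("g9", lv), 0)        # missing gene -> 0
  expect_equal(evaluate_gpr("G1 AND g2", c(G1 = 7, g2 = 3)), 3) # keywords case-insensitive
  expect_error(evaluate_gpr("(g1 and", lv), "grammar")
  expect_error(evaluate_gpr("g1 and and g2", lv), "grammar")
  expect_error(evaluate_gpr("(g1 or g2))", lv), "grammar")
})

test_that("GPR value is invariant under clause permutation", {
  set.seed(42)
  for (i in 1:20) {
    lv <- stats::setNames(runif(4, 0, 10), paste0("g", 1:4))
    a <- evaluate_gpr("(g1 or g2 or g3) and g4", lv)
    b <- evaluate_gpr("g4 and (g3 or g1 or g2)", lv)
    expect_equal(a, b)
  }
})

make_expr <- function(vals, labels = NULL) {
  labels <- labels %||% rep("case", ncol(vals))
  expression_matrix(vals, labels)
}

test_that("Vmax bounds follow scale * kcat * GPR, capped at the model bound", {
  m <- chain_model(r1_ub = 1000)
  kin <- kinetome_table(c(R1 = 2))
  expr <- make_expr(matrix(3, 1, 1, dimnames = list("g1", "s1")))
  b <- compute_vmax_bounds(m, expr, kin, scale = 1)[[1]]
  expect_equal(unname(b$ub["R1"]), 6)            # 1 * 2 * 3
  expect_equal(unname(b$ub["EX_A"]), 1000)       # no GPR -> untouched
  expect_equal(unname(b$lb["EX_A"]), -5)         # exchange lb untouched here

  # zero expression zeroes every GPR+kcat reaction
  b0 <- compute_vmax_bounds(m, make_expr(matrix(0, 1, 1,
          dimnames = list("g1", "s1"))), kin)[[1]]
  expect_equal(unname(b0$ub["R1"]), 0)

  # missing kcat: generic bound kept, unless a default kcat is given
  bnk <- compute_vmax_bounds(m, expr, kinetome_table(c(OTHER = 1)))[[1]]
  expect_equal(unname(bnk$ub["R1"]), 1000)
  bdk <- compute_vmax_bounds(m, expr,
                             kinetome_table(c(OTHER = 1), default_kcat = 1))[[1]]
  expect_equal(unname(bdk$ub["R1"]), 3)

  expect_error(compute_vmax_bounds(m, expr, kin, scale = 0), "positive")
})

test_that("reversible reactions are constrained symmetrically", {
  m <- metabolic_model(
    data.frame(id = c("A[c]", "B[c]"), name = c("A", "B"), compartment = "c"),
    data.frame(id = "R1", lb = -1000, ub = 1000, subsystem = "s", gpr = "g1"),
    list(c("A[c]" = -1, "B[c]" = 1)))
  b <- compute_vmax_bounds(m, make_expr(matrix(4, 1, 1,
         dimnames = list("g1", "s1"))), kinetome_table(c(R1 = 1)))[[1]]
  expect_equal(unname(b$ub["R1"]), 4)
  expect_equal(unname(b$lb["R1"]), -4)
})

test_that("expression scaling is monotone in the computed bounds", {
  net <- make_toy_network(2, 3, seed = 3)
  expr <- simulate_expression(net$model, net$truth, 3, 3, seed = 3)
  kin <- toy_kinetome(net$model)
  b1 <- compute_vmax_bounds(net$model, expr, kin)[[1]]
  expr2 <- expression_matrix(expr$values * 1.7, expr$labels)
  b2 <- compute_vmax_bounds(net$model, expr2, kin)[[1]]
  expect_true(all(b2$ub >= b1$ub - 1e-12))
})

test_that("apply_medium opens listed exchanges and closes the rest", {
  m <- metabolic_model(
    data.frame(id = c("glc[e]", "o2[e]", "g6p[c]"),
               name = c("glc", "o2", "g6p"), compartment = c("e", "e", "c")),
    data.frame(id = c("EX_glc", "EX_o2", "HEX"),
               lb = c(-1000, -1000, 0), ub = c(1000, 1000, 1000),
               subsystem = "s", gpr = ""),
    list(c("glc[e]" = -1), c("o2[e]" = -1), c("glc[e]" = -1, "g6p[c]" = 1)))
  b <- apply_medium(model_bounds(m), m, medium_table(c(EX_glc = -10)))
  expect_equal(unname(b$lb["EX_glc"]), -10)
  expect_equal(unname(b$lb["EX_o2"]), 0)
  expect_equal(unname(b$ub["EX_o2"]), 1000)      # secretion unchanged

  b2 <- apply_medium(model_bounds(m), m, medium_table(numeric(0)))
  expect_equal(unname(b2$lb[c("EX_glc", "EX_o2")]), c(0, 0))

  expect_error(apply_medium(model_bounds(m), m, medium_table(c(HEX = -1))),
               "non-exchange")
  expect_error(medium_table(c(EX_glc = 5)), "<= 0")
})

test_that("planted knockdown shows up as ~0.25 mean bound ratio", {
  net <- make_toy_network(4, 4, seed = 11)
  expr <- simulate_expression(net$model, net$truth, 10, 10, seed = 11)
  kin <- toy_kinetome(net$model)
  bs <- compute_vmax_bounds(net$model, expr, kin)
  planted <- net$truth$planted_reactions
  case_ub <- rowMeans(sapply(bs[expr$labels == "case"],
                             function(b) b$ub[planted]))
  ctrl_ub <- rowMeans(sapply(bs[expr$labels == "control"],
                             function(b) b$ub[planted]))
  ratio <- mean(case_ub / ctrl_ub)
  expect_gt(ratio, 0.2)
  expect_lt(ratio, 0.3)
})
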