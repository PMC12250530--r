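fake_diff <- function(sign, subsystem = NULL) {
  data.frame(reaction = sprintf("R%03d", seq_along(sign)),
             log2fc = sign, p = ifelse(sign == 0, 0.5, 0.001),
             significant = sign != 0, sign = sign,
             stringsAsFactors = FALSE)
}

test_that("DA score arithmetic and bounds", {
  sgn <- c(rep(1, 4), rep(-1, 1), rep(0, 5))
  diff <- fake_diff(sgn)
  subs <- stats::setNames(rep("P1", 10), diff$reaction)
  res <- da_score(diff, subs)
  expect_equal(res$da, 0.3)
  expect_equal(res[, c("n_reactions", "n_up", "n_down")],
               data.frame(n_reactions = 10L, n_up = 4L, n_down = 1L))

  # all-down / all-up attain the bounds
  down <- fake_diff(rep(-1, 5))
  expect_equal(da_score(down, stats::setNames(rep("P", 5), down$reaction))$da, -1)
  up <- fake_diff(rep(1, 5))
  expect_equal(da_score(up, stats::setNames(rep("P", 5), up$reaction))$da, 1)

  # no significant reactions -> all zero
  nil <- fake_diff(rep(0, 6))
  subs2 <- stats::setNames(rep(c("A", "B"), 3), nil$reaction)
  expect_equal(da_score(nil, subs2)$da, c(0, 0))

  expect_error(da_score(diff, character(0)), "empty subsystem map")
})

test_that("signed significant calls partition across subsystems", {
  set.seed(9)
  sgn <- sample(c(-1, 0, 1), 60, replace = TRUE)
  diff <- fake_diff(sgn)
  subs <- stats::setNames(sample(c("A", "B", "C"), 60, replace = TRUE),
                          diff$reaction)
  res <- da_score(diff, subs)
  expect_equal(sum(res$n_up - res$n_down), sum(sgn))
})

test_that("bootstrap p-values: degenerate cases and determinism", {
  sgn <- c(rep(-1, 3), rep(0, 17))
  diff <- fake_diff(sgn)
  subs <- stats::setNames(c(rep("hit", 3), rep("rest", 17)), diff$reaction)
  r1 <- bootstrap_da_pvalue(diff, subs, B = 500, seed = 42)
  r2 <- bootstrap_da_pvalue(diff, subs, B = 500, seed = 42)
  expect_identical(r1, r2)                       # deterministic given seed
  expect_true(all(r1$p >= 1 / 501))

  # observed da = 0 -> p = 1
  nil <- fake_diff(rep(0, 10))
  rn <- bootstrap_da_pvalue(nil, stats::setNames(rep("P", 10), nil$reaction),
                            B = 200, seed = 1)
  expect_equal(rn$p, 1)

  # subsystem containing every reaction: every draw equals the observed set
  all1 <- fake_diff(c(rep(-1, 4), rep(1, 2)))
  ra <- bootstrap_da_pvalue(all1, stats::setNames(rep("P", 6), all1$reaction),
                            B = 200, seed = 1)
  expect_equal(ra$p, 1)

  expect_error(bootstrap_da_pvalue(diff, subs, B = 500), "seed")
  expect_error(bootstrap_da_pvalue(diff, subs, B = 10, seed = 1), ">= 100")
})

test_that("a planted concentrated subsystem gets a small p", {
  sgn <- c(rep(-1, 8), rep(0, 2), rep(0, 90))
  sgn[11:14] <- c(1, -1, 1, -1)                  # background noise
  diff <- fake_diff(sgn)
  subs <- stats::setNames(c(rep("planted", 10), rep("bg", 90)), diff$reaction)
  res <- bootstrap_da_pvalue(diff, subs, B = 2000, seed = 7)
  expect_lt(res$p[res$subsystem == "planted"], 0.01)
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.6)
  # step-up by hand: 0.005, 0.02, 0.065->0.05125, 0.05125, 0.6
  expect_equal(adjust_fdr(p), c(0.005, 0.02, 0.05125, 0.05125, 0.6))
  expect_true(all(adjust_fdr(p) >= p))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("da_table flags pathways with the joint FDR/effect gate", {
  sgn <- c(rep(-1, 9), 0, rep(0, 40))
  diff <- fake_diff(sgn)
  subs <- stats::setNames(c(rep("hit", 10), rep("bg", 40)), diff$reaction)
  res <- da_table(diff, subs, B = 2000, seed = 3)
  expect_true(res$significant[res$subsystem == "hit"])
  expect_false(res$significant[res$subsystem == "bg"])
  expect_equal(res$subsystem[1], "hit")          # sorted by da, most negative first
})
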