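null_flux <- function(n_rxn, n1 = 10, n2 = 10, seed = 1, sigma = 0.1) {
  set.seed(seed)
  baseline <- rlnorm(n_rxn, log(5), 1)
  vals <- baseline * matrix(rlnorm(n_rxn * (n1 + n2), 0, sigma), n_rxn)
  dimnames(vals) <- list(sprintf("R%04d", seq_len(n_rxn)),
                         sprintf("s%02d", seq_len(n1 + n2)))
  list(flux = vals, labels = rep(c("case", "control"), c(n1, n2)))
}

test_that("log2 fold change follows the pseudocount formula", {
  flux <- matrix(c(4, 4, 2, 2,
                   3, 3, 3, 3,
                   0, 0, 0, 0), 3, 4, byrow = TRUE,
                 dimnames = list(c("a", "b", "z"), NULL))
  labels <- c("case", "case", "control", "control")
  fc <- suppressMessages(log2_fold_change(flux, labels, pseudocount = 0))
  expect_equal(unname(fc), c(1, 0, 0))           # 0/0 case defined as 0
  fc2 <- log2_fold_change(flux, labels, pseudocount = 1)
  expect_equal(unname(fc2["a"]), log2(5 / 3))
  expect_error(log2_fold_change(flux, rep("case", 4)), "control")
})

test_that("moderated t with prior_df = 0 equals the ordinary pooled t", {
  nf <- null_flux(50, 6, 8, seed = 2)
  tab <- moderated_t_test(nf$flux, nf$labels, prior_df = 0)
  xc <- nf$flux[, nf$labels == "case"]
  xk <- nf$flux[, nf$labels == "control"]
  n1 <- ncol(xc); n2 <- ncol(xk)
  sp2 <- (apply(xc, 1, var) * (n1 - 1) + apply(xk, 1, var) * (n2 - 1)) /
    (n1 + n2 - 2)
  t_ref <- (rowMeans(xc) - rowMeans(xk)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_ref <- 2 * pt(-abs(t_ref), n1 + n2 - 2)
  expect_equal(tab$t_mod, unname(t_ref), tolerance = 1e-9)
  expect_equal(tab$p, unname(p_ref), tolerance = 1e-9)
})

test_that("moderated t agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  nf <- null_flux(200, 8, 7, seed = 3)
  tab <- moderated_t_test(nf$flux, nf$labels)
  design <- cbind(1, nf$labels == "case")
  fit <- limma::eBayes(limma::lmFit(nf$flux, design))
  expect_equal(tab$d0[1], fit$df.prior, tolerance = 1e-6)
  expect_equal(tab$s02[1], fit$s2.prior, tolerance = 1e-6)
  expect_equal(tab$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(tab$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("constant and degenerate rows are handled", {
  flux <- rbind(const = rep(2, 8), noise = c(rnorm(8, 10)))
  labels <- rep(c("case", "control"), each = 4)
  tab <- moderated_t_test(flux, labels)
  expect_equal(tab$t_mod[1], 0)
  expect_equal(tab$p[1], 1)
  # all reactions identical in both groups -> all p = 1
  allc <- matrix(5, 4, 8)
  rownames(allc) <- paste0("r", 1:4)
  tab2 <- moderated_t_test(allc, labels)
  expect_equal(tab2$p, rep(1, 4))
  expect_error(moderated_t_test(flux, c("case", rep("control", 7))), ">= 2")
})

test_that("label swap negates log2fc and t and preserves p", {
  nf <- null_flux(80, 6, 6, seed = 4)
  swapped <- ifelse(nf$labels == "case", "control", "case")
  t1 <- diff_flux_table(nf$flux, nf$labels, pseudocount = 0)
  t2 <- diff_flux_table(nf$flux, swapped, pseudocount = 0)
  expect_equal(t1$log2fc, -t2$log2fc)
  expect_equal(t1$t_mod, -t2$t_mod)
  expect_equal(t1$p, t2$p)
})

test_that("p-values are invariant under a per-reaction additive shift", {
  nf <- null_flux(40, 5, 5, seed = 5)
  shifted <- nf$flux + 100
  expect_equal(moderated_t_test(nf$flux, nf$labels)$p,
               moderated_t_test(shifted, nf$labels)$p, tolerance = 1e-9)
})

test_that("significance calls apply both gates with the documented signs", {
  tab <- data.frame(reaction = c("a", "b", "c", "d"),
                    log2fc = c(0.5, 0.1, -1, -0.5),
                    p = c(0.01, 0.01, 0.2, 0.001))
  out <- call_significant(tab)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$sign, c(1, 0, 0, -1))
  expect_equal(unname(attr(out, "counts")), c(1, 1))
  expect_error(call_significant(tab, p_threshold = 2), "p_threshold")
})

test_that("null simulation: p uniform, type-I rate near nominal", {
  nf <- null_flux(1000, 10, 10, seed = 6)
  tab <- moderated_t_test(nf$flux, nf$labels)
  expect_gt(ks.test(tab$p, "punif")$p.value, 0.01)
  rate <- mean(tab$p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("planted knockdown drives the subsystem's fold changes down", {
  net <- make_toy_network(4, 4, seed = 21)
  expr <- simulate_expression(net$model, net$truth, 10, 10, seed = 21)
  bs <- compute_vmax_bounds(net$model, expr, toy_kinetome(net$model))
  bs <- lapply(bs, apply_medium, model = net$model,
               medium = toy_medium(net$model))
  fm <- flux_matrix(net$model, bs)
  fc <- log2_fold_change(fm, expr$labels)
  expect_lt(median(fc[net$truth$planted_reactions]), -0.2)
})
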