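# Case-vs-control differential flux statistics. The per-reaction two-group
# linear model is moderated with the standard empirical-Bayes variance
# shrinkage: residual variances are shrunk toward a common prior whose
# scale s0^2 and degrees of freedom d0 are estimated by the method of
# moments on the log residual variances; the moderated t uses the posterior
# variance (d0*s0^2 + d*s^2)/(d0 + d) with d0 + d degrees of freedom. The
# machinery is implemented from the published formulas so it is testable
# against the d0 -> 0 ordinary-t limit (and cross-checked against limma in
# the test suite).

#' Per-reaction log2 fold change (case vs control)
#'
#' `log2((mean_case + eps) / (mean_control + eps))`. With both means and
#' `eps` equal to zero the fold change is defined as 0.
#'
#' @param flux reactions x samples matrix.
#' @param labels per-sample `"case"`/`"control"` vector.
#' @param pseudocount `eps`; default 1e-6 of the grand mean flux.
#' @return named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(flux, labels, pseudocount = NULL) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(flux))
  if (sum(labels == "case") < 1L || sum(labels == "control") < 1L)
    stop("need at least one case and one control sample")
  if (is.null(pseudocount)) pseudocount <- 1e-6 * mean(abs(flux))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  mc <- rowMeans(flux[, labels == "case", drop = FALSE])
  mk <- rowMeans(flux[, labels == "control", drop = FALSE])
  fc <- log2((mc + pseudocount) / (mk + pseudocount))
  zero <- (mc + pseudocount == 0) & (mk + pseudocount == 0)
  if (any(zero)) {
    fc[zero] <- 0
    message(sum(zero), " reaction(s) with zero flux in both groups; log2fc set to 0")
  }
  stats::setNames(fc, rownames(flux))
}

# Method-of-moments fit of a scaled-F prior to sample variances s2 with df
# degrees of freedom each (Smyth 2004 eqs. for fitFDist). Returns d0 (may be
# Inf) and s0^2. Zero/near-zero variances are excluded from the fit.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 1e-300
  if (sum(ok) < 2L)
    return(list(d0 = Inf, s02 = if (any(ok)) exp(mean(log(s2[ok]))) else 1))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = exp(ebar)))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of trigamma (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated two-group t-test per reaction
#'
#' @param flux reactions x samples matrix.
#' @param labels per-sample `"case"`/`"control"` vector (>= 2 per group).
#' @param prior_df `NULL` to estimate `d0` from the data (the default);
#'   `0` forces the ordinary two-sample pooled t; `Inf` fully shrinks to the
#'   common prior variance.
#' @param log_transform log2-transform fluxes (with the [log2_fold_change()]
#'   pseudocount) before testing. Default `FALSE`: fluxes enter untransformed.
#' @return data.frame with columns `reaction`, `log2fc` (NA; filled by
#'   [diff_flux_table()]), `t_mod`, `p`, `df_total`, `d0`, `s02`.
#' @export
moderated_t_test <- function(flux, labels, prior_df = NULL,
                             log_transform = FALSE) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(flux))
  n1 <- sum(labels == "case")
  n2 <- sum(labels == "control")
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  x <- flux
  if (log_transform) {
    eps <- 1e-6 * mean(abs(flux))
    x <- log2(flux + eps)
  }
  xc <- x[, labels == "case", drop = FALSE]
  xk <- x[, labels == "control", drop = FALSE]
  d <- n1 + n2 - 2
  mdiff <- rowMeans(xc) - rowMeans(xk)
  ssq <- (rowSums((xc - rowMeans(xc))^2) + rowSums((xk - rowMeans(xk))^2))
  s2 <- ssq / d
  su <- sqrt(1 / n1 + 1 / n2)

  if (is.null(prior_df)) {
    fit <- fit_variance_prior(s2, d)
  } else if (prior_df == 0) {
    fit <- list(d0 = 0, s02 = 0)
  } else {
    est <- fit_variance_prior(s2, d)
    fit <- list(d0 = prior_df, s02 = est$s02)
  }
  if (is.infinite(fit$d0)) {
    s2post <- rep(fit$s02, length(s2))
    dftot <- rep(Inf, length(s2))
  } else {
    s2post <- (fit$d0 * fit$s02 + d * s2) / (fit$d0 + d)
    dftot <- rep(fit$d0 + d, length(s2))
  }

  tmod <- mdiff / (su * sqrt(s2post))
  p <- 2 * stats::pt(-abs(tmod), df = dftot)
  # constant flux across all samples carries no evidence
  const <- s2 < 1e-300 & abs(mdiff) < 1e-300
  tmod[const] <- 0
  p[const] <- 1
  bad <- !is.finite(tmod)
  tmod[bad] <- 0
  p[bad] <- 1
  data.frame(reaction = rownames(flux), log2fc = NA_real_, t_mod = tmod,
             p = p, df_total = dftot, d0 = fit$d0, s02 = fit$s02,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag significantly changed fluxes
#'
#' A reaction is significant iff `p < p_threshold` and
#' `|log2fc| > fc_threshold`; its `sign` is the sign of `log2fc` when
#' significant and 0 otherwise.
#'
#' @param table data.frame with `p` and `log2fc` columns.
#' @param p_threshold p-value gate in (0, 1); default 0.05.
#' @param fc_threshold |log2fc| gate (> 0 allowed to be 0 to disable);
#'   default 0.2.
#' @return the table with `significant` and `sign` columns set.
#' @export
call_significant <- function(table, p_threshold = 0.05, fc_threshold = 0.2) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must be in (0, 1)")
  if (!is.numeric(fc_threshold) || fc_threshold < 0)
    stop("fc_threshold must be >= 0")
  table$significant <- table$p < p_threshold & abs(table$log2fc) > fc_threshold
  table$sign <- ifelse(table$significant, sign(table$log2fc), 0)
  n_up <- sum(table$sign > 0)
  n_down <- sum(table$sign < 0)
  attr(table, "counts") <- c(up = n_up, down = n_down)
  table
}

#' Full differential flux table
#'
#' Convenience wrapper: fold changes, moderated test, significance calls.
#'
#' @inheritParams moderated_t_test
#' @inheritParams call_significant
#' @param pseudocount passed to [log2_fold_change()].
#' @return a `DiffFluxTable` data.frame (`reaction`, `log2fc`, `t_mod`, `p`,
#'   `significant`, `sign`).
#' @export
diff_flux_table <- function(flux, labels, p_threshold = 0.05,
                            fc_threshold = 0.2, pseudocount = NULL,
                            prior_df = NULL, log_transform = FALSE) {
  tab <- moderated_t_test(flux, labels, prior_df = prior_df,
                          log_transform = log_transform)
  tab$log2fc <- unname(log2_fold_change(flux, labels, pseudocount))
  call_significant(tab, p_threshold, fc_threshold)
}
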