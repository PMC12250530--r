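# Pathway-level Differential Abundance scoring. Per subsystem i,
#   DA_i = (# up-regulated fluxes - # down-regulated fluxes) / (# reactions)
# using the significance calls of the differential flux table, so
# DA is in [-1, 1]. Significance of DA comes from a size-matched
# "bootstrap without replacement" null: B subsets of the same size drawn
# uniformly without replacement from all scored reactions.

#' Differential Abundance score per subsystem
#'
#' @param diff a `DiffFluxTable` (needs `reaction`, `significant`, `sign`).
#' @param subsystems named character vector mapping reaction id -> subsystem,
#'   or a `metabolic_model` (its reaction table is used).
#' @return data.frame with `subsystem`, `n_reactions`, `n_up`, `n_down`,
#'   `da`; subsystems with no scored reaction are excluded.
#' @export
da_score <- function(diff, subsystems) {
  subsystems <- as_subsystem_map(subsystems)
  if (length(subsystems) == 0L) stop("empty subsystem map")
  sub <- subsystems[diff$reaction]
  if (anyNA(sub))
    stop("reaction without subsystem: ", diff$reaction[which(is.na(sub))[1]])
  sgn <- diff$sign
  res <- do.call(rbind, lapply(split(seq_along(sgn), sub), function(idx) {
    up <- sum(sgn[idx] > 0)
    dn <- sum(sgn[idx] < 0)
    data.frame(n_reactions = length(idx), n_up = up, n_down = dn,
               da = (up - dn) / length(idx))
  }))
  res <- data.frame(subsystem = rownames(res), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  res[order(res$subsystem), , drop = FALSE]
}

as_subsystem_map <- function(x) {
  if (inherits(x, "metabolic_model"))
    return(stats::setNames(x$rxns$subsystem, x$rxns$id))
  x
}

#' Bootstrap-without-replacement p-values for DA scores
#'
#' For each subsystem of size k, draws `B` size-k reaction subsets uniformly
#' without replacement from all scored reactions and recomputes the null DA;
#' the two-sided empirical p-value is
#' `(1 + #\{|DA_null| >= |DA_obs|\}) / (B + 1)`, never smaller than
#' `1 / (B + 1)`.
#'
#' @inheritParams da_score
#' @param B number of null draws (>= 100).
#' @param seed integer seed (mandatory: reproducibility is part of the
#'   contract).
#' @return the [da_score()] table with a `p` column.
#' @export
bootstrap_da_pvalue <- function(diff, subsystems, B = 10000, seed) {
  if (missing(seed)) stop("seed is required")
  if (B < 100) stop("B must be >= 100")
  obs <- da_score(diff, subsystems)
  x <- diff$sign                       # in {-1, 0, 1}
  n <- length(x)
  if (any(obs$n_reactions > n)) stop("subsystem larger than the reaction set")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  obs$p <- vapply(seq_len(nrow(obs)), function(i) {
    k <- obs$n_reactions[i]
    null_da <- vapply(seq_len(B), function(b) sum(x[sample.int(n, k)]) / k,
                      numeric(1))
    (1 + sum(abs(null_da) >= abs(obs$da[i]) - 1e-12)) / (B + 1)
  }, numeric(1))
  obs
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return step-up adjusted values (monotone in the sorted order).
#' @export
adjust_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Full pathway DA result table
#'
#' DA scores, bootstrap p-values, BH FDR, and the significance call
#' (`fdr < fdr_threshold` and `|da| > da_threshold`). Sorted by `da`.
#'
#' @inheritParams bootstrap_da_pvalue
#' @param fdr_threshold default 0.05.
#' @param da_threshold default 0.2.
#' @return `DAResult` data.frame.
#' @export
da_table <- function(diff, subsystems, B = 10000, seed,
                     fdr_threshold = 0.05, da_threshold = 0.2) {
  res <- bootstrap_da_pvalue(diff, subsystems, B = B, seed = seed)
  res$fdr <- adjust_fdr(res$p)
  res$significant <- res$fdr < fdr_threshold & abs(res$da) > da_threshold
  res[order(res$da), , drop = FALSE]
}
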