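# Metabolite Effective Scores. For metabolite i,
#   MES_i = sum_j M[i, j] * sign(log2fc_j) * L_j
# where M is the knockout effect matrix and L_j weights reaction j's
# differential-flux evidence (by default the 0/1 significance indicator, so
# only differentially changed fluxes contribute). A positive MES means the
# knockout exacerbates the patient-direction flux changes, i.e. the
# metabolite is an agonist: supplementing it is predicted to rescue them.

#' Metabolite Effective Scores from a knockout matrix
#'
#' @param M knockout effect matrix (metabolites x reactions, entries in
#'   {-1, 0, 1}), e.g. from [ko_effect_matrix()].
#' @param diff a `DiffFluxTable` covering (at least) the columns of `M`.
#' @param l_weight `"indicator"` (L_j = 1 for significant reactions, else 0;
#'   the default) or `"abs_log2fc"` (L_j = |log2fc_j|, restricted to
#'   significant reactions).
#' @return named numeric vector of MES values.
#' @export
mes_scores <- function(M, diff, l_weight = c("indicator", "abs_log2fc")) {
  l_weight <- match.arg(l_weight)
  idx <- match(colnames(M), diff$reaction)
  if (anyNA(idx))
    stop("knockout matrix column not in the differential flux table: ",
         colnames(M)[which(is.na(idx))[1]])
  sgn <- sign(diff$log2fc[idx])
  L <- as.numeric(diff$significant[idx])
  if (l_weight == "abs_log2fc") L <- L * abs(diff$log2fc[idx])
  drop(M %*% (sgn * L))
}

#' Norm-background p-values for MES values
#'
#' Fits a normal background to the full MES vector (mean/sd, or median/MAD
#' with `robust = TRUE`) and reports the two-sided tail probability of each
#' metabolite's score, plus the BH FDR.
#'
#' @param mes named numeric vector (>= 10 metabolites).
#' @param robust use median/MAD instead of mean/sd.
#' @return data.frame with `metabolite`, `mes`, `p`, `fdr`.
#' @export
mes_pvalues <- function(mes, robust = FALSE) {
  if (length(mes) < 10L) stop("need >= 10 metabolites for a norm background")
  mu <- if (robust) stats::median(mes) else mean(mes)
  sigma <- if (robust) stats::mad(mes) else stats::sd(mes)
  if (!is.finite(sigma) || sigma == 0) {
    message("degenerate MES background (sd = 0); all p set to 1")
    p <- rep(1, length(mes))
  } else {
    p <- 2 * stats::pnorm(-abs(mes - mu) / sigma)
  }
  data.frame(metabolite = names(mes) %||% as.character(seq_along(mes)),
             mes = unname(mes), p = p, fdr = adjust_fdr(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify metabolites as agonist / antagonist / neutral
#'
#' Agonist: `mes > 0` and `fdr < fdr_threshold` (its knockout exacerbates
#' the patient flux changes, so supplementation is the predicted rescue).
#' Antagonist: `mes < 0` and `fdr < fdr_threshold`. Otherwise neutral.
#'
#' @param table data.frame with `mes` and `fdr` columns.
#' @param fdr_threshold default 0.05.
#' @return the table with a `class` column.
#' @export
classify_mes <- function(table, fdr_threshold = 0.05) {
  table$class <- ifelse(table$fdr < fdr_threshold & table$mes > 0, "agonist",
                 ifelse(table$fdr < fdr_threshold & table$mes < 0, "antagonist",
                        "neutral"))
  table
}

#' Full MES table
#'
#' @inheritParams mes_scores
#' @inheritParams mes_pvalues
#' @inheritParams classify_mes
#' @return `MESTable` data.frame sorted by decreasing `mes`.
#' @export
mes_table <- function(M, diff, l_weight = c("indicator", "abs_log2fc"),
                      robust = FALSE, fdr_threshold = 0.05) {
  mes <- mes_scores(M, diff, l_weight)
  tab <- classify_mes(mes_pvalues(mes, robust), fdr_threshold)
  tab[order(-tab$mes), , drop = FALSE]
}
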