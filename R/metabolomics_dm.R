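# Paired pre/post-exertion metabolomics contrast. For each metabolite i the
# per-subject paired change is Delta = log2(PEM) - log2(baseline); the
# Differential Metabolite statistic is
#   DM_i = mean(Delta_i | patients) - mean(Delta_i | controls),
# tested with the same empirical-Bayes moderated two-sample machinery as the
# flux contrast. The paired design removes subject-level offsets exactly.

#' Validate a long-format metabolite abundance table
#'
#' @param tab data.frame with columns `metabolite`, `subject`, `group`
#'   (`patient`/`control`), `timepoint` (`baseline`/`PEM`), `tissue`,
#'   `abundance` (> 0).
#' @return the table, invisibly; errors name the offending cell.
#' @export
validate_metabolomics <- function(tab) {
  need <- c("metabolite", "subject", "group", "timepoint", "tissue", "abundance")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("metabolomics table missing column: ", missing[1])
  if (!all(tab$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'")
  if (!all(tab$timepoint %in% c("baseline", "PEM")))
    stop("timepoint must be 'baseline' or 'PEM'")
  bad <- which(!is.finite(tab$abundance) | tab$abundance <= 0)
  if (length(bad))
    stop("non-positive abundance for metabolite ", tab$metabolite[bad[1]],
         ", subject ", tab$subject[bad[1]], ", timepoint ",
         tab$timepoint[bad[1]])
  key <- paste(tab$tissue, tab$metabolite, tab$subject, tab$timepoint)
  if (anyDuplicated(key))
    stop("duplicate observation: ", key[duplicated(key)][1])
  invisible(tab)
}

#' Read a long-format metabolomics TSV
#' @param path TSV with the [validate_metabolomics()] columns.
#' @return validated data.frame.
#' @export
read_metabolomics <- function(path) {
  tab <- read_tsv(path)
  validate_metabolomics(tab)
  tab
}

#' Per-subject paired log2 changes
#'
#' One `Delta = log2(PEM) - log2(baseline)` per (subject, metabolite,
#' tissue). Subjects missing one of the two timepoints for a metabolite are
#' dropped with a logged count.
#'
#' @param tab a validated metabolomics table.
#' @return data.frame with `tissue`, `metabolite`, `subject`, `group`,
#'   `delta`.
#' @export
paired_log2_change <- function(tab) {
  validate_metabolomics(tab)
  base <- tab[tab$timepoint == "baseline", ]
  pem <- tab[tab$timepoint == "PEM", ]
  key <- function(d) paste(d$tissue, d$metabolite, d$subject, sep = "\r")
  i <- match(key(pem), key(base))
  dropped <- sum(is.na(i)) + sum(!key(base) %in% key(pem))
  if (dropped > 0)
    message(dropped, " observation(s) without a matching pair dropped")
  keep <- !is.na(i)
  data.frame(tissue = pem$tissue[keep],
             metabolite = pem$metabolite[keep],
             subject = pem$subject[keep],
             group = pem$group[keep],
             delta = log2(pem$abundance[keep]) - log2(base$abundance[i[keep]]),
             stringsAsFactors = FALSE)
}

#' Differential Metabolite statistics (patients vs controls)
#'
#' `dm = mean(Delta | patients) - mean(Delta | controls)` per metabolite,
#' with a moderated two-sample test on the paired changes and BH FDR.
#' Call once per tissue.
#'
#' @param deltas output of [paired_log2_change()] (one tissue).
#' @param prior_df see [moderated_t_test()].
#' @return `DMTable` data.frame with `metabolite`, `dm`, `t_mod`, `p`, `fdr`.
#' @export
dm_statistic <- function(deltas, prior_df = NULL) {
  if (length(unique(deltas$tissue)) > 1L)
    stop("dm_statistic expects a single tissue; split the table first")
  mets <- sort(unique(deltas$metabolite))
  subj <- unique(deltas[, c("subject", "group")])
  if (anyDuplicated(subj$subject))
    stop("subject assigned to more than one group")
  for (g in c("patient", "control"))
    if (sum(subj$group == g) < 2L)
      stop("need >= 2 subjects per group (", g, ")")
  D <- matrix(NA_real_, length(mets), nrow(subj),
              dimnames = list(mets, subj$subject))
  D[cbind(match(deltas$metabolite, mets), match(deltas$subject, subj$subject))] <-
    deltas$delta
  complete <- stats::complete.cases(D)
  if (!all(complete))
    message(sum(!complete), " metabolite(s) dropped for incomplete pairs")
  D <- D[complete, , drop = FALSE]
  labels <- ifelse(subj$group == "patient", "case", "control")
  tab <- moderated_t_test(D, labels, prior_df = prior_df)
  dm <- rowMeans(D[, labels == "case", drop = FALSE]) -
    rowMeans(D[, labels == "control", drop = FALSE])
  data.frame(metabolite = rownames(D), dm = unname(dm), t_mod = tab$t_mod,
             p = tab$p, fdr = adjust_fdr(tab$p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-tissue DM tables
#' @param tab a validated metabolomics table (any number of tissues).
#' @inheritParams dm_statistic
#' @return named list of `DMTable` data.frames, one per tissue.
#' @export
dm_table <- function(tab, prior_df = NULL) {
  deltas <- paired_log2_change(tab)
  lapply(split(deltas, deltas$tissue), dm_statistic, prior_df = prior_df)
}
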