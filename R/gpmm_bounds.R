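# Expression-constrained bound setting. Per-sample enzyme abundance is read
# off the GPR rule (AND = min over complex subunits, OR = sum over isozymes)
# and converted to a Michaelis-Menten capacity Vmax = scale * kcat * E that
# caps the reaction's flux. The nutrient medium then fixes exchange uptake:
# listed exchanges get their uptake lower bound, every other exchange is
# closed to uptake (lb = 0).

#' Build an expression matrix object
#'
#' @param values genes x samples non-negative matrix with dimnames.
#' @param labels per-sample factor/character, levels `case` and `control`.
#' @return list of class `expression_matrix` with `values` and `labels`.
#' @export
expression_matrix <- function(values, labels) {
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ", colnames(values)[duplicated(colnames(values))][1])
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("one label per sample required")
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  structure(list(values = values, labels = labels),
            class = "expression_matrix")
}

#' Read an expression TSV plus its sample sheet
#'
#' @param path genes x samples TSV (first column gene id).
#' @param samples_path TSV with columns `sample`, `label`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, samples_path) {
  vals <- read_matrix_tsv(path)
  ss <- read_tsv(samples_path)
  if (!all(colnames(vals) %in% ss$sample))
    stop("sample sheet is missing samples present in the expression matrix")
  labels <- ss$label[match(colnames(vals), ss$sample)]
  expression_matrix(vals, labels)
}

#' Read a kinetome table (reaction -> kcat)
#'
#' @param path TSV with columns `reaction_id`, `kcat_per_s`.
#' @param default_kcat fallback kcat for unlisted reactions (`NA` = none;
#'   unlisted reactions then keep their generic model bound).
#' @return named numeric vector with attribute `default`.
#' @export
read_kinetome <- function(path, default_kcat = NA_real_) {
  k <- read_tsv(path)
  kinetome_table(stats::setNames(k$kcat_per_s, k$reaction_id), default_kcat)
}

#' @rdname read_kinetome
#' @param kcat named numeric vector of kcat values (1/s), reaction ids as names.
#' @export
kinetome_table <- function(kcat, default_kcat = NA_real_) {
  if (any(kcat <= 0, na.rm = TRUE)) stop("kcat values must be positive")
  attr(kcat, "default") <- default_kcat
  kcat
}

#' Read a medium table (exchange -> uptake lower bound)
#'
#' @param path TSV with columns `exchange_id`, `uptake_lb` (values <= 0).
#' @return named numeric vector.
#' @export
read_medium <- function(path) {
  m <- read_tsv(path)
  medium_table(stats::setNames(m$uptake_lb, m$exchange_id))
}

#' @rdname read_medium
#' @param uptake named numeric vector, exchange reaction id -> uptake lower
#'   bound (mmol/gDW/h, non-positive).
#' @export
medium_table <- function(uptake) {
  if (any(uptake > 0)) stop("medium uptake bounds must be <= 0")
  uptake
}

new_bound_set <- function(sample, lb, ub) {
  if (any(lb > ub + 1e-12)) stop("bound set with lb > ub")
  structure(list(sample = sample, lb = lb, ub = ub), class = "bound_set")
}

#' Per-sample Michaelis-Menten Vmax bounds
#'
#' For every reaction with a non-empty GPR and a kcat, the sample's upper
#' bound becomes `min(model ub, scale * kcat * E)` where `E` is
#' [evaluate_gpr()] of the sample's gene levels. Reversible reactions are
#' constrained symmetrically (`lb = max(model lb, -Vmax)`): enzyme capacity
#' is direction-agnostic. Reactions with an empty GPR or no kcat keep their
#' generic bounds; exchange lower bounds are not touched here (see
#' [apply_medium()]).
#'
#' @param model a `metabolic_model`.
#' @param expr an [expression_matrix()].
#' @param kinetome a [kinetome_table()].
#' @param scale global abundance calibration constant (> 0). Default 1: in
#'   toy units expression is already on the enzyme-abundance scale.
#' @return list of `bound_set` objects, one per sample (named lb/ub vectors
#'   over reactions).
#' @export
compute_vmax_bounds <- function(model, expr, kinetome, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive number")
  rx <- model$rxns
  kdef <- attr(kinetome, "default") %||% NA_real_
  kcat <- kinetome[rx$id]
  kcat[is.na(kcat)] <- kdef
  constrained <- !vapply(model$gpr_ast, is.null, logical(1)) & !is.na(kcat)

  lapply(seq_len(ncol(expr$values)), function(s) {
    lv <- stats::setNames(expr$values[, s], rownames(expr$values))
    lb <- stats::setNames(rx$lb, rx$id)
    ub <- stats::setNames(rx$ub, rx$id)
    for (j in which(constrained)) {
      e <- eval_gpr_ast(model$gpr_ast[[j]], lv)
      vmax <- scale * kcat[j] * e
      ubj <- min(ub[j], vmax)
      lbj <- if (rx$lb[j] < 0) max(lb[j], -vmax) else lb[j]
      ub[j] <- ubj
      lb[j] <- min(lbj, ubj)
    }
    new_bound_set(colnames(expr$values)[s], lb, ub)
  })
}

#' Apply a nutrient medium to a bound set
#'
#' Exchanges listed in the medium get their uptake lower bound from it;
#' every other exchange has its lower bound raised to 0 (no uptake).
#' Secretion upper bounds are unchanged.
#'
#' @param bounds a `bound_set` (or plain list with named `lb`, `ub`).
#' @param model the `metabolic_model` the bounds belong to.
#' @param medium a [medium_table()]; may be empty (all uptake closed).
#' @return the modified `bound_set`.
#' @export
apply_medium <- function(bounds, model, medium) {
  ex <- identify_exchanges(model)
  bad <- setdiff(names(medium), ex)
  if (length(bad))
    stop("medium names a non-exchange reaction: ", bad[1])
  lb <- bounds$lb
  ub <- bounds$ub
  other <- setdiff(ex, names(medium))
  lb[other] <- 0
  lb[names(medium)] <- unname(medium)
  lb[names(medium)] <- pmin(lb[names(medium)], ub[names(medium)])
  new_bound_set(bounds$sample %||% "model", lb, ub)
}

#' Generic bounds of a model as a bound set
#'
#' @param model a `metabolic_model`.
#' @param sample label to attach.
#' @return a `bound_set` with the model's own lb/ub.
#' @export
model_bounds <- function(model, sample = "model") {
  new_bound_set(sample,
                stats::setNames(model$rxns$lb, model$rxns$id),
                stats::setNames(model$rxns$ub, model$rxns$id))
}
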