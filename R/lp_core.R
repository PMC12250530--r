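# Flux balance analysis, flux variability analysis, and in-silico metabolite
# knockout on a bounded model. All linear programs share the compiled
# two-phase simplex (src/simplex.cpp); per bound set, feasibility is
# established once and each objective re-uses the feasible tableau.

lp_inputs <- function(model, bounds = NULL) {
  if (is.null(bounds)) bounds <- model_bounds(model)
  ids <- model$rxns$id
  lb <- bounds$lb[ids]
  ub <- bounds$ub[ids]
  if (anyNA(lb) || anyNA(ub))
    stop("bound set does not cover every reaction of the model")
  list(S = stoich_matrix(model), lb = unname(lb), ub = unname(ub), ids = ids)
}

lp_status_label <- function(code) {
  c("optimal", "infeasible", "unbounded", "iteration_limit")[code + 1L]
}

infeasibility_diagnostic <- function(model, inp) {
  ex <- identify_exchanges(model)
  idx <- match(ex, inp$ids)
  forced <- ex[inp$lb[idx] > 0 | inp$ub[idx] < 0]
  if (length(forced))
    return(paste0("model infeasible; first forced exchange: ", forced[1],
                  " [", inp$lb[match(forced[1], inp$ids)], ", ",
                  inp$ub[match(forced[1], inp$ids)], "]"))
  paste0("model infeasible under the given bounds; exchange bounds: ",
         paste0(ex, "[", signif(inp$lb[idx], 4), ",", signif(inp$ub[idx], 4),
                "]", collapse = " "))
}

#' Flux balance analysis
#'
#' Solves `max/min v_obj` subject to `S v = 0`, `lb <= v <= ub`.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimise.
#' @param sense `"max"` or `"min"`.
#' @param bounds optional `bound_set`; defaults to the model's generic bounds.
#' @return list with `value`, `flux` (named vector satisfying constraints to
#'   1e-6 when optimal), and `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`).
#' @export
fba <- function(model, objective, sense = c("max", "min"), bounds = NULL) {
  sense <- match.arg(sense)
  inp <- lp_inputs(model, bounds)
  j <- match(objective, inp$ids)
  if (is.na(j)) stop("unknown objective reaction: ", objective)
  obj <- matrix(0, 1, length(inp$ids))
  obj[1, j] <- 1
  res <- lp_solve_cpp(inp$S, inp$lb, inp$ub, obj,
                      if (sense == "max") 1L else -1L, TRUE)
  status <- if (!res$feasible) "infeasible" else lp_status_label(res$status[1])
  flux <- NULL
  if (status == "optimal") {
    flux <- stats::setNames(res$solution[, 1], inp$ids)
    resid <- max(abs(inp$S %*% flux))
    if (resid > 1e-6)
      stop("LP solution violates mass balance (residual ", signif(resid, 3), ")")
  }
  list(value = if (status == "optimal") res$value[1] else NA_real_,
       flux = flux, status = status)
}

#' Flux variability analysis
#'
#' Per reaction, the minimum and maximum attainable steady-state flux over
#' the bounded feasible region. No objective-optimality constraint is
#' imposed: the ranges describe the whole feasible set.
#'
#' @inheritParams fba
#' @param reactions reaction ids to scan (default: all).
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, reactions = NULL, bounds = NULL) {
  inp <- lp_inputs(model, bounds)
  if (is.null(reactions)) reactions <- inp$ids
  idx <- match(reactions, inp$ids)
  if (anyNA(idx)) stop("unknown reaction: ", reactions[which(is.na(idx))[1]])
  k <- length(idx)
  obj <- matrix(0, 2L * k, length(inp$ids))
  obj[cbind(seq_len(k), idx)] <- 1
  obj[cbind(k + seq_len(k), idx)] <- 1
  senses <- c(rep(-1L, k), rep(1L, k))
  res <- lp_solve_cpp(inp$S, inp$lb, inp$ub, obj, senses, FALSE)
  if (!res$feasible) stop(infeasibility_diagnostic(model, inp))
  if (any(res$status != 0L))
    stop("FVA subproblem not optimal (status ",
         lp_status_label(res$status[which(res$status != 0L)[1]]), ")")
  data.frame(reaction = reactions,
             min = res$value[seq_len(k)],
             max = res$value[k + seq_len(k)],
             stringsAsFactors = FALSE)
}

# Internal: feasibility + FVA maxima only (used by the knockout screen).
fva_max <- function(inp, idx) {
  k <- length(idx)
  obj <- matrix(0, k, length(inp$ids))
  obj[cbind(seq_len(k), idx)] <- 1
  res <- lp_solve_cpp(inp$S, inp$lb, inp$ub, obj, rep(1L, k), FALSE)
  if (!res$feasible) return(NULL)
  res$value
}

#' Summarise per-sample flux capacities into a flux matrix
#'
#' Runs FVA under each sample's bounds and keeps one scalar per reaction:
#' the FVA maximum (capacity-like, the default) or the range midpoint.
#'
#' @param model a `metabolic_model`.
#' @param bound_sets list of `bound_set` objects (e.g. from
#'   [compute_vmax_bounds()] + [apply_medium()]).
#' @param summary `"max"` or `"mid"`.
#' @return reactions x samples matrix with attribute
#'   `provenance` = `"fva_max"` or `"fva_mid"`.
#' @export
flux_matrix <- function(model, bound_sets, summary = c("max", "mid")) {
  summary <- match.arg(summary)
  ids <- model$rxns$id
  vals <- vapply(bound_sets, function(b) {
    if (summary == "max") {
      inp <- lp_inputs(model, b)
      v <- fva_max(inp, seq_along(ids))
      if (is.null(v)) stop(infeasibility_diagnostic(model, inp))
      v
    } else {
      r <- fva(model, bounds = b)
      (r$min + r$max) / 2
    }
  }, numeric(length(ids)))
  dimnames(vals) <- list(ids, vapply(bound_sets, function(b)
    b$sample %||% "", character(1)))
  attr(vals, "provenance") <- paste0("fva_", summary)
  vals
}

#' Knock out a metabolite by blocking its consumption
#'
#' Every non-exchange reaction that can consume the metabolite loses the
#' consuming direction: forward consumers (negative coefficient) get
#' `ub = 0`, reverse consumers (positive coefficient, reversible) get
#' `lb = 0`. Production and exchange reactions are untouched, mimicking
#' removal of the metabolite pool from the network.
#'
#' @param model a `metabolic_model`.
#' @param bounds a `bound_set`.
#' @param metabolite metabolite id.
#' @return the modified `bound_set`.
#' @export
knockout_metabolite <- function(model, bounds, metabolite) {
  metabolite <- normalize_met_id(metabolite)
  if (!metabolite %in% model$mets$id)
    stop("unknown metabolite: ", metabolite)
  ex <- identify_exchanges(model)
  lb <- bounds$lb
  ub <- bounds$ub
  for (j in seq_along(model$stoich)) {
    id <- model$rxns$id[j]
    if (id %in% ex) next
    coef <- model$stoich[[j]][metabolite]
    if (is.na(coef) || coef == 0) next
    if (coef < 0) {          # consumed at forward flux
      ub[id] <- min(ub[id], 0)
      lb[id] <- min(lb[id], ub[id])
    } else {                 # consumed at reverse flux
      lb[id] <- max(lb[id], 0)
      ub[id] <- max(ub[id], lb[id])
    }
  }
  new_bound_set(bounds$sample %||% "model", lb, ub)
}

#' All-against-all metabolite knockout effect matrix
#'
#' Builds the knockout matrix M(KO): rows are metabolites, columns
#' reactions. `M[i, j]` is -1 if knocking out metabolite i lowers reaction
#' j's FVA maximum by more than the tolerance, +1 if it raises it, else 0.
#' Wild-type FVA maxima are computed once and reused. If a knockout model is
#' infeasible its whole row is -1 for reactions with a non-trivial wild-type
#' maximum (0 otherwise) and a message is logged.
#'
#' @param model a `metabolic_model`.
#' @param bounds the reference `bound_set` (wild type).
#' @param metabolites metabolite ids (default: all).
#' @param reactions reaction ids forming the columns (default: all).
#' @param tol relative change tolerance.
#' @param tol_abs absolute change floor.
#' @return integer matrix in {-1, 0, 1} with dimnames.
#' @export
ko_effect_matrix <- function(model, bounds = NULL, metabolites = NULL,
                             reactions = NULL, tol = 1e-6, tol_abs = 1e-9) {
  if (is.null(bounds)) bounds <- model_bounds(model)
  if (is.null(metabolites)) metabolites <- model$mets$id
  if (is.null(reactions)) reactions <- model$rxns$id
  inp <- lp_inputs(model, bounds)
  idx <- match(reactions, inp$ids)
  if (anyNA(idx)) stop("unknown reaction: ", reactions[which(is.na(idx))[1]])

  wt <- fva_max(inp, idx)
  if (is.null(wt)) stop(infeasibility_diagnostic(model, inp))

  M <- matrix(0L, length(metabolites), length(reactions),
              dimnames = list(normalize_met_id(metabolites), reactions))
  thresh <- pmax(tol * abs(wt), tol_abs)
  for (i in seq_along(metabolites)) {
    kb <- knockout_metabolite(model, bounds, metabolites[i])
    kinp <- lp_inputs(model, kb)
    ko <- fva_max(kinp, idx)
    if (is.null(ko)) {
      message("knockout of ", metabolites[i],
              " makes the model infeasible; row set to -1 where wild-type max > tol")
      M[i, ] <- ifelse(wt > thresh, -1L, 0L)
      next
    }
    M[i, ] <- ifelse(ko < wt - thresh, -1L, ifelse(ko > wt + thresh, 1L, 0L))
  }
  M
}
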