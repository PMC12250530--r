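# Independent oracles, deliberately naive:
#  * vertex enumeration of {v : S v = 0, lb <= v <= ub} for exact FBA/FVA
#    reference values on models with <= 8 reactions;
#  * a per-cell LP recomputation of the knockout effect matrix with its own
#    bound-editing logic.

oracle_vertices <- function(S, lb, ub) {
  n <- ncol(S)
  r <- qr(S)$rank
  nfix <- n - r
  verts <- list()
  push <- function(v) {
    if (max(abs(S %*% v)) < 1e-7 &&
        all(v >= lb - 1e-7) && all(v <= ub + 1e-7))
      verts[[length(verts) + 1]] <<- pmin(pmax(v, lb), ub)
  }
  if (nfix == 0) {
    push(rep(0, n))
    return(verts)
  }
  combs <- utils::combn(n, nfix)
  for (ci in seq_len(ncol(combs))) {
    fixed <- combs[, ci]
    free <- setdiff(seq_len(n), fixed)
    qrf <- qr(S[, free, drop = FALSE])
    if (qrf$rank < length(free)) next
    for (mask in seq_len(2^nfix) - 1) {
      at_ub <- bitwAnd(mask, 2^(seq_len(nfix) - 1)) > 0
      a <- ifelse(at_ub, ub[fixed], lb[fixed])
      if (any(!is.finite(a))) next
      rhs <- -S[, fixed, drop = FALSE] %*% a
      x <- qr.coef(qrf, rhs)
      v <- numeric(n)
      v[fixed] <- a
      v[free] <- x
      push(v)
    }
  }
  verts
}

oracle_fba <- function(model, objective, sense = "max") {
  S <- stoich_matrix(model)
  v <- oracle_vertices(S, model$rxns$lb, model$rxns$ub)
  if (!length(v)) return(NA_real_)
  j <- match(objective, model$rxns$id)
  vals <- vapply(v, function(x) x[j], numeric(1))
  if (sense == "max") max(vals) else min(vals)
}

oracle_fva <- function(model, bounds = NULL) {
  S <- stoich_matrix(model)
  lb <- if (is.null(bounds)) model$rxns$lb else unname(bounds$lb[model$rxns$id])
  ub <- if (is.null(bounds)) model$rxns$ub else unname(bounds$ub[model$rxns$id])
  v <- oracle_vertices(S, lb, ub)
  if (!length(v)) return(NULL)
  V <- do.call(cbind, v)
  data.frame(reaction = model$rxns$id,
             min = apply(V, 1, min), max = apply(V, 1, max))
}

# Independent knockout semantics: edit bounds straight from the signed
# stoichiometry, then measure each column with its own per-cell LP.
oracle_ko_matrix <- function(model, tol = 1e-6, tol_abs = 1e-9) {
  ids <- model$rxns$id
  ex <- identify_exchanges(model)
  wt <- vapply(ids, function(j) fba(model, j, "max")$value, numeric(1))
  thresh <- pmax(tol * abs(wt), tol_abs)
  M <- matrix(0L, nrow(model$mets), length(ids),
              dimnames = list(model$mets$id, ids))
  for (i in seq_len(nrow(model$mets))) {
    met <- model$mets$id[i]
    b <- model_bounds(model)
    for (j in seq_along(ids)) {
      if (ids[j] %in% ex) next
      coef <- model$stoich[[j]][met]
      if (is.na(coef) || coef == 0) next
      if (coef < 0) b$ub[ids[j]] <- min(b$ub[ids[j]], 0)
      else b$lb[ids[j]] <- max(b$lb[ids[j]], 0)
    }
    b$lb <- pmin(b$lb, b$ub)
    for (j in seq_along(ids)) {
      ko <- fba(model, ids[j], "max", bounds = b)
      if (ko$status != "optimal") {
        M[i, j] <- if (wt[j] > thresh[j]) -1L else 0L
      } else {
        M[i, j] <- if (ko$value < wt[j] - thresh[j]) -1L
                   else if (ko$value > wt[j] + thresh[j]) 1L else 0L
      }
    }
  }
  M
}
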