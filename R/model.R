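#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` bundles a stoichiometric network: metabolites
#' (compartment-qualified ids), reactions (sparse stoichiometry, flux bounds
#' in mmol/gDW/h, a pathway/subsystem label, and a gene-protein-reaction
#' rule), and the gene universe. It is the container every pipeline stage
#' consumes.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#'   Ids may use either the `met[c]` or `met_c` compartment syntax; they are
#'   normalised to the bracket form.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `subsystem`,
#'   `gpr` (infix boolean text over gene ids; `""` means unconstrained).
#' @param stoichiometry list, parallel to `reactions`, of named numeric
#'   vectors mapping metabolite id to signed coefficient (negative =
#'   consumed at forward flux).
#' @param genes character vector of gene ids. Defaults to the union of the
#'   genes appearing in the GPR rules.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = NULL) {
  metabolites$id <- normalize_met_id(as.character(metabolites$id))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  stoichiometry <- lapply(stoichiometry, function(s) {
    names(s) <- normalize_met_id(names(s))
    s
  })
  gpr_ast <- lapply(as.character(reactions$gpr), parse_gpr)
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(gpr_ast, gpr_genes))))
    if (is.null(genes)) genes <- character(0)
  }
  model <- structure(list(
    mets = data.frame(id = metabolites$id,
                      name = as.character(metabolites$name),
                      compartment = as.character(metabolites$compartment),
                      stringsAsFactors = FALSE),
    rxns = data.frame(id = as.character(reactions$id),
                      lb = as.numeric(reactions$lb),
                      ub = as.numeric(reactions$ub),
                      subsystem = as.character(reactions$subsystem),
                      gpr = as.character(reactions$gpr),
                      stringsAsFactors = FALSE),
    stoich = stoichiometry,
    gpr_ast = gpr_ast,
    genes = as.character(genes)
  ), class = "metabolic_model")
  validate_metabolic_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, non-empty compartments, `lb <= ub`, non-empty
#' stoichiometries referencing known metabolites, and that every gene used
#' in a GPR is in the model's gene list.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; errors describe the offending record.
#' @export
validate_metabolic_model <- function(model) {
  mets <- model$mets
  rxns <- model$rxns
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite id: ", mets$id[duplicated(mets$id)][1])
  if (anyDuplicated(rxns$id))
    stop("duplicate reaction id: ", rxns$id[duplicated(rxns$id)][1])
  if (any(!nzchar(mets$compartment)))
    stop("metabolite with empty compartment: ",
         mets$id[!nzchar(mets$compartment)][1])
  if (length(model$stoich) != nrow(rxns))
    stop("stoichiometry list length does not match reaction table")
  bad <- which(rxns$lb > rxns$ub)
  if (length(bad))
    stop("reaction ", rxns$id[bad[1]], ": lb > ub")
  for (i in seq_len(nrow(rxns))) {
    s <- model$stoich[[i]]
    if (length(s) == 0L || all(s == 0))
      stop("reaction ", rxns$id[i], ": empty stoichiometry")
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown))
      stop("reaction ", rxns$id[i], ": unknown metabolite ", unknown[1])
  }
  used <- unique(unlist(lapply(model$gpr_ast, gpr_genes)))
  missing <- setdiff(used, model$genes)
  if (length(missing))
    stop("GPR gene not in model gene list: ", missing[1])
  invisible(model)
}

# Accept "asp_L[c]" and "asp_c"; normalise the single-letter "_x" suffix
# (lower case, common compartment letters only) to the bracket form.
normalize_met_id <- function(ids) {
  plain <- !grepl("\\[[a-z0-9]+\\]$", ids)
  suf <- plain & grepl("_[cemxrgln]$", ids)
  ids[suf] <- sub("_([cemxrgln])$", "[\\1]", ids[suf])
  ids
}

#' Dense stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$mets), nrow(model$rxns),
              dimnames = list(model$mets$id, model$rxns$id))
  for (j in seq_along(model$stoich)) {
    s <- model$stoich[[j]]
    S[names(s), j] <- s
  }
  S
}

#' Identify exchange (boundary) reactions
#'
#' Exchanges are the reactions whose stoichiometry involves exactly one
#' metabolite; negative flux is uptake, positive flux secretion.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids, in model order.
#' @export
identify_exchanges <- function(model) {
  n <- vapply(model$stoich, function(s) sum(s != 0), integer(1))
  model$rxns$id[n == 1L]
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$mets), "metabolites,",
      nrow(x$rxns), "reactions,", length(x$genes), "genes\n")
  cat("  subsystems:", length(unique(x$rxns$subsystem)),
      " exchanges:", length(identify_exchanges(x)), "\n")
  invisible(x)
}
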