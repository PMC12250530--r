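# Model readers/writers. Two dialects:
#  * "cobra-json": the common COBRA JSON export (metabolites / reactions /
#    genes arrays; bounds as lower_bound/upper_bound; GPR as
#    gene_reaction_rule). Annotations and FBC extras are ignored.
#  * "tabular": a hand-editable three-file TSV directory
#    (metabolites.tsv, reactions.tsv with "A[c]:-1;B[c]:1" stoichiometry
#    strings and infix GPR text, genes.tsv).

#' Read a metabolic model
#'
#' @param path file (`cobra-json`) or directory (`tabular`).
#' @param format `"cobra-json"` or `"tabular"`.
#' @return a validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("cobra-json", "tabular")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model path does not exist: ", path)
  if (format == "cobra-json") read_model_json(path) else read_model_tabular(path)
}

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (fld in c("metabolites", "reactions"))
    if (is.null(doc[[fld]]))
      stop("malformed cobra-json model (missing '", fld, "'): ", path)
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
    name = vapply(doc$metabolites, function(m)
      if (is.null(m$name)) as.character(m$id) else as.character(m$name),
      character(1)),
    compartment = vapply(doc$metabolites, function(m)
      if (is.null(m$compartment)) "" else as.character(m$compartment),
      character(1)),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = vapply(doc$reactions, function(r) as.character(r$id), character(1)),
    lb = vapply(doc$reactions, function(r) as.numeric(r$lower_bound), numeric(1)),
    ub = vapply(doc$reactions, function(r) as.numeric(r$upper_bound), numeric(1)),
    subsystem = vapply(doc$reactions, function(r)
      if (is.null(r$subsystem)) "" else as.character(r$subsystem), character(1)),
    gpr = vapply(doc$reactions, function(r)
      if (is.null(r$gene_reaction_rule)) "" else as.character(r$gene_reaction_rule),
      character(1)),
    stringsAsFactors = FALSE)
  stoich <- lapply(doc$reactions, function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s)) stop("reaction ", r$id, ": empty stoichiometry")
    storage.mode(s) <- "double"
    s
  })
  genes <- if (is.null(doc$genes)) NULL else
    vapply(doc$genes, function(g) as.character(g$id), character(1))
  metabolic_model(mets, rxns, stoich, genes)
}

parse_stoich_string <- function(txt, rxn_id) {
  parts <- strsplit(trimws(txt), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  if (!length(parts))
    stop("reaction ", rxn_id, ": empty stoichiometry string")
  ids <- character(length(parts))
  coef <- numeric(length(parts))
  for (k in seq_along(parts)) {
    i <- regexpr(":[^:]*$", parts[k])  # split at last ':' (ids may contain ':')
    if (i < 1) stop("reaction ", rxn_id, ": malformed stoichiometry term '",
                    parts[k], "'")
    ids[k] <- trimws(substr(parts[k], 1, i - 1))
    coef[k] <- suppressWarnings(as.numeric(substr(parts[k], i + 1, nchar(parts[k]))))
    if (is.na(coef[k]))
      stop("reaction ", rxn_id, ": non-numeric coefficient in '", parts[k], "'")
  }
  stats::setNames(coef, ids)
}

deparse_stoich <- function(s) {
  paste(paste0(names(s), ":", format(s, trim = TRUE, digits = 15,
                                     scientific = FALSE)),
        collapse = ";")
}

read_model_tabular <- function(dir) {
  files <- file.path(dir, c("metabolites.tsv", "reactions.tsv", "genes.tsv"))
  for (f in files[1:2])
    if (!file.exists(f)) stop("missing tabular model file: ", f)
  mets <- utils::read.delim(files[1], stringsAsFactors = FALSE,
                            comment.char = "#")
  rx <- utils::read.delim(files[2], stringsAsFactors = FALSE,
                          comment.char = "#",
                          colClasses = c(gpr = "character"))
  rx$gpr[is.na(rx$gpr)] <- ""
  genes <- if (file.exists(files[3])) {
    g <- utils::read.delim(files[3], stringsAsFactors = FALSE,
                           comment.char = "#")
    as.character(g$id)
  } else NULL
  stoich <- mapply(parse_stoich_string, rx$stoichiometry, rx$id,
                   SIMPLIFY = FALSE, USE.NAMES = FALSE)
  rxns <- rx[, c("id", "lb", "ub", "subsystem", "gpr")]
  metabolic_model(mets, rxns, stoich, genes)
}

#' Write a metabolic model
#'
#' Inverse of [read_model()]; `read_model(write_model(m, ...))` reproduces
#' every field.
#'
#' @param model a `metabolic_model`.
#' @param path output file (`cobra-json`) or directory (`tabular`).
#' @param format `"cobra-json"` or `"tabular"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("cobra-json", "tabular")) {
  format <- match.arg(format)
  validate_metabolic_model(model)
  if (format == "cobra-json") {
    doc <- list(
      metabolites = lapply(seq_len(nrow(model$mets)), function(i)
        list(id = model$mets$id[i], name = model$mets$name[i],
             compartment = model$mets$compartment[i])),
      reactions = lapply(seq_len(nrow(model$rxns)), function(i)
        list(id = model$rxns$id[i],
             metabolites = as.list(model$stoich[[i]]),
             lower_bound = model$rxns$lb[i],
             upper_bound = model$rxns$ub[i],
             subsystem = model$rxns$subsystem[i],
             gene_reaction_rule = model$rxns$gpr[i])),
      genes = lapply(model$genes, function(g) list(id = g))
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    write_tsv(model$mets, file.path(path, "metabolites.tsv"))
    rx <- model$rxns
    rx$stoichiometry <- vapply(model$stoich, deparse_stoich, character(1))
    rx <- rx[, c("id", "stoichiometry", "lb", "ub", "subsystem", "gpr")]
    write_tsv(rx, file.path(path, "reactions.tsv"))
    write_tsv(data.frame(id = model$genes), file.path(path, "genes.tsv"))
  }
  invisible(path)
}
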