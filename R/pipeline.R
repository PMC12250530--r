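# Pipeline orchestration. A study directory holds the inputs named by a
# JSON config (JSON is read as the config dialect because it is a YAML
# subset and needs no extra reader); every stage writes TSV outputs with a
# provenance header (package version, config hash, seed) so reruns with the
# same config and seed are byte-identical.

#' Default pipeline configuration
#'
#' Thresholds default to the published analysis conventions: DE fluxes at
#' `p < 0.05` and `|log2fc| > 0.2`; pathways at `FDR < 0.05` and
#' `|DA| > 0.2`; agonists/antagonists at `FDR < 0.05`.
#'
#' @return named list of config values.
#' @export
default_config <- function() {
  list(
    model = "model", model_format = "tabular",
    expression = "expression.tsv", samples = "samples.tsv",
    kinetome = "kinetome.tsv", medium = "medium.tsv",
    metabolomics = "metabolomics.tsv",
    scale = 1, default_kcat = NA, fva_summary = "max",
    p_threshold = 0.05, fc_threshold = 0.2,
    fdr_threshold = 0.05, da_threshold = 0.2,
    B = 10000, seed = 1,
    l_weight = "indicator", robust_fit = FALSE,
    ko_columns = "significant", log_transform = FALSE
  )
}

read_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  cfg <- utils::modifyList(default_config(),
                           jsonlite::fromJSON(path, simplifyVector = TRUE))
  cfg
}

provenance_header <- function(cfg) {
  ver <- as.character(utils::packageVersion("fluxscreen"))
  hash <- config_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  c(paste0("fluxscreen ", ver),
    paste0("config: ", hash),
    paste0("seed: ", cfg$seed))
}

need_input <- function(path, what) {
  if (!file.exists(path))
    stop("missing input for this stage: ", what, " (", path, ")")
  path
}

pipeline_model <- function(cfg, dir) {
  read_model(need_input(file.path(dir, cfg$model), "model"),
             format = cfg$model_format)
}

pipeline_bound_sets <- function(cfg, dir, model) {
  expr <- read_expression(need_input(file.path(dir, cfg$expression), "expression"),
                          need_input(file.path(dir, cfg$samples), "sample sheet"))
  kin <- read_kinetome(need_input(file.path(dir, cfg$kinetome), "kinetome"),
                       default_kcat = if (is.null(cfg$default_kcat)) NA_real_
                                      else as.numeric(cfg$default_kcat))
  med <- read_medium(need_input(file.path(dir, cfg$medium), "medium"))
  bs <- compute_vmax_bounds(model, expr, kin, scale = cfg$scale)
  bs <- lapply(bs, apply_medium, model = model, medium = med)
  list(bounds = bs, expr = expr, kinetome = kin, medium = med)
}

stage_model <- function(cfg, dir, outdir) {
  model <- pipeline_model(cfg, dir)
  parts <- pipeline_bound_sets(cfg, dir, model)
  fm <- flux_matrix(model, parts$bounds, summary = cfg$fva_summary)
  hdr <- c(provenance_header(cfg),
           paste0("provenance: ", attr(fm, "provenance")))
  write_matrix_tsv(fm, file.path(outdir, "flux_matrix.tsv"),
                   id_col = "reaction", header = hdr)
  invisible(fm)
}

stage_diff <- function(cfg, dir, outdir) {
  fm <- read_matrix_tsv(need_input(file.path(outdir, "flux_matrix.tsv"),
                                   "flux matrix (run 'model' first)"))
  labels <- stage_labels(cfg, dir, colnames(fm))
  diff <- diff_flux_table(fm, labels, p_threshold = cfg$p_threshold,
                          fc_threshold = cfg$fc_threshold,
                          log_transform = cfg$log_transform)
  write_tsv(diff, file.path(outdir, "diff_flux.tsv"),
            header = provenance_header(cfg))
  invisible(diff)
}

stage_labels <- function(cfg, dir, samples) {
  ss <- read_tsv(need_input(file.path(dir, cfg$samples), "sample sheet"))
  lab <- ss$label[match(samples, ss$sample)]
  if (anyNA(lab)) stop("sample sheet is missing sample: ",
                       samples[which(is.na(lab))[1]])
  ifelse(lab == "case", "case", "control")
}

stage_da <- function(cfg, dir, outdir) {
  diff <- read_diff_table(outdir)
  model <- pipeline_model(cfg, dir)
  da <- da_table(diff, model, B = cfg$B, seed = cfg$seed,
                 fdr_threshold = cfg$fdr_threshold,
                 da_threshold = cfg$da_threshold)
  write_tsv(da, file.path(outdir, "da_scores.tsv"),
            header = provenance_header(cfg))
  invisible(da)
}

read_diff_table <- function(outdir) {
  diff <- read_tsv(need_input(file.path(outdir, "diff_flux.tsv"),
                              "differential flux table (run 'diff' first)"))
  diff$significant <- as.logical(diff$significant)
  diff
}

# Reference bounds for the knockout screen: the control-group mean
# expression under the study medium (the wild-type state the knockouts are
# measured against).
reference_bounds <- function(cfg, dir, model) {
  parts <- pipeline_bound_sets(cfg, dir, model)
  expr <- parts$expr
  ref <- matrix(rowMeans(expr$values[, expr$labels == "control", drop = FALSE]),
                ncol = 1, dimnames = list(rownames(expr$values), "reference"))
  b <- compute_vmax_bounds(model, expression_matrix(ref, "control"),
                           parts$kinetome, scale = cfg$scale)[[1]]
  apply_medium(b, model, parts$medium)
}

stage_ko <- function(cfg, dir, outdir) {
  diff <- read_diff_table(outdir)
  model <- pipeline_model(cfg, dir)
  ref <- reference_bounds(cfg, dir, model)
  cols <- if (identical(cfg$ko_columns, "significant")) {
    diff$reaction[diff$significant]
  } else model$rxns$id
  if (!length(cols)) {
    message("no significant reactions; knockout screen runs on all columns")
    cols <- model$rxns$id
  }
  M <- ko_effect_matrix(model, ref, reactions = cols)
  write_matrix_tsv(M, file.path(outdir, "ko_matrix.tsv"),
                   id_col = "metabolite", header = provenance_header(cfg))
  mes <- mes_table(M, diff, l_weight = cfg$l_weight,
                   robust = cfg$robust_fit, fdr_threshold = cfg$fdr_threshold)
  write_tsv(mes, file.path(outdir, "mes.tsv"),
            header = provenance_header(cfg))
  invisible(mes)
}

stage_dm <- function(cfg, dir, outdir) {
  path <- file.path(dir, cfg$metabolomics)
  tab <- read_metabolomics(need_input(path, "metabolomics"))
  res <- dm_table(tab)
  for (tissue in names(res))
    write_tsv(res[[tissue]], file.path(outdir, paste0("dm_", tissue, ".tsv")),
              header = provenance_header(cfg))
  invisible(res)
}

#' Run pipeline stages
#'
#' Subcommands: `simulate` (write a synthetic study into `outdir`),
#' `model` (expression-constrained bounds + per-sample FVA -> flux matrix),
#' `diff` (differential flux), `da` (pathway DA scores), `ko` (knockout
#' matrix + MES), `dm` (paired metabolomics contrast), `all` (the flux chain
#' and, if a metabolomics input is present, the DM chain).
#'
#' @param subcommand one of the above.
#' @param config path to a JSON config file (see [default_config()]);
#'   ignored by `simulate`.
#' @param outdir output directory; for analysis stages defaults to
#'   `<study>/results`.
#' @param dir study directory holding the inputs; defaults to the config
#'   file's directory.
#' @param seed optional seed override.
#' @return invisibly, the last stage's result.
#' @export
run_pipeline <- function(subcommand = c("simulate", "model", "diff", "da",
                                        "ko", "dm", "all"),
                         config = NULL, outdir = NULL, dir = NULL,
                         seed = NULL) {
  subcommand <- match.arg(subcommand)
  if (subcommand == "simulate") {
    if (is.null(outdir)) stop("simulate needs --outdir")
    return(invisible(write_study(outdir, seed = seed %||% 1L)))
  }
  if (is.null(config)) stop("missing --config")
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(dir)) dir <- dirname(config)
  if (is.null(outdir)) outdir <- file.path(dir, "results")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  res <- switch(subcommand,
    model = stage_model(cfg, dir, outdir),
    diff = stage_diff(cfg, dir, outdir),
    da = stage_da(cfg, dir, outdir),
    ko = stage_ko(cfg, dir, outdir),
    dm = stage_dm(cfg, dir, outdir),
    all = {
      stage_model(cfg, dir, outdir)
      stage_diff(cfg, dir, outdir)
      stage_da(cfg, dir, outdir)
      r <- stage_ko(cfg, dir, outdir)
      if (file.exists(file.path(dir, cfg$metabolomics)))
        r <- stage_dm(cfg, dir, outdir)
      r
    })
  invisible(res)
}
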