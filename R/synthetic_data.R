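# Ground-truthed synthetic data. The toy network is a bundle of linear
# pathways (uptake -> transport -> chain of conversions -> secretion), each
# its own subsystem with one gene per reaction (plus one AND complex and one
# OR isozyme pair per pathway to exercise GPR semantics), all tied to a
# shared "hub" co-product that is secreted through a core reaction. One
# pathway, "AspLike", is the planted target: its genes are knocked down
# multiplicatively in case samples, and its cytosolic substrate is recorded
# as the rescue metabolite the knockout screen should recover as an agonist.
# Topology is deterministic given the size parameters; the seed drives the
# stochastic simulators and is recorded in the ground truth.

#' Generate a toy metabolic network with recorded ground truth
#'
#' @param n_pathways number of parallel pathways (>= 2). Default 10: keeps
#'   the planted pathway's metabolites at ~10% of the network, the sparse-
#'   signal regime the norm-background MES test assumes.
#' @param reactions_per_pathway chain length per pathway (>= 3). Default 5.
#' @param seed integer; recorded in the truth and used by the simulators.
#' @param enzyme_effect multiplicative expression effect on the planted
#'   pathway's genes in case samples. Default 0.25 (a 4-fold knockdown).
#' @param noise_sigma log-normal noise sd for [simulate_expression()].
#'   Default 0.1.
#' @return list with elements `model` (a [metabolic_model()]) and `truth`
#'   (planted subsystem, effect size, rescue metabolite, planted DM
#'   metabolites, noise sd, seed, substrate exchange ids).
#' @export
make_toy_network <- function(n_pathways = 10, reactions_per_pathway = 5,
                             seed = 1, enzyme_effect = 0.25,
                             noise_sigma = 0.1) {
  if (n_pathways < 2) stop("n_pathways must be >= 2")
  if (reactions_per_pathway < 3) stop("reactions_per_pathway must be >= 3")
  r <- reactions_per_pathway
  tokens <- c("asp", sprintf("pw%02d", seq_len(n_pathways - 1) + 1))
  subsystems <- c("AspLike", sprintf("Pathway%02d", seq_len(n_pathways - 1) + 1))

  mets <- list()
  rxns <- list()
  stoich <- list()
  add_met <- function(id, comp) {
    mets[[length(mets) + 1]] <<- data.frame(
      id = id, name = id, compartment = comp, stringsAsFactors = FALSE)
  }
  add_rxn <- function(id, s, lb, ub, subsystem, gpr) {
    rxns[[length(rxns) + 1]] <<- data.frame(
      id = id, lb = lb, ub = ub, subsystem = subsystem, gpr = gpr,
      stringsAsFactors = FALSE)
    stoich[[length(stoich) + 1]] <<- s
  }

  add_met("hub[c]", "c")
  add_met("hub[e]", "e")
  for (p in seq_len(n_pathways)) {
    tk <- tokens[p]
    ss <- subsystems[p]
    chain <- c(sprintf("sub_%s[c]", tk),
               sprintf("int_%s_%d[c]", tk, seq_len(r - 1)),
               sprintf("prod_%s[c]", tk))
    add_met(sprintf("sub_%s[e]", tk), "e")
    for (m in chain) add_met(m, "c")
    add_met(sprintf("prod_%s[e]", tk), "e")

    tin <- sprintf("TIN_%s", tk)
    add_rxn(tin, stats::setNames(c(-1, 1), c(sprintf("sub_%s[e]", tk), chain[1])),
            0, 1000, ss, sprintf("g_%s", tin))
    for (k in seq_len(r)) {
      rid <- sprintf("R_%s_%d", tk, k)
      s <- stats::setNames(c(-1, 1), c(chain[k], chain[k + 1]))
      gpr <- sprintf("g_%s", rid)
      if (k == 2) {
        s <- c(s, stats::setNames(1, "hub[c]"))
        gpr <- sprintf("(g_%s_a and g_%s_b)", rid, rid)
      } else if (k == 3) {
        gpr <- sprintf("(g_%s_a or g_%s_b)", rid, rid)
      }
      add_rxn(rid, s, 0, 1000, ss, gpr)
    }
    tout <- sprintf("TOUT_%s", tk)
    add_rxn(tout,
            stats::setNames(c(-1, 1), sprintf(c("prod_%s[c]", "prod_%s[e]"), tk)),
            0, 1000, ss, sprintf("g_%s", tout))
    add_rxn(sprintf("EX_sub_%s", tk),
            stats::setNames(-1, sprintf("sub_%s[e]", tk)),
            -1000, 1000, "Exchange", "")
    add_rxn(sprintf("EX_prod_%s", tk),
            stats::setNames(-1, sprintf("prod_%s[e]", tk)),
            -1000, 1000, "Exchange", "")
  }
  add_rxn("HUBOUT", stats::setNames(c(-1, 1), c("hub[c]", "hub[e]")),
          0, 1000, "Core", "g_HUBOUT")
  add_rxn("EX_hub", stats::setNames(-1, "hub[e]"), -1000, 1000, "Exchange", "")

  model <- metabolic_model(do.call(rbind, mets), do.call(rbind, rxns), stoich)
  planted <- model$rxns$id[model$rxns$subsystem == "AspLike"]
  truth <- list(
    planted_subsystem = "AspLike",
    planted_reactions = planted,
    planted_genes = sort(unique(unlist(
      lapply(model$gpr_ast[model$rxns$subsystem == "AspLike"], gpr_genes)))),
    enzyme_effect = enzyme_effect,
    rescue_metabolites = "sub_asp[c]",
    substrate_exchanges = sprintf("EX_sub_%s", tokens),
    planted_dm_metabolites = stats::setNames(rep(-0.8, 5),
                                             sprintf("met_%03d", 1:5)),
    noise_sigma = noise_sigma,
    seed = seed
  )
  list(model = model, truth = truth)
}

#' Default medium for a toy network
#'
#' Opens uptake (-10 mmol/gDW/h) for every pathway substrate exchange; all
#' other exchanges are closed to uptake by [apply_medium()].
#'
#' @param model a toy `metabolic_model` from [make_toy_network()].
#' @param uptake uptake lower bound (<= 0).
#' @return a [medium_table()].
#' @export
toy_medium <- function(model, uptake = -10) {
  ex <- grep("^EX_sub_", model$rxns$id, value = TRUE)
  medium_table(stats::setNames(rep(uptake, length(ex)), ex))
}

#' Default kinetome for a toy network
#'
#' A flat kcat for every GPR-bearing reaction; in toy units the interesting
#' structure lives in the expression, not the kinetics.
#'
#' @param model a toy `metabolic_model`.
#' @param kcat turnover number (1/s).
#' @return a [kinetome_table()].
#' @export
toy_kinetome <- function(model, kcat = 1) {
  ids <- model$rxns$id[nzchar(model$rxns$gpr)]
  kinetome_table(stats::setNames(rep(kcat, length(ids)), ids))
}

#' Simulate case/control expression with a planted knockdown
#'
#' Per-gene baselines are log-normal (meanlog `log(5)`, sdlog 0.5: on the
#' toy scale Vmax = kcat * expression, so typical capacities sit just below
#' the 10 mmol/gDW/h substrate uptake and the expression bound binds);
#' per-sample values multiply the baseline by log-normal noise
#' `exp(N(0, noise_sigma^2))`. Genes of the planted subsystem are multiplied
#' by `truth$enzyme_effect` in case samples only.
#'
#' @param model a toy `metabolic_model`.
#' @param truth the ground truth from [make_toy_network()].
#' @param n_case,n_ctrl group sizes (>= 3). Defaults 13/12, the shape of
#'   the case/control muscle transcriptome the pipeline emulates.
#' @param seed integer.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @return an [expression_matrix()].
#' @export
simulate_expression <- function(model, truth, n_case = 13, n_ctrl = 12,
                                seed = 1, baseline_meanlog = log(5),
                                baseline_sdlog = 0.5) {
  if (n_case < 3 || n_ctrl < 3) stop("group sizes must be >= 3")
  genes <- model$genes
  set.seed(seed)
  baseline <- stats::rlnorm(length(genes), baseline_meanlog, baseline_sdlog)
  n <- n_case + n_ctrl
  noise <- matrix(stats::rlnorm(length(genes) * n, 0, truth$noise_sigma),
                  length(genes), n)
  vals <- baseline * noise
  dimnames(vals) <- list(genes,
                         c(sprintf("case_%02d", seq_len(n_case)),
                           sprintf("ctrl_%02d", seq_len(n_ctrl))))
  planted <- genes %in% truth$planted_genes
  vals[planted, seq_len(n_case)] <-
    vals[planted, seq_len(n_case)] * truth$enzyme_effect
  expression_matrix(vals, rep(c("case", "control"), c(n_case, n_ctrl)))
}

#' Simulate paired pre/post metabolomics with a planted interaction
#'
#' Log2 abundance = metabolite baseline + subject offset + a common
#' timepoint effect + planted `delta` (patients' PEM samples only, for the
#' metabolites named in `truth$planted_dm_metabolites`) + residual noise.
#' Exponentiating keeps every abundance positive; the subject offsets cancel
#' exactly in the paired contrast.
#'
#' @param n_patients,n_controls group sizes (>= 3). Defaults 25/21, the
#'   shape of the paired exercise-challenge cohort the pipeline emulates.
#' @param n_metabolites panel size; default 116 (a muscle-panel-sized set).
#' @param truth ground truth carrying `planted_dm_metabolites`.
#' @param seed integer.
#' @param tissue tissue label for the table.
#' @param baseline_sd,subject_sd,timepoint_sd,resid_sd log2-scale spread of
#'   the corresponding effects.
#' @return a validated long-format metabolomics data.frame.
#' @export
simulate_metabolomics <- function(n_patients = 25, n_controls = 21,
                                  n_metabolites = 116, truth, seed = 1,
                                  tissue = "muscle", baseline_sd = 1.5,
                                  subject_sd = 0.5, timepoint_sd = 0.15,
                                  resid_sd = 0.25) {
  if (n_patients < 3 || n_controls < 3) stop("group sizes must be >= 3")
  set.seed(seed)
  mets <- sprintf("met_%03d", seq_len(n_metabolites))
  delta <- stats::setNames(rep(0, n_metabolites), mets)
  planted <- intersect(names(truth$planted_dm_metabolites), mets)
  delta[planted] <- truth$planted_dm_metabolites[planted]

  subjects <- c(sprintf("pat_%02d", seq_len(n_patients)),
                sprintf("con_%02d", seq_len(n_controls)))
  groups <- rep(c("patient", "control"), c(n_patients, n_controls))
  b <- stats::rnorm(n_metabolites, 5, baseline_sd)
  u <- stats::rnorm(length(subjects), 0, subject_sd)
  tau <- stats::rnorm(n_metabolites, 0, timepoint_sd)

  grid <- expand.grid(metabolite = seq_len(n_metabolites),
                      subject = seq_along(subjects),
                      timepoint = c("baseline", "PEM"),
                      stringsAsFactors = FALSE)
  log2ab <- b[grid$metabolite] + u[grid$subject] +
    ifelse(grid$timepoint == "PEM",
           tau[grid$metabolite] +
             delta[grid$metabolite] * (groups[grid$subject] == "patient"),
           0) +
    stats::rnorm(nrow(grid), 0, resid_sd)
  tab <- data.frame(metabolite = mets[grid$metabolite],
                    subject = subjects[grid$subject],
                    group = groups[grid$subject],
                    timepoint = grid$timepoint,
                    tissue = tissue,
                    abundance = 2^log2ab,
                    stringsAsFactors = FALSE)
  validate_metabolomics(tab)
  tab
}

#' Write a self-contained synthetic study directory
#'
#' Emits the toy model (tabular dialect), expression + sample sheet,
#' kinetome, medium, paired metabolomics, the ground truth (`truth.json`)
#' and a ready-to-run pipeline `config.json`.
#'
#' @param dir output directory (created).
#' @param n_pathways,reactions_per_pathway,seed,enzyme_effect,noise_sigma
#'   passed to [make_toy_network()].
#' @param n_case,n_ctrl passed to [simulate_expression()].
#' @param n_patients,n_controls,n_metabolites passed to
#'   [simulate_metabolomics()].
#' @return `dir`, invisibly.
#' @export
write_study <- function(dir, n_pathways = 10, reactions_per_pathway = 5,
                        seed = 1, enzyme_effect = 0.25, noise_sigma = 0.1,
                        n_case = 13, n_ctrl = 12, n_patients = 25,
                        n_controls = 21, n_metabolites = 116) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_toy_network(n_pathways, reactions_per_pathway, seed,
                          enzyme_effect, noise_sigma)
  write_model(net$model, file.path(dir, "model"), format = "tabular")
  expr <- simulate_expression(net$model, net$truth, n_case, n_ctrl,
                              seed = seed)
  write_matrix_tsv(expr$values, file.path(dir, "expression.tsv"),
                   id_col = "gene")
  write_tsv(data.frame(sample = colnames(expr$values), label = expr$labels),
            file.path(dir, "samples.tsv"))
  kin <- toy_kinetome(net$model)
  write_tsv(data.frame(reaction_id = names(kin), kcat_per_s = unname(kin)),
            file.path(dir, "kinetome.tsv"))
  med <- toy_medium(net$model)
  write_tsv(data.frame(exchange_id = names(med), uptake_lb = unname(med)),
            file.path(dir, "medium.tsv"))
  metab <- simulate_metabolomics(n_patients, n_controls, n_metabolites,
                                 net$truth, seed = seed)
  write_tsv(metab, file.path(dir, "metabolomics.tsv"))
  jsonlite::write_json(net$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- default_config()
  cfg$seed <- seed
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
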