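# Pipeline orchestration: a flat YAML config (stage blocks, no code
# execution) drives the stages rankgenes -> date (per clock model) -> asr
# (per character) -> xval -> identity -> report. Every stage writes TSV
# artifacts plus a log echoing its RNG seed, so identical config + seed
# reproduce byte-identical outputs.

.pipeline_stage_names <- c("fixture", "simulate", "rankgenes", "date",
                           "asr", "xval", "identity", "report")

#' Read and validate a pipeline configuration
#'
#' @param file YAML path. Top-level keys: \code{outdir}, \code{seed},
#'   \code{stages} (ordered subset of fixture, simulate, rankgenes, date,
#'   asr, xval, identity, report) plus one block per named stage. Unknown
#'   keys are rejected.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  known <- c("outdir", "seed", "stages", .pipeline_stage_names)
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$stages)) stop("config needs a 'stages' list")
  bad <- setdiff(unlist(cfg$stages), .pipeline_stage_names)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$outdir)) stop("config needs 'outdir'")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  stage_keys <- list(
    fixture = character(0),
    simulate = c("n_tips", "lambda", "mu", "clock", "nu", "sigma2", "theta",
                 "sites", "n_calibrations"),
    rankgenes = c("gene_trees", "species_tree", "k", "outgroup"),
    date = c("tree", "calibrations", "models", "n_gen", "sample_every",
             "chains", "sites", "root_max"),
    asr = c("tree", "traits", "characters", "n_maps", "structure"),
    xval = c("tree", "calibrations", "n_gen", "sites", "root_max"),
    identity = c("fasta", "convention"),
    report = c("flag_nonoverlap"))
  for (st in intersect(names(stage_keys), names(cfg))) {
    bad <- setdiff(names(cfg[[st]]), stage_keys[[st]])
    if (length(bad))
      stop("unknown key(s) in stage '", st, "': ",
           paste(bad, collapse = ", "))
  }
  for (st in unlist(cfg$stages)) {
    for (key in intersect(c("tree", "traits", "calibrations", "fasta",
                            "species_tree"), names(cfg[[st]]))) {
      if (!file.exists(cfg[[st]][[key]]))
        stop("stage '", st, "': file not found: ", cfg[[st]][[key]])
    }
  }
  cfg
}

.stage_log <- function(outdir, stage, lines, seed = NULL) {
  logdir <- file.path(outdir, "logs")
  dir.create(logdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(paste0("stage: ", stage),
           if (!is.null(seed)) paste0("seed: ", seed))
  writeLines(c(hdr, lines), file.path(logdir, paste0(stage, ".log")))
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) .fmt_num(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the configured pipeline
#'
#' Executes the configured stages in their declared order. A stage failure
#' aborts with a structured error log (\code{logs/error.log}) and a nonzero
#' status when run from the command-line wrapper.
#'
#' @param config Path to a YAML config or a list from
#'   \code{read_pipeline_config}.
#' @return Invisibly, a list of per-stage artifact paths/results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  chronograms <- list()
  for (stage in unlist(cfg$stages)) {
    res <- tryCatch(
      switch(stage,
        fixture = .stage_fixture(cfg, outdir),
        simulate = .stage_simulate(cfg, outdir),
        rankgenes = .stage_rankgenes(cfg, outdir),
        date = .stage_date(cfg, outdir),
        asr = .stage_asr(cfg, outdir),
        xval = .stage_xval(cfg, outdir),
        identity = .stage_identity(cfg, outdir),
        report = .stage_report(cfg, outdir, chronograms)),
      error = function(e) e)
    if (inherits(res, "error")) {
      .stage_log(outdir, "error",
                 c(paste0("failed_stage: ", stage),
                   paste0("message: ", conditionMessage(res))))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(res))
    }
    if (stage == "date") chronograms <- res$chronograms
    artifacts[[stage]] <- res
  }
  invisible(artifacts)
}

.stage_fixture <- function(cfg, outdir) {
  fx <- build_volvocine_fixture(file.path(outdir, "fixture"))
  .stage_log(outdir, "fixture",
             paste0("tips: ", ape::Ntip(fx$tree)))
  fx
}

.stage_simulate <- function(cfg, outdir) {
  p <- cfg$simulate
  seed <- cfg$seed
  n_tips <- p$n_tips %||% 20L
  clock <- p$clock %||% "CIR"
  nu <- p$nu %||% 0.001
  sigma2 <- p$sigma2 %||% (if (clock %in% c("UGAM", "WN")) nu^2 / 4 else 0.05)
  sites <- p$sites %||% 1000L
  tree <- sim_bd_tree(n_tips, p$lambda %||% 0.05, p$mu %||% 0, seed = seed)
  params <- rate_process(clock, nu = nu, sigma2 = sigma2,
                         theta = p$theta %||% if (clock == "CIR") 1 else NULL)
  rates <- sim_rates(tree, params, seed = seed + 1L)
  data <- sim_branch_data(tree, rates, sites = sites, seed = seed + 2L)
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  ncal <- p$n_calibrations %||% 3L
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  nodes <- c(ntip + 1L,
             internal[order(-ages[internal])][seq_len(min(ncal,
                                                          length(internal)))])
  cal <- sim_calibrations(tree, ages, unique(nodes)[seq_len(ncal)],
                          seed = seed + 3L)
  simdir <- file.path(outdir, "synthetic")
  dir.create(simdir, recursive = TRUE, showWarnings = FALSE)
  write_newick(tree, file.path(simdir, "true_tree.nwk"))
  obs <- tree
  obs$edge.length <- attr(data, "implied_lengths")
  write_newick(obs, file.path(simdir, "observed_tree.nwk"))
  write_calibrations(cal, file.path(simdir, "calibrations.tsv"))
  truth <- data.frame(node = internal, true_age = ages[internal])
  .write_tsv(truth, file.path(simdir, "true_ages.tsv"))
  .stage_log(outdir, "simulate",
             c(paste0("n_tips: ", n_tips), paste0("clock: ", clock)),
             seed = seed)
  list(tree = tree, rates = rates, data = data, calibrations = cal,
       dir = simdir)
}

.stage_rankgenes <- function(cfg, outdir) {
  p <- cfg$rankgenes
  sp <- read_newick(p$species_tree, allow_polytomy = TRUE)
  stats <- gene_tree_stats(p$gene_trees, sp, outgroup = p$outgroup)
  ranked <- rank_and_select(stats, k = p$k %||% 8L)
  path <- .write_tsv(ranked, file.path(outdir, "gene_ranking.tsv"))
  writeLines(attr(ranked, "selected"),
             file.path(outdir, "selected_genes.txt"))
  .stage_log(outdir, "rankgenes",
             paste0("selected: ", paste(attr(ranked, "selected"),
                                        collapse = ",")))
  list(table = ranked, path = path)
}

.stage_date <- function(cfg, outdir) {
  p <- cfg$date
  seed <- cfg$seed
  tree <- read_newick(p$tree, length_kind = "subst")
  cal <- read_calibrations(p$calibrations)
  data <- branch_data("normal", lengths = tree$edge.length,
                      sites = p$sites %||% 1000L)
  models <- unlist(p$models %||% list("CIR"))
  chronograms <- list()
  for (mdl in models) {
    dm <- dating_model(tree, cal, clock = mdl,
                       root_max = p$root_max %||% 2000)
    n_chains <- p$chains %||% 2L
    ps <- mcmc_date(dm, data, n_gen = p$n_gen %||% 10000L,
                    sample_every = p$sample_every %||% 10L,
                    seed = seed, n_chains = n_chains)
    conv <- if (n_chains >= 2L) convergence_check(ps) else
      list(pass = NA)
    chron <- summarize_chronogram(
      ps, file = file.path(outdir, paste0("chronogram_", mdl, ".nex")))
    .write_tsv(as.data.frame(chron),
               file.path(outdir, paste0("chronogram_", mdl, ".tsv")))
    .write_tsv(as.data.frame(.stacked(ps, "ages")),
               file.path(outdir, paste0("samples_", mdl, ".tsv")))
    chronograms[[mdl]] <- chron
    .stage_log(outdir, paste0("date_", mdl),
               c(paste0("converged: ", conv$pass),
                 paste0("acceptance: ",
                        paste(round(ps$chains[[1]]$acceptance, 3),
                              collapse = ","))), seed = seed)
  }
  list(chronograms = chronograms)
}

.stage_asr <- function(cfg, outdir) {
  p <- cfg$asr
  seed <- cfg$seed
  tree <- read_newick(p$tree, length_kind = "time")
  states_file <- if (file.exists(paste0(p$traits, ".states")))
    paste0(p$traits, ".states") else NULL
  traits <- read_traits(p$traits, states_file)
  chars <- unlist(p$characters %||% names(traits))
  rows <- lapply(chars, function(ch) {
    x <- .trait_column(traits, ch, tree)
    obs <- x[!is.na(x) & x != MISSING_SYMBOL]
    if (length(unique(obs)) < 2L)
      return(data.frame(character = ch, states = NA, origins_parsimony = 0,
                        fitch_changes = 0, origins_simmap_mode = 0))
    states <- attr(x, "states")
    derived <- setdiff(states, states[1L])   # states beyond the first-listed
    fc <- fitch_count(tree, x, states = states)
    po <- count_origins(tree, x, derived = derived, states = states)
    fit <- fit_mk(tree, x, "ER", states = states, seed = cfg$seed)
    asr <- marginal_asr(tree, x, fit$model)
    .write_tsv(asr_node_table(asr),
               file.path(outdir, paste0("asr_nodes_", ch, ".tsv")))
    so <- count_origins(tree, x, derived = derived, states = states,
                        method = "simmap-modal",
                        n_maps = p$n_maps %||% 500L, seed = seed)
    data.frame(character = ch, states = paste(states, collapse = "|"),
               origins_parsimony = po, fitch_changes = fc$count,
               origins_simmap_mode = so$count)
  })
  tab <- do.call(rbind, rows)
  path <- .write_tsv(tab, file.path(outdir, "asr_origin_counts.tsv"))
  .stage_log(outdir, "asr", paste0("characters: ", length(chars)),
             seed = seed)
  list(table = tab, path = path)
}

.stage_xval <- function(cfg, outdir) {
  p <- cfg$xval
  tree <- read_newick(p$tree, length_kind = "subst")
  cal <- read_calibrations(p$calibrations)
  data <- branch_data("normal", lengths = tree$edge.length,
                      sites = p$sites %||% 1000L)
  dm <- dating_model(tree, cal, root_max = p$root_max %||% 2000)
  xv <- fossil_cross_validate(dm, data, n_gen = p$n_gen %||% 4000L,
                              seed = cfg$seed)
  path <- .write_tsv(xv, file.path(outdir, "fossil_xval.tsv"))
  .stage_log(outdir, "xval",
             paste0("total_ss: ", .fmt_num(attr(xv, "total_ss"))),
             seed = cfg$seed)
  list(table = xv, path = path)
}

.stage_identity <- function(cfg, outdir) {
  p <- cfg$identity
  seqs <- read_fasta(p$fasta)
  rep <- identity_report(seqs, convention = p$convention %||% "all-columns")
  path <- .write_tsv(rep, file.path(outdir, "identity_report.tsv"))
  .stage_log(outdir, "identity", paste0("pairs: ", nrow(rep)))
  list(table = rep, path = path)
}

.stage_report <- function(cfg, outdir, chronograms) {
  if (length(chronograms) < 2L) {
    .stage_log(outdir, "report", "cross-model report needs >= 2 dated models")
    return(list(table = NULL))
  }
  tab <- cross_model_report(chronograms)
  path <- .write_tsv(tab, file.path(outdir, "cross_model_report.tsv"))
  .stage_log(outdir, "report",
             paste0("flagged_models: ",
                    paste(unique(tab$model[tab$nonoverlap]),
                          collapse = ",")))
  list(table = tab, path = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-model node-age comparison
#'
#' For every node, flags a clock model whose 95\% HPD fails to overlap the
#' HPD of \emph{any} other model at that node (the outlier pattern used to
#' exclude discordant clock models). The flag is symmetric in the interval
#' overlap test.
#'
#' @param chronograms Named list (by model) of \code{chronogram} tables.
#' @return data.frame: node, model, mean_age, hpd_lower, hpd_upper,
#'   nonoverlap.
#' @export
cross_model_report <- function(chronograms) {
  models <- names(chronograms)
  nodes <- chronograms[[1L]]$node
  rows <- list()
  for (nd in nodes) {
    iv <- lapply(chronograms, function(ch) {
      r <- ch[ch$node == nd, ]
      c(r$hpd_lower, r$hpd_upper, r$mean_age)
    })
    for (m in models) {
      others <- setdiff(models, m)
      overlaps <- vapply(others, function(o)
        iv[[m]][1L] <= iv[[o]][2L] && iv[[o]][1L] <= iv[[m]][2L], TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        node = nd, model = m, mean_age = iv[[m]][3L],
        hpd_lower = iv[[m]][1L], hpd_upper = iv[[m]][2L],
        nonoverlap = !any(overlaps))
    }
  }
  do.call(rbind, rows)
}
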