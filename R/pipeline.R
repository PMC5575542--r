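# End-to-end orchestration: inputs -> (rooting, branch lengths) -> ASR ->
# region map -> windows -> enrichment report, with per-stage status and a
# machine-readable run report.

#' Assemble a pipeline run configuration
#'
#' @param alignment Path to the aligned FASTA.
#' @param tree Path to the Newick tree.
#' @param out_dir Output directory.
#' @param query_structure Path to the query dimer PDB.
#' @param formI_reference,formIII_reference,subdomain_reference Paths to the
#'   reference structures (see [region_config()]); `subdomain_reference`
#'   defaults to the query structure.
#' @param formI_partner_ll,formI_partner_ls,formIII_partners Partner chain
#'   ids in the respective reference complexes.
#' @param subdomains List with integer residue vectors `barrel_strands`,
#'   `loop6`, `n_terminal`, `c_terminal` (reference numbering).
#' @param reference_row Alignment taxon matching the query structure.
#' @param ancestors Named list: ancestor name -> taxon set (MRCA spec).
#' @param outgroup Optional character vector of outgroup taxa for rooting.
#' @param model_name,gamma_shape,n_rate_categories Substitution model.
#' @param optimize_lengths Re-optimize branch lengths before ASR.
#' @param bl_tol,bl_max_rounds Branch-length optimizer controls.
#' @param cutoff Interface cutoff (Angstrom).
#' @param or_threshold,p_threshold Significance thresholds.
#' @param alternative,gap_policy Passed to [enrichment_scan()].
#' @param n_alternates Posterior-sampled alternate ancestors per node.
#' @param seed Integer seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(alignment, tree, out_dir,
                       query_structure = NULL,
                       formI_reference = NULL, formIII_reference = NULL,
                       subdomain_reference = query_structure,
                       formI_partner_ll = "C", formI_partner_ls = "S",
                       formIII_partners = "D",
                       subdomains = NULL,
                       reference_row = NULL,
                       ancestors = NULL, outgroup = NULL,
                       model_name = "WAG", gamma_shape = 1,
                       n_rate_categories = 4,
                       optimize_lengths = TRUE, bl_tol = 1e-2,
                       bl_max_rounds = 2,
                       cutoff = 5, or_threshold = 1.5, p_threshold = 0.05,
                       alternative = "two.sided", gap_policy = "exclude",
                       n_alternates = 5, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' @param config A [run_config()] (or plain list).
#' @return Character vector of problems (empty when valid); never throws.
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  for (f in c("alignment", "tree")) {
    p <- config[[f]]
    need(is.character(p) && length(p) == 1 && file.exists(p),
         sprintf("%s: path missing or does not exist", f))
  }
  for (f in c("query_structure", "formI_reference", "formIII_reference",
              "subdomain_reference")) {
    p <- config[[f]]
    if (!is.null(p))
      need(file.exists(p), sprintf("%s: file '%s' does not exist", f, p))
  }
  need(is.numeric(config$cutoff) && config$cutoff > 0,
       "cutoff: must be > 0")
  need(is.numeric(config$or_threshold) && config$or_threshold > 0,
       "or_threshold: must be > 0")
  need(is.numeric(config$p_threshold) && config$p_threshold > 0 &&
         config$p_threshold < 1, "p_threshold: must be in (0, 1)")
  need(is.numeric(config$seed) && length(config$seed) == 1,
       "seed: must be a single integer")
  if (!is.null(config$ancestors)) {
    need(length(names(config$ancestors)) == length(config$ancestors),
         "ancestors: must be a named list")
    if (is.character(config$tree) && file.exists(config$tree)) {
      tr <- tryCatch(ape::read.tree(config$tree), error = function(e) NULL)
      if (!is.null(tr)) {
        for (nm in names(config$ancestors)) {
          unknown <- setdiff(config$ancestors[[nm]], tr$tip.label)
          for (u in unknown)
            problems <- c(problems,
                          sprintf("ancestors[%s]: unknown taxon '%s'", nm, u))
        }
      }
    }
  }
  problems
}

#' Run the full analysis pipeline
#'
#' Stages: load inputs -> optional outgroup rooting -> optional
#' branch-length optimization -> marginal ASR (+ Fitch indels, ML
#' sequences, posterior bins, sampled alternates) -> structural region map
#' -> phylogenetic windows -> enrichment scan.  Each stage's status is
#' recorded; a failed stage is recorded as an error and the stages that
#' depend on it are skipped, while independent stages still run and their
#' artifacts are still written.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report` (also written as `report.json` in
#'   `out_dir`): per-stage status, input checksums, seed, posterior-bin
#'   table, enrichment results, warnings.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop_pe("config_error", "invalid config: %s",
            paste(problems, collapse = "; "))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  warnings_log <- character()
  run_stage <- function(name, deps = character(), expr) {
    failed_deps <- deps[vapply(deps, function(d)
      !identical(stages[[d]]$status, "ok"), logical(1))]
    if (length(failed_deps)) {
      stages[[name]] <<- list(status = "skipped",
                              reason = paste("failed dependency:",
                                             paste(failed_deps,
                                                   collapse = " ")))
      return(NULL)
    }
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stages[[name]] <<- list(status = "error",
                                message = conditionMessage(e))
        NULL
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (is.null(stages[[name]])) stages[[name]] <<- list(status = "ok")
    res
  }

  inputs <- run_stage("load", character(), {
    aln <- read_fasta(config$alignment)
    tree <- ape::read.tree(config$tree)
    if (!is.null(config$outgroup))
      tree <- root_with_outgroup(tree, config$outgroup)
    tree <- ensure_node_labels(tree)
    list(aln = aln, tree = tree)
  })

  model <- aa_model(config$model_name, config$gamma_shape,
                    config$n_rate_categories)

  tree_opt <- run_stage("branch_lengths", "load", {
    if (isTRUE(config$optimize_lengths))
      optimize_branch_lengths(inputs$tree, inputs$aln, model,
                              tol = config$bl_tol,
                              max_rounds = config$bl_max_rounds)
    else inputs$tree
  })

  recon <- run_stage("asr", c("load", "branch_lengths"), {
    rec <- marginal_ancestral_posteriors(tree_opt, inputs$aln, model)
    write_fasta(rec$ml, file.path(out_dir, "ancestors_ml.fasta"))
    for (nd in names(rec$posteriors)) {
      p <- rec$posteriors[[nd]]
      tab <- data.frame(site = seq_len(ncol(p)),
                        present = as.integer(rec$presence[[nd]]),
                        ml_state = rec$ml[[nd]],
                        max_posterior = signif(rec$max_posterior[[nd]], 6),
                        t(signif(p, 6)))
      colnames(tab)[-(1:4)] <- paste0("p_", AA_CODES)
      write.table(tab, file.path(out_dir, sprintf("asr_%s.tsv", nd)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    bins <- do.call(rbind, lapply(names(rec$posteriors), function(nd)
      data.frame(node = nd, bin = names(bin_posteriors(rec, nd)),
                 proportion = as.numeric(bin_posteriors(rec, nd)))))
    write.table(bins, file.path(out_dir, "posterior_bins.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    alts <- list()
    for (nd in names(rec$posteriors)) {
      am <- sample_alternate_ancestors(rec, nd, n = config$n_alternates,
                                       seed = (config$seed %% 1000000000) +
                                         match(nd, names(rec$posteriors)))
      for (i in seq_len(nrow(am)))
        alts[[sprintf("%s_alt%d", nd, i)]] <- am[i, ]
    }
    write_fasta(alts, file.path(out_dir, "ancestors_alternates.fasta"))
    rec
  })

  rmap <- run_stage("regions", "load", {
    if (is.null(config$query_structure))
      stop_pe("config_error", "no query structure configured")
    rc <- region_config(
      cutoff = config$cutoff,
      formI = if (!is.null(config$formI_reference))
        list(model = config$formI_reference,
             partner_ll_chains = config$formI_partner_ll,
             partner_ls_chains = config$formI_partner_ls),
      formIII = if (!is.null(config$formIII_reference))
        list(model = config$formIII_reference,
             partner_chains = config$formIII_partners),
      subdomain = if (!is.null(config$subdomain_reference))
        c(list(model = config$subdomain_reference), config$subdomains))
    rm <- build_region_map(rc, config$query_structure, inputs$aln,
                           config$reference_row)
    write_region_map(rm, file.path(out_dir, "region_map.tsv"))
    write_region_map(rm, file.path(out_dir, "region_map.json"))
    rm
  })

  windows <- run_stage("windows", "load", {
    if (is.null(config$ancestors))
      stop_pe("config_error", "no ancestor specs configured")
    w <- define_windows(inputs$tree, config$ancestors)
    jsonlite::write_json(w, file.path(out_dir, "windows.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    w
  })

  results <- run_stage("scan", c("asr", "regions", "windows"), {
    res <- enrichment_scan(recon, windows, rmap,
                           or_threshold = config$or_threshold,
                           p_threshold = config$p_threshold,
                           alternative = config$alternative,
                           gap_policy = config$gap_policy)
    out <- res
    out$odds_ratio <- ifelse(is.finite(out$odds_ratio),
                             signif(out$odds_ratio, 8),
                             out$odds_ratio)
    out$p_value <- signif(out$p_value, 8)
    out$bh_q <- signif(out$bh_q, 8)
    write.table(out, file.path(out_dir, "results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res
  })

  input_files <- Filter(function(p) is.character(p) && length(p) == 1 &&
                          file.exists(p),
                        config[c("alignment", "tree", "query_structure",
                                 "formI_reference", "formIII_reference",
                                 "subdomain_reference")])
  report <- list(
    package = "paleoenrich",
    version = as.character(utils::packageVersion("paleoenrich")),
    seed = config$seed,
    stages = stages,
    input_checksums = as.list(vapply(input_files, function(p)
      unname(tools::md5sum(p)), character(1))),
    thresholds = list(cutoff = config$cutoff, or = config$or_threshold,
                      p = config$p_threshold,
                      alternative = config$alternative,
                      gap_policy = config$gap_policy),
    n_results = if (is.null(results)) 0L else nrow(results),
    warnings = warnings_log,
    config = lapply(unclass(config), function(x)
      if (is.atomic(x) || is.list(x)) x else NULL))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  out <- list(stages = stages, results = results, region_map = rmap,
              windows = windows, reconstruction = recon,
              warnings = warnings_log, report = report)
  class(out) <- "run_report"
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-15s %s\n", nm, x$stages[[nm]]$status))
  if (!is.null(x$results))
    cat(sprintf("  %d enrichment rows, %d significant\n",
                nrow(x$results), sum(x$results$significant)))
  invisible(x)
}
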