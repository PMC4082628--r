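#' Validate a run configuration
#'
#' Accepts `NULL` (all defaults), a YAML file path, or a nested list.
#' Unknown keys are rejected with their key path; threshold defaults are the
#' printed clustering/detection values (see [cluster_params()],
#' [pseudo_params()]).
#'
#' @param x `NULL`, a YAML path, or a list.
#' @return object of class `run_config`: list with `seed`, `dataset_dir`,
#'   `out_dir`, `cluster` (`cluster_params`), `pseudo` (`pseudo_params`),
#'   `stats`, `phylo`, `pathways`, `simulate` (extra arguments for
#'   [simulate_study()]).
#' @export
validate_config <- function(x = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x) %||% list()
  }
  x <- x %||% list()
  known <- c("seed", "dataset_dir", "out_dir", "cluster", "pseudo", "stats",
             "phylo", "pathways", "simulate")
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  check_sub <- function(sub, fn, where) {
    extra <- setdiff(names(sub), names(formals(fn)))
    if (length(extra)) {
      stop("unknown config key: ", paste(paste0(where, ".", extra),
                                         collapse = ", "))
    }
    sub
  }
  cl <- do.call(cluster_params, check_sub(x$cluster %||% list(),
                                          cluster_params, "cluster"))
  ps <- do.call(pseudo_params, check_sub(x$pseudo %||% list(),
                                         pseudo_params, "pseudo"))
  stats_opts <- x$stats %||% list()
  bad <- setdiff(names(stats_opts), c("window"))
  if (length(bad)) stop("unknown config key: stats.", paste(bad, collapse = ", "))
  phylo_opts <- x$phylo %||% list()
  bad <- setdiff(names(phylo_opts), c("n_boot", "model", "support_threshold"))
  if (length(bad)) stop("unknown config key: phylo.", paste(bad, collapse = ", "))
  pw_opts <- x$pathways %||% list()
  bad <- setdiff(names(pw_opts), c("defs", "observed"))
  if (length(bad)) stop("unknown config key: pathways.", paste(bad, collapse = ", "))
  sim_opts <- check_sub(x$simulate %||% list(), simulate_study, "simulate")

  structure(list(
    seed = as.integer(x$seed %||% 1L),
    dataset_dir = x$dataset_dir, out_dir = x$out_dir,
    cluster = cl, pseudo = ps,
    stats = list(window = as.integer(stats_opts$window %||% 10000L)),
    phylo = list(n_boot = as.integer(phylo_opts$n_boot %||% 1000L),
                 model = phylo_opts$model %||% "p",
                 support_threshold = phylo_opts$support_threshold %||% 70),
    pathways = pw_opts, simulate = sim_opts
  ), class = "run_config")
}

#' Run the full comparative-genomics pipeline
#'
#' Executes the stages end-to-end on a dataset directory (written by
#' [emit_dataset()] or equivalently formatted) or, without one, on a
#' freshly simulated study: pseudogene detection, composition statistics,
#' ortholog clustering with core-partitioning and fragment rescue, MLST
#' phylogeny with bootstrap and clade checks, and pathway-based phenotype
#' prediction.  With planted truth available, recovery metrics are attached.
#' Deterministic for a fixed config and seed; per-stage progress goes to
#' `message()` (stderr), never into results.
#'
#' @param config a [validate_config()] result (or anything it accepts).
#' @param study optionally a prebuilt `reducto_study` (overrides simulation).
#' @return object of class `reducto_run`: list of stage outputs plus
#'   `summary` (flat, JSON-friendly).  If `config$out_dir` is set, tables
#'   and `summary.json` are written there.
#' @export
run_all <- function(config = validate_config(), study = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[reducto] %-12s %6.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  ds <- stage("load", {
    if (!is.null(study)) {
      study
    } else if (!is.null(config$dataset_dir)) {
      rd <- read_dataset(config$dataset_dir)
      list(strains = rd$strains, truth = rd$truth,
           meta = stats::setNames(rd$meta$subspecies, rd$meta$strain_id),
           mlst_scheme = NULL, pathway_defs = NULL)
    } else {
      do.call(simulate_study, c(list(seed = config$seed), config$simulate))
    }
  })
  strains <- ds$strains
  meta <- ds$meta

  calls <- stage("pseudogenes", {
    pro_all <- strain_proteomes(strains)
    do.call(rbind, lapply(names(strains), function(sid) {
      call_pseudogenes(strains[[sid]], pro_all[pro_all$strain_id != sid, ],
                       config$pseudo)
    }))
  })

  stats <- stage("stats", {
    lapply(strains, stats_report, pseudo_calls = calls,
           window = config$stats$window)
  })

  ortho <- stage("orthology", {
    frag <- calls[calls$verdict == "pseudogene_fragment",
                  c("strain_id", "cds_id")]
    pro <- strain_proteomes(strains, exclude = frag)
    edges <- similarity_edges(pro, config$cluster)
    groups <- cluster_single_linkage(pro, edges)
    part <- partition_core(groups, meta)
    resc_A <- fragment_rescue(part$groups$A, groups, calls, meta,
                              part$subspecies[2])
    resc_C <- fragment_rescue(part$groups$C, groups, calls, meta,
                              part$subspecies[1])
    list(proteome = pro, edges = edges, groups = groups, partition = part,
         rescue_A = resc_A, rescue_C = resc_C)
  })

  phylo <- if (!is.null(ds$mlst_scheme)) {
    stage("phylogeny", {
      ml <- mlst_run(strains, ds$mlst_scheme, n_boot = config$phylo$n_boot,
                     seed = config$seed, model = config$phylo$model)
      mono <- vapply(unique(unname(meta)), function(ssp) {
        clade_monophyletic(ml$tree, names(meta)[meta == ssp])
      }, logical(1))
      list(mlst = ml, monophyletic = mono)
    })
  } else NULL

  pathways <- if (!is.null(ds$pathway_defs) || !is.null(config$pathways$defs)) {
    stage("pathways", {
      defs <- ds$pathway_defs %||% read_pathway_defs(config$pathways$defs)
      statuses <- gene_status_table(strains, calls)
      predicted <- predict_phenotypes(defs, statuses)
      observed <- if (!is.null(config$pathways$observed)) {
        read_phenotype_table(config$pathways$observed)$matrix
      } else if (!is.null(ds$truth)) {
        truth_phenotypes(defs, ds$truth)
      } else NULL
      cmp <- if (!is.null(observed)) {
        compare_and_discriminate(observed, meta, predicted)
      } else NULL
      list(defs = defs, statuses = statuses, predicted = predicted,
           observed = observed, comparison = cmp)
    })
  } else NULL

  truth_eval <- if (!is.null(ds$truth)) {
    stage("truth-eval", {
      tp <- truth_partition(ds$truth, meta)
      part <- ortho$partition
      cm <- caller_metrics(calls, ds$truth, strains)
      exp_A <- truth_rescue(ds$truth, meta, tp$genes$A, part$subspecies[2])
      exp_C <- truth_rescue(ds$truth, meta, tp$genes$C, part$subspecies[1])
      list(truth_partition = tp, caller = cm,
           partition_abs_error = sum(abs(part$counts - tp$counts)) +
             abs(part$overall_core - tp$overall_core),
           rescue_abs_error = abs(ortho$rescue_A$n_rescued - exp_A) +
             abs(ortho$rescue_C$n_rescued - exp_C))
    })
  } else NULL

  summary <- list(
    seed = config$seed,
    n_strains = length(strains),
    n_pseudogene_calls = sum(calls$verdict == "pseudogene_fragment"),
    overall_core = ortho$partition$overall_core,
    counts = as.list(ortho$partition$counts),
    rescue_A = ortho$rescue_A$n_rescued,
    rescue_C = ortho$rescue_C$n_rescued,
    monophyletic = if (!is.null(phylo)) as.list(phylo$monophyletic) else NULL,
    discriminating = if (!is.null(pathways$comparison))
      pathways$comparison$discriminating else NULL,
    prediction_concordance = if (!is.null(pathways$comparison))
      pathways$comparison$concordance else NULL,
    partition_abs_error = truth_eval$partition_abs_error,
    rescue_abs_error = truth_eval$rescue_abs_error,
    pseudo_false_positives = truth_eval$caller$false_positives,
    pseudo_recall = truth_eval$caller$recall)

  out <- structure(list(
    config = config, strains = strains, meta = meta, calls = calls,
    stats = stats, orthology = ortho, phylo = phylo, pathways = pathways,
    truth_eval = truth_eval, summary = summary
  ), class = "reducto_run")
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' @export
print.reducto_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("reducto run (seed %d): %d strains, core %d, A=%d B=%d C=%d D=%d, %d pseudogene calls\n",
              s$seed, s$n_strains, s$overall_core, s$counts$A, s$counts$B,
              s$counts$C, s$counts$D, s$n_pseudogene_calls))
  invisible(x)
}

#' Is a set of tips a clade of the (unrooted) tree?
#' @param tree `phylo` object.
#' @param tips tip labels.
#' @return logical.
#' @export
clade_monophyletic <- function(tree, tips) {
  all_tips <- tree$tip.label
  stopifnot(all(tips %in% all_tips))
  n_in <- length(tips)
  if (n_in <= 1L || n_in >= length(all_tips) - 1L) return(TRUE)
  ref <- sort(all_tips)[1]
  side <- if (ref %in% tips) sort(setdiff(all_tips, tips)) else sort(tips)
  paste(side, collapse = "|") %in% tree_bipartitions(tree)
}

# Ground-truth phenotypes: pathway completeness evaluated on planted gene
# statuses instead of caller output.
#' @keywords internal
truth_phenotypes <- function(defs, truth) {
  statuses <- data.frame(
    strain_id = truth$strain_id, gene_id = truth$gene_id,
    status = c(intact = "present", hgt = "present", pseudogene = "pseudo",
               absent = "absent")[truth$status],
    stringsAsFactors = FALSE)
  predict_phenotypes(defs, statuses)
}

#' Write pipeline outputs to a directory
#'
#' Emits the stage tables as TSV, the MLST tree as Newick (bootstrap
#' supports as internal node labels) and the run summary as JSON.
#' @param run a `reducto_run` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(run$calls, "pseudogene_calls.tsv")
  wt(run$orthology$edges, "similarity_edges.tsv")
  wt(run$orthology$groups, "ortholog_groups.tsv")
  st <- do.call(rbind, lapply(run$stats, function(s) {
    data.frame(strain_id = s$strain_id, assembled_size = s$assembled_size,
               overall_gc_pct = s$printed["overall_gc_pct"],
               cds_gc_pct = s$printed["cds_gc_pct"],
               gc3_pct = s$printed["gc3_pct"],
               coding_density_pct = s$printed["coding_density_pct"],
               n_cds = s$n_cds,
               n_pseudogene_fragments = s$n_pseudogene_fragments,
               n_is = sum(s$is_counts), is_free_width = s$is_free_width,
               stringsAsFactors = FALSE)
  }))
  wt(st, "genome_stats.tsv")
  if (!is.null(run$phylo)) {
    ape::write.tree(run$phylo$mlst$tree, file.path(dir, "mlst.nwk"))
  }
  if (!is.null(run$pathways)) {
    pred <- run$pathways$predicted
    wt(cbind(data.frame(strain_id = rownames(pred)), as.data.frame(pred)),
       "predicted_phenotypes.tsv")
  }
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}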