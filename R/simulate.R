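#' Simulate the two-clade study dataset with planted ground truth
#'
#' Generates an ancestral pangenome and evolves two subspecies-like clades
#' of strains from it at contrasting intensities of reductive evolution —
#' the "lactis-like" clade diverges less and loses/pseudogenises fewer
#' genes, the "bulgaricus-like" clade more, mirroring a pair of dairy
#' subspecies at different distances from their common ancestor.  Planted
#' features: seven protected MLST marker loci and one rRNA locus; pathway
#' gene sets with clade-level knockouts (driving predictable fermentation
#' differences); clade-specific gene sets, a subset of which survive as
#' pseudogene fragments in the opposite clade (fragment rescue);
#' horizontally acquired genes at foreign GC including one recent
#' cross-clade transfer (phylogenetic incongruence); and IS elements, more
#' numerous in the lactis-like clade.
#'
#' @param seed integer master seed; the whole dataset is reproducible.
#' @param n_genes ancestral gene count.
#' @param n_per_clade strains per clade.
#' @param clade_div per-site divergence of the clade ancestors from the
#'   common ancestor (named `lactis`/`bulgaricus`).
#' @param strain_div per-site divergence of each strain from its clade
#'   ancestor.
#' @param subclade_div extra shared divergence of the first two lactis-like
#'   strains, giving the clade internal structure (a resolved subclade) so
#'   that transfer-induced tree conflicts are detectable against supported
#'   within-clade edges.
#' @param loss_prob,pseudo_prob named per-clade per-gene probabilities.
#' @param n_is named per-clade IS insertion counts.
#' @param n_specific named counts of planted clade-specific genes.
#' @param n_rescue named counts of clade-specific genes additionally planted
#'   as pseudogene fragments in one opposite-clade strain each.
#' @param n_pathways planted pathways (3 genes each: transporter + 2
#'   enzymes).
#' @return object of class `reducto_study`: list with `ancestor`, `strains`
#'   (named list of `strain_genome`), `truth`, `meta` (named subspecies
#'   vector), `mlst_scheme`, `pathway_defs`, `planted` (id sets), `seed`.
#' @export
simulate_study <- function(seed = 1L, n_genes = 120L, n_per_clade = 5L,
                           clade_div = c(lactis = 0.015, bulgaricus = 0.030),
                           strain_div = 0.005, subclade_div = 0.008,
                           loss_prob = c(lactis = 0.05, bulgaricus = 0.12),
                           pseudo_prob = c(lactis = 0.05, bulgaricus = 0.10),
                           n_is = c(lactis = 20L, bulgaricus = 6L),
                           n_specific = c(lactis = 12L, bulgaricus = 6L),
                           n_rescue = c(lactis = 5L, bulgaricus = 2L),
                           n_pathways = 8L) {
  markers <- c("fusA", "gyrB", "hsp60", "ileS", "pyrG", "recA", "recG")
  n_marker <- length(markers)
  n_pw_genes <- 3L * n_pathways
  n_reserved <- n_marker + n_pw_genes + sum(n_specific)
  stopifnot(n_genes > n_reserved, n_rescue <= n_specific,
            n_per_clade >= 2, n_pathways >= 3)

  seeds <- with_seed(seed, sample.int(1e8L, 6L + 2L * n_per_clade))
  anc <- generate_ancestor(n_genes, c(300L, 900L), gc_target = 0.50,
                           seed = seeds[1])
  ids <- anc$gene_table$gene_id

  mlst_scheme <- stats::setNames(ids[seq_len(n_marker)], markers)
  pw_ids <- ids[n_marker + seq_len(n_pw_genes)]
  pathway_genes <- split(pw_ids, rep(seq_len(n_pathways), each = 3L))
  pathway_defs <- stats::setNames(lapply(seq_len(n_pathways), function(p) {
    g <- pathway_genes[[p]]
    pathway_def(sprintf("substrate%02d", p), list(
      list(genes = g[1], transporter = TRUE),
      list(genes = g[2]), list(genes = g[3])))
  }), sprintf("substrate%02d", seq_len(n_pathways)))

  off <- n_marker + n_pw_genes
  spec_lactis <- ids[off + seq_len(n_specific["lactis"])]
  spec_bulg <- ids[off + n_specific["lactis"] + seq_len(n_specific["bulgaricus"])]
  rescue_lactis <- spec_lactis[seq_len(n_rescue["lactis"])]
  rescue_bulg <- spec_bulg[seq_len(n_rescue["bulgaricus"])]
  protected <- c(unname(mlst_scheme), pw_ids, spec_lactis, spec_bulg)

  # horizontally acquired genes, foreign GC signature
  hgt_seqs <- with_seed(seeds[2], c(
    hgtA = random_orf(600L, 0.42),   # carried by the lactis-like clade
    hgtB = random_orf(540L, 0.42),   # carried by the bulgaricus-like clade
    hgtX = random_orf(1200L, 0.42))) # in all strains; recent cross-clade transfer
  hgt_universe <- names(hgt_seqs)

  is_library <- with_seed(seeds[3], c(
    IS30 = random_dna(795L, 0.5), IS256 = random_dna(900L, 0.5),
    ISL3 = random_dna(1000L, 0.5)))

  anc_lactis <- mutate_pangenome(anc, clade_div["lactis"], seed = seeds[4])
  anc_bulg <- mutate_pangenome(anc, clade_div["bulgaricus"], seed = seeds[5])
  # the first two lactis-like strains share a resolved subclade
  anc_lactis_sub <- mutate_pangenome(anc_lactis, subclade_div,
                                     seed = seeds[4] + 1L)
  hgt_lactis_clade <- with_seed(seeds[6], {
    c(hgtA = mutate_orf(hgt_seqs[["hgtA"]], clade_div["lactis"]),
      hgtX = mutate_orf(hgt_seqs[["hgtX"]], clade_div["lactis"]))
  })
  hgt_lactis_sub <- with_seed(seeds[6] + 1L, {
    vapply(hgt_lactis_clade, mutate_orf, character(1), rate = subclade_div)
  })
  hgt_bulg_base <- with_seed(seeds[6] + 2L, {
    c(hgtB = mutate_orf(hgt_seqs[["hgtB"]], clade_div["bulgaricus"]))
  })

  # planted knockouts: pathway n_pathways lost and pathway n_pathways-1
  # fragmented in the bulgaricus-like clade (both discriminate the clades);
  # one transporter fragmented in a single lactis strain (intra-clade
  # variability, non-discriminating)
  ko_lost <- pathway_genes[[n_pathways]][1]
  ko_frag <- pathway_genes[[n_pathways - 1L]][2]
  var_frag <- pathway_genes[[n_pathways - 2L]][1]

  strains <- list()
  k <- 0L
  xfer_base <- NULL
  for (clade in c("lactis", "bulgaricus")) {
    own_spec <- if (clade == "lactis") spec_lactis else spec_bulg
    opp_spec <- if (clade == "lactis") spec_bulg else spec_lactis
    opp_rescue <- if (clade == "lactis") rescue_bulg else rescue_lactis
    for (i in seq_len(n_per_clade)) {
      k <- k + 1L
      sid <- sprintf("%s%02d", if (clade == "lactis") "LAC" else "BLG", i)
      in_sub <- clade == "lactis" && i <= 2L
      cl_anc <- if (clade == "lactis") {
        if (in_sub) anc_lactis_sub else anc_lactis
      } else anc_bulg
      cl_hgt <- if (clade == "lactis") {
        if (in_sub) hgt_lactis_sub else hgt_lactis_clade
      } else {
        # xenologous replacement: every bulgaricus-like strain carries a
        # copy of hgtX transferred from the LAC01 lineage (one event),
        # nesting the recipients inside the donor subclade in the gene tree
        c(hgt_bulg_base, hgtX = xfer_base)
      }
      forced <- stats::setNames(rep("intact", length(own_spec)), own_spec)
      forced[opp_spec] <- "absent"
      # rescue gene r is a detectable fragment in opposite-clade strain
      # 1 + (r-1) %% n_per_clade, rotating over strains
      for (r in seq_along(opp_rescue)) {
        if (1L + (r - 1L) %% n_per_clade == i) {
          forced[opp_rescue[r]] <- if (r %% 2L == 1L)
            "pseudogene:frameshift" else "pseudogene:premature_stop"
        }
      }
      if (clade == "bulgaricus") {
        forced[ko_lost] <- "absent"
        forced[ko_frag] <- "pseudogene:premature_stop"
      }
      if (clade == "lactis" && i == 2L) {
        forced[var_frag] <- "pseudogene:frameshift"
      }
      params <- evolution_params(
        strain_id = sid, subspecies = clade,
        substitution_rate = strain_div,
        loss_prob = unname(loss_prob[clade]),
        pseudo_prob = unname(pseudo_prob[clade]),
        hgt_genes = cl_hgt, is_library = is_library,
        n_is_insertions = unname(n_is[clade]),
        protected_genes = protected, forced_status = forced,
        hgt_universe = hgt_universe, seed = seeds[6L + k])
      strains[[sid]] <- evolve_strain(cl_anc, params)
      if (sid == sprintf("LAC%02d", 1L)) {
        donor <- strains[[sid]]
        f <- donor$features[donor$features$gene_id == "hgtX" &
                              donor$features$type == "CDS", ]
        dseq <- substr(donor$genome, f$start[1], f$end[1])
        if (f$strand[1] == "-") dseq <- revcomp_chr(dseq)
        xfer_base <- with_seed(seeds[6] + 3L, mutate_orf(dseq, 0.002))
      }
    }
  }

  truth <- do.call(rbind, lapply(strains, `[[`, "truth"))
  rownames(truth) <- NULL
  meta <- stats::setNames(vapply(strains, `[[`, character(1), "subspecies"),
                          names(strains))
  structure(list(
    ancestor = anc, strains = strains, truth = truth, meta = meta,
    mlst_scheme = mlst_scheme, pathway_defs = pathway_defs,
    planted = list(markers = mlst_scheme, pathway_genes = pathway_genes,
                   spec_lactis = spec_lactis, spec_bulg = spec_bulg,
                   rescue_lactis = rescue_lactis, rescue_bulg = rescue_bulg,
                   hgt = hgt_universe, ko_lost = ko_lost, ko_frag = ko_frag,
                   var_frag = var_frag),
    seed = as.integer(seed)
  ), class = "reducto_study")
}

#' @export
print.reducto_study <- function(x, ...) {
  cat(sprintf("simulated study: %d strains (%s), %d ancestral genes, seed %d\n",
              length(x$strains),
              paste(names(table(x$meta)), table(x$meta), collapse = "+",
                    sep = ":"),
              nrow(x$ancestor$gene_table), x$seed))
  invisible(x)
}

# ---- ground-truth evaluation helpers ---------------------------------------

#' Expected core partition from the truth table
#'
#' Computes the A/B/C/D category counts and the overall core directly from
#' planted gene statuses (presence = `intact` or `hgt`; pseudogene fragments
#' and absences are not presence), i.e. what a perfect pipeline should
#' recover.
#'
#' @param truth truth table (rows per strain x gene).
#' @param meta named `strain_id -> subspecies` vector (two labels).
#' @param first subspecies whose categories are A/B (same convention as
#'   [partition_core()]).
#' @return list with `overall_core`, `counts` (A-D), `genes` (named list of
#'   gene-id vectors per category).
#' @export
truth_partition <- function(truth, meta, first = NULL) {
  ssp <- unique(unname(meta))
  stopifnot(length(ssp) == 2L)
  ssp <- order_subspecies(ssp, first)
  pres <- with(truth, table(gene_id, strain_id,
                            factor(status %in% c("intact", "hgt"),
                                   c(FALSE, TRUE)))[, , "TRUE"])
  s1 <- names(meta)[meta == ssp[1]]
  s2 <- names(meta)[meta == ssp[2]]
  n1 <- rowSums(pres[, s1, drop = FALSE] > 0)
  n2 <- rowSums(pres[, s2, drop = FALSE] > 0)
  genes <- rownames(pres)
  in_all1 <- n1 == length(s1); in_all2 <- n2 == length(s2)
  cats <- list(A = genes[in_all1 & n2 == 0],
               B = genes[in_all1 & n2 > 0 & !in_all2],
               C = genes[in_all2 & n1 == 0],
               D = genes[in_all2 & n1 > 0 & !in_all1])
  list(overall_core = sum(in_all1 & in_all2),
       counts = vapply(cats, length, integer(1)), genes = cats)
}

#' Expected fragment-rescue counts from the truth table
#'
#' A clade-specific gene counts as rescued when at least one opposite-clade
#' strain carries it as a pseudogene with a frameshift or premature-stop
#' lesion (the lesion classes whose fragments the detection procedure is
#' designed to catch; bare 3'-truncations leave no frameshift/stop evidence).
#'
#' @param truth truth table.
#' @param meta named subspecies vector.
#' @param specific_genes gene ids of one clade-specific category (A or C).
#' @param opposite the opposite subspecies label.
#' @return integer count.
#' @export
truth_rescue <- function(truth, meta, specific_genes, opposite) {
  frag <- truth[truth$status == "pseudogene" &
                  truth$lesion_type %in% c("frameshift", "premature_stop") &
                  meta[truth$strain_id] == opposite, , drop = FALSE]
  length(intersect(specific_genes, unique(frag$gene_id)))
}

#' Sensitivity/specificity of pseudogene calls against planted truth
#'
#' False positives are calls on genes planted intact (or horizontally
#' acquired).  Recall is measured over planted frameshift and
#' premature-stop pseudogenes — the lesion classes that leave the evidence
#' the procedure requires (the generator places them at least 30 codons from
#' either terminus).  Also checks the evidence class and, for frameshifts,
#' the reported lesion position against the planted one.
#'
#' @param calls calls from [call_pseudogenes()] (possibly several strains).
#' @param truth truth table.
#' @param strains named list of `strain_genome` objects (for lesion
#'   coordinates).
#' @param max_pos_error tolerated frameshift localisation error in bp.
#' @return list with `false_positives`, `n_intact_tested`, `recall`,
#'   `n_target`, `missed` (data.frame), `evidence_ok`, `max_fs_error`.
#' @export
caller_metrics <- function(calls, truth, strains, max_pos_error = 60L) {
  key <- function(s, g) paste(s, g)
  tr <- truth[!is.na(truth$start), , drop = FALSE]
  st_of <- stats::setNames(tr$status, key(tr$strain_id, tr$gene_id))
  lt_of <- stats::setNames(tr$lesion_type, key(tr$strain_id, tr$gene_id))

  called <- calls[calls$verdict == "pseudogene_fragment", , drop = FALSE]
  ck <- key(called$strain_id, called$cds_id)
  fp <- sum(st_of[ck] %in% c("intact", "hgt"), na.rm = TRUE)

  target <- tr[tr$status == "pseudogene" &
                 tr$lesion_type %in% c("frameshift", "premature_stop") &
                 key(tr$strain_id, tr$gene_id) %in%
                   key(calls$strain_id, calls$cds_id), , drop = FALSE]
  tk <- key(target$strain_id, target$gene_id)
  hit <- tk %in% ck
  evid_ok <- TRUE; max_err <- 0
  for (i in which(hit)) {
    row <- called[match(tk[i], ck), ]
    want <- if (target$lesion_type[i] == "frameshift") "frameshift" else "internal_stop"
    if (!grepl(want, row$evidence)) evid_ok <- FALSE
    if (target$lesion_type[i] == "frameshift" && !is.na(row$fs_pos)) {
      st <- strains[[target$strain_id[i]]]
      cds <- st$features[st$features$gene_id == target$gene_id[i] &
                           st$features$type == "CDS", ]
      planted <- if (cds$strand[1] == "+") cds$start[1] + target$lesion_offset[i]
                 else cds$end[1] - target$lesion_offset[i]
      max_err <- max(max_err, abs(row$fs_pos - planted))
    }
  }
  list(false_positives = fp,
       n_intact_tested = sum(calls$verdict == "intact"),
       recall = if (nrow(target)) mean(hit) else NA_real_,
       n_target = nrow(target),
       missed = target[!hit, c("strain_id", "gene_id", "lesion_type"),
                       drop = FALSE],
       evidence_ok = evid_ok, max_fs_error = max_err)
}
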