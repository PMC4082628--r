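#' Similarity edges for ortholog clustering
#'
#' All-vs-all protein comparison under the clustering thresholds: an
#' undirected edge joins two proteins iff their best local alignment
#' simultaneously satisfies e-value strictly below `evalue_max`, identity
#' strictly above `identity_min` over aligned columns, and coverage strictly
#' above `coverage_min` of the longer sequence.  Proteins flagged as
#' pseudogene products are rejected: only non-pseudogene proteins enter the
#' clustering.
#'
#' A shared-peptide prefilter (`min_shared_kmers` words of length
#' `kmer_len`) selects candidate pairs before alignment; pairs below the
#' identity/coverage thresholds cannot lose their qualifying word count, so
#' the edge set equals the brute-force all-pairs evaluation.
#'
#' @param proteome data.frame with `strain_id`, `protein_id`, `sequence`,
#'   `is_pseudo` (see [strain_proteomes()]).
#' @param params a [cluster_params()] object.
#' @param cross_strain_only if `TRUE` (default), only pairs from different
#'   strains are considered (paralog splitting is out of scope).
#' @return data.frame of edges: `p1`, `p2` (protein keys
#'   `"strain|protein"`), `score`, `evalue`, `identity`, `longest_coverage`.
#' @export
similarity_edges <- function(proteome, params = cluster_params(),
                             cross_strain_only = TRUE) {
  stopifnot(is.data.frame(proteome),
            all(c("strain_id", "protein_id", "sequence") %in% names(proteome)))
  if (!is.null(proteome$is_pseudo) && any(proteome$is_pseudo)) {
    stop("proteome contains pseudogene-flagged proteins; ",
         "only proteins encoded by non-pseudogenes may be clustered")
  }
  keys <- protein_keys(proteome)
  if (anyDuplicated(keys)) stop("duplicate (strain_id, protein_id) keys")
  n <- nrow(proteome)
  empty <- data.frame(p1 = character(0), p2 = character(0),
                      score = numeric(0), evalue = numeric(0),
                      identity = numeric(0), longest_coverage = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)

  cand <- candidate_pairs(proteome$sequence, params$kmer_len,
                          params$min_shared_kmers)
  if (cross_strain_only && nrow(cand)) {
    cand <- cand[proteome$strain_id[cand$i] != proteome$strain_id[cand$j], ,
                 drop = FALSE]
  }
  if (!nrow(cand)) return(empty)

  search_n <- sum(nchar(proteome$sequence))
  mat <- get_submat(params$matrix_name)
  rows <- list()
  # batch: all candidate partners of one subject in a single alignment call
  for (j in sort(unique(cand$j))) {
    is <- cand$i[cand$j == j]
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(stats::setNames(proteome$sequence[is], keys[is])),
      Biostrings::AAString(proteome$sequence[j]), type = "local",
      substitutionMatrix = mat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend)
    sc <- Biostrings::score(al)
    identity <- Biostrings::nmatch(al) / Biostrings::nchar(al)
    q_w <- IRanges::width(Biostrings::pattern(al))
    s_w <- IRanges::width(Biostrings::subject(al))
    la <- nchar(proteome$sequence[is]); lb <- nchar(proteome$sequence[j])
    span <- ifelse(la >= lb, q_w, s_w)
    coverage <- span / pmax(la, lb)
    evalue <- ka_evalue(sc, la, search_n)
    keep <- evalue < params$evalue_max & identity > params$identity_min &
      coverage > params$coverage_min
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        p1 = keys[is][keep], p2 = keys[j], score = sc[keep],
        evalue = evalue[keep], identity = identity[keep],
        longest_coverage = coverage[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
protein_keys <- function(proteome) {
  paste(proteome$strain_id, proteome$protein_id, sep = "|")
}

# Candidate pairs sharing >= min_shared distinct k-mers (i < j).
#' @keywords internal
candidate_pairs <- function(seqs, kmer_len, min_shared) {
  idx <- kmer_index(seqs, kmer_len)
  if (!nrow(idx)) return(data.frame(i = integer(0), j = integer(0)))
  dt <- data.table::as.data.table(idx)
  pairs <- dt[dt, on = "kmer", allow.cartesian = TRUE
              ][seq_id < i.seq_id,
                .N, by = .(i = seq_id, j = i.seq_id)]
  pairs <- pairs[pairs$N >= min_shared, c("i", "j")]
  as.data.frame(pairs)
}

# Distinct k-mers per sequence, as a (kmer, seq_id) long table.
#' @keywords internal
kmer_index <- function(seqs, k) {
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    if (nchar(s) < k) return(NULL)
    km <- unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
    data.frame(kmer = km, seq_id = i, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.frame(kmer = character(0), seq_id = integer(0)))
  do.call(rbind, rows)
}

#' Single-linkage ortholog groups
#'
#' Groups are the connected components of the similarity graph: any
#' qualifying hit links two proteins, and linkage is transitive.  Proteins
#' without edges become singleton groups.  Groups are ordered
#' lexicographically by their smallest member key and numbered `OG0001`,
#' `OG0002`, ...
#'
#' @param proteome proteome data.frame (defines the universe of proteins).
#' @param edges edge data.frame from [similarity_edges()] (columns `p1`,
#'   `p2`); endpoints must be known proteins.
#' @return data.frame with `group_id`, `strain_id`, `protein_id`, `key`.
#' @export
cluster_single_linkage <- function(proteome, edges) {
  keys <- protein_keys(proteome)
  if (anyDuplicated(keys)) stop("duplicate (strain_id, protein_id) keys")
  if (nrow(edges)) {
    bad <- setdiff(c(edges$p1, edges$p2), keys)
    if (length(bad)) {
      stop("edge endpoint not in proteome: ", paste(head(bad, 3), collapse = ", "))
    }
  }
  parent <- seq_along(keys)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    e1 <- match(edges$p1, keys); e2 <- match(edges$p2, keys)
    for (r in seq_along(e1)) {
      a <- find(e1[r]); b <- find(e2[r])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  comp <- vapply(seq_along(keys), find, integer(1))
  rep_key <- vapply(split(keys, comp), min, character(1))
  ord <- order(rep_key)
  gid <- stats::setNames(sprintf("OG%04d", order(ord)), names(rep_key))
  out <- data.frame(group_id = unname(gid[as.character(comp)]),
                    strain_id = proteome$strain_id,
                    protein_id = proteome$protein_id,
                    key = keys, stringsAsFactors = FALSE)
  out[order(out$group_id, out$key), , drop = FALSE]
}

#' Core-proteome partition of ortholog groups across two subspecies
#'
#' Computes the overall core (groups with at least one member in every
#' strain) and the four subspecies-specific categories of the core-proteome
#' comparison: `A` = groups present in all strains of the first subspecies
#' and absent from every strain of the second; `B` = present in all of the
#' first, absent from 1 to (n-1) strains of the second; `C` and `D` the
#' mirror images.  Pseudogene fragments never count as presence (they are
#' excluded upstream of clustering); [fragment_rescue()] reports them
#' separately.
#'
#' @param groups clustering result from [cluster_single_linkage()].
#' @param strain_meta named character vector `strain_id -> subspecies`;
#'   exactly two subspecies labels are required and every strain in `groups`
#'   must be present.
#' @param first subspecies whose categories are `A`/`B` (figure convention:
#'   `A` = present in all `first` strains, absent from every strain of the
#'   other).  Defaults to `"lactis"` when that label is present, otherwise
#'   the alphabetically first label.
#' @return object of class `core_partition`: list with `overall_core`,
#'   `counts` (named A/B/C/D), `groups` (named list of group-id vectors per
#'   category), `subspecies` (the two labels, A/B belong to the first),
#'   `per_subspecies_core` (group counts present in all strains of each
#'   subspecies), `n_groups`.
#' @export
partition_core <- function(groups, strain_meta, first = NULL) {
  strains <- unique(groups$strain_id)
  missing <- setdiff(strains, names(strain_meta))
  if (length(missing)) {
    stop("strains missing from strain_meta: ", paste(missing, collapse = ", "))
  }
  ssp <- unique(unname(strain_meta[strains]))
  if (length(ssp) != 2L) {
    stop("exactly two subspecies labels are required, got: ",
         paste(ssp, collapse = ", "))
  }
  ssp <- order_subspecies(ssp, first)
  s1 <- strains[strain_meta[strains] == ssp[1]]
  s2 <- strains[strain_meta[strains] == ssp[2]]

  pres <- table(groups$group_id, groups$strain_id) > 0
  n1 <- rowSums(pres[, s1, drop = FALSE])
  n2 <- rowSums(pres[, s2, drop = FALSE])
  gids <- rownames(pres)

  in_all1 <- n1 == length(s1)
  in_all2 <- n2 == length(s2)
  cat_A <- gids[in_all1 & n2 == 0]
  cat_B <- gids[in_all1 & n2 > 0 & !in_all2]
  cat_C <- gids[in_all2 & n1 == 0]
  cat_D <- gids[in_all2 & n1 > 0 & !in_all1]

  structure(list(
    overall_core = sum(in_all1 & in_all2),
    counts = c(A = length(cat_A), B = length(cat_B),
               C = length(cat_C), D = length(cat_D)),
    groups = list(A = cat_A, B = cat_B, C = cat_C, D = cat_D),
    subspecies = ssp,
    per_subspecies_core = stats::setNames(c(sum(in_all1), sum(in_all2)), ssp),
    n_groups = length(gids)
  ), class = "core_partition")
}

#' @export
print.core_partition <- function(x, ...) {
  cat(sprintf("core partition (%s vs %s): overall core %d of %d groups\n",
              x$subspecies[1], x$subspecies[2], x$overall_core, x$n_groups))
  cat(sprintf("  A=%d (all %s, no %s)  B=%d  C=%d (all %s, no %s)  D=%d\n",
              x$counts["A"], x$subspecies[1], x$subspecies[2], x$counts["B"],
              x$counts["C"], x$subspecies[2], x$subspecies[1], x$counts["D"]))
  invisible(x)
}

#' @keywords internal
order_subspecies <- function(ssp, first = NULL) {
  if (is.null(first)) first <- if ("lactis" %in% ssp) "lactis" else sort(ssp)[1]
  if (!first %in% ssp) stop("'first' is not one of the subspecies labels")
  c(first, setdiff(ssp, first))
}

#' Rescue subspecies-specific groups through pseudogene fragments
#'
#' A subspecies-specific ortholog group is "rescued" when at least one
#' strain of the opposite subspecies carries a pseudogene fragment whose
#' best-hit protein belongs to the group — evidence that the specificity
#' arose by differential gene loss rather than acquisition.
#'
#' @param specific_groups character vector of group ids (category A or C of
#'   [partition_core()]).
#' @param groups clustering result (maps proteins to groups).
#' @param pseudo_calls data.frame of pseudogene calls with `strain_id`,
#'   `cds_id`, `verdict`, `best_hit` (protein key `"strain|protein"`).
#' @param strain_meta named `strain_id -> subspecies` vector.
#' @param opposite subspecies label in which fragments are sought.
#' @return list with `n_rescued`, `rescued` (group ids), `n_specific`.
#' @export
fragment_rescue <- function(specific_groups, groups, pseudo_calls,
                            strain_meta, opposite) {
  if (is.null(pseudo_calls) || !nrow(pseudo_calls)) {
    return(list(n_rescued = 0L, rescued = character(0),
                n_specific = length(specific_groups)))
  }
  frag <- pseudo_calls[pseudo_calls$verdict == "pseudogene_fragment" &
                         strain_meta[pseudo_calls$strain_id] == opposite &
                         !is.na(pseudo_calls$best_hit), , drop = FALSE]
  hit_group <- groups$group_id[match(frag$best_hit, groups$key)]
  rescued <- intersect(specific_groups, hit_group)
  list(n_rescued = length(rescued), rescued = sort(rescued),
       n_specific = length(specific_groups))
}
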