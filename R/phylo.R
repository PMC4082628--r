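#' Pairwise distance matrix from an alignment
#'
#' Pairwise deletion of gap (and ambiguous) columns; `p` is the mismatch
#' fraction over valid columns, `K2P` the Kimura two-parameter closed form
#' from transition/transversion fractions.  Pairs where the K2P logarithm is
#' undefined are flagged `NA` (never fabricated).
#'
#' @param aln an `msa` object or character matrix.
#' @param model `"p"` or `"K2P"` (nucleotide alignments only).
#' @return symmetric numeric matrix with row/column labels.
#' @export
distance_matrix <- function(aln, model = c("p", "K2P")) {
  model <- match.arg(model)
  m <- msa_matrix(aln)
  n <- nrow(m)
  valid_chr <- if (model == "K2P") c("A", "C", "G", "T") else NULL
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  purine <- c("A", "G")
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- m[i, ]; b <- m[j, ]
    ok <- a != "-" & b != "-"
    if (model == "K2P") ok <- ok & a %in% valid_chr & b %in% valid_chr
    a <- a[ok]; b <- b[ok]
    nv <- length(a)
    if (nv == 0L) { D[i, j] <- D[j, i] <- NA_real_; next }
    if (model == "p") {
      d <- sum(a != b) / nv
    } else {
      diff <- a != b
      ts <- sum(diff & (a %in% purine) == (b %in% purine)) / nv
      tv <- sum(diff) / nv - ts
      arg1 <- 1 - 2 * ts - tv
      arg2 <- 1 - 2 * tv
      d <- if (arg1 <= 0 || arg2 <= 0) NA_real_ else
        -0.5 * log(arg1 * sqrt(arg2))
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (Saitou & Nei agglomeration) from a distance
#' matrix; recovers any additive tree exactly, topology and branch lengths.
#' Negative branch lengths are clamped to zero with the deficit moved to the
#' sister edge; ties in the Q criterion break deterministically on the
#' smallest pair of node labels.
#'
#' @param d symmetric numeric matrix with zero diagonal, labels as
#'   dimnames, `n >= 3`; `NA` entries are rejected.
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (ncol(d) != n || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)) ||
      any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be square and symmetric with zero diagonal")
  }
  if (any(is.na(d))) stop("distance matrix contains NA")
  labels <- rownames(d) %||% paste0("t", seq_len(n))

  nodes <- lapply(seq_len(n), function(i) list(nwk = escape_label(labels[i]),
                                               min_label = labels[i]))
  D <- d
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.10g", max(x, 0))

  while (length(active) > 3L) {
    r <- length(active)
    Dsub <- D[active, active, drop = FALSE]
    R <- rowSums(Dsub)
    Q <- (r - 2) * Dsub - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-9, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_lab <- apply(cand, 1L, function(rc) {
      paste(sort(c(nodes[[active[rc[1]]]]$min_label,
                   nodes[[active[rc[2]]]]$min_label)), collapse = "\r")
    })
    pick <- cand[order(pair_lab)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    dij <- D[i, j]
    li <- dij / 2 + (R[pick[1]] - R[pick[2]]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_id <- nrow(D) + 1L
    newD <- (D[i, active] + D[j, active] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    D[new_id, active] <- newD
    D[active, new_id] <- newD
    D[new_id, new_id] <- 0
    nodes[[new_id]] <- list(
      nwk = sprintf("(%s:%s,%s:%s)", nodes[[i]]$nwk, fmt(li),
                    nodes[[j]]$nwk, fmt(lj)),
      min_label = min(nodes[[i]]$min_label, nodes[[j]]$min_label))
    active <- c(setdiff(active, c(i, j)), new_id)
  }

  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[[a]]$nwk, fmt(la),
                 nodes[[b]]$nwk, fmt(lb), nodes[[c3]]$nwk, fmt(lc))
  ape::read.tree(text = nwk)
}

#' @keywords internal
escape_label <- function(x) {
  if (grepl("[ ,();:\\[\\]]", x)) gsub("[ ,();:\\[\\]]", "_", x) else x
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the split is canonicalised
#' as the sorted leaf set on the side not containing the alphabetically
#' first leaf, serialised to a string.
#'
#' @param tree a `phylo` object.
#' @param support_min if not `NULL`, keep only bipartitions whose edge
#'   support (numeric node labels; absent labels count as 100) is at least
#'   this value.
#' @return character vector of bipartition strings.
#' @export
tree_bipartitions <- function(tree, support_min = NULL) {
  tips <- tree$tip.label
  n <- length(tips)
  ref <- sort(tips)[1]
  desc <- clade_tips(tree)
  out <- character(0)
  has_lab <- !is.null(tree$node.label)
  for (node in (n + 2L):(n + tree$Nnode)) {   # skip the root
    set <- desc[[node]]
    if (length(set) < 2L || length(set) > n - 2L) next
    if (!is.null(support_min) && has_lab) {
      lab <- tree$node.label[node - n]
      sup <- suppressWarnings(as.numeric(lab))
      if (!is.na(sup) && sup < support_min) next
    }
    side <- if (ref %in% set) setdiff(tips, set) else set
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# tip labels under each node (index = node id)
#' @keywords internal
clade_tips <- function(tree) {
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Robinson-Foulds incongruence between two trees
#'
#' Trees are restricted to their shared leaves (at least 4 required); the RF
#' distance is the size of the symmetric difference of non-trivial
#' bipartition sets.  The incongruence flag — the screen used to call
#' horizontal transfer from a marker-gene tree that disagrees with the
#' 16S/MLST tree — is stricter than RF > 0: it requires a well-supported
#' split of one tree (bootstrap >= `support_threshold`; edges without
#' support values count as supported) to be *incompatible* with a
#' well-supported split of the other.  A split merely unresolved in the
#' other tree is not evidence of transfer.
#'
#' @param t1,t2 `phylo` objects.
#' @param support_threshold minimal bootstrap support for an edge to enter
#'   the incongruence test.
#' @return list with `rf`, `n_shared_leaves`, `incongruent`, `conflicts`
#'   (data.frame of conflicting split pairs).
#' @export
rf_incongruence <- function(t1, t2, support_threshold = 70) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) stop("need at least 4 shared leaves")
  t1 <- ape::keep.tip(t1, shared)
  t2 <- ape::keep.tip(t2, shared)
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  s1 <- tree_bipartitions(t1, support_min = support_threshold)
  s2 <- tree_bipartitions(t2, support_min = support_threshold)
  conflicts <- list()
  for (a in s1) for (b in s2) {
    if (splits_incompatible(a, b, shared)) {
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        split1 = a, split2 = b, stringsAsFactors = FALSE)
    }
  }
  list(rf = rf, n_shared_leaves = length(shared),
       incongruent = length(conflicts) > 0,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
         data.frame(split1 = character(0), split2 = character(0)))
}

# Two unrooted splits are compatible iff at least one of the four side
# intersections is empty (they can then coexist in one tree).
#' @keywords internal
splits_incompatible <- function(a, b, tips) {
  a1 <- strsplit(a, "|", fixed = TRUE)[[1]]
  b1 <- strsplit(b, "|", fixed = TRUE)[[1]]
  a2 <- setdiff(tips, a1)
  b2 <- setdiff(tips, b1)
  length(intersect(a1, b1)) > 0 && length(intersect(a1, b2)) > 0 &&
    length(intersect(a2, b1)) > 0 && length(intersect(a2, b2)) > 0
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal edge of the full-data tree with
#' the percentage of replicates containing its bipartition.
#'
#' @param aln an `msa` object or character matrix.
#' @param n_reps bootstrap replicates (>= 1).
#' @param seed integer seed (deterministic supports for a fixed seed).
#' @param model distance model passed to [distance_matrix()].
#' @return a `phylo` tree whose `node.label` holds supports in `[0, 100]`
#'   (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L, model = "p") {
  stopifnot(n_reps >= 1)
  m <- msa_matrix(aln)
  base <- nj_tree(distance_matrix(m, model))
  n <- length(base$tip.label)
  counts <- stats::setNames(numeric(0), character(0))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      Dr <- distance_matrix(m[, cols, drop = FALSE], model)
      if (any(is.na(Dr))) next
      bp <- tree_bipartitions(nj_tree(Dr))
      for (b in bp) {
        cur <- counts[b]
        counts[b] <- if (is.na(cur)) 1 else cur + 1
      }
    }
  })
  base_bp <- tree_bipartitions(base)
  sup <- vapply(base_bp, function(b) {
    100 * (if (is.na(counts[b])) 0 else counts[b]) / n_reps
  }, numeric(1))
  # map supports onto internal nodes
  desc <- clade_tips(base)
  tips <- base$tip.label
  ref <- sort(tips)[1]
  labs <- rep("", base$Nnode)
  for (node in (n + 2L):(n + base$Nnode)) {
    set <- desc[[node]]
    if (length(set) < 2L || length(set) > n - 2L) next
    side <- if (ref %in% set) setdiff(tips, set) else set
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(sup)) labs[node - n] <- sprintf("%g", sup[[key]])
  }
  base$node.label <- labs
  base
}

#' Bootstrap support of the split defined by a tip set
#'
#' @param tree a `phylo` object with numeric node labels (e.g. from
#'   [bootstrap_support()]).
#' @param tips tip labels on one side of the split.
#' @return support in `[0, 100]`, or `NA` if the split is not an edge of the
#'   tree.
#' @export
split_support <- function(tree, tips) {
  all_tips <- tree$tip.label
  n <- length(all_tips)
  ref <- sort(all_tips)[1]
  key <- {
    side <- if (ref %in% tips) sort(setdiff(all_tips, tips)) else sort(tips)
    paste(side, collapse = "|")
  }
  desc <- clade_tips(tree)
  for (node in (n + 2L):(n + tree$Nnode)) {
    set <- desc[[node]]
    if (length(set) < 2L || length(set) > n - 2L) next
    side <- if (ref %in% set) setdiff(all_tips, set) else set
    if (paste(sort(side), collapse = "|") == key) {
      return(suppressWarnings(as.numeric(tree$node.label[node - n])))
    }
  }
  NA_real_
}

#' Extract marker-locus sequences and build the MLST tree
#'
#' Pulls each scheme locus (a gene id) out of every strain's annotation,
#' aligns the loci separately, concatenates the alignments in scheme order
#' and returns the neighbor-joining tree of the concatenation.  Strains
#' missing a locus are excluded with a warning.
#'
#' @param strains list of `strain_genome` objects.
#' @param scheme named character vector `locus name -> gene id` (e.g. the
#'   seven housekeeping loci fusA, gyrB, hsp60, ileS, pyrG, recA, recG).
#' @param n_boot bootstrap replicates for edge supports (0 = none).
#' @param seed seed for the bootstrap.
#' @param model distance model.
#' @return list with `alignment` (concatenated `msa`), `tree`,
#'   `strains_used`, `per_locus` (list of per-locus alignments).
#' @export
mlst_run <- function(strains, scheme, n_boot = 0L, seed = 1L, model = "p") {
  stopifnot(length(scheme) >= 1)
  seqs_by_locus <- lapply(scheme, function(gid) {
    out <- list()
    for (st in strains) {
      f <- st$features
      k <- which(f$type == "CDS" & f$gene_id == gid)
      if (!length(k)) next
      s <- substr(st$genome, f$start[k[1]], f$end[k[1]])
      if (f$strand[k[1]] == "-") s <- revcomp_chr(s)
      out[[st$strain_id]] <- s
    }
    unlist(out)
  })
  all_ids <- vapply(strains, `[[`, character(1), "strain_id")
  have <- Reduce(intersect, lapply(seqs_by_locus, names))
  dropped <- setdiff(all_ids, have)
  if (length(dropped)) {
    warning("strains excluded (missing locus): ", paste(dropped, collapse = ", "))
  }
  if (length(have) < 3L) stop("fewer than 3 strains carry all loci")
  per_locus <- lapply(seqs_by_locus, function(s) progressive_align(s[have]))
  cat_aln <- do.call(cbind, lapply(per_locus, function(a) msa_matrix(a)[have, , drop = FALSE]))
  aln <- structure(list(labels = have,
                        aln = apply(cat_aln, 1L, paste, collapse = ""),
                        ncol = ncol(cat_aln)), class = "msa")
  tree <- if (n_boot > 0) {
    bootstrap_support(cat_aln, n_reps = n_boot, seed = seed, model = model)
  } else {
    nj_tree(distance_matrix(cat_aln, model))
  }
  list(alignment = aln, tree = tree, strains_used = have,
       per_locus = per_locus)
}

#' Subspecies-diagnostic alignment columns
#'
#' A column qualifies when every member of every `share_groups` group (plus
#' the query, if given) carries one identical state, and the `differ_group`
#' members carry a state conserved within their group but different from the
#' shared one.  Gap-containing columns (among the rows considered) are
#' skipped.  This is the scan used to place an unclassified strain relative
#' to named subspecies from its 16S sequence.
#'
#' @param aln an `msa` object or character matrix.
#' @param groups named list: group label -> member row labels.
#' @param share_groups group labels that must share the query's state.
#' @param differ_group single group label that must differ.
#' @param query optional row label of the query sequence.
#' @return data.frame with `site` (1-based alignment column),
#'   `shared_state`, `differ_state`.
#' @export
diagnostic_sites <- function(aln, groups, share_groups, differ_group,
                             query = NULL) {
  m <- msa_matrix(aln)
  if (any(!vapply(groups, length, integer(1)))) stop("empty group")
  stopifnot(all(share_groups %in% names(groups)),
            differ_group %in% names(groups))
  rows_share <- c(unlist(groups[share_groups], use.names = FALSE), query)
  rows_diff <- groups[[differ_group]]
  missing <- setdiff(c(rows_share, rows_diff), rownames(m))
  if (length(missing)) {
    stop("labels not in alignment: ", paste(missing, collapse = ", "))
  }
  out <- list()
  for (j in seq_len(ncol(m))) {
    a <- m[rows_share, j]; b <- m[rows_diff, j]
    if (any(a == "-") || any(b == "-")) next
    if (length(unique(a)) == 1L && length(unique(b)) == 1L && a[1] != b[1]) {
      out[[length(out) + 1L]] <- data.frame(site = j, shared_state = a[1],
                                            differ_state = b[1],
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(site = integer(0), shared_state = character(0),
                      differ_state = character(0)))
  }
  do.call(rbind, out)
}
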