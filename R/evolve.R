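#' Evolution parameters for one simulated strain
#'
#' @param strain_id strain label.
#' @param subspecies subspecies label (clade) the strain belongs to.
#' @param substitution_rate per-site substitution probability applied to all
#'   ancestral sequence. Substitutions in coding genes are ORF-preserving:
#'   they never create an in-frame stop nor touch the start/stop codons, so
#'   that planted lesions remain the only source of gene disruption.
#' @param loss_prob per-gene probability of complete loss.
#' @param pseudo_prob per-gene probability of pseudogenisation.
#' @param pseudo_mix named proportions over lesion types
#'   `frameshift`, `premature_stop`, `truncation`; must sum to 1.
#' @param hgt_genes named `DNAStringSet` (or named character vector) of
#'   horizontally acquired genes carried by this strain.
#' @param is_library named `DNAStringSet`/character vector of IS element
#'   sequences; names are family labels.
#' @param n_is_insertions number of IS insertions, at most one per
#'   intergenic spacer.
#' @param protected_genes gene ids never lost or pseudogenised (e.g. MLST
#'   marker loci).
#' @param forced_status named character vector `gene_id -> status` overriding
#'   the random draw; values are `"intact"`, `"absent"`, `"pseudogene"`, or
#'   `"pseudogene:frameshift"` / `"pseudogene:premature_stop"` /
#'   `"pseudogene:truncation"`.
#' @param hgt_universe character vector of all HGT gene ids in the study
#'   (carried or not); the truth table gets one row per strain for each.
#' @param seed integer seed; evolution is byte-reproducible for a fixed seed.
#' @return an object of class `evolution_params`.
#' @export
evolution_params <- function(strain_id, subspecies = NA_character_,
                             substitution_rate = 0, loss_prob = 0,
                             pseudo_prob = 0,
                             pseudo_mix = c(frameshift = 1 / 3,
                                            premature_stop = 1 / 3,
                                            truncation = 1 / 3),
                             hgt_genes = NULL, is_library = NULL,
                             n_is_insertions = 0L,
                             protected_genes = character(),
                             forced_status = character(),
                             hgt_universe = NULL, seed = 1L) {
  probs <- c(substitution_rate, loss_prob, pseudo_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("substitution_rate, loss_prob and pseudo_prob must lie in [0, 1]")
  }
  if (loss_prob + pseudo_prob > 1) stop("loss_prob + pseudo_prob must be <= 1")
  if (!setequal(names(pseudo_mix),
                c("frameshift", "premature_stop", "truncation")) ||
      abs(sum(pseudo_mix) - 1) > 1e-8 || any(pseudo_mix < 0)) {
    stop("pseudo_mix must be named proportions over frameshift/premature_stop/truncation summing to 1")
  }
  as_chr_set <- function(x) {
    if (is.null(x)) return(character(0))
    stats::setNames(as.character(x), names(x))
  }
  hgt <- as_chr_set(hgt_genes)
  structure(list(
    strain_id = strain_id, subspecies = subspecies,
    substitution_rate = substitution_rate, loss_prob = loss_prob,
    pseudo_prob = pseudo_prob,
    pseudo_mix = pseudo_mix[c("frameshift", "premature_stop", "truncation")],
    hgt_genes = hgt, is_library = as_chr_set(is_library),
    n_is_insertions = as.integer(n_is_insertions),
    protected_genes = protected_genes, forced_status = forced_status,
    hgt_universe = hgt_universe %||% names(hgt) %||% character(0),
    seed = as.integer(seed)
  ), class = "evolution_params")
}

# ---- substitution machinery ------------------------------------------------

#' @keywords internal
subst_bases <- function(v, idx) {
  if (!length(idx)) return(v)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- sample.int(3L, length(idx), replace = TRUE)
  v[idx] <- mapply(function(b, k) alt[[b]][k], v[idx], pick)
  v
}

# Uniform substitutions preserving the reading frame semantics: start codon
# and terminal stop untouched, internal codons resampled until non-stop.
#' @keywords internal
mutate_orf <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "")[[1]]
  L <- length(v)
  if (L < 9L) return(s)
  idx <- which(runif(L) < rate)
  idx <- idx[idx > 3L & idx <= L - 3L]
  if (!length(idx)) return(s)
  v <- subst_bases(v, idx)
  cod_starts <- unique(((idx - 1L) %/% 3L) * 3L + 1L)
  for (guard in 1:100) {
    bad <- cod_starts[vapply(cod_starts, function(cs) {
      paste(v[cs:(cs + 2L)], collapse = "") %in% .STOP_CODONS
    }, logical(1))]
    if (!length(bad)) break
    for (cs in bad) v <- subst_bases(v, idx[idx >= cs & idx <= cs + 2L])
  }
  paste(v, collapse = "")
}

#' @keywords internal
mutate_dna <- function(s, rate) {
  if (rate <= 0 || !nzchar(s)) return(s)
  v <- strsplit(s, "")[[1]]
  idx <- which(runif(length(v)) < rate)
  paste(subst_bases(v, idx), collapse = "")
}

#' Derive a diverged copy of a pangenome (e.g. a clade ancestor)
#'
#' Applies ORF-preserving substitutions to every gene and plain substitutions
#' to spacers and the rRNA locus.
#' @param anc an `ancestral_pangenome`.
#' @param rate per-site substitution probability.
#' @param seed integer seed.
#' @return a new `ancestral_pangenome`.
#' @export
mutate_pangenome <- function(anc, rate, seed = 1L) {
  stopifnot(inherits(anc, "ancestral_pangenome"))
  with_seed(seed, {
    out <- anc
    out$genes <- stats::setNames(Biostrings::DNAStringSet(
      vapply(as.character(anc$genes), mutate_orf, character(1), rate = rate)
    ), names(anc$genes))
    out$spacers <- Biostrings::DNAStringSet(
      vapply(as.character(anc$spacers), mutate_dna, character(1), rate = rate))
    out$rrna <- mutate_dna(anc$rrna, rate)
    out$rrna_spacer <- mutate_dna(anc$rrna_spacer, rate)
    out
  })
}

# ---- lesion planting -------------------------------------------------------

# Scan codons of `seq_plus_context` from position 1; returns the protein
# length (aa, excluding stop) of the open reading frame, and the CDS length
# in nt (including the stop codon, or the last complete codon if no stop).
#' @keywords internal
scan_orf <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return(list(aa = 0L, nt = 0L, has_stop = FALSE))
  codons <- substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  idx <- which(codons %in% .STOP_CODONS)[1]
  if (is.na(idx)) return(list(aa = n %/% 3L, nt = n, has_stop = FALSE))
  list(aa = idx - 1L, nt = 3L * idx, has_stop = TRUE)
}

# Plant a single +-1 frameshift at a codon offset chosen so that the
# re-annotated ORF is short enough to trigger the +/-10% length anomaly
# (margin 1.15); `context` is the downstream sequence in coding orientation.
#' @keywords internal
plant_frameshift <- function(s, context, margin = 1.15) {
  P <- nchar(s) %/% 3L - 1L
  lo <- 30L; hi <- P - 30L
  if (hi < lo) { lo <- 2L; hi <- max(2L, P - 2L) }
  cand <- expand.grid(t = lo:hi, op = c("ins", "del"), stringsAsFactors = FALSE)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  ins_base <- sample(c("A", "C", "G", "T"), 1L)
  for (i in seq_len(nrow(cand))) {
    t <- cand$t[i]
    lesioned <- if (cand$op[i] == "ins") {
      paste0(substr(s, 1L, 3L * t), ins_base, substr(s, 3L * t + 1L, nchar(s)))
    } else {
      paste0(substr(s, 1L, 3L * t), substr(s, 3L * t + 2L, nchar(s)))
    }
    f <- scan_orf(paste0(lesioned, context))$aa
    if (P > margin * f && f >= t) {
      return(list(seq = lesioned, offset = 3L * t, op = cand$op[i],
                  type = "frameshift"))
    }
  }
  NULL
}

#' @keywords internal
plant_premature_stop <- function(s, margin = 1.15) {
  P <- nchar(s) %/% 3L - 1L
  lo <- 30L; hi <- min(P - 30L, floor(P / margin))
  if (hi < lo) { lo <- max(2L, min(30L, P - 2L)); hi <- max(lo, floor(P / 1.2)) }
  t <- if (hi > lo) sample(lo:hi, 1L) else lo
  stopc <- sample(.STOP_CODONS, 1L)
  seq <- paste0(substr(s, 1L, 3L * (t - 1L)), stopc,
                substr(s, 3L * t + 1L, nchar(s)))
  list(seq = seq, offset = 3L * (t - 1L), op = "stop", type = "premature_stop")
}

# Remove 30-70% of the 3' end (stop codon included); the surviving prefix is
# short enough that it can never satisfy the coverage threshold of the
# ortholog clustering.
#' @keywords internal
plant_truncation <- function(s) {
  len <- nchar(s)
  cut <- ceiling(runif(1, 0.3, 0.7) * len)
  list(seq = substr(s, 1L, len - cut), offset = len - cut, op = "cut",
       type = "truncation")
}

# ---- strain evolution ------------------------------------------------------

#' Evolve one strain genome from a (clade) ancestor
#'
#' Applies substitutions, gene loss, pseudogenising lesions (one event per
#' gene: a single +-1 frameshift, an in-frame stop substitution, or a
#' 3'-truncation), horizontal acquisitions, and IS-element insertions that
#' are confined to intergenic spacers.  Re-annotates every surviving gene the
#' way a naive gene caller would: the CDS runs from the ancestral start codon
#' to the first in-frame stop, so lesioned genes yield shortened or
#' frame-shifted CDS fragments.
#'
#' @param ancestor an `ancestral_pangenome` (typically a clade ancestor from
#'   [mutate_pangenome()]).
#' @param params an [evolution_params()] object.
#' @return an object of class `strain_genome`: list with `strain_id`,
#'   `subspecies`, `genome` (character), `features` (data.frame: `type`,
#'   `feature_id`, `gene_id`, `start`, `end`, `strand`, `family`), `truth`
#'   (one row per ancestral or HGT gene: `strain_id`, `gene_id`, `status`,
#'   `lesion_type`, `lesion_offset`, `start`, `end`), and `proteins`
#'   (named character vector of intact-gene translations).
#' @export
evolve_strain <- function(ancestor, params) {
  stopifnot(inherits(ancestor, "ancestral_pangenome"),
            inherits(params, "evolution_params"))
  with_seed(params$seed, {
    gt <- ancestor$gene_table
    n <- nrow(gt)

    genes <- vapply(as.character(ancestor$genes), mutate_orf, character(1),
                    rate = params$substitution_rate)
    spacers <- vapply(as.character(ancestor$spacers), mutate_dna, character(1),
                      rate = params$substitution_rate)
    rrna <- mutate_dna(ancestor$rrna, params$substitution_rate)
    rrna_spacer <- mutate_dna(ancestor$rrna_spacer, params$substitution_rate)
    hgt <- vapply(params$hgt_genes, mutate_orf, character(1),
                  rate = params$substitution_rate)

    status <- character(n)
    lesion_type <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      gid <- gt$gene_id[i]
      forced <- unname(params$forced_status[gid])
      if (!is.na(forced) && length(forced)) {
        if (startsWith(forced, "pseudogene")) {
          status[i] <- "pseudogene"
          lesion_type[i] <- if (grepl(":", forced)) {
            sub("^pseudogene:", "", forced)
          } else {
            sample(names(params$pseudo_mix), 1L, prob = params$pseudo_mix)
          }
        } else {
          status[i] <- match.arg(forced, c("intact", "absent"))
        }
      } else if (gid %in% params$protected_genes) {
        status[i] <- "intact"
      } else {
        u <- runif(1)
        if (u < params$loss_prob) {
          status[i] <- "absent"
        } else if (u < params$loss_prob + params$pseudo_prob) {
          status[i] <- "pseudogene"
          lesion_type[i] <- sample(names(params$pseudo_mix), 1L,
                                   prob = params$pseudo_mix)
        } else {
          status[i] <- "intact"
        }
      }
    }

    # ordered piece list; gene/hgt sequences kept in coding orientation
    pc <- function(kind, id, seq, strand = "+", status = NA_character_) {
      data.frame(kind = kind, id = id, seq = seq, strand = strand,
                 status = status, lesion_type = NA_character_,
                 lesion_offset = NA_integer_, stringsAsFactors = FALSE)
    }
    pieces <- list()
    for (i in seq_len(n)) {
      pieces[[length(pieces) + 1L]] <- pc("spacer", sprintf("sp%04d", i), spacers[i])
      if (status[i] != "absent") {
        pieces[[length(pieces) + 1L]] <-
          pc("gene", gt$gene_id[i], unname(genes[i]), gt$strand[i], status[i])
      }
    }
    pieces[[length(pieces) + 1L]] <- pc("spacer", sprintf("sp%04d", n + 1L),
                                        spacers[n + 1L])
    for (k in seq_along(hgt)) {
      pieces[[length(pieces) + 1L]] <- pc("spacer", sprintf("sph%02d", k),
                                          random_dna(ancestor$spacer_len,
                                                     ancestor$gc_target))
      pieces[[length(pieces) + 1L]] <- pc("hgt", names(hgt)[k], unname(hgt[k]),
                                          "+", "hgt")
    }
    if (nzchar(rrna)) {
      pieces[[length(pieces) + 1L]] <- pc("spacer", "spr", rrna_spacer)
      pieces[[length(pieces) + 1L]] <- pc("rrna", "rrna16S", rrna)
    }
    pieces <- do.call(rbind, pieces)
    rownames(pieces) <- NULL
    pieces$lesion_type[match(gt$gene_id[status == "pseudogene"], pieces$id)] <-
      lesion_type[status == "pseudogene"]

    pieces <- plant_all_lesions(pieces)
    asm <- assemble_pieces(pieces)
    ann <- annotate_cds(asm$genome, pieces, asm$starts)
    res <- insert_is_elements(pieces, asm, ann, params)

    truth <- build_truth(gt, params, pieces, res$ann)
    proteins <- extract_proteins(res$genome, res$ann,
                                 statuses = c("intact", "hgt"))

    structure(list(
      strain_id = params$strain_id, subspecies = params$subspecies,
      genome = res$genome, features = res$features, truth = truth,
      proteins = proteins, seed = params$seed
    ), class = "strain_genome")
  })
}

#' @export
print.strain_genome <- function(x, ...) {
  cat(sprintf("strain %s (%s): %d bp, %d features, %d intact proteins\n",
              x$strain_id, x$subspecies, nchar(x$genome), nrow(x$features),
              length(x$proteins)))
  invisible(x)
}

# Plant all lesions, then verify against the assembled genome that every
# frameshift still produces an anomaly-triggering ORF (an ORF may run past
# its own gene into downstream sequence whose final content depends on other
# lesions); replant the rare inconsistent ones until stable.
#' @keywords internal
plant_all_lesions <- function(pieces, max_iter = 10L, cap = 6000L) {
  todo <- which(pieces$kind == "gene" & pieces$status == "pseudogene")
  for (j in todo) {
    pieces <- plant_one_lesion(pieces, j, cap)
  }
  for (iter in seq_len(max_iter)) {
    bad <- integer(0)
    for (j in todo) {
      if (pieces$lesion_type[j] != "frameshift") next
      P <- orig_protein_len(pieces, j)
      f <- scan_orf(paste0(pieces$seq[j], coding_context(pieces, j, cap)))$aa
      if (P <= 1.1 * f) bad <- c(bad, j)
    }
    if (!length(bad)) break
    for (j in bad) {
      pieces$lesion_offset[j] <- NA_integer_
      pieces <- plant_one_lesion(pieces, j, cap, reuse = TRUE)
    }
    if (iter == max_iter) {
      for (j in bad) {
        pieces$lesion_type[j] <- "premature_stop"
        pieces$lesion_offset[j] <- NA_integer_
        pieces <- plant_one_lesion(pieces, j, cap, reuse = TRUE)
      }
    }
  }
  pieces
}

# Ancestral (pre-lesion) protein length is not recoverable from a lesioned
# piece; stash it in an attribute the first time we see the gene.
#' @keywords internal
orig_protein_len <- function(pieces, j) {
  lens <- attr(pieces, "orig_aa")
  lens[[pieces$id[j]]]
}

#' @keywords internal
plant_one_lesion <- function(pieces, j, cap = 6000L, reuse = FALSE) {
  lens <- attr(pieces, "orig_aa") %||% list()
  if (!reuse) lens[[pieces$id[j]]] <- nchar(pieces$seq[j]) %/% 3L - 1L
  attr(pieces, "orig_aa") <- lens
  s <- if (reuse) attr(pieces, "orig_seq")[[pieces$id[j]]] else pieces$seq[j]
  seqs <- attr(pieces, "orig_seq") %||% list()
  seqs[[pieces$id[j]]] <- s
  attr(pieces, "orig_seq") <- seqs

  ctx <- coding_context(pieces, j, cap)
  les <- switch(pieces$lesion_type[j],
    frameshift = plant_frameshift(s, ctx) %||% plant_premature_stop(s),
    premature_stop = plant_premature_stop(s),
    truncation = plant_truncation(s)
  )
  pieces$seq[j] <- les$seq
  pieces$lesion_type[j] <- les$type
  pieces$lesion_offset[j] <- les$offset
  pieces
}

# Downstream sequence in coding orientation for the gene in piece row j:
# for '+' genes the following pieces, for '-' genes the reverse complement
# of the preceding ones.  Always reflects the current state of `pieces`.
#' @keywords internal
coding_context <- function(pieces, j, cap = 6000L) {
  emit <- function(i) {
    s <- pieces$seq[i]
    if (pieces$kind[i] %in% c("gene", "hgt") && pieces$strand[i] == "-") {
      revcomp_chr(s)
    } else s
  }
  out <- character(0)
  total <- 0L
  if (pieces$strand[j] == "+") {
    idx <- seq_len(nrow(pieces))
    idx <- idx[idx > j]
    for (i in idx) {
      out <- c(out, emit(i)); total <- total + nchar(pieces$seq[i])
      if (total >= cap) break
    }
    ctx <- paste(out, collapse = "")
  } else {
    idx <- rev(seq_len(j - 1L))
    for (i in idx) {
      out <- c(emit(i), out); total <- total + nchar(pieces$seq[i])
      if (total >= cap) break
    }
    ctx <- revcomp_chr(paste(out, collapse = ""))
  }
  ctx
}

#' @keywords internal
assemble_pieces <- function(pieces) {
  emitted <- vapply(seq_len(nrow(pieces)), function(i) {
    s <- pieces$seq[i]
    if (pieces$kind[i] %in% c("gene", "hgt") && pieces$strand[i] == "-") {
      revcomp_chr(s)
    } else s
  }, character(1))
  w <- nchar(emitted)
  starts <- cumsum(c(1L, w[-length(w)]))
  list(genome = paste(emitted, collapse = ""), starts = starts,
       ends = starts + w - 1L)
}

# Annotate every gene/hgt piece by naive ORF calling from the ancestral start
# codon; returns a data.frame of CDS and rRNA intervals (1-based, closed).
#' @keywords internal
annotate_cds <- function(genome, pieces, starts, cap = 6000L) {
  ends <- starts + nchar(vapply(seq_len(nrow(pieces)), function(i) {
    pieces$seq[i]
  }, character(1))) - 1L
  Lg <- nchar(genome)
  rows <- list()
  for (i in seq_len(nrow(pieces))) {
    kind <- pieces$kind[i]
    if (kind == "rrna") {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "rRNA", feature_id = pieces$id[i], gene_id = pieces$id[i],
        start = starts[i], end = ends[i], strand = "+",
        family = NA_character_, status = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    if (!kind %in% c("gene", "hgt")) next
    if (pieces$strand[i] == "+") {
      s <- starts[i]
      region <- substr(genome, s, min(Lg, s + cap - 1L))
      orf <- scan_orf(region)
      cds <- c(s, s + orf$nt - 1L)
    } else {
      e <- ends[i]
      region <- revcomp_chr(substr(genome, max(1L, e - cap + 1L), e))
      orf <- scan_orf(region)
      cds <- c(e - orf$nt + 1L, e)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      type = "CDS", feature_id = pieces$id[i], gene_id = pieces$id[i],
      start = cds[1], end = cds[2], strand = pieces$strand[i],
      family = NA_character_, status = pieces$status[i],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# IS insertions: at most one per spacer, only in the CDS-free part of the
# spacer (ORFs of lesioned neighbours may overrun into a spacer; those parts
# are excluded so no insertion ever interrupts an annotated CDS).
#' @keywords internal
insert_is_elements <- function(pieces, asm, ann, params) {
  n_is <- params$n_is_insertions
  genome <- asm$genome
  features <- ann
  if (n_is > 0) {
    if (!length(params$is_library)) stop("n_is_insertions > 0 but is_library is empty")
    sp_idx <- which(pieces$kind == "spacer")
    cds <- ann[ann$type == "CDS", , drop = FALSE]
    free <- lapply(sp_idx, function(i) {
      lo <- asm$starts[i]; hi <- asm$ends[i]
      if (nrow(cds)) {
        ov <- cds$start <= hi & cds$end >= lo
        if (any(ov)) lo <- max(lo, max(cds$end[ov]) + 1L)
        # CDS never start inside a spacer, so only left-side overlap occurs
        # for '+' overruns; '-' overruns come from the right:
        ov2 <- cds$start >= lo & cds$start <= hi
        if (any(ov2)) hi <- min(hi, min(cds$start[ov2]) - 1L)
      }
      c(lo, hi)
    })
    ok <- vapply(free, function(f) f[2] >= f[1], logical(1))
    if (sum(ok) < n_is) {
      stop(sprintf("n_is_insertions (%d) exceeds available intergenic spacers (%d)",
                   n_is, sum(ok)))
    }
    chosen <- sample(which(ok), n_is)
    ins <- data.frame(
      pos = vapply(free[chosen], function(f) {
        if (f[2] > f[1]) sample(f[1]:f[2], 1L) else f[1]
      }, integer(1)),
      fam_idx = sample(length(params$is_library), n_is, replace = TRUE),
      strand = sample(c("+", "-"), n_is, replace = TRUE),
      stringsAsFactors = FALSE)
    ins <- ins[order(-ins$pos), , drop = FALSE]
    is_feats <- list()
    for (r in seq_len(nrow(ins))) {
      el <- params$is_library[ins$fam_idx[r]]
      el_seq <- if (ins$strand[r] == "-") revcomp_chr(el) else unname(el)
      w <- nchar(el_seq)
      p <- ins$pos[r]
      genome <- paste0(substr(genome, 1L, p - 1L), el_seq,
                       substr(genome, p, nchar(genome)))
      # insertion points lie outside every annotated feature, so a feature
      # either shifts wholesale or is untouched
      shift <- features$start >= p
      features$start[shift] <- features$start[shift] + w
      features$end[shift] <- features$end[shift] + w
      is_feats[[r]] <- data.frame(
        type = "mobile_genetic_element", feature_id = NA_character_,
        gene_id = NA_character_, start = p, end = p + w - 1L,
        strand = ins$strand[r], family = names(params$is_library)[ins$fam_idx[r]],
        status = NA_character_, stringsAsFactors = FALSE)
      # earlier-processed (rightward) IS features must shift too
      if (r > 1L) {
        for (q in seq_len(r - 1L)) {
          is_feats[[q]]$start <- is_feats[[q]]$start + w
          is_feats[[q]]$end <- is_feats[[q]]$end + w
        }
      }
    }
    is_feats <- do.call(rbind, is_feats)
    is_feats <- is_feats[order(is_feats$start), , drop = FALSE]
    is_feats$feature_id <- sprintf("is%03d", seq_len(nrow(is_feats)))
    features <- rbind(features, is_feats)
  }
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  list(genome = genome, features = features, ann = features)
}

#' @keywords internal
build_truth <- function(gt, params, pieces, features) {
  cds <- features[features$type == "CDS", , drop = FALSE]
  loc <- function(id) {
    k <- match(id, cds$gene_id)
    if (is.na(k)) c(NA_integer_, NA_integer_) else c(cds$start[k], cds$end[k])
  }
  n <- nrow(gt)
  rows <- vector("list", n + length(params$hgt_universe))
  for (i in seq_len(n)) {
    gid <- gt$gene_id[i]
    k <- match(gid, pieces$id)
    st <- if (is.na(k)) "absent" else pieces$status[k]
    iv <- loc(gid)
    rows[[i]] <- data.frame(
      strain_id = params$strain_id, gene_id = gid, status = st,
      lesion_type = if (!is.na(k)) pieces$lesion_type[k] else NA_character_,
      lesion_offset = if (!is.na(k)) pieces$lesion_offset[k] else NA_integer_,
      start = iv[1], end = iv[2], stringsAsFactors = FALSE)
  }
  for (k in seq_along(params$hgt_universe)) {
    hid <- params$hgt_universe[k]
    carried <- hid %in% names(params$hgt_genes)
    iv <- loc(hid)
    rows[[n + k]] <- data.frame(
      strain_id = params$strain_id, gene_id = hid,
      status = if (carried) "hgt" else "absent",
      lesion_type = NA_character_, lesion_offset = NA_integer_,
      start = iv[1], end = iv[2], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Translate CDS features of the requested statuses from the genome.
#' @keywords internal
extract_proteins <- function(genome, features, statuses = c("intact", "hgt")) {
  cds <- features[features$type == "CDS" &
                    features$status %in% statuses, , drop = FALSE]
  if (!nrow(cds)) return(stats::setNames(character(0), character(0)))
  out <- vapply(seq_len(nrow(cds)), function(i) {
    s <- substr(genome, cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") s <- revcomp_chr(s)
    sub("\\*$", "", translate_nt(s))
  }, character(1))
  stats::setNames(out, cds$gene_id)
}
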