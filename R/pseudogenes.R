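#' Parameters of the pseudogene-fragment detection procedure
#'
#' A CDS is marked `pseudogene_fragment` when (i) it aligns with database
#' proteins whose length deviates from the CDS-encoded protein by strictly
#' more than `length_tol` (the +/-10% trigger), (ii) back-aligning such a
#' protein to the genomic context produces a chained alignment whose genomic
#' extent exceeds the CDS interval, and (iii) the chain contains a frameshift
#' (frame change between collinear segments) or an in-frame stop codon.
#'
#' @param length_tol length-anomaly fraction (strict inequality).
#' @param context_window bp of genomic context on each side of the CDS for
#'   the back-alignment.
#' @param chain_max_gap maximal genomic gap (bp) between chained segments; a
#'   reported frameshift position is accurate to within this distance.
#' @param min_segment_score minimal segment score, in bits, for a per-frame
#'   local alignment to enter the chain.
#' @param evalue_max significance cutoff for translated-search hits.
#' @param max_candidates proteins aligned per CDS after the shared-word
#'   prefilter.
#' @param max_backaligns at most this many anomalous hits are back-aligned
#'   per CDS before giving up.
#' @param kmer_len word length of the translated-search prefilter.
#' @param matrix_name,gap_open,gap_extend alignment scoring.
#' @return object of class `pseudo_params`.
#' @export
pseudo_params <- function(length_tol = 0.10, context_window = 3000L,
                          chain_max_gap = 60L, min_segment_score = 25,
                          evalue_max = 1e-3, max_candidates = 10L,
                          max_backaligns = 3L, kmer_len = 5L,
                          matrix_name = "BLOSUM62", gap_open = 11,
                          gap_extend = 1) {
  stopifnot(length_tol > 0, length_tol < 1, context_window >= 0,
            chain_max_gap >= 0)
  structure(list(length_tol = length_tol,
                 context_window = as.integer(context_window),
                 chain_max_gap = as.integer(chain_max_gap),
                 min_segment_score = min_segment_score,
                 evalue_max = evalue_max,
                 max_candidates = as.integer(max_candidates),
                 max_backaligns = as.integer(max_backaligns),
                 kmer_len = as.integer(kmer_len),
                 matrix_name = matrix_name, gap_open = gap_open,
                 gap_extend = gap_extend), class = "pseudo_params")
}

#' Length-anomaly trigger
#'
#' `TRUE` iff the database protein is longer or smaller than the CDS-encoded
#' protein by strictly more than `length_tol` of the CDS-encoded length.
#' @param cds_protein_len,hit_protein_len lengths in residues (>= 1).
#' @param length_tol tolerance fraction.
#' @return logical.
#' @examples
#' length_anomaly(100, 110) # FALSE: exactly 10% is not an anomaly
#' length_anomaly(100, 111) # TRUE
#' @export
length_anomaly <- function(cds_protein_len, hit_protein_len,
                           length_tol = 0.10) {
  stopifnot(cds_protein_len >= 1, hit_protein_len >= 1)
  abs(hit_protein_len - cds_protein_len) / cds_protein_len > length_tol
}

# Six conceptual translations of a nucleotide sequence: strand x frame.
#' @keywords internal
six_frames <- function(seq) {
  rc <- revcomp_chr(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (fr in 0:2) {
      out[[paste0(strand, fr)]] <- list(
        strand = strand, frame = fr,
        aa = translate_nt(substr(s, fr + 1L, nchar(s))))
    }
  }
  out
}

#' Translated search of a CDS against a protein database
#'
#' Conceptually translates the CDS in all six frames and reports the
#' best-scoring local alignments against the database (blastx-style), with a
#' shared-peptide prefilter selecting candidate proteins.  Ties are broken
#' by score, then lexicographic protein key.
#'
#' @param cds_seq CDS nucleotide sequence (character, genomic orientation).
#' @param protein_db proteome data.frame (`strain_id`, `protein_id`,
#'   `sequence`) or named character vector.
#' @param params a [pseudo_params()] object.
#' @param db_index optional prebuilt index from [build_db_index()] for
#'   repeated calls against the same database.
#' @return data.frame of hits ordered best-first: `protein`, `score`,
#'   `bits`, `evalue`, `hit_len`, `strand`, `frame`; zero rows if nothing
#'   aligns above `min_segment_score` bits.
#' @export
translated_search <- function(cds_seq, protein_db, params = pseudo_params(),
                              db_index = NULL) {
  if (nchar(cds_seq) < 3L) stop("CDS shorter than 3 nt")
  if (is.data.frame(protein_db)) {
    if (!nrow(protein_db)) stop("empty protein database")
    db <- stats::setNames(protein_db$sequence, protein_keys(protein_db))
  } else {
    if (!length(protein_db)) stop("empty protein database")
    db <- protein_db
  }
  idx <- db_index %||% build_db_index(db, params$kmer_len)
  mat <- get_submat(params$matrix_name)
  frames <- six_frames(cds_seq)
  empty <- data.frame(protein = character(0), score = numeric(0),
                      bits = numeric(0), evalue = numeric(0),
                      hit_len = integer(0), strand = character(0),
                      frame = integer(0), stringsAsFactors = FALSE)

  # shared-word counts per (protein, frame)
  counts <- list()
  for (fname in names(frames)) {
    aa <- frames[[fname]]$aa
    k <- params$kmer_len
    if (nchar(aa) < k) next
    km <- unique(substring(aa, 1:(nchar(aa) - k + 1L), k:nchar(aa)))
    hit <- idx$table[data.table::data.table(kmer = km), on = "kmer",
                     nomatch = NULL]
    if (!nrow(hit)) next
    tab <- table(hit$protein)
    counts[[fname]] <- data.frame(protein = names(tab),
                                  n = as.integer(tab),
                                  fname = fname, stringsAsFactors = FALSE)
  }
  if (!length(counts)) return(empty)
  counts <- do.call(rbind, counts)
  tot <- tapply(counts$n, counts$protein, sum)
  top <- names(sort(tot, decreasing = TRUE))
  top <- top[seq_len(min(length(top), params$max_candidates))]

  counts <- counts[counts$protein %in% top, , drop = FALSE]
  n_db <- sum(nchar(db))
  # one score-only alignment batch per frame
  best <- list()
  for (fname in unique(counts$fname)) {
    prots <- counts$protein[counts$fname == fname]
    fr <- frames[[fname]]
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(db[prots]), Biostrings::AAString(fr$aa),
      type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE)
    for (q in seq_along(prots)) {
      p <- prots[q]
      if (is.null(best[[p]]) || sc[q] > best[[p]]$score) {
        best[[p]] <- list(score = sc[q], strand = fr$strand, frame = fr$frame)
      }
    }
  }
  rows <- lapply(names(best), function(p) {
    b <- best[[p]]
    if (ka_bits(b$score) < params$min_segment_score) return(NULL)
    data.frame(protein = p, score = b$score, bits = ka_bits(b$score),
               evalue = ka_evalue(b$score, nchar(cds_seq) %/% 3L, n_db),
               hit_len = nchar(db[[p]]), strand = b$strand, frame = b$frame,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a reusable shared-word index of a protein database
#' @param db named character vector of protein sequences.
#' @param kmer_len word length.
#' @return list with `table` (data.table keyed by `kmer`, columns `kmer`,
#'   `protein`) and `db`.
#' @export
build_db_index <- function(db, kmer_len = 5L) {
  rows <- lapply(names(db), function(p) {
    s <- db[[p]]
    if (nchar(s) < kmer_len) return(NULL)
    data.frame(kmer = unique(substring(s, 1:(nchar(s) - kmer_len + 1L),
                                       kmer_len:nchar(s))),
               protein = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kmer = character(0), protein = character(0))
  tab <- data.table::as.data.table(tab)
  data.table::setkey(tab, kmer)
  list(table = tab, db = db)
}

#' Back-align a database protein to a genomic region
#'
#' tblastn-style: the region of interest (CDS plus `context_window` flanking
#' bp) is translated in all six frames; per-frame optimal local alignments
#' of the protein above `min_segment_score` bits become segments, collinear
#' same-strand segments are chained (genomic gap at most `chain_max_gap`), a
#' frame change between adjacent chained segments is recorded as a
#' frameshift, and stop codons inside aligned segments are recorded as
#' internal stops.
#'
#' @param protein protein sequence (character).
#' @param genome genome sequence (character).
#' @param cds_start,cds_end CDS interval (1-based, closed).
#' @param params a [pseudo_params()] object.
#' @return list with `segments` (data.frame: `strand`, `frame`, `g_start`,
#'   `g_end`, `p_start`, `p_end`, `score`, `bits`, `chained`), `frameshifts`
#'   (genomic junction positions), `internal_stops` (genomic stop-codon
#'   positions strictly inside chained alignment), `extent`
#'   (`c(start, end)` of the chained alignment, or `NULL`), `chain_score`.
#' @export
back_align <- function(protein, genome, cds_start, cds_end,
                       params = pseudo_params()) {
  Lg <- nchar(genome)
  if (cds_start < 1L || cds_end > Lg || cds_start > cds_end) {
    stop("region of interest outside genome")
  }
  roi_s <- max(1L, cds_start - params$context_window)
  roi_e <- min(Lg, cds_end + params$context_window)
  roi <- substr(genome, roi_s, roi_e)
  mat <- get_submat(params$matrix_name)

  frames <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") roi else revcomp_chr(roi)
    for (fr in 0:2) {
      aa <- translate_nt(substr(s, fr + 1L, nchar(s)))
      if (nchar(aa) >= 5L) {
        frames[[paste0(strand, fr)]] <- list(strand = strand, frame = fr,
                                             aa = aa)
      }
    }
  }
  # one batched call, six frame translations against the protein
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(vapply(frames, `[[`, character(1), "aa")),
    Biostrings::AAString(protein), type = "local",
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
  scores <- Biostrings::score(al)
  keep_i <- which(ka_bits(scores) >= params$min_segment_score)
  al <- al[keep_i]
  # gapped-string extraction is expensive; only done for scoring frames
  aln_t <- as.character(Biostrings::alignedPattern(al))   # translation side
  aln_p <- as.character(Biostrings::alignedSubject(al))   # protein side
  t0s <- IRanges::start(Biostrings::pattern(al))
  p0s <- IRanges::start(Biostrings::subject(al))

  segs <- list()
  for (i in seq_along(keep_i)) {
    strand <- frames[[keep_i[i]]]$strand; fr <- frames[[keep_i[i]]]$frame
    aa <- frames[[keep_i[i]]]$aa
    blocks <- split_hsp(aln_p[i], aln_t[i], p0s[i], t0s[i], mat, params)
    for (blk in blocks) {
      if (blk$bits < params$min_segment_score) next
      ss <- blk$s_start; se <- blk$s_end
      if (strand == "+") {
        g1 <- roi_s + fr + 3L * (ss - 1L)
        g2 <- roi_s + fr + 3L * se - 1L
      } else {
        g2 <- roi_e - fr - 3L * (ss - 1L)
        g1 <- roi_e - fr - 3L * se + 1L
      }
      stops_aa <- which(strsplit(substr(aa, ss, se), "")[[1]] == "*")
      stops_g <- if (length(stops_aa)) {
        abs_aa <- ss + stops_aa - 1L
        if (strand == "+") roi_s + fr + 3L * (abs_aa - 1L)
        else roi_e - fr - 3L * abs_aa + 1L
      } else integer(0)
      # a stop at the very edge of the aligned span is not internal
      internal <- stops_aa > 1L & stops_aa < (se - ss + 1L)
      cols <- blk$cols
      if (strand == "+") {
        cols$g1 <- roi_s + fr + 3L * (cols$s - 1L)
        cols$g2 <- cols$g1 + 2L
      } else {
        cols$g2 <- roi_e - fr - 3L * (cols$s - 1L)
        cols$g1 <- cols$g2 - 2L
      }
      segs[[length(segs) + 1L]] <- list(
        strand = strand, frame = fr, g_start = g1, g_end = g2,
        p_start = blk$p_start, p_end = blk$p_end, score = blk$score,
        bits = blk$bits, stops = stops_g[internal], cols = cols)
    }
  }
  if (!length(segs)) {
    return(list(segments = NULL, frameshifts = integer(0),
                internal_stops = integer(0), extent = NULL, chain_score = 0))
  }
  chain_segments(segs, params)
}

# Split one local alignment into HSP-like blocks at gap runs longer than
# chain_max_gap/3 residues.  A single Smith-Waterman alignment will happily
# bridge a long genomic insertion through a cheap gap extension where a
# seeded aligner reports separate HSPs; chaining (with its gap cap) must see
# separate segments there, otherwise spacer homology downstream of a gene
# can masquerade as alignment extent.  Block scores are recomputed with the
# same matrix and affine penalties.  `pstr`/`sstr` are the gapped aligned
# strings (protein side / translation side), `p0`/`s0` the positions of
# their first residues.
#' @keywords internal
split_hsp <- function(pstr, sstr, p0, s0, mat, params) {
  pv <- strsplit(pstr, "")[[1]]
  sv <- strsplit(sstr, "")[[1]]
  max_gap_aa <- max(1L, params$chain_max_gap %/% 3L)
  gap <- pv == "-" | sv == "-"
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  breaks <- which(r$values & r$lengths > max_gap_aa)
  block_bounds <- list()
  lo <- 1L
  for (b in breaks) {
    hi <- ends[b] - r$lengths[b]
    if (hi >= lo) block_bounds[[length(block_bounds) + 1L]] <- c(lo, hi)
    lo <- ends[b] + 1L
  }
  if (lo <= length(pv)) {
    block_bounds[[length(block_bounds) + 1L]] <- c(lo, length(pv))
  }

  p_off <- cumsum(pv != "-")   # protein residues consumed up to column
  s_off <- cumsum(sv != "-")
  out <- list()
  for (bb in block_bounds) {
    cols <- bb[1]:bb[2]
    pc <- pv[cols]; sc <- sv[cols]
    keep <- !(pc == "-" & sc == "-")
    pc <- pc[keep]; sc <- sc[keep]
    if (!sum(pc != "-" & sc != "-")) next
    aligned <- pc != "-" & sc != "-"
    score <- sum(mat[cbind(pc[aligned], sc[aligned])])
    for (gr in c("p", "s")) {
      gv <- if (gr == "p") pc == "-" else sc == "-"
      runs <- rle(gv)
      glen <- runs$lengths[runs$values]
      if (length(glen)) {
        score <- score - sum(params$gap_open + glen * params$gap_extend)
      }
    }
    np_before <- if (bb[1] == 1L) 0L else p_off[bb[1] - 1L]
    ns_before <- if (bb[1] == 1L) 0L else s_off[bb[1] - 1L]
    # per-column record of aligned (residue-residue) positions, used to
    # locate the optimal splice point between chained segments
    al_cols <- which(aligned)
    col_tab <- data.frame(
      p = p0 + p_off[cols][keep][al_cols] - 1L,
      s = s0 + s_off[cols][keep][al_cols] - 1L,
      sc = mat[cbind(pc[al_cols], sc[al_cols])])
    # first/last residue of the block (residue counts are monotone in columns)
    out[[length(out) + 1L]] <- list(
      p_start = p0 + np_before, p_end = p0 + p_off[bb[2]] - 1L,
      s_start = s0 + ns_before, s_end = s0 + s_off[bb[2]] - 1L,
      score = score, bits = ka_bits(score), cols = col_tab)
  }
  out
}

# Chain collinear same-strand segments (best-score chain per strand, kept if
# better); returns the back_align() result structure.
#' @keywords internal
chain_segments <- function(segs, params) {
  df <- do.call(rbind, lapply(segs, function(x) {
    data.frame(strand = x$strand, frame = x$frame, g_start = x$g_start,
               g_end = x$g_end, p_start = x$p_start, p_end = x$p_end,
               score = x$score, bits = x$bits, stringsAsFactors = FALSE)
  }))
  stops_by_seg <- lapply(segs, `[[`, "stops")
  cols_by_seg <- lapply(segs, `[[`, "cols")

  best <- NULL
  for (strand in unique(df$strand)) {
    idx <- which(df$strand == strand)
    idx <- idx[order(df$p_start[idx])]
    k <- length(idx)
    dp <- df$score[idx]
    pred <- rep(NA_integer_, k)
    for (b in seq_len(k)) {
      for (a in seq_len(k)) {
        if (a == b) next
        ia <- idx[a]; ib <- idx[b]
        # local alignments overrun a lesion arbitrarily far into the other
        # segment's protein range, so chainability is decided by the splice
        # test itself: some protein position must join the two segments
        # with a genomic gap within the cap
        collinear <- df$p_start[ib] > df$p_start[ia] &&
          df$p_end[ib] - df$p_end[ia] >= 10L
        gap_ok <- collinear &&
          can_splice(cols_by_seg[[ia]], cols_by_seg[[ib]], strand,
                     params$chain_max_gap)
        if (collinear && gap_ok && dp[a] + df$score[ib] > dp[b]) {
          dp[b] <- dp[a] + df$score[ib]
          pred[b] <- a
        }
      }
    }
    b <- which.max(dp)
    chain <- b
    while (!is.na(pred[chain[1]])) chain <- c(pred[chain[1]], chain)
    cand <- list(score = dp[b], rows = idx[chain])
    if (is.null(best) || cand$score > best$score) best <- cand
  }

  rows <- best$rows
  df$chained <- seq_len(nrow(df)) %in% rows
  fs <- integer(0)
  if (length(rows) > 1L) {
    for (r in seq_len(length(rows) - 1L)) {
      a <- rows[r]; b <- rows[r + 1L]
      if (df$frame[a] != df$frame[b]) {
        fs <- c(fs, splice_junction(cols_by_seg[[a]], cols_by_seg[[b]],
                                    df$strand[a]))
      }
    }
  }
  stops <- sort(unique(unlist(stops_by_seg[rows])))
  extent <- c(min(df$g_start[rows]), max(df$g_end[rows]))
  list(segments = df, frameshifts = fs, internal_stops = as.integer(stops),
       extent = extent, chain_score = best$score)
}

# Can segments a and b be spliced at some protein position with a genomic
# gap of at most `cap` bp?  Works from the per-column tables, so internal
# alignment gaps cannot distort the geometry.
#' @keywords internal
can_splice <- function(ca, cb, strand, cap) {
  lo <- max(min(cb$p) - 1L, min(ca$p))
  hi <- min(max(ca$p), max(cb$p) - 1L)
  if (hi < lo) {                       # disjoint protein intervals
    gap <- if (strand == "+") min(cb$g1) - max(ca$g2) - 1L
           else min(ca$g1) - max(cb$g2) - 1L
    return(abs(gap) <= cap)
  }
  for (t in lo:hi) {
    ga <- ca[ca$p <= t, , drop = FALSE]
    gb <- cb[cb$p > t, , drop = FALSE]
    if (!nrow(ga) || !nrow(gb)) next
    gap <- if (strand == "+") min(gb$g1) - max(ga$g2) - 1L
           else min(ga$g1) - max(gb$g2) - 1L
    if (abs(gap) <= cap) return(TRUE)
  }
  FALSE
}

# Locate a frameshift junction between two chained segments.  Either
# alignment can overrun the lesion into the other's protein range, so the
# reported position is the optimal splice point: the protein position t that
# maximises (score of a's columns <= t) + (score of b's columns > t),
# mapped back to the genomic coordinate of a's last used codon.
#' @keywords internal
splice_junction <- function(ca, cb, strand) {
  lo <- min(cb$p) - 1L; hi <- max(ca$p)
  if (hi < lo) {
    return(if (strand == "+") max(ca$g2) else min(ca$g1))
  }
  ts <- lo:hi
  sa <- vapply(ts, function(t) sum(ca$sc[ca$p <= t]), numeric(1))
  sb <- vapply(ts, function(t) sum(cb$sc[cb$p > t]), numeric(1))
  t_best <- ts[which.max(sa + sb)]
  used_a <- ca[ca$p <= t_best, , drop = FALSE]
  if (!nrow(used_a)) {
    return(if (strand == "+") min(cb$g1) - 1L else max(cb$g2) + 1L)
  }
  if (strand == "+") max(used_a$g2) else min(used_a$g1)
}

#' Classify one CDS from its translated search and back-alignment
#'
#' Verdict `pseudogene_fragment` requires all three lines of evidence:
#' length anomaly, back-alignment extent exceeding the CDS interval, and a
#' frameshift or internal stop; otherwise `intact`.
#'
#' @param cds_len_aa CDS-encoded protein length (residues).
#' @param cds_start,cds_end CDS interval.
#' @param hit one row of a [translated_search()] result (the back-aligned
#'   protein).
#' @param back result of [back_align()] for that protein.
#' @param params a [pseudo_params()] object.
#' @return list with `verdict`, `evidence` (character vector), `best_hit`,
#'   `anomaly_ratio`, `frameshifts`, `internal_stops`, `extent`.
#' @export
classify_cds <- function(cds_len_aa, cds_start, cds_end, hit, back,
                         params = pseudo_params()) {
  anom <- length_anomaly(cds_len_aa, hit$hit_len, params$length_tol)
  ratio <- abs(hit$hit_len - cds_len_aa) / cds_len_aa
  evidence <- character(0)
  if (anom) evidence <- "length_anomaly"
  longer <- !is.null(back$extent) &&
    (back$extent[2] - back$extent[1] + 1L) > (cds_end - cds_start + 1L)
  if (length(back$frameshifts)) evidence <- c(evidence, "frameshift")
  if (length(back$internal_stops)) evidence <- c(evidence, "internal_stop")
  pseudo <- anom && longer &&
    (length(back$frameshifts) > 0 || length(back$internal_stops) > 0)
  list(verdict = if (pseudo) "pseudogene_fragment" else "intact",
       evidence = if (pseudo) evidence else character(0),
       best_hit = hit$protein, anomaly_ratio = ratio,
       frameshifts = back$frameshifts, internal_stops = back$internal_stops,
       extent = back$extent)
}

#' Call pseudogene fragments over all CDS of one strain
#'
#' Runs the full procedure per annotated CDS: translated search against the
#' database, the +/-10% length-anomaly trigger evaluated over the
#' significant hits (any anomalous hit can trigger, not only the top one),
#' back-alignment of the anomalous proteins, and classification.
#'
#' @param strain a `strain_genome` object (genome + features).
#' @param protein_db proteome data.frame of the reference proteins,
#'   typically all annotated-CDS translations of the other strains.
#' @param params a [pseudo_params()] object.
#' @return data.frame of calls, one row per CDS: `strain_id`, `cds_id`,
#'   `verdict`, `evidence`, `best_hit`, `anomaly_ratio`, `n_frameshifts`,
#'   `n_internal_stops`, `fs_pos` (first frameshift position or `NA`).
#' @export
call_pseudogenes <- function(strain, protein_db, params = pseudo_params()) {
  stopifnot(inherits(strain, "strain_genome"))
  cds <- strain$features[strain$features$type == "CDS", , drop = FALSE]
  db <- stats::setNames(protein_db$sequence, protein_keys(protein_db))
  idx <- build_db_index(db, params$kmer_len)
  rows <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    seq_i <- substr(strain$genome, cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") seq_i <- revcomp_chr(seq_i)
    aa_len <- nchar(sub("\\*$", "", translate_nt(seq_i)))
    hits <- translated_search(seq_i, protein_db, params, db_index = idx)
    hits <- hits[hits$evalue < params$evalue_max, , drop = FALSE]
    res <- list(verdict = "intact", evidence = character(0),
                best_hit = if (nrow(hits)) hits$protein[1] else NA_character_,
                anomaly_ratio = if (nrow(hits)) {
                  abs(hits$hit_len[1] - aa_len) / aa_len
                } else NA_real_,
                frameshifts = integer(0), internal_stops = integer(0))
    if (nrow(hits) && aa_len >= 1) {
      anom <- hits[length_anomaly(aa_len, hits$hit_len, params$length_tol), ,
                   drop = FALSE]
      n_try <- min(nrow(anom), params$max_backaligns)
      for (k in seq_len(n_try)) {
        prot <- db[[anom$protein[k]]]
        back <- back_align(prot, strain$genome, cds$start[i], cds$end[i],
                           params)
        cl <- classify_cds(aa_len, cds$start[i], cds$end[i], anom[k, ],
                           back, params)
        if (cl$verdict == "pseudogene_fragment") { res <- cl; break }
      }
    }
    rows[[i]] <- data.frame(
      strain_id = strain$strain_id, cds_id = cds$gene_id[i],
      verdict = res$verdict,
      evidence = paste(res$evidence, collapse = ","),
      best_hit = res$best_hit, anomaly_ratio = res$anomaly_ratio,
      n_frameshifts = length(res$frameshifts),
      n_internal_stops = length(res$internal_stops),
      fs_pos = if (length(res$frameshifts)) res$frameshifts[1] else NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
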