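#' GC content of a nucleotide sequence
#'
#' (G+C) / (A+C+G+T); `N` is excluded from the denominator.  Ambiguity codes
#' other than `N` are rejected so that a silently mis-parsed input cannot
#' shift a statistic reported to one decimal.
#'
#' @param seq nucleotide sequence (character or `DNAString`).
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gc_content("GGCC") # 1
#' gc_content("AATT") # 0
#' @export
gc_content <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("empty sequence")
  counts <- table(strsplit(seq, "")[[1]])
  bad <- setdiff(names(counts), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("unexpected characters in sequence: ", paste(bad, collapse = ", "),
         " (only ACGTN are accepted)")
  }
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0) stop("sequence contains no unambiguous bases")
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  unname(gc / acgt)
}

#' GC content at third codon positions (GC3)
#'
#' Strand-corrected G+C fraction over every third position of every complete
#' codon of the supplied CDS; an aberrant GC3 relative to overall GC is a
#' signature of rapid ongoing sequence evolution.  CDS whose length is not a
#' multiple of 3 are skipped with a warning.  Pseudogene exclusion is the
#' caller's responsibility (pass only intact CDS).
#'
#' @param cds_seqs character vector of CDS sequences in coding orientation
#'   (already strand-corrected), or a list of such.
#' @return GC3 fraction in `[0, 1]`.
#' @export
gc3 <- function(cds_seqs) {
  cds_seqs <- toupper(unlist(cds_seqs, use.names = FALSE))
  ok <- nchar(cds_seqs) %% 3L == 0L & nchar(cds_seqs) >= 3L
  if (any(!ok)) {
    warning(sum(!ok), " CDS skipped (length not a multiple of 3)")
  }
  cds_seqs <- cds_seqs[ok]
  if (!length(cds_seqs)) stop("no valid CDS")
  third <- unlist(lapply(cds_seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    v[seq(3L, length(v), 3L)]
  }))
  third <- third[third != "N"]
  if (!length(third)) stop("no unambiguous third-position bases")
  sum(third %in% c("G", "C")) / length(third)
}

#' Coding density
#'
#' Length of the union of CDS intervals divided by genome length, as a
#' percentage; overlapping CDS are counted once.
#'
#' @param genome_len genome length in bp.
#' @param starts,ends CDS interval endpoints (1-based, closed).
#' @return percentage in `[0, 100]`.
#' @export
coding_density <- function(genome_len, starts, ends) {
  stopifnot(genome_len >= 1, length(starts) == length(ends))
  if (!length(starts)) return(0)
  if (any(starts < 1) || any(ends > genome_len) || any(starts > ends)) {
    stop("CDS interval outside genome")
  }
  covered <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(starts, ends))))
  100 * covered / genome_len
}

#' Gap-aware genome size estimate
#'
#' Sum of contig lengths plus the estimated sizes of the inter-contig
#' sequence gaps; with no gap estimates the assembled size is returned with
#' attribute `estimated = FALSE`.
#'
#' @param contig_lengths contig lengths in bp.
#' @param gap_estimates one estimate per inter-contig gap (may be empty).
#' @return estimated size in bp (attribute `estimated` says whether gap
#'   estimates were applied).
#' @examples
#' estimate_genome_size(c(600, 400))        # 1000
#' estimate_genome_size(c(600, 400), 75)    # 1075
#' @export
estimate_genome_size <- function(contig_lengths, gap_estimates = numeric(0)) {
  stopifnot(length(contig_lengths) >= 1, all(contig_lengths >= 0))
  if (any(gap_estimates < 0)) stop("negative gap estimate")
  if (length(gap_estimates) &&
      length(gap_estimates) != length(contig_lengths) - 1L) {
    stop("need one gap estimate per inter-contig gap (contigs - 1)")
  }
  out <- sum(contig_lengths) + sum(gap_estimates)
  attr(out, "estimated") <- length(gap_estimates) > 0
  out
}

#' IS-element landscape of a genome
#'
#' Per-family counts, a sliding-window density track, and the largest
#' element-free interval (the quantity behind statements like "a region of
#' 415 kbp is exempt of IS elements").  The free interval is measured
#' between element boundaries (end of one element to start of the next) by
#' default; midpoint mode is available.  On circular genomes the gap
#' wrapping the origin is included.
#'
#' @param genome_len genome length in bp.
#' @param is_ann data.frame of IS annotations: `family`, `start`, `end`
#'   (and optionally `strand`).
#' @param window sliding-window width in bp.
#' @param step window step in bp.
#' @param circular treat the genome as circular.
#' @param mode `"boundary"` (default) or `"midpoint"`.
#' @return list with `family_counts` (named integer vector), `density`
#'   (data.frame `win_start`, `win_end`, `count`), `free_interval`
#'   (`c(start, end)`, wrapping if circular), `free_width`.
#' @export
is_landscape <- function(genome_len, is_ann, window = 10000L,
                         step = window %/% 2L, circular = TRUE,
                         mode = c("boundary", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(window > 0, step > 0)
  if (is.null(is_ann) || !nrow(is_ann)) {
    return(list(family_counts = integer(0),
                density = data.frame(win_start = integer(0),
                                     win_end = integer(0), count = integer(0)),
                free_interval = c(1L, genome_len), free_width = genome_len))
  }
  if (any(is_ann$start < 1) || any(is_ann$end > genome_len)) {
    stop("IS interval outside genome")
  }
  fam <- sort(table(is_ann$family), decreasing = TRUE)
  family_counts <- stats::setNames(as.integer(fam), names(fam))

  win_start <- seq(1L, max(1L, genome_len - window + 1L), by = step)
  mid <- (is_ann$start + is_ann$end) / 2
  count <- vapply(win_start, function(ws) {
    sum(mid >= ws & mid < ws + window)
  }, numeric(1))
  density <- data.frame(win_start = win_start,
                        win_end = pmin(win_start + window - 1L, genome_len),
                        count = as.integer(count))

  if (mode == "midpoint") {
    pos <- sort(round(mid))
    lo <- pos; hi <- pos
  } else {
    ord <- order(is_ann$start)
    lo <- is_ann$start[ord]; hi <- is_ann$end[ord]
  }
  # gaps between consecutive elements (boundary: end_i+1 .. start_{i+1}-1)
  n <- length(lo)
  gaps <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      gs <- hi[i] + 1L; ge <- lo[i + 1L] - 1L
      if (ge >= gs) gaps[[length(gaps) + 1L]] <- c(gs, ge)
    }
  }
  if (circular) {
    gs <- hi[n] + 1L; ge <- lo[1L] - 1L + genome_len  # wraps the origin
    if (ge >= gs) gaps[[length(gaps) + 1L]] <- c(gs, ge)
  } else {
    if (lo[1L] > 1L) gaps[[length(gaps) + 1L]] <- c(1L, lo[1L] - 1L)
    if (hi[n] < genome_len) gaps[[length(gaps) + 1L]] <- c(hi[n] + 1L, genome_len)
  }
  if (!length(gaps)) {
    free_interval <- c(NA_integer_, NA_integer_); free_width <- 0L
  } else {
    widths <- vapply(gaps, function(g) g[2] - g[1] + 1L, numeric(1))
    best <- gaps[[which.max(widths)]]
    free_interval <- c(((best[1] - 1L) %% genome_len) + 1L,
                       ((best[2] - 1L) %% genome_len) + 1L)
    free_width <- as.integer(max(widths))
  }
  list(family_counts = family_counts, density = density,
       free_interval = free_interval, free_width = free_width)
}

#' Composition report for one strain
#'
#' The per-genome row of the composition table: overall GC, CDS GC, GC3,
#' coding density, assembled and estimated genome size, pseudogene-fragment
#' count (if calls are given), IS family counts and largest IS-free region.
#' Percentages are rounded half-up to one decimal in the `printed` element;
#' raw fractions are kept alongside.
#'
#' @param strain a `strain_genome` object.
#' @param pseudo_calls optional calls from [call_pseudogenes()]; called
#'   fragments are excluded from the CDS-based statistics.
#' @param gap_estimates optional inter-contig gap estimates in bp.
#' @param window IS density window (bp).
#' @return object of class `stats_report` (a list).
#' @export
stats_report <- function(strain, pseudo_calls = NULL,
                         gap_estimates = numeric(0), window = 10000L) {
  stopifnot(inherits(strain, "strain_genome"))
  genome_len <- nchar(strain$genome)
  feats <- strain$features
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  pseudo_ids <- character(0)
  if (!is.null(pseudo_calls)) {
    pseudo_ids <- pseudo_calls$cds_id[
      pseudo_calls$strain_id == strain$strain_id &
        pseudo_calls$verdict == "pseudogene_fragment"]
  }
  intact <- cds[!cds$gene_id %in% pseudo_ids, , drop = FALSE]
  cds_seqs <- vapply(seq_len(nrow(intact)), function(i) {
    s <- substr(strain$genome, intact$start[i], intact$end[i])
    if (intact$strand[i] == "-") revcomp_chr(s) else s
  }, character(1))
  is_ann <- feats[feats$type == "mobile_genetic_element", , drop = FALSE]
  land <- is_landscape(genome_len, is_ann, window = window)

  raw <- list(
    overall_gc = gc_content(strain$genome),
    cds_gc = if (length(cds_seqs)) gc_content(paste(cds_seqs, collapse = "")) else NA_real_,
    gc3 = if (length(cds_seqs)) gc3(cds_seqs) else NA_real_,
    coding_density = coding_density(genome_len, intact$start, intact$end),
    assembled_size = genome_len,
    estimated_size = as.numeric(estimate_genome_size(genome_len, gap_estimates)),
    n_cds = nrow(intact),
    n_pseudogene_fragments = length(pseudo_ids),
    is_counts = land$family_counts,
    is_free_interval = land$free_interval,
    is_free_width = land$free_width)
  round1 <- function(x) floor(x * 10 + 0.5) / 10  # half-up, table style
  raw$printed <- c(
    overall_gc_pct = round1(100 * raw$overall_gc),
    cds_gc_pct = if (is.na(raw$cds_gc)) NA_real_ else round1(100 * raw$cds_gc),
    gc3_pct = if (is.na(raw$gc3)) NA_real_ else round1(100 * raw$gc3),
    coding_density_pct = round1(raw$coding_density))
  structure(c(list(strain_id = strain$strain_id), raw), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("strain %s: %d bp (est. %.0f), GC %.1f%%, GC3 %.1f%%, coding %.1f%%, %d CDS, %d pseudogene fragments, %d IS\n",
              x$strain_id, x$assembled_size, x$estimated_size,
              x$printed["overall_gc_pct"], x$printed["gc3_pct"],
              x$printed["coding_density_pct"], x$n_cds,
              x$n_pseudogene_fragments, sum(x$is_counts)))
  invisible(x)
}
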