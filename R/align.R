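#' Clustering parameters for all-vs-all protein comparison
#'
#' Defaults are the thresholds used to define orthologous groups:
#' e-value < 1e-3, identity > 78% over > 76% of the longest sequence length,
#' all inequalities strict.
#'
#' @param evalue_max e-value cutoff (hits must fall strictly below).
#' @param identity_min identity fraction over aligned columns, gap columns
#'   included (hits must exceed strictly).
#' @param coverage_min aligned span on the longer sequence divided by its
#'   length (hits must exceed strictly).
#' @param matrix_name substitution matrix label (a matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param min_shared_kmers candidate-pair prefilter: only pairs sharing at
#'   least this many length-`kmer_len` peptides are aligned (a seed heuristic
#'   in the spirit of blastp word matching; at default thresholds a
#'   qualifying pair is never lost).
#' @param kmer_len word length of the prefilter.
#' @return object of class `cluster_params`.
#' @export
cluster_params <- function(evalue_max = 1e-3, identity_min = 0.78,
                           coverage_min = 0.76, matrix_name = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           min_shared_kmers = 2L, kmer_len = 5L) {
  stopifnot(evalue_max > 0, identity_min > 0, identity_min <= 1,
            coverage_min > 0, coverage_min <= 1)
  structure(list(evalue_max = evalue_max, identity_min = identity_min,
                 coverage_min = coverage_min, matrix_name = matrix_name,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_shared_kmers = as.integer(min_shared_kmers),
                 kmer_len = as.integer(kmer_len)),
            class = "cluster_params")
}

#' @keywords internal
get_submat <- function(matrix_name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = matrix_name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(matrix_name, envir = e)) {
    stop("unknown substitution matrix: ", matrix_name)
  }
  get(matrix_name, envir = e)
}

# Karlin-Altschul parameters for gapped BLOSUM62 with gap penalties 11/1
# (the blastp defaults); used for all matrices as an approximation, which is
# ample for a 1e-3 cutoff that the identity/coverage thresholds dominate.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' @keywords internal
ka_evalue <- function(score, m, n) {
  .KA_K * m * n * exp(-.KA_LAMBDA * score)
}

#' @keywords internal
ka_bits <- function(score) {
  (.KA_LAMBDA * score - log(.KA_K)) / log(2)
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman with affine gaps (via Biostrings), reporting the quantities
#' the ortholog-clustering thresholds are expressed in: identity over aligned
#' columns (gap columns included, the blastp convention) and the aligned span
#' on the longer sequence divided by its length.  The e-value uses the
#' Karlin-Altschul approximation with a caller-supplied search-space size.
#'
#' @param a,b named single protein sequences (character), or rows of a
#'   proteome data.frame (`strain_id`, `protein_id`, `sequence`).
#' @param params a [cluster_params()] object.
#' @param search_n total residue count of the database for the e-value;
#'   defaults to `nchar(b)`.
#' @return list with `query_id`, `subject_id`, `score`, `bit_score`,
#'   `evalue`, `identity`, `longest_coverage`, `q_start`, `q_end`,
#'   `s_start`, `s_end`.
#' @examples
#' local_align(c(p1 = "MKVLLT"), c(p2 = "MKVLLT"))
#' @export
local_align <- function(a, b, params = cluster_params(), search_n = NULL) {
  as_seq <- function(x) {
    if (is.data.frame(x)) {
      stats::setNames(x$sequence[1], paste(x$strain_id[1], x$protein_id[1], sep = "|"))
    } else stats::setNames(as.character(x)[1], names(x)[1] %||% "seq")
  }
  a <- as_seq(a); b <- as_seq(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  mat <- get_submat(params$matrix_name)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(unname(a)), Biostrings::AAString(unname(b)),
    type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  sc <- Biostrings::score(al)
  ncol_aln <- Biostrings::nchar(al)  # alignment length incl. gap columns
  nid <- Biostrings::nmatch(al)
  qr <- c(IRanges::start(Biostrings::pattern(al)),
          IRanges::end(Biostrings::pattern(al)))
  sr <- c(IRanges::start(Biostrings::subject(al)),
          IRanges::end(Biostrings::subject(al)))
  la <- nchar(a); lb <- nchar(b)
  span_on_longer <- if (la >= lb) qr[2] - qr[1] + 1L else sr[2] - sr[1] + 1L
  n_db <- search_n %||% lb
  list(query_id = names(a), subject_id = names(b),
       score = sc, bit_score = ka_bits(sc),
       evalue = ka_evalue(sc, la, n_db),
       identity = nid / ncol_aln,
       longest_coverage = span_on_longer / max(la, lb),
       q_start = qr[1], q_end = qr[2], s_start = sr[1], s_end = sr[2])
}
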