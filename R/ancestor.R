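#' Ancestral pangenome generator
#'
#' Builds the planted common ancestor from which simulated strains evolve: a
#' set of protein-coding genes (ATG start, stop end, no internal stop),
#' fixed-length intergenic spacers and a single rRNA-like marker locus, all
#' drawn at a target GC content.
#'
#' @param n_genes number of ancestral genes (>= 0).
#' @param length_range two gene lengths in bp (multiples of 3, >= 33); gene
#'   lengths are drawn uniformly over codon counts in this range.
#' @param gc_target target GC fraction in `[0, 1]` for all emitted sequence.
#' @param pathway_assignments optional named character vector mapping
#'   `gene_id` to a pathway identifier.
#' @param seed integer seed; the ancestor is byte-reproducible for a fixed
#'   seed.
#' @param spacer_len fixed intergenic spacer length in bp.
#' @param rrna_len length of the rRNA-like locus in bp (0 to omit).
#' @return an object of class `ancestral_pangenome`: list with `genes`
#'   (named `DNAStringSet`), `gene_table` (`gene_id`, `length`, `strand`,
#'   `pathway_id`), `spacers` (`DNAStringSet`, one per gene plus a trailing
#'   one), `rrna`, `rrna_spacer`, `gc_target`, `spacer_len`.
#' @examples
#' anc <- generate_ancestor(5, c(300, 450), 0.5, seed = 1)
#' names(anc$genes)
#' @export
generate_ancestor <- function(n_genes, length_range = c(300L, 900L),
                              gc_target = 0.5, pathway_assignments = NULL,
                              seed = 1L, spacer_len = 200L, rrna_len = 1500L) {
  stopifnot(length(n_genes) == 1L, n_genes >= 0)
  if (length(length_range) != 2L || any(length_range %% 3L != 0L) ||
      any(length_range < 33L) || length_range[2] < length_range[1]) {
    stop("'length_range' must be two increasing lengths, multiples of 3, >= 33")
  }
  stopifnot(gc_target >= 0, gc_target <= 1, spacer_len >= 1)

  with_seed(seed, {
    n_genes <- as.integer(n_genes)
    codon_range <- seq.int(length_range[1] %/% 3L, length_range[2] %/% 3L)
    lens <- 3L * codon_range[sample.int(length(codon_range), n_genes,
                                        replace = TRUE)]
    ids <- sprintf("g%04d", seq_len(n_genes))
    genes <- vapply(lens, random_orf, character(1), gc = gc_target)
    strands <- if (n_genes > 0) sample(c("+", "-"), n_genes, replace = TRUE) else character(0)
    spacers <- vapply(rep(spacer_len, n_genes + 1L), random_dna, character(1),
                      gc = gc_target)
    rrna <- if (rrna_len > 0) random_dna(rrna_len, gc_target) else ""
    rrna_spacer <- if (rrna_len > 0) random_dna(spacer_len, gc_target) else ""

    pw <- rep(NA_character_, n_genes)
    if (!is.null(pathway_assignments)) {
      hit <- match(ids, names(pathway_assignments))
      pw[!is.na(hit)] <- unname(pathway_assignments[hit[!is.na(hit)]])
    }
    anc <- structure(list(
      genes = stats::setNames(Biostrings::DNAStringSet(genes), ids),
      gene_table = data.frame(gene_id = ids, length = lens, strand = strands,
                              pathway_id = pw, stringsAsFactors = FALSE),
      spacers = Biostrings::DNAStringSet(spacers),
      rrna = rrna, rrna_spacer = rrna_spacer,
      gc_target = gc_target, spacer_len = as.integer(spacer_len),
      seed = as.integer(seed)
    ), class = "ancestral_pangenome")
    validate_ancestor(anc)
    anc
  })
}

#' @export
print.ancestral_pangenome <- function(x, ...) {
  cat(sprintf("ancestral pangenome: %d genes (%s bp), GC target %.2f, spacer %d bp\n",
              length(x$genes),
              if (length(x$genes)) paste(range(x$gene_table$length), collapse = "-") else "0",
              x$gc_target, x$spacer_len))
  invisible(x)
}

#' Check ancestral pangenome invariants
#'
#' Every gene must start with ATG, end with a stop codon, have length a
#' multiple of 3 and carry no internal in-frame stop; gene ids must be unique.
#' @param anc an `ancestral_pangenome`.
#' @return `anc`, invisibly; errors on violation.
#' @export
validate_ancestor <- function(anc) {
  stopifnot(inherits(anc, "ancestral_pangenome"))
  ids <- names(anc$genes)
  if (anyDuplicated(ids)) stop("duplicate gene ids in ancestor")
  for (i in seq_along(anc$genes)) {
    s <- as.character(anc$genes[[i]])
    if (nchar(s) %% 3L != 0L) stop("gene length not a multiple of 3: ", ids[i])
    if (substr(s, 1L, 3L) != "ATG") stop("gene does not start with ATG: ", ids[i])
    codons <- substring(s, seq(1L, nchar(s) - 2L, 3L), seq(3L, nchar(s), 3L))
    if (!codons[length(codons)] %in% .STOP_CODONS)
      stop("gene does not end with a stop codon: ", ids[i])
    if (any(codons[-length(codons)] %in% .STOP_CODONS))
      stop("internal stop codon in gene: ", ids[i])
  }
  invisible(anc)
}

# Random open reading frame: ATG + sense codons + stop, bases drawn at the
# requested GC (stop-codon exclusion shifts realised GC up by ~1%).
#' @keywords internal
random_orf <- function(len, gc) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codons <- as.vector(outer(outer(names(base_p), names(base_p), paste0),
                            names(base_p), paste0))
  p <- apply(do.call(rbind, strsplit(codons, "")), 1L,
             function(b) prod(base_p[b]))
  sense <- !codons %in% .STOP_CODONS
  body <- sample(codons[sense], len %/% 3L - 2L, replace = TRUE,
                 prob = p[sense] / sum(p[sense]))
  stopc <- sample(.STOP_CODONS, 1L,
                  prob = p[match(.STOP_CODONS, codons)] /
                    sum(p[match(.STOP_CODONS, codons)]))
  paste0("ATG", paste(body, collapse = ""), stopc)
}

#' @keywords internal
random_dna <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
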