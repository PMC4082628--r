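#' Write a simulated strain set to disk
#'
#' Emits, per strain, a genome FASTA (`<id>.fna`), a GFF3 feature table
#' (`<id>.gff3`, CDS / rRNA / mobile_genetic_element features; no
#' ground-truth attributes), and a protein FASTA of intact-gene translations
#' (`<id>.faa`); plus a study-wide `truth.tsv` and `strains.tsv`
#' (strain -> subspecies).  [read_dataset()] is the exact inverse for the
#' emitted information.
#'
#' @param strains non-empty list of `strain_genome` objects.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
emit_dataset <- function(strains, out_dir) {
  if (!length(strains)) stop("'strains' must be a non-empty list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  for (st in strains) {
    stopifnot(inherits(st, "strain_genome"))
    contig <- paste0(st$strain_id, "_c1")
    fna <- Biostrings::DNAStringSet(stats::setNames(st$genome, contig))
    Biostrings::writeXStringSet(fna, file.path(out_dir, paste0(st$strain_id, ".fna")))
    if (length(st$proteins)) {
      faa <- Biostrings::AAStringSet(st$proteins)
      Biostrings::writeXStringSet(faa, file.path(out_dir, paste0(st$strain_id, ".faa")))
    } else {
      writeLines(character(0), file.path(out_dir, paste0(st$strain_id, ".faa")))
    }
    write_gff3(st$features, contig, file.path(out_dir, paste0(st$strain_id, ".gff3")))
  }
  truth <- do.call(rbind, lapply(strains, `[[`, "truth"))
  write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- data.frame(
    strain_id = vapply(strains, `[[`, character(1), "strain_id"),
    subspecies = vapply(strains, `[[`, character(1), "subspecies"),
    stringsAsFactors = FALSE)
  write.table(meta, file.path(out_dir, "strains.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

# Feature table (1-based closed intervals) -> GFF3 via rtracklayer.
#' @keywords internal
write_gff3 <- function(features, contig, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand)
  gr$source <- "reducto_sim"
  gr$type <- features$type
  gr$phase <- ifelse(features$type == "CDS", 0L, NA_integer_)
  gr$ID <- features$feature_id
  gr$locus_tag <- features$gene_id
  gr$family <- features$family
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @keywords internal
read_gff3_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    type = as.character(gr$type),
    feature_id = as.character(gr$ID),
    gene_id = if (!is.null(gr$locus_tag)) as.character(gr$locus_tag) else NA_character_,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    family = if (!is.null(gr$family)) as.character(gr$family) else NA_character_,
    stringsAsFactors = FALSE)
  df[order(df$start, df$end), , drop = FALSE]
}

#' Read back a simulated (or equivalently formatted) strain set
#'
#' @param dir directory written by [emit_dataset()].
#' @return list with `strains` (list of `strain_genome`-shaped objects:
#'   `strain_id`, `subspecies`, `genome`, `features`, `proteins`), `truth`
#'   (data.frame, `NULL` if absent) and `meta` (strain -> subspecies).
#' @export
read_dataset <- function(dir) {
  meta <- read.delim(file.path(dir, "strains.tsv"), stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    read.delim(truth_path, stringsAsFactors = FALSE)
  } else NULL
  strains <- lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$strain_id[i]
    fna <- Biostrings::readDNAStringSet(file.path(dir, paste0(sid, ".fna")))
    faa_path <- file.path(dir, paste0(sid, ".faa"))
    prot <- if (file.size(faa_path) > 0) {
      aa <- Biostrings::readAAStringSet(faa_path)
      stats::setNames(as.character(aa), names(aa))
    } else stats::setNames(character(0), character(0))
    structure(list(
      strain_id = sid, subspecies = meta$subspecies[i],
      genome = as.character(fna[[1]]),
      features = read_gff3_features(file.path(dir, paste0(sid, ".gff3"))),
      truth = if (!is.null(truth)) truth[truth$strain_id == sid, , drop = FALSE] else NULL,
      proteins = prot
    ), class = "strain_genome")
  })
  names(strains) <- meta$strain_id
  list(strains = strains, truth = truth, meta = meta)
}

#' Proteome table of one or more strains
#'
#' Translates every annotated CDS of each strain into the tabular proteome
#' used by the clustering stage (one row per protein).
#' @param strains list of `strain_genome` objects.
#' @param exclude optional data.frame (`strain_id`, `cds_id`) of CDS to drop,
#'   typically pseudogene-fragment calls.
#' @return data.frame with `strain_id`, `protein_id`, `sequence`, `is_pseudo`.
#' @export
strain_proteomes <- function(strains, exclude = NULL) {
  rows <- lapply(strains, function(st) {
    cds <- st$features[st$features$type == "CDS", , drop = FALSE]
    if (!nrow(cds)) return(NULL)
    seqs <- vapply(seq_len(nrow(cds)), function(i) {
      s <- substr(st$genome, cds$start[i], cds$end[i])
      if (cds$strand[i] == "-") s <- revcomp_chr(s)
      sub("\\*$", "", translate_nt(s))
    }, character(1))
    data.frame(strain_id = st$strain_id, protein_id = cds$gene_id,
               sequence = seqs, is_pseudo = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- paste(out$strain_id, out$protein_id) %in%
      paste(exclude$strain_id, exclude$cds_id)
    out <- out[!drop, , drop = FALSE]
  }
  out[nzchar(out$sequence), , drop = FALSE]
}
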