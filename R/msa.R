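#' Progressive multiple sequence alignment
#'
#' ClustalW-style progressive alignment: pairwise shared-word distances give
#' a guide tree (average-linkage), profiles are merged bottom-up by global
#' profile-profile alignment with affine gaps (sum-of-pairs column scores;
#' existing gap symbols score zero).  The computation is canonicalised on
#' sorted labels, so permuting the input order changes nothing but the row
#' order of the output.
#'
#' @param seqs named character vector of >= 2 sequences (unique names).
#' @param type `"dna"` or `"protein"`.
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @param kmer_len word length for guide-tree distances.
#' @return object of class `msa`: list with `labels`, `aln` (aligned strings
#'   in input order), `ncol`.
#' @export
progressive_align <- function(seqs, type = c("dna", "protein"),
                              gap_open = 10, gap_extend = 0.5,
                              kmer_len = NULL) {
  type <- match.arg(type)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) ||
      any(!nzchar(names(seqs)))) {
    stop("sequences must carry unique non-empty names")
  }
  seqs <- vapply(seqs, toupper, character(1))
  input_order <- names(seqs)
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  k <- kmer_len %||% if (type == "dna") 8L else 3L

  if (type == "dna") {
    alphabet <- c("A", "C", "G", "T")
    S <- matrix(-4, 4, 4, dimnames = list(alphabet, alphabet))
    diag(S) <- 5
  } else {
    full <- get_submat("BLOSUM62")
    alphabet <- setdiff(rownames(full), "-")
    S <- full[alphabet, alphabet]
  }

  # guide tree from fractional shared-word distances
  kms <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    denom <- min(length(kms[[i]]), length(kms[[j]]))
    d <- if (denom == 0) 1 else 1 - length(intersect(kms[[i]], kms[[j]])) / denom
    D[i, j] <- D[j, i] <- d
  }
  merges <- if (n == 2L) {
    matrix(c(-1L, -2L), 1L)
  } else {
    stats::hclust(stats::as.dist(D), method = "average")$merge
  }

  profiles <- vector("list", nrow(merges))
  get_profile <- function(ref) {
    if (ref < 0) {
      m <- matrix(strsplit(seqs[[-ref]], "")[[1]], nrow = 1)
      rownames(m) <- names(seqs)[-ref]
      m
    } else profiles[[ref]]
  }
  for (r in seq_len(nrow(merges))) {
    A <- get_profile(merges[r, 1]); B <- get_profile(merges[r, 2])
    profiles[[r]] <- merge_profiles(A, B, S, alphabet, gap_open, gap_extend)
  }
  final <- profiles[[nrow(merges)]]
  aln <- apply(final, 1L, paste, collapse = "")
  aln <- aln[input_order]
  structure(list(labels = input_order, aln = aln, ncol = ncol(final)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences, %d columns\n", length(x$labels), x$ncol))
  invisible(x)
}

#' Alignment as a character matrix (rows = sequences)
#' @param x an `msa` object (or character matrix, returned as is).
#' @return character matrix of single characters.
#' @export
msa_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(inherits(x, "msa"))
  m <- do.call(rbind, strsplit(unname(x$aln), ""))
  rownames(m) <- x$labels
  m
}

# Sum-of-pairs column-score matrix, then affine DP in C++.
#' @keywords internal
merge_profiles <- function(A, B, S, alphabet, gap_open, gap_extend) {
  count_mat <- function(P) {
    idx <- match(P, alphabet)       # gaps and unknowns -> NA -> score 0
    dim(idx) <- dim(P)
    C <- matrix(0, length(alphabet), ncol(P))
    for (i in seq_len(nrow(P))) {
      j <- which(!is.na(idx[i, ]))
      if (length(j)) {
        C[cbind(idx[i, j], j)] <- C[cbind(idx[i, j], j)] + 1
      }
    }
    C
  }
  CA <- count_mat(A); CB <- count_mat(B)
  M <- crossprod(CA, S %*% CB) / (nrow(A) * nrow(B))
  path <- align_profiles_cpp(M, gap_open, gap_extend)
  na <- length(path$a)
  out <- matrix("-", nrow(A) + nrow(B), na)
  rownames(out) <- c(rownames(A), rownames(B))
  ia <- path$a > 0
  out[seq_len(nrow(A)), ia] <- A[, path$a[ia], drop = FALSE]
  ib <- path$b > 0
  out[nrow(A) + seq_len(nrow(B)), ib] <- B[, path$b[ib], drop = FALSE]
  out
}
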