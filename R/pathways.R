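#' Pathway definition for one fermentable substrate
#'
#' A pathway is an AND over gene groups, each group an OR over alternative
#' genes (isoenzymes or alternative systems); transporter groups are flagged
#' so reports can separate uptake from catabolism.
#'
#' @param substrate substrate label.
#' @param groups list of groups; each group is a list with `genes`
#'   (non-empty character vector) and optional `transporter` flag.
#' @return object of class `pathway_def`.
#' @export
pathway_def <- function(substrate, groups) {
  if (!length(groups)) stop("pathway needs at least one gene group")
  groups <- lapply(groups, function(g) {
    if (is.character(g)) g <- list(genes = g)
    if (!length(g$genes)) stop("empty gene group in pathway ", substrate)
    list(genes = as.character(g$genes),
         transporter = isTRUE(g$transporter))
  })
  structure(list(substrate = substrate, groups = groups),
            class = "pathway_def")
}

#' Read pathway definitions from YAML
#'
#' Expected layout: a top-level `substrates` mapping, each substrate a list
#' of groups with `genes` and optional `transporter`.
#'
#' @param path YAML file.
#' @return named list of [pathway_def()] objects.
#' @export
read_pathway_defs <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$substrates)) stop("no 'substrates' key in ", path)
  defs <- lapply(names(y$substrates), function(s) {
    pathway_def(s, y$substrates[[s]])
  })
  stats::setNames(defs, names(y$substrates))
}

#' Status of one gene in one strain
#'
#' `present` if an intact CDS matches any synonym, `pseudo` if only
#' pseudogene fragments match, `absent` otherwise.
#'
#' @param intact_genes gene identifiers annotated intact in the strain.
#' @param pseudo_genes gene identifiers with pseudogene-fragment calls.
#' @param synonyms non-empty character vector of identifiers for the gene.
#' @return `"present"`, `"pseudo"` or `"absent"`.
#' @export
gene_status <- function(intact_genes, pseudo_genes, synonyms) {
  if (!length(synonyms)) stop("synonym list must be non-empty")
  if (any(synonyms %in% intact_genes)) return("present")
  if (any(synonyms %in% pseudo_genes)) return("pseudo")
  "absent"
}

#' Gene status table from annotations and pseudogene calls
#'
#' @param strains list of `strain_genome` objects (annotated CDS define the
#'   gene universe per strain).
#' @param pseudo_calls calls from [call_pseudogenes()] across strains;
#'   called CDS get status `pseudo`, remaining CDS `present`.
#' @return data.frame with `strain_id`, `gene_id`, `status`.
#' @export
gene_status_table <- function(strains, pseudo_calls = NULL) {
  rows <- lapply(strains, function(st) {
    cds <- st$features[st$features$type == "CDS", , drop = FALSE]
    if (!nrow(cds)) return(NULL)
    data.frame(strain_id = st$strain_id, gene_id = cds$gene_id,
               status = "present", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(pseudo_calls) && nrow(pseudo_calls)) {
    frag <- pseudo_calls[pseudo_calls$verdict == "pseudogene_fragment", ]
    hit <- paste(out$strain_id, out$gene_id) %in%
      paste(frag$strain_id, frag$cds_id)
    out$status[hit] <- "pseudo"
  }
  rownames(out) <- NULL
  out
}

#' Pathway completeness for one strain
#'
#' Complete iff every group has at least one `present` member; `pseudo`
#' never satisfies a group (fragments are non-functional).  Failing groups
#' are classified `fragmentation` when a member is a pseudogene fragment,
#' `absence` otherwise — the distinction behind "lack or fragmentation of
#' one or two pathway-specific genes".
#'
#' @param def a [pathway_def()].
#' @param statuses status table from [gene_status_table()].
#' @param strain strain id.
#' @return list with `complete`, `failing` (data.frame `group`, `class`,
#'   `transporter`).
#' @export
pathway_complete <- function(def, statuses, strain) {
  stopifnot(inherits(def, "pathway_def"))
  sub <- statuses[statuses$strain_id == strain, , drop = FALSE]
  st_of <- stats::setNames(sub$status, sub$gene_id)
  failing <- list()
  for (gi in seq_along(def$groups)) {
    g <- def$groups[[gi]]
    st <- st_of[g$genes]
    st[is.na(st)] <- "absent"
    if (!any(st == "present")) {
      failing[[length(failing) + 1L]] <- data.frame(
        group = gi,
        class = if (any(st == "pseudo")) "fragmentation" else "absence",
        transporter = g$transporter, stringsAsFactors = FALSE)
    }
  }
  list(complete = !length(failing),
       failing = if (length(failing)) do.call(rbind, failing) else
         data.frame(group = integer(0), class = character(0),
                    transporter = logical(0)))
}

#' Predict fermentation phenotypes from pathway completeness
#'
#' `+` iff the substrate's pathway (transporter and catabolic groups alike)
#' is complete; substrates without a definition are `untested`.
#'
#' @param defs named list of [pathway_def()] objects.
#' @param statuses status table from [gene_status_table()].
#' @param strains strain ids (default: all in `statuses`).
#' @param substrates substrate labels (default: names of `defs`).
#' @return character matrix strains x substrates with `"+"`, `"-"`,
#'   `"untested"`.
#' @export
predict_phenotypes <- function(defs, statuses,
                               strains = unique(statuses$strain_id),
                               substrates = names(defs)) {
  out <- matrix("untested", length(strains), length(substrates),
                dimnames = list(strains, substrates))
  for (s in substrates) {
    if (is.null(defs[[s]])) next
    for (st in strains) {
      out[st, s] <- if (pathway_complete(defs[[s]], statuses, st)$complete)
        "+" else "-"
    }
  }
  out
}

#' Read a fermentation phenotype table
#'
#' Tab-separated, one row per strain: `strain_id`, optional `subspecies`,
#' then one column per substrate holding `+`, `-` or `NA` (untested).
#'
#' @param path TSV file.
#' @return list with `matrix` (strains x substrates), `meta` (named
#'   subspecies vector, possibly empty).
#' @export
read_phenotype_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("strain_id" %in% names(df))
  meta <- if ("subspecies" %in% names(df)) {
    stats::setNames(df$subspecies, df$strain_id)
  } else stats::setNames(character(0), character(0))
  subs <- setdiff(names(df), c("strain_id", "subspecies"))
  m <- as.matrix(df[, subs, drop = FALSE])
  rownames(m) <- df$strain_id
  m[is.na(m)] <- "untested"
  list(matrix = m, meta = meta)
}

#' Fermented-substrate counts and subspecies-discriminating substrates
#'
#' Per-strain fermented counts (row sums of `+`), concordance with a
#' predicted matrix when given, and the substrates that discriminate the two
#' subspecies: uniformly `+` in every tested strain of one subspecies and
#' uniformly `-` in every tested strain of the other (untested cells are
#' excluded, never imputed; at least one tested strain per subspecies).
#'
#' @param observed character matrix strains x substrates (`+`, `-`,
#'   `untested`).
#' @param meta named `strain_id -> subspecies` vector covering the rows;
#'   exactly two subspecies required.
#' @param predicted optional matrix of the same shape for concordance.
#' @return list with `counts` (named integer), `discriminating` (character),
#'   `concordance` (fraction, `NA` without predictions), `n_compared`.
#' @export
compare_and_discriminate <- function(observed, meta, predicted = NULL) {
  strains <- rownames(observed)
  ssp <- unique(unname(meta[strains]))
  if (length(ssp) != 2L) stop("exactly two subspecies required")
  s1 <- strains[meta[strains] == ssp[1]]
  s2 <- strains[meta[strains] == ssp[2]]
  counts <- apply(observed == "+", 1L, sum)

  disc <- character(0)
  for (s in colnames(observed)) {
    a <- observed[s1, s]; a <- a[a != "untested"]
    b <- observed[s2, s]; b <- b[b != "untested"]
    if (!length(a) || !length(b)) next
    if ((all(a == "+") && all(b == "-")) || (all(a == "-") && all(b == "+"))) {
      disc <- c(disc, s)
    }
  }
  concordance <- NA_real_; n_compared <- 0L
  if (!is.null(predicted)) {
    common_r <- intersect(rownames(observed), rownames(predicted))
    common_c <- intersect(colnames(observed), colnames(predicted))
    o <- observed[common_r, common_c, drop = FALSE]
    p <- predicted[common_r, common_c, drop = FALSE]
    ok <- o != "untested" & p != "untested"
    n_compared <- sum(ok)
    if (n_compared) concordance <- sum(o[ok] == p[ok]) / n_compared
  }
  list(counts = counts, discriminating = disc, concordance = concordance,
       n_compared = n_compared)
}
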