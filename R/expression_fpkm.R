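#' Construct a validated count matrix
#'
#' Bundles a gene x sample matrix of fragment counts with per-gene transcript
#' lengths and per-sample library sizes. Library sizes default to the column
#' sums of the counted genes; an explicit vector (e.g. total mapped
#' fragments, which may exceed the counted total) can be supplied.
#'
#' @param counts gene x sample matrix of non-negative integers with row and
#'   column names.
#' @param gene_lengths named numeric vector, nt per gene.
#' @param library_sizes optional named numeric vector per sample; must be at
#'   least the column sums.
#' @return list of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_lengths, library_sizes = NULL) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(rownames(counts) %in% names(gene_lengths))) {
    stop("gene_lengths missing for: ",
         paste(setdiff(rownames(counts), names(gene_lengths)), collapse = ", "))
  }
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(gene_lengths <= 0)) stop("gene_lengths must be positive")
  cs <- colSums(counts)
  if (is.null(library_sizes)) {
    library_sizes <- cs
  } else {
    library_sizes <- library_sizes[colnames(counts)]
    if (any(is.na(library_sizes))) stop("library_sizes missing for some samples")
    if (any(library_sizes < cs)) {
      stop("library_sizes smaller than counted fragments in some samples")
    }
  }
  structure(list(counts = counts, gene_lengths = gene_lengths,
                 library_sizes = library_sizes),
            class = "count_matrix")
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (library_sizes[s] * gene_lengths[g])`:
#' counts scaled per kilobase of transcript (1e3) and per million mapped
#' fragments (1e6).
#'
#' @param cm a [count_matrix()].
#' @return gene x sample matrix of FPKM values.
#' @export
fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$library_sizes == 0)) stop("zero library size")
  sweep(sweep(cm$counts * 1e9, 2, cm$library_sizes, "/"),
        1, cm$gene_lengths, "/")
}

#' Cross-taxon expression comparison
#'
#' Summarises replicate FPKM matrices per taxon for a set of genes of
#' interest: the replicate mean (or median) per taxon, the rank order of
#' taxa, and -- when habitat groups are supplied -- a direction label naming
#' the group with the higher mean, or `"tie"`. Genes missing from any taxon
#' are flagged and excluded from ranking.
#'
#' @param fpkm_by_taxon named list of FPKM matrices (genes x replicates).
#' @param genes character vector of genes of interest.
#' @param replicate_policy `"mean"` (default) or `"median"`.
#' @param habitat_groups optional named list of two character vectors of
#'   taxa.
#' @param tie_tol relative tolerance for calling a tie (default 1e-8).
#' @return data.frame: gene, one `<taxon>` column per taxon, `rank_order`,
#'   `direction`, `flagged`.
#' @export
cross_taxa_expression <- function(fpkm_by_taxon, genes,
                                  replicate_policy = c("mean", "median"),
                                  habitat_groups = NULL, tie_tol = 1e-8) {
  replicate_policy <- match.arg(replicate_policy)
  agg <- if (replicate_policy == "mean") rowMeans else
    function(m) apply(m, 1, stats::median)
  taxa <- names(fpkm_by_taxon)
  rows <- lapply(genes, function(g) {
    present <- vapply(fpkm_by_taxon, function(m) g %in% rownames(m), logical(1))
    vals <- rep(NA_real_, length(taxa))
    names(vals) <- taxa
    for (t in taxa[present]) {
      vals[t] <- agg(fpkm_by_taxon[[t]][g, , drop = FALSE])
    }
    flagged <- !all(present)
    rank_order <- if (flagged) NA_character_ else
      paste(taxa[order(vals, decreasing = TRUE)], collapse = ">")
    direction <- NA_character_
    if (!flagged && !is.null(habitat_groups)) {
      gm <- vapply(habitat_groups, function(tx) mean(vals[tx]), numeric(1))
      spread <- abs(gm[1] - gm[2])
      scale_ref <- max(abs(gm), tie_tol)
      direction <- if (spread <= tie_tol * scale_ref) "tie" else
        names(gm)[which.max(gm)]
    }
    out <- data.frame(gene = g, t(vals), rank_order = rank_order,
                      direction = direction, flagged = flagged,
                      stringsAsFactors = FALSE)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
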