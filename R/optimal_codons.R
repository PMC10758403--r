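#' Select putative high- and low-expression gene sets
#'
#' Ranks genes by an expression proxy and takes the extreme `fraction` at
#' each end (k = ceiling(fraction * n), at least 1). With `metric = "cai"`
#' the high set is the top-k by CAI and the low set the bottom-k; with
#' `"enc"` the high set is the bottom-k by ENc (strong bias implies high
#' expression) and the low set the top-k; `"both"` intersects the CAI and
#' ENc choices and errors when either intersection is empty. Ties are broken
#' by gene_id so the selection is deterministic.
#'
#' @param records data.frame from [gene_cub_table()].
#' @param metric `"cai"` (default), `"enc"`, or `"both"`.
#' @param fraction extreme fraction in (0, 0.5), default 0.05.
#' @return list with `high` and `low` data.frames (subsets of `records`)
#'   and `k`.
#' @export
select_extreme_genes <- function(records, metric = c("cai", "enc", "both"),
                                 fraction = 0.05) {
  metric <- match.arg(metric)
  stopifnot(fraction > 0, fraction < 0.5)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 genes, got ", n)
  k <- max(1L, as.integer(ceiling(fraction * n)))
  if (2L * k > n) {
    stop("high and low sets overlap: n = ", n, ", k = ", k)
  }
  # metric ties are broken by gene_id, from opposite ends for the high and
  # low sets so they stay disjoint on fully tied input
  pick <- function(value, decreasing) {
    ord <- order(value, records$gene_id,
                 decreasing = c(decreasing, !decreasing), method = "radix")
    records$gene_id[ord][seq_len(k)]
  }
  sets <- switch(metric,
    cai = list(high = pick(records$cai, TRUE), low = pick(records$cai, FALSE)),
    enc = list(high = pick(records$enc, FALSE), low = pick(records$enc, TRUE)),
    both = {
      hi <- intersect(pick(records$cai, TRUE), pick(records$enc, FALSE))
      lo <- intersect(pick(records$cai, FALSE), pick(records$enc, TRUE))
      if (length(hi) == 0L || length(lo) == 0L) {
        stop("metric 'both': empty intersection of CAI and ENc extremes ",
             "(n = ", n, ", k = ", k, ")")
      }
      list(high = hi, low = lo)
    })
  if (length(intersect(sets$high, sets$low)) > 0L) {
    stop("high and low sets overlap: n = ", n, ", k = ", k)
  }
  list(high = records[records$gene_id %in% sets$high, , drop = FALSE],
       low = records[records$gene_id %in% sets$low, , drop = FALSE],
       k = k)
}

#' Call optimal codons from high/low-expression RSCU contrast
#'
#' Computes RSCU on the pooled high-expression and pooled low-expression
#' count tables; `delta_rscu = rscu_high - rscu_low`. A codon is optimal
#' when `delta_rscu > delta` and the anchor RSCU exceeds 1 (strict
#' comparisons). The anchor defaults to the high-set RSCU; `"all"` uses the
#' whole-genome RSCU instead -- both values are reported so either reading
#' can be audited. Stop codons and singleton families never produce calls.
#'
#' @param high,low,all `codon_counts` tables for the pooled high set, pooled
#'   low set and all genes.
#' @param delta ΔRSCU threshold (default 0.08).
#' @param code a [genetic_code()] object.
#' @param anchor `"high"` (default) or `"all"`: which RSCU must exceed 1.
#' @param taxon label attached to the calls.
#' @return data.frame: codon, amino_acid, rscu_high, rscu_low, delta_rscu,
#'   rscu_all, is_optimal, taxon.
#' @export
call_optimal <- function(high, low, all, delta = 0.08,
                         code = genetic_code(), anchor = c("high", "all"),
                         taxon = "") {
  anchor <- match.arg(anchor)
  stopifnot(sum(high) > 0L, sum(low) > 0L, sum(all) > 0L)
  r_hi <- unclass(rscu(high, code))
  r_lo <- unclass(rscu(low, code))
  r_all <- unclass(rscu(all, code))
  fam_sizes <- family_sizes(code)
  cods <- code$sense_codons[fam_sizes[code$sense_codons] > 1L]
  keep <- !is.na(r_hi[cods]) & !is.na(r_lo[cods])
  cods <- cods[keep]
  d <- r_hi[cods] - r_lo[cods]
  anchor_val <- if (anchor == "high") r_hi[cods] else r_all[cods]
  out <- data.frame(
    codon = cods,
    amino_acid = unname(code$codon_to_aa[cods]),
    rscu_high = unname(r_hi[cods]),
    rscu_low = unname(r_lo[cods]),
    delta_rscu = unname(d),
    rscu_all = unname(r_all[cods]),
    is_optimal = unname(d > delta & !is.na(anchor_val) & anchor_val > 1),
    taxon = taxon,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Optimal codons shared across taxa
#'
#' @param calls_by_taxon named list of [call_optimal()] tables.
#' @param habitat_groups optional named list mapping group name to a
#'   character vector of taxa; codons shared within a group but absent from
#'   all other taxa are reported per group.
#' @return list: `shared` (codons optimal in every taxon), `per_taxon`
#'   (optimal sets), `specific` (per taxon, codons optimal there only),
#'   `group_shared` (per habitat group, if given).
#' @export
shared_optimal <- function(calls_by_taxon, habitat_groups = NULL) {
  stopifnot(length(calls_by_taxon) >= 2L)
  sets <- lapply(calls_by_taxon, function(d) d$codon[d$is_optimal])
  shared <- Reduce(intersect, sets)
  specific <- lapply(names(sets), function(t) {
    others <- unlist(sets[setdiff(names(sets), t)])
    setdiff(sets[[t]], others)
  })
  names(specific) <- names(sets)
  group_shared <- NULL
  if (!is.null(habitat_groups)) {
    group_shared <- lapply(habitat_groups, function(taxa) {
      inside <- Reduce(intersect, sets[taxa])
      outside <- unlist(sets[setdiff(names(sets), taxa)])
      setdiff(inside, outside)
    })
  }
  list(shared = shared, per_taxon = sets, specific = specific,
       group_shared = group_shared)
}

#' Overrepresented codons
#'
#' Codons whose RSCU strictly exceeds a threshold (1.6 is the conventional
#' overrepresentation cut-off; 1 marks any positive bias).
#'
#' @param rscu_table an `rscu_table`.
#' @param threshold strict lower bound (default 1.6).
#' @return character vector of codons.
#' @export
overrepresented <- function(rscu_table, threshold = 1.6) {
  v <- unclass(rscu_table)
  names(v)[!is.na(v) & v > threshold]
}
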