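#' Count codons in a coding sequence
#'
#' Splits the sequence into in-frame triplets and tallies them over the 64
#' codons. Codons containing any non-ACGT base are skipped (the whole codon
#' is excluded, the gene is kept). Stop codons are tallied but excluded from
#' all downstream 61-codon analyses, which subset by the genetic code.
#'
#' @param sequence a CDS string, or a one-row data.frame with a `sequence`
#'   column.
#' @param gene_id,taxon labels recorded on the table (taken from the
#'   data.frame when one is supplied).
#' @return object of class `codon_counts`: named integer vector over the 64
#'   codons with attributes `source`, `taxon`, `n_ambiguous`.
#' @export
count_codons <- function(sequence, gene_id = "gene", taxon = "") {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    gene_id <- sequence$gene_id
    if (!is.null(sequence$taxon)) taxon <- sequence$taxon
    sequence <- sequence$sequence
  }
  cods <- codon_split(toupper(sequence))
  ok <- !grepl("[^ACGT]", cods)
  counts <- integer(64L)
  names(counts) <- all_codons()
  tab <- table(cods[ok])
  counts[names(tab)] <- as.integer(tab)
  # stop codons live in a separate tally, never in the 61-codon analyses
  stop_cod <- names(which(Biostrings::getGeneticCode("11") == "*"))
  stop_counts <- counts[stop_cod]
  counts[stop_cod] <- 0L
  structure(counts, source = gene_id, taxon = taxon,
            stop_counts = stop_counts,
            n_ambiguous = sum(!ok), class = "codon_counts")
}

#' Pool several codon count tables
#' @param tables list of `codon_counts` objects.
#' @param label source label of the pooled table.
#' @return a pooled `codon_counts` object.
#' @export
pool_counts <- function(tables, label = "pool") {
  stopifnot(length(tables) > 0L)
  m <- do.call(cbind, lapply(tables, as.integer))
  counts <- as.integer(rowSums(m))
  names(counts) <- all_codons()
  taxa <- unique(vapply(tables, function(t) attr(t, "taxon") %||% "", character(1)))
  stop_tallies <- lapply(tables, function(t) attr(t, "stop_counts"))
  stop_tallies <- stop_tallies[!vapply(stop_tallies, is.null, logical(1))]
  stop_counts <- if (length(stop_tallies)) {
    Reduce(`+`, stop_tallies)
  } else NULL
  structure(counts, source = label,
            taxon = if (length(taxa) == 1L) taxa else "",
            stop_counts = stop_counts,
            n_ambiguous = sum(vapply(tables, function(t)
              attr(t, "n_ambiguous") %||% 0L, integer(1))),
            class = "codon_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nucleotide composition of a codon count table
#'
#' Computes overall and per-position base fractions, GC content overall and
#' at codon positions 1-3 (over the counted sense codons; the terminal stop
#' codon lives in a separate tally and is excluded), GC3s (third-position GC
#' restricted to codons whose amino acid is neither Met, Trp nor stop), and
#' third-position base counts A3/T3/G3/C3 over sense codons (the PR2
#' default scope).
#'
#' @param table a `codon_counts` object with positive total.
#' @param code a [genetic_code()] object.
#' @return list with elements `base_freq` (4 x 4 matrix: rows A,C,G,T;
#'   columns overall + positions 1-3), `gc_total`, `gc1`, `gc2`, `gc3`,
#'   `gc3s` (NA when no eligible codon), `a3`, `t3`, `g3`, `c3`,
#'   `n_codons`.
#' @export
composition <- function(table, code = genetic_code()) {
  counts <- as.integer(table)
  codons <- all_codons()
  total <- sum(counts)
  if (total == 0L) stop("empty codon count table")
  bases <- c("A", "C", "G", "T")
  pos_counts <- sapply(1:3, function(p) {
    b <- substr(codons, p, p)
    vapply(bases, function(x) sum(counts[b == x]), numeric(1))
  })
  overall <- rowSums(pos_counts)
  freq <- cbind(overall / sum(overall), sweep(pos_counts, 2, colSums(pos_counts), "/"))
  dimnames(freq) <- list(bases, c("overall", "pos1", "pos2", "pos3"))
  gc_pos <- colSums(freq[c("G", "C"), ])

  # GC3s: exclude codons of singleton families and stops
  aa <- code$codon_to_aa[codons]
  eligible <- aa != "*" & !(aa %in% names(code$families)[lengths(code$families) == 1L])
  n_elig <- sum(counts[eligible])
  gc3s <- if (n_elig > 0L) {
    third <- substr(codons, 3L, 3L)
    sum(counts[eligible & third %in% c("G", "C")]) / n_elig
  } else NA_real_

  sense <- aa != "*"
  third <- substr(codons, 3L, 3L)
  third_count <- function(b) sum(counts[sense & third == b])
  list(
    base_freq = freq,
    gc_total = unname(gc_pos["overall"]),
    gc1 = unname(gc_pos["pos1"]), gc2 = unname(gc_pos["pos2"]),
    gc3 = unname(gc_pos["pos3"]),
    gc3s = gc3s,
    a3 = third_count("A"), t3 = third_count("T"),
    g3 = third_count("G"), c3 = third_count("C"),
    n_codons = total
  )
}

#' Relative synonymous codon usage
#'
#' RSCU of codon j in a synonymous family of size k is its observed count
#' divided by the count expected under equal usage within the family:
#' `RSCU_j = X_j / ((1/k) * sum_j X_j)`. A value of 1 means no preference.
#' Families with zero total are undefined (NA). Singleton families (Met, Trp)
#' are reported as 1 by convention when observed. Stop codons are excluded.
#'
#' @param table a `codon_counts` object.
#' @param code a [genetic_code()] object.
#' @return named numeric vector over the sense codons (class `rscu_table`).
#' @export
rscu <- function(table, code = genetic_code()) {
  counts <- as.integer(table)
  names(counts) <- all_codons()
  out <- rep(NA_real_, length(code$sense_codons))
  names(out) <- code$sense_codons
  for (fam in code$families) {
    tot <- sum(counts[fam])
    if (tot == 0L) next
    if (length(fam) == 1L) {
      out[fam] <- 1.0
    } else {
      out[fam] <- counts[fam] * length(fam) / tot
    }
  }
  structure(out, class = "rscu_table")
}

#' Effective number of codons (Wright's estimator)
#'
#' For each synonymous family with n >= 2 counted codons, the homozygosity
#' estimate is `F = (n * sum(p^2) - 1) / (n - 1)` with p the within-family
#' codon frequencies. Families are grouped by degeneracy k and averaged;
#' `ENc = N1 + N2/F2 + N3/F3 + N4/F4 + N6/F6` with Nk the number of families
#' of size k in the code (2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 for the plastid
#' code). Fallbacks follow common practice: a family with n < 2 is skipped;
#' a missing mean F3 is imputed as (F2 + F4)/2; any other missing or
#' non-positive mean makes ENc undefined (NA). The result is clamped to
#' [20, 61].
#'
#' @param table a `codon_counts` object.
#' @param code a [genetic_code()] object.
#' @return ENc value in [20, 61], or NA when undefined.
#' @export
enc <- function(table, code = genetic_code()) {
  counts <- as.integer(table)
  names(counts) <- all_codons()
  fam_sizes <- lengths(code$families)
  fhat <- lapply(code$families, function(fam) {
    n <- sum(counts[fam])
    if (n < 2L) return(NA_real_)
    p <- counts[fam] / n
    (n * sum(p^2) - 1) / (n - 1)
  })
  fhat <- unlist(fhat)
  ks <- sort(unique(fam_sizes[fam_sizes > 1L]))
  fbar <- vapply(ks, function(k) {
    v <- fhat[fam_sizes == k]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  names(fbar) <- as.character(ks)
  # impute a missing 3-fold mean from its neighbours (only Ile is 3-fold)
  if (("3" %in% names(fbar)) && is.na(fbar["3"]) &&
      !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  }
  if (any(is.na(fbar)) || any(fbar <= 0)) return(NA_real_)
  n1 <- sum(fam_sizes == 1L)
  nk <- vapply(ks, function(k) sum(fam_sizes == k), numeric(1))
  val <- n1 + sum(nk / fbar)
  min(max(val, 20), 61)
}

#' Expected ENc under mutation pressure alone
#'
#' Wright's null curve relating ENc to third-position synonymous GC content:
#' `ENc_exp(s) = 2 + s + 29 / (s^2 + (1 - s)^2)`. Genes whose codon usage is
#' shaped only by compositional (mutation) pressure fall on or near this
#' curve; selection on synonymous sites pulls genes below it.
#'
#' @param gc3s GC3s fraction(s) in [0, 1]; vectorised.
#' @return expected ENc value(s).
#' @examples
#' enc_expected(0.5)  # 60.5, the curve maximum
#' @export
enc_expected <- function(gc3s) {
  if (any(gc3s < 0 | gc3s > 1, na.rm = TRUE)) {
    stop("gc3s must be within [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Codon adaptation index (Sharp & Li construction)
#'
#' Relative adaptiveness of codon j is `w_j = RSCU_ref(j) / max(RSCU_ref)`
#' over its synonymous family; CAI is the count-weighted geometric mean of w
#' over all counted codons, excluding stop codons and singleton families
#' (Met, Trp). Reference codons with w = 0 are floored at `w_floor` before
#' taking logs so that a single absent codon cannot collapse CAI to 0.
#'
#' @param table a `codon_counts` object for the gene.
#' @param reference an `rscu_table` for the reference gene set (by default
#'   the pooled usage of the same taxon, supplied by the caller).
#' @param code a [genetic_code()] object.
#' @param w_floor lower bound applied to zero adaptiveness values.
#' @return CAI in (0, 1].
#' @export
cai <- function(table, reference, code = genetic_code(), w_floor = 0.01) {
  counts <- as.integer(table)
  names(counts) <- all_codons()
  fam_sizes <- lengths(code$families)
  multi <- names(fam_sizes)[fam_sizes > 1L]
  w_all <- rep(NA_real_, length(code$sense_codons))
  names(w_all) <- code$sense_codons
  for (a in multi) {
    fam <- code$families[[a]]
    ref <- unclass(reference)[fam]
    if (all(is.na(ref))) next
    mx <- max(ref, na.rm = TRUE)
    if (mx <= 0) next
    w <- ref / mx
    w[is.na(w)] <- 0
    w_all[fam] <- pmax(w, w_floor)
  }
  use <- code$sense_codons[code$sense_codons %in% unlist(code$families[multi])]
  use <- use[counts[use] > 0L]
  use <- use[!is.na(w_all[use])]
  if (length(use) == 0L) {
    stop("no overlap between gene codons and defined reference RSCU")
  }
  n <- counts[use]
  exp(sum(n * log(w_all[use])) / sum(n))
}

#' PR2 (parity rule 2) coordinates
#'
#' Third-codon-position base bias coordinates:
#' x = G3/(G3+C3), y = A3/(A3+T3). Under parity rule 2 (pure, strand-
#' symmetric mutation pressure) both equal 0.5. `family_scope = "fourfold"`
#' restricts the tallies to four-fold degenerate families, where the third
#' position is free of amino-acid constraint; the default `"all"` uses every
#' sense codon.
#'
#' @param table a `codon_counts` object.
#' @param code a [genetic_code()] object.
#' @param family_scope `"all"` (default) or `"fourfold"`.
#' @return named numeric `c(pr2_x=..., pr2_y=...)`; a coordinate is NA when
#'   its denominator is zero.
#' @export
pr2_coordinates <- function(table, code = genetic_code(),
                            family_scope = c("all", "fourfold")) {
  family_scope <- match.arg(family_scope)
  counts <- as.integer(table)
  names(counts) <- all_codons()
  scope <- if (family_scope == "all") {
    code$sense_codons
  } else {
    unlist(code$families[lengths(code$families) == 4L], use.names = FALSE)
  }
  third <- substr(scope, 3L, 3L)
  tot <- function(b) sum(counts[scope[third == b]])
  a3 <- tot("A"); t3 <- tot("T"); g3 <- tot("G"); c3 <- tot("C")
  x <- if (g3 + c3 > 0) g3 / (g3 + c3) else NA_real_
  y <- if (a3 + t3 > 0) a3 / (a3 + t3) else NA_real_
  c(pr2_x = x, pr2_y = y)
}

#' Per-gene codon usage statistics table
#'
#' Runs the full per-gene battery over a filtered CDS set: composition
#' (GC, GC1-3, GC3s), ENc and its expected value, CAI against a reference
#' (default: pooled usage of all genes of the same taxon), and PR2
#' coordinates.
#'
#' @param cds data.frame from [validate_and_filter()]`$cds`.
#' @param code a [genetic_code()] object.
#' @param cai_reference optional `rscu_table` used as the CAI reference for
#'   every gene; when NULL the pooled RSCU of each taxon is used.
#' @param pr2_scope passed to [pr2_coordinates()].
#' @return data.frame, one row per gene: gene_id, taxon, category,
#'   length_codons, gc_total, gc1, gc2, gc3, gc3s, gc12, enc, enc_expected,
#'   cai, pr2_x, pr2_y.
#' @export
gene_cub_table <- function(cds, code = genetic_code(), cai_reference = NULL,
                           pr2_scope = "all") {
  stopifnot(is.data.frame(cds), nrow(cds) > 0L)
  tabs <- lapply(seq_len(nrow(cds)), function(i) count_codons(cds[i, ]))
  refs <- if (is.null(cai_reference)) {
    by_tax <- split(seq_len(nrow(cds)), cds$taxon)
    lapply(by_tax, function(idx) rscu(pool_counts(tabs[idx]), code))
  } else NULL
  rows <- lapply(seq_len(nrow(cds)), function(i) {
    tb <- tabs[[i]]
    cp <- composition(tb, code)
    reference <- if (is.null(cai_reference)) refs[[cds$taxon[i]]] else cai_reference
    data.frame(
      gene_id = cds$gene_id[i],
      taxon = cds$taxon[i],
      category = if (!is.null(cds$category)) cds$category[i] else
        classify_gene(cds$gene_id[i]),
      length_codons = cp$n_codons,
      gc_total = cp$gc_total, gc1 = cp$gc1, gc2 = cp$gc2, gc3 = cp$gc3,
      gc3s = cp$gc3s,
      gc12 = (cp$gc1 + cp$gc2) / 2,
      enc = enc(tb, code),
      enc_expected = if (is.na(cp$gc3s)) NA_real_ else enc_expected(cp$gc3s),
      cai = cai(tb, reference, code),
      pr2_x = pr2_coordinates(tb, code, pr2_scope)[["pr2_x"]],
      pr2_y = pr2_coordinates(tb, code, pr2_scope)[["pr2_y"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
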