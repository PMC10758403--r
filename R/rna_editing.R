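#' Classify the effect of one C-to-U RNA edit
#'
#' Given a CDS-relative, 1-based edit position whose reference base must be
#' C, derives the affected codon, its position within the codon (1-3), the
#' reference and edited codons and amino acids, whether the edit is
#' synonymous, and the amino-acid class transition under `classes`.
#'
#' @param site list or one-row data.frame with `gene_id`, `cds_position`,
#'   and optionally `taxon` (ref base C and edited base T are implied and
#'   verified).
#' @param cds one-row data.frame with the matching `sequence` (and
#'   `gene_id`).
#' @param classes amino-acid class map from [aa_class_table()].
#' @param code a [genetic_code()] object.
#' @return one-row data.frame: taxon, gene_id, cds_position, codon_index,
#'   codon_position, ref_codon, edited_codon, ref_aa, edited_aa, synonymous,
#'   class_from, class_to, class_transition.
#' @export
classify_edit <- function(site, cds, classes = aa_class_table(),
                          code = genetic_code()) {
  pos <- as.integer(site$cds_position)
  seqs <- cds$sequence
  if (pos < 1L || pos > nchar(seqs)) {
    stop("edit position ", pos, " out of range for ", cds$gene_id,
         " (length ", nchar(seqs), ")")
  }
  found <- substr(seqs, pos, pos)
  if (found != "C") {
    stop("reference mismatch at ", cds$gene_id, ":", pos,
         " expected C, found ", found)
  }
  codon_index <- (pos - 1L) %/% 3L + 1L
  codon_position <- (pos - 1L) %% 3L + 1L
  ref_codon <- substr(seqs, 3L * codon_index - 2L, 3L * codon_index)
  edited_codon <- ref_codon
  substr(edited_codon, codon_position, codon_position) <- "T"
  ref_aa <- unname(code$codon_to_aa[ref_codon])
  edited_aa <- unname(code$codon_to_aa[edited_codon])
  cls <- function(a) if (a == "*") "stop" else unname(classes[a])
  data.frame(
    taxon = if (!is.null(site$taxon)) site$taxon else
      if (!is.null(cds$taxon)) cds$taxon else "",
    gene_id = cds$gene_id,
    cds_position = pos,
    codon_index = codon_index,
    codon_position = codon_position,
    ref_codon = ref_codon,
    edited_codon = edited_codon,
    ref_aa = ref_aa,
    edited_aa = edited_aa,
    synonymous = ref_aa == edited_aa,
    class_from = cls(ref_aa),
    class_to = cls(edited_aa),
    class_transition = paste(cls(ref_aa), cls(edited_aa), sep = "->"),
    stringsAsFactors = FALSE
  )
}

#' Classify a table of edit sites against a CDS set
#'
#' @param sites data.frame with `taxon`, `gene_id`, `cds_position` (columns
#'   `ref`/`alt`, if present, must be C and T/U).
#' @param cds_set data.frame of validated coding sequences.
#' @param classes,code see [classify_edit()].
#' @return data.frame of edit effects, one row per site.
#' @export
classify_edits <- function(sites, cds_set, classes = aa_class_table(),
                           code = genetic_code()) {
  # a TSV column holding only "T" comes back logical from read.delim
  if (is.logical(sites$alt)) sites$alt <- ifelse(sites$alt, "T", "F")
  if (is.logical(sites$ref)) sites$ref <- ifelse(sites$ref, "T", "F")
  if (!is.null(sites$ref) && any(toupper(sites$ref) != "C")) {
    stop("all edit sites must have reference base C")
  }
  if (!is.null(sites$alt) && any(!toupper(sites$alt) %in% c("T", "U"))) {
    stop("all edit sites must have edited base T/U")
  }
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    key <- cds_set$gene_id == sites$gene_id[i]
    if (!is.null(sites$taxon) && "taxon" %in% names(cds_set)) {
      key <- key & cds_set$taxon == sites$taxon[i]
    }
    idx <- which(key)
    if (length(idx) == 0L) {
      stop("edit site references unknown gene: ", sites$gene_id[i])
    }
    classify_edit(sites[i, ], cds_set[idx[1L], ], classes, code)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise edit effects
#'
#' Counts and percentages by codon position and by amino-acid class
#' transition; percentage denominators are the total number of effects.
#'
#' @param effects data.frame from [classify_edits()].
#' @return list with `n`, `by_position` (data.frame codon_position, n,
#'   percent) and `by_transition` (data.frame class_transition, n, percent).
#' @export
summarize_edits <- function(effects) {
  n <- nrow(effects)
  by_pos <- data.frame(codon_position = 1:3,
                       n = vapply(1:3, function(p)
                         sum(effects$codon_position == p), integer(1)))
  by_pos$percent <- if (n > 0) 100 * by_pos$n / n else 0
  if (n > 0) {
    tt <- table(effects$class_transition)
    by_tr <- data.frame(class_transition = names(tt), n = as.integer(tt),
                        stringsAsFactors = FALSE)
    by_tr$percent <- 100 * by_tr$n / n
    by_tr <- by_tr[order(-by_tr$n, by_tr$class_transition), ]
    rownames(by_tr) <- NULL
  } else {
    by_tr <- data.frame(class_transition = character(0), n = integer(0),
                        percent = numeric(0))
  }
  list(n = n, by_position = by_pos, by_transition = by_tr)
}

#' Association between RNA editing and codon RSCU
#'
#' Tests whether edited reference codons sit in codons of higher RSCU than
#' expected by chance. The observed statistic is the mean RSCU of the edited
#' reference codons; the null distribution is built by replacing each edit's
#' codon with a codon drawn uniformly from the counted sense codons of the
#' same gene (labels permuted within genes), repeated `n_perm` times under a
#' fixed seed. The one-sided p-value uses the add-one estimator. With fewer
#' than 2 edits the report is emitted with p flagged NA.
#'
#' @param effects data.frame from [classify_edits()].
#' @param rscu_table pooled `rscu_table` used to score codons.
#' @param cds_set CDS data.frame supplying each gene's codon pool.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed (required for reproducibility).
#' @param code a [genetic_code()] object.
#' @return list: n_edits, mean_rscu_edited, mean_rscu_background (mean RSCU
#'   over sense codons with nonzero counts), p_value (NA when n_edits < 2),
#'   n_perm, seed.
#' @export
rscu_editing_association <- function(effects, rscu_table, cds_set,
                                     n_perm = 10000L, seed,
                                     code = genetic_code()) {
  stopifnot(!missing(seed))
  r <- unclass(rscu_table)
  obs_vals <- r[effects$ref_codon]
  if (any(is.na(obs_vals))) {
    stop("RSCU undefined for edited codon(s): ",
         paste(unique(effects$ref_codon[is.na(obs_vals)]), collapse = ", "))
  }
  obs <- mean(obs_vals)
  # background: mean RSCU over sense codons actually used in the pool
  pool_counts_all <- Reduce(`+`, lapply(seq_len(nrow(cds_set)), function(i)
    as.integer(count_codons(cds_set[i, ]))))
  names(pool_counts_all) <- all_codons()
  used <- code$sense_codons[pool_counts_all[code$sense_codons] > 0L &
                              !is.na(r[code$sense_codons])]
  background <- mean(r[used])
  n_edits <- nrow(effects)
  if (n_edits < 2L) {
    return(list(n_edits = n_edits, mean_rscu_edited = obs,
                mean_rscu_background = background, p_value = NA_real_,
                n_perm = 0L, seed = seed,
                note = "fewer than 2 edits: p-value undefined"))
  }
  # per-gene codon pools (sense codons with their multiplicities)
  gene_pools <- lapply(unique(effects$gene_id), function(g) {
    idx <- which(cds_set$gene_id == g)[1L]
    cods <- codon_split(cds_set$sequence[idx])
    cods <- cods[!grepl("[^ACGT]", cods)]
    cods <- cods[code$codon_to_aa[cods] != "*"]
    cods[!is.na(r[cods])]
  })
  names(gene_pools) <- unique(effects$gene_id)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_means <- replicate(n_perm, {
    mean(vapply(effects$gene_id, function(g) {
      pool <- gene_pools[[g]]
      r[pool[sample.int(length(pool), 1L)]]
    }, numeric(1)))
  })
  p <- (1 + sum(null_means >= obs)) / (n_perm + 1)
  list(n_edits = n_edits, mean_rscu_edited = obs,
       mean_rscu_background = background, p_value = p,
       n_perm = n_perm, seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
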