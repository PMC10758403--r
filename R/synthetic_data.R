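# Seeded generators producing chloroplast-like fixture data with known
# ground truth for every pipeline stage. A single integer seed drives a
# fixed per-generator offset so adding a generator never perturbs the
# streams of existing ones.

seed_offset <- c(mutation = 101L, selection = 211L, edits = 307L,
                 counts = 401L)

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Generate CDS under a mutation-driven regime
#'
#' Every base of a gene is drawn i.i.d. with P(G) = P(C) = g/2 and
#' P(A) = P(T) = (1-g)/2, where the GC pressure g is drawn per gene from
#' `gc_range`. All three codon positions therefore share one compositional
#' pressure -- the regime in which genes fall on Wright's expected-ENc curve
#' and the neutrality slope tends to 1. In-frame stop codons are resampled
#' in place (whole-codon redraws), ATG is prepended and TAA appended.
#'
#' @param n_genes number of genes.
#' @param length_range nt range of the gene body; draws are rounded down to
#'   multiples of 3. Defaults to 150-4500 nt as in small plastid gene sets.
#' @param gc_range GC-pressure range (default 0.2-0.8).
#' @param seed integer seed; the same seed reproduces the set byte for byte.
#' @param taxon taxon label.
#' @return list with `cds` (data.frame gene_id, taxon, sequence, category)
#'   and `manifest` (data.frame gene_id, gc_pressure, length_nt).
#' @export
generate_mutation_driven <- function(n_genes = 80L,
                                     length_range = c(150L, 4500L),
                                     gc_range = c(0.2, 0.8),
                                     seed = 1L, taxon = "taxonA") {
  stopifnot(length_range[1] >= 9L, length_range[2] >= length_range[1],
            gc_range[1] >= 0, gc_range[2] <= 1, gc_range[2] >= gc_range[1])
  with_seed(seed + seed_offset[["mutation"]], {
    gs <- stats::runif(n_genes, gc_range[1], gc_range[2])
    lens <- length_range[1] +
      floor(stats::runif(n_genes) * (length_range[2] - length_range[1] + 1L))
    lens <- (as.integer(lens) %/% 3L) * 3L
    stops <- c("TAA", "TAG", "TGA")
    seqs <- vapply(seq_len(n_genes), function(i) {
      g <- gs[i]
      draw <- function(n) sample(c("A", "T", "G", "C"), n, replace = TRUE,
                                 prob = c((1 - g) / 2, (1 - g) / 2, g / 2, g / 2))
      body <- draw(lens[i])
      cods <- matrix(body, nrow = 3L)
      bad <- which(apply(cods, 2, paste, collapse = "") %in% stops)
      while (length(bad) > 0L) {
        for (j in bad) cods[, j] <- draw(3L)
        bad <- which(apply(cods, 2, paste, collapse = "") %in% stops)
      }
      paste0("ATG", paste(cods, collapse = ""), "TAA")
    }, character(1))
    ids <- sprintf("mut%03d", seq_len(n_genes))
    cds <- data.frame(gene_id = ids, taxon = taxon, sequence = seqs,
                      category = "other", stringsAsFactors = FALSE)
    manifest <- data.frame(gene_id = ids, gc_pressure = gs,
                           length_nt = nchar(seqs), regime = "mutation",
                           stringsAsFactors = FALSE)
    list(cds = cds, manifest = manifest)
  })
}

#' Default preferred-codon set for selection-driven simulation
#'
#' One codon per multi-codon family, ending in A where the family has an
#' A-ending member and in T otherwise -- mimicking the A/U-ending bias of
#' chloroplast optimal codons.
#'
#' @param code a [genetic_code()] object.
#' @return character vector of codons, one per multi-codon family.
#' @export
default_preferred_codons <- function(code = genetic_code()) {
  fams <- code$families[lengths(code$families) > 1L]
  vapply(fams, function(fam) {
    third <- substr(fam, 3L, 3L)
    if (any(third == "A")) fam[third == "A"][1L] else fam[third == "T"][1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Generate CDS under a selection-driven regime
#'
#' Amino acids are drawn from a fixed composition, decoupling first/second
#' codon positions from the third; within each synonymous family the codon
#' is chosen with probability proportional to `exp(beta * is_preferred)`,
#' with the selection strength beta drawn per gene from `beta_range`. Strong
#' beta concentrates usage on the preferred codons, pulling ENc below
#' Wright's curve while leaving GC12 flat -- the regime with neutrality
#' slope near 0. beta = 0 reduces to uniform synonymous usage.
#'
#' @param n_genes number of genes.
#' @param length_range nt range of the gene body (multiples of 3).
#' @param preferred preferred codon set, at most one per family (default
#'   [default_preferred_codons()]).
#' @param beta_range per-gene selection-strength range (default 0.5-3).
#' @param seed integer seed.
#' @param taxon taxon label.
#' @param code a [genetic_code()] object.
#' @return list with `cds` and `manifest` (gene_id, beta, length_nt) plus
#'   the preferred set as attribute `preferred` on the manifest.
#' @export
generate_selection_driven <- function(n_genes = 80L,
                                      length_range = c(150L, 4500L),
                                      preferred = default_preferred_codons(),
                                      beta_range = c(0.5, 3),
                                      seed = 1L, taxon = "taxonA",
                                      code = genetic_code()) {
  fam_of <- code$codon_to_aa[preferred]
  if (anyDuplicated(fam_of)) stop("preferred set has >1 codon in a family")
  with_seed(seed + seed_offset[["selection"]], {
    betas <- stats::runif(n_genes, beta_range[1], beta_range[2])
    lens <- length_range[1] +
      floor(stats::runif(n_genes) * (length_range[2] - length_range[1] + 1L))
    lens <- (as.integer(lens) %/% 3L) * 3L
    fams <- code$families[lengths(code$families) > 1L]
    aas <- names(fams)
    seqs <- vapply(seq_len(n_genes), function(i) {
      n_aa <- lens[i] %/% 3L
      aa_seq <- sample(aas, n_aa, replace = TRUE)
      cods <- vapply(aa_seq, function(a) {
        fam <- fams[[a]]
        w <- exp(betas[i] * (fam %in% preferred))
        fam[sample.int(length(fam), 1L, prob = w)]
      }, character(1))
      paste0("ATG", paste(cods, collapse = ""), "TAA")
    }, character(1))
    ids <- sprintf("sel%03d", seq_len(n_genes))
    cds <- data.frame(gene_id = ids, taxon = taxon, sequence = seqs,
                      category = "other", stringsAsFactors = FALSE)
    manifest <- data.frame(gene_id = ids, beta = betas,
                           length_nt = nchar(seqs), regime = "selection",
                           stringsAsFactors = FALSE)
    attr(manifest, "preferred") <- sort(preferred)
    list(cds = cds, manifest = manifest)
  })
}

#' Default C-to-U edit plan
#'
#' The stated fixture mix: 20 edits split 4/13/3 over codon positions 1/2/3
#' and 8/8/2/2 over class transitions (neutral to hydrophobic, hydrophobic
#' to hydrophobic, basic to neutral, basic to basic).
#'
#' @return data.frame with columns codon_position, class_from, class_to, n.
#' @export
default_edit_plan <- function() {
  data.frame(
    codon_position = c(1L, 1L, 2L, 2L, 3L, 3L),
    class_from = c("basic", "hydrophobic", "neutral", "hydrophobic",
                   "hydrophobic", "basic"),
    class_to = c("neutral", "hydrophobic", "hydrophobic", "hydrophobic",
                 "hydrophobic", "basic"),
    n = c(2L, 2L, 8L, 5L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Generate C-to-U edit sites realising a requested effect mix
#'
#' Scans every C in the in-frame codons of the CDS set, classifies the
#' effect each candidate edit would have (skipping edits that would create a
#' stop codon, edits in the start or stop codon, and second edits in an
#' already-used codon), then samples the requested number of sites from each
#' (codon position, class transition) stratum of the plan.
#'
#' @param cds_set data.frame of coding sequences.
#' @param plan data.frame as in [default_edit_plan()].
#' @param seed integer seed.
#' @param classes amino-acid class map.
#' @param code a [genetic_code()] object.
#' @return list with `sites` (data.frame taxon, gene_id, cds_position, ref,
#'   alt) and `manifest` (the expected effects as classified at generation
#'   time).
#' @export
generate_edit_sites <- function(cds_set, plan = default_edit_plan(),
                                seed = 1L, classes = aa_class_table(),
                                code = genetic_code()) {
  candidates <- list()
  for (i in seq_len(nrow(cds_set))) {
    s <- cds_set$sequence[i]
    n_cod <- nchar(s) %/% 3L
    pos_all <- which(strsplit(s, "")[[1]] == "C")
    for (p in pos_all) {
      ci <- (p - 1L) %/% 3L + 1L
      if (ci == 1L || ci == n_cod) next   # keep start/stop codons intact
      ref_codon <- substr(s, 3L * ci - 2L, 3L * ci)
      edited <- ref_codon
      cp <- (p - 1L) %% 3L + 1L
      substr(edited, cp, cp) <- "T"
      if (code$codon_to_aa[edited] == "*") next
      candidates[[length(candidates) + 1L]] <- data.frame(
        taxon = if ("taxon" %in% names(cds_set)) cds_set$taxon[i] else "",
        gene_id = cds_set$gene_id[i], cds_position = p,
        codon_key = paste0(cds_set$gene_id[i], ":", ci),
        codon_position = cp,
        class_from = unname(classes[code$codon_to_aa[ref_codon]]),
        class_to = unname(classes[code$codon_to_aa[edited]]),
        stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, candidates)
  if (nrow(plan) == 0L) {
    empty <- data.frame(taxon = character(0), gene_id = character(0),
                        cds_position = integer(0), ref = character(0),
                        alt = character(0), stringsAsFactors = FALSE)
    return(list(sites = empty, manifest = empty))
  }
  with_seed(seed + seed_offset[["edits"]], {
    chosen <- list()
    used_codons <- character(0)
    for (j in seq_len(nrow(plan))) {
      hit <- cand$codon_position == plan$codon_position[j] &
        cand$class_from == plan$class_from[j] &
        cand$class_to == plan$class_to[j] &
        !(cand$codon_key %in% used_codons)
      pool <- which(hit)
      if (length(pool) < plan$n[j]) {
        stop("infeasible edit plan: stratum pos=", plan$codon_position[j],
             " ", plan$class_from[j], "->", plan$class_to[j],
             " needs ", plan$n[j], ", found ", length(pool))
      }
      take <- pool[sample.int(length(pool), plan$n[j])]
      used_codons <- c(used_codons, cand$codon_key[take])
      chosen[[j]] <- cand[take, , drop = FALSE]
    }
    sel <- do.call(rbind, chosen)
    sites <- data.frame(taxon = sel$taxon, gene_id = sel$gene_id,
                        cds_position = sel$cds_position,
                        ref = "C", alt = "T", stringsAsFactors = FALSE)
    rownames(sites) <- NULL
    manifest <- classify_edits(sites, cds_set, classes, code)
    list(sites = sites, manifest = manifest)
  })
}

#' Generate replicate count matrices with planted fold changes
#'
#' Negative-binomial counts per gene and replicate with mean
#' `base_mean * fold * length_kb` so that FPKM differences track the planted
#' folds. `dispersion = 0` degenerates to the (rounded) mean. Three
#' replicates per taxon by default, as in designs with at least three
#' biological replicates.
#'
#' @param gene_lengths named numeric vector of transcript lengths (nt).
#' @param taxa character vector of taxon names.
#' @param fold_plan named list: taxon -> named numeric vector of per-gene
#'   fold changes (genes absent from the vector default to 1).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed integer seed.
#' @param base_mean baseline expected count for a 1 kb gene at fold 1.
#' @param n_reps replicates per taxon (default 3).
#' @return named list of [count_matrix()] objects, one per taxon, plus an
#'   attribute `fold_plan`.
#' @export
generate_counts <- function(gene_lengths, taxa, fold_plan = list(),
                            dispersion = 0.05, seed = 1L,
                            base_mean = 500, n_reps = 3L) {
  stopifnot(!is.null(names(gene_lengths)))
  genes <- names(gene_lengths)
  with_seed(seed + seed_offset[["counts"]], {
    out <- lapply(taxa, function(t) {
      folds <- rep(1, length(genes))
      names(folds) <- genes
      if (!is.null(fold_plan[[t]])) {
        fp <- fold_plan[[t]]
        folds[names(fp)] <- fp
      }
      mu <- base_mean * folds * gene_lengths / 1000
      m <- sapply(seq_len(n_reps), function(rep) {
        if (dispersion <= 0) round(mu) else
          stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      })
      rownames(m) <- genes
      colnames(m) <- paste0(t, "_rep", seq_len(n_reps))
      count_matrix(m, gene_lengths)
    })
    names(out) <- taxa
    attr(out, "fold_plan") <- fold_plan
    out
  })
}

#' Write a CDS set as FASTA
#' @param cds_set data.frame with gene_id, sequence.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds_set, path) {
  x <- Biostrings::DNAStringSet(cds_set$sequence)
  names(x) <- cds_set$gene_id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write a CDS set as a synthetic GenBank flat file
#'
#' Builds one LOCUS holding all genes separated by 10 nt spacers; every
#' second gene is written on the complement strand (and one multi-exon gene
#' as a join) so the twin exercises location parsing. Reading the file back
#' with [read_cds_genbank()] recovers the same CDS multiset as the FASTA
#' twin.
#'
#' @param cds_set data.frame with gene_id, taxon, sequence.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cds_genbank <- function(cds_set, path) {
  spacer <- "AACCGGTTAA"
  genome <- character(0)
  feats <- character(0)
  offset <- 0L
  for (i in seq_len(nrow(cds_set))) {
    s <- cds_set$sequence[i]
    n <- nchar(s)
    strand_minus <- i %% 2L == 0L
    stored <- if (strand_minus) revcomp(s) else s
    from <- offset + 1L
    to <- offset + n
    loc <- if (i == 1L && n >= 6L) {
      # first gene as a two-segment join to exercise join() parsing
      cut <- 3L * (n %/% 6L)
      sprintf("join(%d..%d,%d..%d)", from, from + cut - 1L,
              from + cut, to)
    } else if (strand_minus) {
      sprintf("complement(%d..%d)", from, to)
    } else {
      sprintf("%d..%d", from, to)
    }
    feats <- c(feats,
               sprintf("     CDS             %s", loc),
               sprintf("                     /gene=\"%s\"", cds_set$gene_id[i]))
    genome <- c(genome, stored, spacer)
    offset <- to + nchar(spacer)
  }
  genome <- paste(genome, collapse = "")
  taxon <- if ("taxon" %in% names(cds_set)) cds_set$taxon[1] else "synthetic"
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   SYN", "SYNFIX01",
            nchar(genome)),
    "DEFINITION  synthetic fixture chloroplast-like CDS bundle.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(genome)),
    sprintf("                     /organism=\"%s\"", taxon),
    feats,
    "ORIGIN"
  )
  # 60 bases per line, GenBank numbering
  starts <- seq(1L, nchar(genome), by = 60L)
  seq_lines <- vapply(starts, function(st) {
    chunk <- substr(genome, st, min(st + 59L, nchar(genome)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", st, tolower(paste(groups, collapse = " ")))
  }, character(1))
  writeLines(c(lines, seq_lines, "//"), path)
  invisible(path)
}

#' Write a generator manifest as flat key-value text
#' @param manifest data.frame or named list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  if (is.data.frame(manifest)) {
    utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(paste0(names(manifest), "=",
                      vapply(manifest, function(v)
                        paste(v, collapse = ","), character(1))), path)
  }
  invisible(path)
}
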