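# Pipeline runner and flat-file configuration. The config format is one
# key=value per line; '#' starts a comment. Recognised keys:
#   taxon.<name>.fasta=path      input CDS FASTA per taxon (or .genbank=path)
#   outdir=path                  output directory (required)
#   genetic_code=11  min_length=300  start_codons=ATG,GTG  dedupe=true
#   fraction=0.05  delta=0.08  metric=cai  anchor=high
#   over_threshold=1.6  bias_threshold=1.0  pr2_scope=all
#   counts.<taxon>=path  lengths=path        optional FPKM inputs
#   edits=path                               optional edit-site TSV
#   habitat.<group>=taxonA,taxonB            optional habitat grouping
#   genes_of_interest=g1,g2                  optional expression focus set
#   seed=1  n_perm=10000                     editing association test

#' Parse and validate a pipeline configuration file
#'
#' Reads a flat key=value config, applies defaults, and validates every
#' field, returning all violations rather than stopping at the first.
#'
#' @param path config file path, or a named list of already-parsed values.
#' @return list with `config` (named list) and `violations` (character
#'   vector, empty when the config is valid).
#' @export
validate_config <- function(path) {
  kv <- if (is.list(path)) {
    path
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
    out <- lapply(parts, function(p) trimws(p[2]))
    names(out) <- vapply(parts, function(p) trimws(p[1]), character(1))
    out
  }
  defaults <- list(genetic_code = "11", min_length = "300",
                   start_codons = "ATG,GTG", dedupe = "true",
                   fraction = "0.05", delta = "0.08", metric = "cai",
                   anchor = "high", over_threshold = "1.6",
                   bias_threshold = "1.0", pr2_scope = "all",
                   seed = "1", n_perm = "10000")
  for (k in names(defaults)) if (is.null(kv[[k]])) kv[[k]] <- defaults[[k]]
  v <- character(0)
  num <- function(k) suppressWarnings(as.numeric(kv[[k]]))
  tax_keys <- grep("^taxon\\.", names(kv), value = TRUE)
  if (length(tax_keys) == 0L) v <- c(v, "no taxon.<name>.fasta/.genbank inputs")
  for (k in tax_keys) {
    if (!file.exists(kv[[k]])) v <- c(v, paste0(k, ": file not found: ", kv[[k]]))
  }
  if (is.null(kv$outdir)) v <- c(v, "outdir is required")
  if (is.na(num("fraction")) || num("fraction") <= 0 || num("fraction") >= 0.5)
    v <- c(v, "fraction must be in (0,0.5)")
  if (is.na(num("delta")) || num("delta") < 0)
    v <- c(v, "delta must be >= 0")
  if (is.na(num("min_length")) || num("min_length") < 3)
    v <- c(v, "min_length must be >= 3")
  if (!kv$metric %in% c("cai", "enc", "both"))
    v <- c(v, "metric must be one of cai, enc, both")
  if (!kv$anchor %in% c("high", "all"))
    v <- c(v, "anchor must be high or all")
  if (!kv$pr2_scope %in% c("all", "fourfold"))
    v <- c(v, "pr2_scope must be all or fourfold")
  if (is.na(num("over_threshold")) || num("over_threshold") <= 0)
    v <- c(v, "over_threshold must be > 0")
  if (is.na(suppressWarnings(as.integer(kv$seed))))
    v <- c(v, "seed must be an integer")
  for (k in grep("^counts\\.", names(kv), value = TRUE)) {
    if (!file.exists(kv[[k]])) v <- c(v, paste0(k, ": file not found: ", kv[[k]]))
  }
  if (!is.null(kv$edits) && !file.exists(kv$edits))
    v <- c(v, paste0("edits: file not found: ", kv$edits))
  if (!is.null(kv$lengths) && !file.exists(kv$lengths))
    v <- c(v, paste0("lengths: file not found: ", kv$lengths))
  list(config = kv, violations = v)
}

read_config_inputs <- function(cfg) {
  tax_keys <- grep("^taxon\\.", names(cfg), value = TRUE)
  raw <- lapply(tax_keys, function(k) {
    name <- sub("^taxon\\.([^.]+)\\..*$", "\\1", k)
    kind <- sub("^taxon\\.[^.]+\\.", "", k)
    if (kind == "fasta") read_cds_fasta(cfg[[k]], name)
    else if (kind == "genbank") read_cds_genbank(cfg[[k]], taxon = name)
    else stop("unknown taxon input kind: ", kind)
  })
  do.call(rbind, raw)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full codon-usage-bias pipeline
#'
#' Executes filtering, per-gene statistics, RSCU matrices, the three
#' mutation-vs-selection diagnostics, optimal-codon calling, and -- when the
#' config supplies count tables or edit-site lists -- FPKM quantification
#' and RNA-editing effect classification. All outputs are TSV files under
#' `outdir`, plus an append-only `log.txt` with one line per stage.
#' Identical config and inputs give byte-identical outputs.
#'
#' @param config path to a config file, or the `config` element of
#'   [validate_config()].
#' @return named list of output paths and key in-memory results, invisibly.
#' @export
run_pipeline <- function(config) {
  vc <- validate_config(config)
  if (length(vc$violations) > 0L) {
    stop("invalid config:\n  ", paste(vc$violations, collapse = "\n  "))
  }
  cfg <- vc$config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$outdir, "log.txt")
  log_line <- function(...) cat(paste0(..., "\n"), file = logf, append = TRUE)
  cat(sprintf("# cpcub run | code=%s seed=%s\n", cfg$genetic_code, cfg$seed),
      file = logf)
  code <- genetic_code(as.integer(cfg$genetic_code),
                       strsplit(cfg$start_codons, ",")[[1]])
  outputs <- list()

  raw <- read_config_inputs(cfg)
  log_line("sequence_io: read ", nrow(raw), " raw records")
  filt <- validate_and_filter(raw, code,
                              min_length = as.integer(cfg$min_length),
                              start_codons = strsplit(cfg$start_codons, ",")[[1]],
                              dedupe = tolower(cfg$dedupe) %in% c("true", "1", "yes"))
  outputs$rejections <- write_tsv(filt$rejected,
                                  file.path(cfg$outdir, "rejections.tsv"))
  log_line("filter: kept ", nrow(filt$cds), ", rejected ", nrow(filt$rejected))
  if (nrow(filt$cds) == 0L) stop("filter: no sequences passed filtering")

  genes <- gene_cub_table(filt$cds, code, pr2_scope = cfg$pr2_scope)
  outputs$genes <- write_tsv(genes, file.path(cfg$outdir, "genes.tsv"))
  log_line("codon_stats: ", nrow(genes), " gene records")

  taxa <- unique(filt$cds$taxon)
  tabs_by_taxon <- lapply(taxa, function(t) {
    idx <- which(filt$cds$taxon == t)
    pool_counts(lapply(idx, function(i) count_codons(filt$cds[i, ])), t)
  })
  names(tabs_by_taxon) <- taxa
  rscu_by_taxon <- lapply(tabs_by_taxon, rscu, code = code)
  rmat <- do.call(cbind, lapply(rscu_by_taxon, unclass))
  rmat <- data.frame(codon = rownames(rmat),
                     amino_acid = unname(code$codon_to_aa[rownames(rmat)]),
                     rmat, check.names = FALSE)
  outputs$rscu_matrix <- write_tsv(rmat, file.path(cfg$outdir, "rscu_matrix.tsv"))

  ept <- enc_plot_table(genes)
  outputs$encplot <- write_tsv(ept, file.path(cfg$outdir, "encplot.tsv"))
  outputs$pr2 <- write_tsv(
    genes[, c("gene_id", "taxon", "category", "pr2_x", "pr2_y")],
    file.path(cfg$outdir, "pr2.tsv"))
  neut <- neutrality_by_pool(genes)
  outputs$neutrality <- write_tsv(neut, file.path(cfg$outdir, "neutrality.tsv"))
  log_line("selection_analysis: ", nrow(neut), " neutrality pools")

  calls <- lapply(taxa, function(t) {
    g <- genes[genes$taxon == t, , drop = FALSE]
    sel <- select_extreme_genes(g, cfg$metric, as.numeric(cfg$fraction))
    ctab <- function(ids) {
      idx <- which(filt$cds$taxon == t & filt$cds$gene_id %in% ids)
      pool_counts(lapply(idx, function(i) count_codons(filt$cds[i, ])))
    }
    call_optimal(ctab(sel$high$gene_id), ctab(sel$low$gene_id),
                 tabs_by_taxon[[t]], as.numeric(cfg$delta), code,
                 cfg$anchor, taxon = t)
  })
  names(calls) <- taxa
  opt <- do.call(rbind, calls)
  outputs$optimal <- write_tsv(opt, file.path(cfg$outdir, "optimal.tsv"))
  log_line("optimal_codons: ",
           sum(opt$is_optimal), " optimal calls over ", length(taxa), " taxa")
  habitat_keys <- grep("^habitat\\.", names(cfg), value = TRUE)
  habitat_groups <- NULL
  if (length(habitat_keys)) {
    habitat_groups <- lapply(cfg[habitat_keys], function(x)
      strsplit(x, ",")[[1]])
    names(habitat_groups) <- sub("^habitat\\.", "", habitat_keys)
  }
  if (length(taxa) >= 2L) {
    sh <- shared_optimal(calls, habitat_groups)
    outputs$shared_optimal <- write_manifest(
      list(shared = sh$shared,
           n_shared = length(sh$shared)),
      file.path(cfg$outdir, "shared_optimal.txt"))
  }

  count_keys <- grep("^counts\\.", names(cfg), value = TRUE)
  if (length(count_keys) && !is.null(cfg$lengths)) {
    lens_df <- utils::read.delim(cfg$lengths)
    lens <- stats::setNames(lens_df[[2]], lens_df[[1]])
    fmats <- lapply(count_keys, function(k) {
      m <- as.matrix(utils::read.delim(cfg[[k]], row.names = 1L))
      fpkm(count_matrix(m, lens))
    })
    names(fmats) <- sub("^counts\\.", "", count_keys)
    for (t in names(fmats)) {
      outputs[[paste0("fpkm_", t)]] <- write_tsv(
        data.frame(gene = rownames(fmats[[t]]), fmats[[t]], check.names = FALSE),
        file.path(cfg$outdir, paste0("fpkm_", t, ".tsv")))
    }
    goi <- if (!is.null(cfg$genes_of_interest))
      strsplit(cfg$genes_of_interest, ",")[[1]] else rownames(fmats[[1]])
    cmp <- cross_taxa_expression(fmats, goi, habitat_groups = habitat_groups)
    outputs$expression <- write_tsv(cmp,
                                    file.path(cfg$outdir, "expression_comparison.tsv"))
    log_line("expression_fpkm: ", length(fmats), " taxa, ",
             length(goi), " genes compared")
  }

  if (!is.null(cfg$edits)) {
    sites <- utils::read.delim(cfg$edits)
    effects <- classify_edits(sites, filt$cds, code = code)
    outputs$editing_effects <- write_tsv(effects,
                                         file.path(cfg$outdir, "editing_effects.tsv"))
    sm <- summarize_edits(effects)
    outputs$editing_summary <- write_tsv(
      rbind(data.frame(key = paste0("position_", sm$by_position$codon_position),
                       n = sm$by_position$n, percent = sm$by_position$percent),
            data.frame(key = sm$by_transition$class_transition,
                       n = sm$by_transition$n,
                       percent = sm$by_transition$percent)),
      file.path(cfg$outdir, "editing_summary.tsv"))
    pooled_rscu <- rscu(pool_counts(tabs_by_taxon), code)
    assoc <- rscu_editing_association(effects, pooled_rscu, filt$cds,
                                      n_perm = as.integer(cfg$n_perm),
                                      seed = as.integer(cfg$seed), code = code)
    outputs$editing_association <- write_manifest(
      assoc[c("n_edits", "mean_rscu_edited", "mean_rscu_background",
              "p_value", "n_perm", "seed")],
      file.path(cfg$outdir, "editing_association.txt"))
    log_line("rna_editing: ", nrow(effects), " effects classified")
  }

  log_line("done")
  invisible(c(outputs, list(gene_table = genes, optimal_calls = calls,
                            neutrality = neut, log = logf)))
}
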