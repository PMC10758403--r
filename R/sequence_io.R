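#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record nucleotide FASTA. Gene identifiers are taken from the
#' first whitespace-delimited token of each header; sequences are upper-cased
#' and U is normalised to T. No validation beyond the character set is done
#' here -- see [validate_and_filter()].
#'
#' @param path path to a FASTA file.
#' @param taxon taxon label attached to every record.
#' @return data.frame with columns `gene_id`, `taxon`, `sequence`.
#' @export
read_cds_fasta <- function(path, taxon) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(recs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  data.frame(gene_id = ids, taxon = taxon, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Read coding sequences from a GenBank flat file
#'
#' Extracts every CDS feature of each LOCUS in a GenBank flat file, honouring
#' `join(...)` and `complement(...)` location operators (multi-segment CDS are
#' concatenated in feature order). Gene identifiers come from the `/gene`
#' qualifier, falling back to `/locus_tag`, then to `CDS_<n>`. The taxon label
#' is taken from the `/organism` qualifier when present, else the LOCUS name.
#'
#' GenBank locations are 1-based inclusive; coordinates are converted
#' internally and never exposed.
#'
#' @param path path to a GenBank flat file.
#' @param taxon optional taxon label overriding the file's organism.
#' @return data.frame with columns `gene_id`, `taxon`, `sequence`.
#' @export
read_cds_genbank <- function(path, taxon = NULL) {
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("GenBank file is empty: ", path)
  # split into LOCUS records
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) stop("no LOCUS record in: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    out[[r]] <- parse_genbank_record(rec, taxon)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Parse one LOCUS..// block into a CDS data.frame.
parse_genbank_record <- function(rec, taxon = NULL) {
  locus <- sub("^LOCUS\\s+(\\S+).*", "\\1", rec[1])
  ori <- grep("^ORIGIN", rec)
  if (length(ori) != 1L) stop("GenBank record ", locus, " has no ORIGIN block")
  seq_lines <- rec[(ori + 1L):length(rec)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  genome <- gsub("U", "T", genome, fixed = TRUE)

  feat <- grep("^FEATURES", rec)
  body <- if (length(feat)) rec[(feat + 1L):(ori - 1L)] else character(0)
  # feature table: new feature starts at column 6; qualifiers/continuations at 22
  key_idx <- grep("^ {5}\\S", body)
  org <- regmatches(body, regexpr('/organism="[^"]*"', body))
  organism <- if (length(org)) sub('/organism="([^"]*)"', "\\1", org[1]) else locus
  if (is.null(taxon)) taxon <- organism

  cds <- list()
  n_cds <- 0L
  for (i in seq_along(key_idx)) {
    first <- key_idx[i]
    last <- if (i < length(key_idx)) key_idx[i + 1L] - 1L else length(body)
    block <- body[first:last]
    key <- sub("^ {5}(\\S+).*", "\\1", block[1])
    if (key != "CDS") next
    n_cds <- n_cds + 1L
    # location may continue over lines until the first qualifier line
    qual_start <- grep("^\\s+/", block)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
    loc <- paste(gsub("\\s", "", sub("^ {5}CDS\\s+", "", block[1:loc_end])),
                 collapse = "")
    loc <- sub("^CDS", "", loc)
    seqs <- extract_location(loc, genome, locus)
    quals <- paste(block, collapse = " ")
    gene <- regmatches(quals, regexpr('/gene="[^"]*"', quals))
    lt <- regmatches(quals, regexpr('/locus_tag="[^"]*"', quals))
    gid <- if (length(gene)) sub('/gene="([^"]*)"', "\\1", gene) else
      if (length(lt)) sub('/locus_tag="([^"]*)"', "\\1", lt) else
        paste0("CDS_", n_cds)
    cds[[length(cds) + 1L]] <- data.frame(
      gene_id = gid, taxon = taxon, sequence = seqs, stringsAsFactors = FALSE)
  }
  if (length(cds) == 0L) {
    return(data.frame(gene_id = character(0), taxon = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, cds)
}

# Recursively evaluate a GenBank location string against the genome sequence.
extract_location <- function(loc, genome, locus) {
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
    return(revcomp(extract_location(inner, genome, locus)))
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- split_toplevel(inner)
    return(paste(vapply(parts, extract_location, character(1),
                        genome = genome, locus = locus), collapse = ""))
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) == 3L) {
    from <- as.integer(m[2]); to <- as.integer(m[3])
  } else if (grepl("^\\d+$", loc)) {
    from <- to <- as.integer(loc)
  } else {
    stop("unresolvable CDS location in ", locus, ": ", loc)
  }
  if (from < 1L || to > nchar(genome) || from > to) {
    stop("CDS location out of range in ", locus, ": ", loc)
  }
  substr(genome, from, to)
}

# split "a..b,complement(c..d),..." at top-level commas only
split_toplevel <- function(x) {
  chars <- strsplit(x, "")[[1]]
  depth <- 0L; cur <- character(0); out <- character(0)
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      out <- c(out, paste(cur, collapse = "")); cur <- character(0)
    } else cur <- c(cur, ch)
  }
  c(out, paste(cur, collapse = ""))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Validate and filter raw coding sequences
#'
#' Applies the CDS validity rules: length divisible by 3 and at least
#' `min_length` nt, first codon in the start-codon set, and no internal stop
#' codon under `code`. Duplicated records (identical `gene_id` and sequence,
#' e.g. genes annotated in both inverted-repeat copies) are kept once when
#' `dedupe` is on. Rejections are returned as data, not raised as errors.
#'
#' @param raw data.frame with `gene_id`, `taxon`, `sequence` (as produced by
#'   [read_cds_fasta()] / [read_cds_genbank()]).
#' @param code a [genetic_code()] object.
#' @param min_length minimum CDS length in nucleotides (default 300).
#' @param start_codons accepted first codons; defaults to the code's set.
#' @param dedupe drop exact gene_id+sequence duplicates (default TRUE).
#' @param rules category rules from [default_category_rules()]; each kept
#'   gene is classified.
#' @return list with `cds` (data.frame: gene_id, taxon, sequence, category)
#'   and `rejected` (data.frame: gene_id, taxon, rule_failed).
#' @export
validate_and_filter <- function(raw, code = genetic_code(),
                                min_length = 300L,
                                start_codons = code$start_codons,
                                dedupe = TRUE,
                                rules = default_category_rules()) {
  stopifnot(is.data.frame(raw), all(c("gene_id", "taxon", "sequence") %in% names(raw)))
  keep <- logical(nrow(raw))
  why <- character(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    s <- raw$sequence[i]
    n <- nchar(s)
    if (n %% 3L != 0L) { why[i] <- "length_not_multiple_of_3"; next }
    if (n < min_length) { why[i] <- "below_min_length"; next }
    first <- substr(s, 1L, 3L)
    if (!(first %in% start_codons)) { why[i] <- "invalid_start_codon"; next }
    cods <- codon_split(s)
    internal <- cods[-length(cods)]
    internal <- internal[!grepl("[^ACGT]", internal)]
    if (any(code$codon_to_aa[internal] == "*")) {
      why[i] <- "internal_stop_codon"; next
    }
    keep[i] <- TRUE
  }
  cds <- raw[keep, , drop = FALSE]
  rejected <- data.frame(gene_id = raw$gene_id[!keep],
                         taxon = raw$taxon[!keep],
                         rule_failed = why[!keep],
                         stringsAsFactors = FALSE)
  if (dedupe && nrow(cds) > 0L) {
    dup <- duplicated(cds[, c("gene_id", "taxon", "sequence")])
    cds <- cds[!dup, , drop = FALSE]
  }
  cds$category <- vapply(cds$gene_id, classify_gene, character(1), rules = rules)
  rownames(cds) <- NULL
  rownames(rejected) <- NULL
  list(cds = cds, rejected = rejected)
}

codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Default gene-category rules
#'
#' Ordered first-match-wins regex rules assigning chloroplast genes to
#' functional categories: photosynthesis (psa/psb/pet/ndh/rbcL/atp),
#' transcription and translation (rpo/rps/rpl/infA), and other.
#'
#' @return data.frame with columns `pattern` and `category`, plus an
#'   attribute `default` giving the fall-through category.
#' @export
default_category_rules <- function() {
  rules <- data.frame(
    pattern = c("^psa", "^psb", "^pet", "^ndh", "^rbcL", "^atp",
                "^rpo", "^rps", "^rpl", "^infA"),
    category = c(rep("photosynthesis", 6L), rep("transcription_translation", 4L)),
    stringsAsFactors = FALSE
  )
  attr(rules, "default") <- "other"
  rules
}

#' Classify a gene name into a functional category
#'
#' @param gene_id gene name (e.g. `"psbA"`).
#' @param rules rule table from [default_category_rules()] or a user table of
#'   the same shape.
#' @return the category of the first matching rule, or the default category.
#' @examples
#' classify_gene("psbA")  # photosynthesis
#' classify_gene("rps3")  # transcription_translation
#' classify_gene("matK")  # other
#' @export
classify_gene <- function(gene_id, rules = default_category_rules()) {
  for (i in seq_len(nrow(rules))) {
    if (grepl(rules$pattern[i], gene_id)) return(rules$category[i])
  }
  attr(rules, "default")
}
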