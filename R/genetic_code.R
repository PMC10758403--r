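#' Build a genetic code object
#'
#' Wraps an NCBI translation table as a list with the full codon-to-amino-acid
#' map, the synonymous-family structure and a configurable start-codon set.
#' The default is translation table 11 (bacterial/archaeal/plant plastid),
#' the table used for chloroplast protein-coding genes.
#'
#' @param table_id NCBI genetic code table number (default 11).
#' @param start_codons character vector of accepted initiation codons.
#'   Defaults to ATG and GTG, the two common plastid starts.
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character vector over the 64 codons,
#'   `"*"` for stop), `start_codons`, `sense_codons`, `stop_codons`, and
#'   `families` (list of sense-codon vectors, one per amino acid).
#' @examples
#' code <- genetic_code()
#' code$codon_to_aa[["ATG"]]   # "M"
#' lengths(code$families)[["L"]]  # 6: leucine is six-fold degenerate
#' @export
genetic_code <- function(table_id = 11L, start_codons = c("ATG", "GTG")) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  # Biostrings returns codons in DNA alphabet, names like "TTT"
  stopifnot(length(map) == 64L)
  codons <- names(map)
  sense <- codons[map != "*"]
  stops <- codons[map == "*"]
  fams <- split(sense, map[sense])
  start_codons <- toupper(start_codons)
  if (!all(start_codons %in% codons)) {
    stop("start_codons must be valid codons")
  }
  structure(
    list(
      table_id = as.integer(table_id),
      codon_to_aa = map,
      start_codons = start_codons,
      sense_codons = sense,
      stop_codons = stops,
      families = fams
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table", x$table_id, "-", length(x$sense_codons),
      "sense codons,", length(x$stop_codons), "stop codons\n")
  cat("Family sizes:", paste(sort(table(lengths(x$families))), collapse = " "),
      "\nStart codons:", paste(x$start_codons, collapse = ", "), "\n")
  invisible(x)
}

#' Family size of each sense codon
#' @param code a `genetic_code` object
#' @return named integer vector over sense codons giving the degeneracy of
#'   the synonymous family the codon belongs to.
#' @keywords internal
family_sizes <- function(code) {
  fs <- lengths(code$families)
  out <- fs[code$codon_to_aa[code$sense_codons]]
  names(out) <- code$sense_codons
  out
}

#' Default amino-acid physico-chemical class table
#'
#' Four-way partition of the 20 amino acids used to label the effect of
#' C-to-U RNA edits. Membership is a package default (configurable in every
#' function that consumes it): hydrophobic A,V,L,I,P,F,M,W,G; neutral
#' S,T,C,Y,N,Q; basic K,R,H; acidic D,E.
#'
#' @return named character vector mapping one-letter amino-acid codes to one
#'   of `"hydrophobic"`, `"neutral"`, `"basic"`, `"acidic"`.
#' @export
aa_class_table <- function() {
  c(
    A = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
    P = "hydrophobic", F = "hydrophobic", M = "hydrophobic", W = "hydrophobic",
    G = "hydrophobic",
    S = "neutral", T = "neutral", C = "neutral", Y = "neutral",
    N = "neutral", Q = "neutral",
    K = "basic", R = "basic", H = "basic",
    D = "acidic", E = "acidic"
  )
}

# all 64 codons in the fixed order used by NCBI tables (TTT, TTC, ... GGG)
all_codons <- function() {
  names(Biostrings::getGeneticCode("1"))
}
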