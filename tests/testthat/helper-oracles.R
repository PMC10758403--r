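# Independent brute-force oracles. These re-derive each statistic from the
# defining formula with plain loops, sharing no code path with the package.

oracle_map <- Biostrings::getGeneticCode("11")
all_codons_vec <- names(oracle_map)

oracle_families <- local({
  sense <- names(oracle_map)[oracle_map != "*"]
  split(sense, oracle_map[sense])
})

# RSCU_j = X_j * k / sum(X_family)
oracle_rscu <- function(counts) {
  out <- c()
  for (aa in names(oracle_families)) {
    fam <- oracle_families[[aa]]
    tot <- 0
    for (cd in fam) tot <- tot + counts[[cd]]
    for (cd in fam) {
      out[cd] <- if (tot == 0) NA_real_ else
        if (length(fam) == 1) 1.0 else counts[[cd]] * length(fam) / tot
    }
  }
  out
}

# Wright's ENc with the plastid-code family counts written out explicitly:
# 2 singletons + 9 two-fold + 1 three-fold + 5 four-fold + 3 six-fold.
oracle_enc <- function(counts) {
  fvals <- list("2" = c(), "3" = c(), "4" = c(), "6" = c())
  for (aa in names(oracle_families)) {
    fam <- oracle_families[[aa]]
    k <- length(fam)
    if (k == 1) next
    n <- 0
    for (cd in fam) n <- n + counts[[cd]]
    if (n < 2) next
    sp2 <- 0
    for (cd in fam) sp2 <- sp2 + (counts[[cd]] / n)^2
    fvals[[as.character(k)]] <- c(fvals[[as.character(k)]],
                                  (n * sp2 - 1) / (n - 1))
  }
  fbar <- sapply(fvals, function(v) if (length(v) == 0) NA_real_ else mean(v))
  if (is.na(fbar[["3"]]) && !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  }
  if (any(is.na(fbar)) || any(fbar <= 0)) return(NA_real_)
  val <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] + 3 / fbar[["6"]]
  min(max(val, 20), 61)
}

# CAI in the log domain, with the same 0.01 floor convention.
oracle_cai <- function(counts, ref_rscu, w_floor = 0.01) {
  log_sum <- 0
  n_tot <- 0
  for (aa in names(oracle_families)) {
    fam <- oracle_families[[aa]]
    if (length(fam) == 1) next
    ref <- ref_rscu[fam]
    if (all(is.na(ref))) next
    mx <- max(ref, na.rm = TRUE)
    for (cd in fam) {
      n <- counts[[cd]]
      if (n == 0) next
      w <- ref[[cd]] / mx
      if (is.na(w)) w <- 0
      w <- max(w, w_floor)
      log_sum <- log_sum + n * log(w)
      n_tot <- n_tot + n
    }
  }
  exp(log_sum / n_tot)
}

oracle_fpkm <- function(counts, lengths, lib_sizes) {
  out <- counts * 0
  for (g in seq_len(nrow(counts))) {
    for (s in seq_len(ncol(counts))) {
      out[g, s] <- counts[g, s] * 1e9 / (lib_sizes[s] * lengths[g])
    }
  }
  out
}

# random codon-count table over the 61 sense codons (stops zero)
random_count_table <- function(lambda = 30) {
  counts <- integer(64)
  names(counts) <- names(oracle_map)
  sense <- names(oracle_map)[oracle_map != "*"]
  counts[sense] <- rpois(length(sense), lambda)
  structure(counts, class = "codon_counts", source = "random", taxon = "")
}

# build a codon_counts object from an explicit named count vector
make_counts <- function(...) {
  v <- c(...)
  counts <- integer(64)
  names(counts) <- names(oracle_map)
  counts[names(v)] <- as.integer(v)
  stop_cod <- names(oracle_map)[oracle_map == "*"]
  stop_counts <- counts[stop_cod]
  counts[stop_cod] <- 0L
  structure(counts, class = "codon_counts", source = "manual", taxon = "",
            stop_counts = stop_counts)
}
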