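code <- genetic_code()

test_that("count_codons tallies sense codons, stops and ambiguity separately", {
  tb <- count_codons("ATGAAATAA", "g")
  expect_equal(unname(tb[["ATG"]]), 1L)
  expect_equal(unname(tb[["AAA"]]), 1L)
  expect_equal(sum(tb), 2L)                        # stop excluded from table
  expect_equal(unname(attr(tb, "stop_counts")[["TAA"]]), 1L)
  # codon containing N is skipped, total decremented
  tb2 <- count_codons("ATGANAAAATAA", "g")
  expect_equal(sum(tb2), 2L)
  expect_equal(attr(tb2, "n_ambiguous"), 1L)
})

test_that("pooled totals equal the sum over the generator manifest", {
  gen <- generate_mutation_driven(15, c(150, 600), seed = 21, taxon = "t")
  tabs <- lapply(seq_len(nrow(gen$cds)), function(i) count_codons(gen$cds[i, ]))
  pooled <- pool_counts(tabs, "t")
  expect_equal(sum(pooled), sum(gen$manifest$length_nt / 3 - 1))
})

test_that("composition matches hand arithmetic on tiny tables", {
  cp <- composition(make_counts(ATG = 1, GCC = 1), code)
  expect_equal(cp$gc1, 0.5)   # A,G at position 1
  expect_equal(cp$gc2, 0.5)   # T,C at position 2
  expect_equal(cp$gc3, 1.0)   # G,C at position 3
  expect_equal(cp$gc_total, 4 / 6)
  expect_equal(cp$gc3s, 1.0)        # only GCC is GC3s-eligible
  # Met and Trp both excluded: GC3s undefined
  expect_true(is.na(composition(make_counts(ATG = 1, TGG = 1), code)$gc3s))
  expect_error(composition(make_counts(), code), "empty")
})

test_that("composition base fractions per position sum to 1", {
  set.seed(42)
  for (i in 1:20) {
    cp <- composition(random_count_table(), code)
    expect_equal(unname(colSums(cp$base_freq)), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("mutation-model genes recover their GC pressure at all positions", {
  g <- 0.30
  # exact per-position GC expectation conditional on the codon not being a
  # stop (the generator resamples in-frame stops, which skews positions 1-2
  # slightly upward at low g): enumerate all 64 codons under the iid model.
  base_p <- c(A = (1 - g) / 2, T = (1 - g) / 2, G = g / 2, C = g / 2)
  cods <- all_codons_vec
  p_cod <- apply(sapply(1:3, function(k) base_p[substr(cods, k, k)]), 1, prod)
  keep <- !(cods %in% c("TAA", "TAG", "TGA"))
  p_cod <- p_cod[keep] / sum(p_cod[keep])
  exp_gc <- sapply(1:3, function(k)
    sum(p_cod[substr(cods[keep], k, k) %in% c("G", "C")]))
  gen <- generate_mutation_driven(5, c(2997, 2997), gc_range = c(g, g),
                                  seed = 7, taxon = "t")
  for (i in 1:5) {
    cp <- composition(count_codons(gen$cds[i, ]), code)
    # ~999 codons per gene: 4 sigma ~ 0.06 absolute
    expect_lt(abs(cp$gc1 - exp_gc[1]), 0.06)
    expect_lt(abs(cp$gc2 - exp_gc[2]), 0.06)
    expect_lt(abs(cp$gc3 - exp_gc[3]), 0.06)
  }
})

test_that("rscu follows the defining formula on forced examples", {
  r <- rscu(make_counts(AAA = 5, AAG = 5), code)   # Lys two-fold
  expect_equal(unname(unclass(r)[c("AAA", "AAG")]), c(1, 1))
  r <- rscu(make_counts(AAA = 3, AAG = 1), code)
  expect_equal(unname(unclass(r)[c("AAA", "AAG")]), c(1.5, 0.5))
  # absent family undefined, singleton convention 1
  r <- rscu(make_counts(ATG = 2), code)
  expect_equal(unname(unclass(r)[["ATG"]]), 1.0)
  expect_true(is.na(unclass(r)[["AAA"]]))
})

test_that("rscu family sums equal family size on random tables", {
  set.seed(1)
  fams <- code$families
  for (i in 1:50) {
    tb <- random_count_table()
    r <- unclass(rscu(tb, code))
    for (fam in fams) {
      if (sum(as.integer(tb)[match(fam, all_codons_vec)]) == 0) next
      expect_equal(sum(r[fam]), length(fam), tolerance = 1e-12)
    }
  }
})

test_that("enc reaches its closed-form limits", {
  # one codon per amino acid, large n -> 20
  one_per_aa <- vapply(code$families, `[`, character(1), 1L)
  tb <- make_counts(stats::setNames(rep(500, length(one_per_aa)), one_per_aa))
  expect_equal(enc(tb, code), 20)
  # uniform usage, 6000 counts per family -> ~61
  v <- unlist(lapply(code$families, function(fam)
    stats::setNames(rep(6000 / length(fam), length(fam)), fam)))
  names(v) <- unlist(code$families)
  expect_gt(enc(make_counts(v), code), 60.9)
})

test_that("enc handles sparse tables with fallbacks and clamping", {
  # only a 2-fold family present: other means missing -> NA
  expect_true(is.na(enc(make_counts(AAA = 10, AAG = 10), code)))
  # perfectly even tiny counts can push the raw estimator above 61: clamped
  v <- unlist(lapply(code$families, function(fam)
    stats::setNames(rep(2, length(fam)), fam)))
  names(v) <- unlist(code$families)
  e <- enc(make_counts(v), code)
  expect_true(is.na(e) || (e >= 20 && e <= 61))
})

test_that("enc_expected evaluates Wright's curve", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  expect_error(enc_expected(1.2), "within")
  # the +s term breaks the symmetry of the quadratic denominator
  expect_false(isTRUE(all.equal(enc_expected(0.3), enc_expected(0.7))))
  expect_equal(enc_expected(0.7) - enc_expected(0.3), 0.4)
  grid <- seq(0, 1, by = 0.01)
  expect_equal(grid[which.max(enc_expected(grid))], 0.5)
})

test_that("cai limits and scale invariance", {
  # reference with a clear bias in Lys
  ref <- rscu(make_counts(AAA = 30, AAG = 10, GAA = 20, GAG = 20), code)
  # gene using only family-maximal codons -> 1
  expect_equal(cai(make_counts(AAA = 7), ref, code), 1.0)
  # gene using only a w = 0.5 codon: RSCU 0.5/1.5
  ref2 <- rscu(make_counts(AAA = 3, AAG = 1), code)
  expect_equal(cai(make_counts(AAG = 5), ref2, code), 1 / 3)
  expect_error(cai(make_counts(GGG = 3), ref2, code), "overlap")
  # scale invariance
  set.seed(9)
  tb <- random_count_table()
  ref3 <- rscu(random_count_table(), code)
  tb10 <- tb
  tb10[] <- as.integer(tb) * 10L
  expect_equal(cai(tb, ref3, code), cai(tb10, ref3, code), tolerance = 1e-12)
})

test_that("pr2 coordinates at the parity point and off it", {
  tb <- make_counts(GGA = 2, GGT = 2, GGG = 2, GGC = 2)  # A3=T3, G3=C3
  expect_equal(unname(pr2_coordinates(tb, code)), c(0.5, 0.5))
  tb2 <- make_counts(GGT = 3, GGG = 1, GGC = 1)          # A3 = 0
  expect_equal(pr2_coordinates(tb2, code)[["pr2_y"]], 0)
  # zero denominator flagged as NA
  tb3 <- make_counts(GGA = 3)
  expect_true(is.na(pr2_coordinates(tb3, code)[["pr2_x"]]))
  # fourfold scope ignores non-fourfold families
  tb4 <- make_counts(GGA = 5, AAA = 100)
  expect_equal(pr2_coordinates(tb4, code, "fourfold")[["pr2_y"]], 1)
})

test_that("pr2 distance from centre shrinks with gene length under mutation", {
  short <- generate_mutation_driven(30, c(300, 300), c(0.5, 0.5), seed = 13)
  long <- generate_mutation_driven(30, c(4500, 4500), c(0.5, 0.5), seed = 13)
  dist_of <- function(cds) {
    mean(vapply(seq_len(nrow(cds)), function(i) {
      xy <- pr2_coordinates(count_codons(cds[i, ]), code)
      sqrt(sum((xy - 0.5)^2))
    }, numeric(1)))
  }
  expect_lt(dist_of(long$cds), dist_of(short$cds))
})

test_that("rscu, enc and cai match the brute-force oracles", {
  set.seed(100)
  for (i in 1:60) {
    tb <- random_count_table(lambda = sample(c(2, 10, 40), 1))
    counts <- stats::setNames(as.integer(tb), all_codons_vec)
    expect_equal(unclass(rscu(tb, code))[names(oracle_rscu(counts))],
                 oracle_rscu(counts), tolerance = 1e-9)
    e1 <- enc(tb, code); e2 <- oracle_enc(counts)
    if (is.na(e2)) expect_true(is.na(e1)) else
      expect_equal(e1, e2, tolerance = 1e-9)
    ref <- rscu(random_count_table(20), code)
    expect_equal(log(cai(tb, ref, code)),
                 log(oracle_cai(counts, unclass(ref))), tolerance = 1e-12)
  }
})

test_that("gene_cub_table assembles consistent per-gene records", {
  gen <- generate_mutation_driven(10, c(300, 900), seed = 31, taxon = "tA")
  filt <- validate_and_filter(gen$cds)
  g <- gene_cub_table(filt$cds, code)
  expect_equal(nrow(g), 10)
  expect_equal(g$gc12, (g$gc1 + g$gc2) / 2)
  expect_true(all(g$enc >= 20 & g$enc <= 61, na.rm = TRUE))
  expect_true(all(g$cai > 0 & g$cai <= 1))
  expect_true(all(g$pr2_x >= 0 & g$pr2_x <= 1, na.rm = TRUE))
  expect_equal(g$length_codons, nchar(filt$cds$sequence) / 3 - 1)
})
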