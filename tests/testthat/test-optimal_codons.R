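code <- genetic_code()

make_records <- function(n, cai = NULL, enc = NULL) {
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), taxon = "t",
             cai = if (is.null(cai)) seq(0.1, 0.9, length.out = n) else cai,
             enc = if (is.null(enc)) seq(61, 30, length.out = n) else enc,
             stringsAsFactors = FALSE)
}

test_that("extreme-gene selection uses the ceiling rule and is deterministic", {
  expect_equal(select_extreme_genes(make_records(40))$k, 2)
  expect_equal(select_extreme_genes(make_records(10))$k, 1)
  r <- make_records(40)
  sel <- select_extreme_genes(r, "cai", 0.05)
  expect_equal(sel$high$gene_id, c("g039", "g040"))
  expect_equal(sel$low$gene_id, c("g001", "g002"))
  # enc metric: high expression = lowest ENc
  sel_e <- select_extreme_genes(r, "enc", 0.05)
  expect_equal(sel_e$high$gene_id, c("g039", "g040"))
  # ties broken by gene_id, from opposite ends
  rt <- make_records(10, cai = rep(0.5, 10))
  sel_t <- select_extreme_genes(rt, "cai", 0.1)
  expect_equal(sel_t$high$gene_id, "g001")
  expect_equal(sel_t$low$gene_id, "g010")
  # n too small for disjoint sets
  expect_error(select_extreme_genes(make_records(3), fraction = 0.49),
               "overlap")
  expect_error(select_extreme_genes(make_records(1)), "at least 2")
})

test_that("metric 'both' intersects CAI and ENc extremes", {
  r <- make_records(40)   # cai increasing, enc decreasing: fully concordant
  sel <- select_extreme_genes(r, "both", 0.05)
  expect_equal(sel$high$gene_id, c("g039", "g040"))
  # discordant metrics: empty intersection errors
  r2 <- make_records(40, enc = seq(30, 61, length.out = 40))
  expect_error(select_extreme_genes(r2, "both", 0.05), "empty intersection")
})

test_that("call_optimal applies the strict delta and anchor rules", {
  # 2-fold Lys family: high 65:35 (RSCU 1.3/0.7), low 50:50
  high <- make_counts(AAA = 65, AAG = 35)
  low <- make_counts(AAA = 50, AAG = 50)
  all <- make_counts(AAA = 115, AAG = 85)
  calls <- call_optimal(high, low, all, 0.08, code, taxon = "t")
  aaa <- calls[calls$codon == "AAA", ]
  expect_equal(aaa$delta_rscu, 0.3, tolerance = 1e-12)
  expect_true(aaa$is_optimal)
  expect_false(calls$is_optimal[calls$codon == "AAG"])
  # delta at 0.05 is not > 0.08
  high2 <- make_counts(AAA = 525, AAG = 475)
  calls2 <- call_optimal(high2, low, all, 0.08, code)
  expect_equal(calls2[calls2$codon == "AAA", "delta_rscu"], 0.05,
               tolerance = 1e-12)
  expect_false(calls2[calls2$codon == "AAA", "is_optimal"])
  # optimal calls always satisfy both conditions post hoc
  expect_true(all(calls$delta_rscu[calls$is_optimal] > 0.08))
  expect_true(all(calls$rscu_high[calls$is_optimal] > 1))
  # stop codons and singletons never appear
  expect_false(any(calls$codon %in% c("TAA", "TAG", "TGA", "ATG", "TGG")))
})

test_that("raising delta never enlarges the optimal set", {
  set.seed(11)
  high <- random_count_table(40)
  low <- random_count_table(40)
  all <- pool_counts(list(high, low))
  sizes <- vapply(c(0, 0.05, 0.08, 0.2, 0.5), function(d)
    sum(call_optimal(high, low, all, d, code)$is_optimal), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("planted preferred codons are recovered by the delta-RSCU rule", {
  pref <- default_preferred_codons(code)
  hi <- generate_selection_driven(40, c(900, 1500), pref, c(2, 2), seed = 5,
                                  taxon = "hi")
  lo <- generate_selection_driven(40, c(900, 1500), pref, c(0, 0), seed = 6,
                                  taxon = "lo")
  ctab <- function(cds) pool_counts(lapply(seq_len(nrow(cds)), function(i)
    count_codons(cds[i, ])))
  h <- ctab(hi$cds); l <- ctab(lo$cds)
  calls <- call_optimal(h, l, pool_counts(list(h, l)), 0.08, code)
  expect_setequal(calls$codon[calls$is_optimal], pref)
})

test_that("planted high-bias genes surface in the CAI-high set", {
  pref <- default_preferred_codons(code)
  strong <- generate_selection_driven(4, c(1200, 1500), pref, c(3, 3),
                                      seed = 41, taxon = "t")
  weak <- generate_selection_driven(36, c(1200, 1500), pref, c(0, 0.2),
                                    seed = 42, taxon = "t")
  strong$cds$gene_id <- paste0("hot", 1:4)
  cds <- rbind(strong$cds, weak$cds)
  g <- gene_cub_table(cds, code)
  sel <- select_extreme_genes(g, "cai", 0.1)   # k = 4
  expect_setequal(sel$high$gene_id, paste0("hot", 1:4))
})

test_that("shared and taxon-specific optimal sets", {
  mk <- function(codons, all_codons_called = c("AAA", "GAA", "TTA", "GCA")) {
    data.frame(codon = all_codons_called,
               is_optimal = all_codons_called %in% codons,
               stringsAsFactors = FALSE)
  }
  calls <- list(t1 = mk(c("AAA", "GAA")), t2 = mk(c("AAA", "GAA")))
  sh <- shared_optimal(calls)
  expect_setequal(sh$shared, c("AAA", "GAA"))
  calls2 <- list(t1 = mk("AAA"), t2 = mk("GAA"))
  expect_length(shared_optimal(calls2)$shared, 0)
  # habitat-group sharing: codon in both group members, absent elsewhere
  calls3 <- list(t1 = mk(c("AAA", "TTA")), t2 = mk(c("AAA", "TTA")),
                 t3 = mk("AAA"), t4 = mk("AAA"))
  sh3 <- shared_optimal(calls3, habitat_groups = list(open = c("t1", "t2"),
                                                      shade = c("t3", "t4")))
  expect_equal(sh3$group_shared$open, "TTA")
  expect_length(sh3$group_shared$shade, 0)
  expect_error(shared_optimal(calls3[1]), ">= 2")
})

test_that("four planted taxa share exactly the planted overlap", {
  pref <- default_preferred_codons(code)
  # six codons shared by all four taxa; each taxon adds its own extras
  shared6 <- pref[1:6]
  extras <- split(pref[7:14], rep(1:4, each = 2))
  calls <- lapply(1:4, function(i) {
    gen_hi <- generate_selection_driven(30, c(900, 1200),
                                        c(shared6, extras[[i]]), c(2.5, 2.5),
                                        seed = 100 + i, taxon = paste0("t", i))
    gen_lo <- generate_selection_driven(30, c(900, 1200),
                                        c(shared6, extras[[i]]), c(0, 0),
                                        seed = 200 + i, taxon = paste0("t", i))
    ctab <- function(cds) pool_counts(lapply(seq_len(nrow(cds)), function(j)
      count_codons(cds[j, ])))
    h <- ctab(gen_hi$cds); l <- ctab(gen_lo$cds)
    call_optimal(h, l, pool_counts(list(h, l)), 0.08, code,
                 taxon = paste0("t", i))
  })
  names(calls) <- paste0("t", 1:4)
  sh <- shared_optimal(calls)
  expect_setequal(sh$shared, shared6)
})

test_that("overrepresented uses a strict threshold", {
  r <- rscu(make_counts(AAA = 50, AAG = 50), code)
  expect_length(overrepresented(r, 1.6), 0)
  r2 <- structure(c(AAA = 1.61, AAG = 0.39), class = "rscu_table")
  expect_equal(overrepresented(r2, 1.6), "AAA")
  r3 <- structure(c(AAA = 1.6), class = "rscu_table")
  expect_length(overrepresented(r3, 1.6), 0)   # strictly greater
  # brute-force scan agreement on a pooled four-taxon fixture
  pools <- lapply(1:4, function(i)
    generate_selection_driven(20, c(600, 900), seed = 300 + i)$cds)
  cds <- do.call(rbind, pools)
  tab <- pool_counts(lapply(seq_len(nrow(cds)), function(i)
    count_codons(cds[i, ])))
  r4 <- rscu(tab, code)
  v <- unclass(r4)
  expect_setequal(overrepresented(r4, 1.6),
                  names(v)[!is.na(v) & v > 1.6])
})
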