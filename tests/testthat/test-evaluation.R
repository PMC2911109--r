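test_that("evaluating the designer's own output reproduces design-time metrics", {
  b <- design_bundle()
  lib <- generate_library(b$designs, b$regions, "none")
  evals <- evaluate_library(lib$library, b$index, b$opts)
  for (i in seq_len(nrow(b$designs))) {
    r <- evals[[i]]
    expect_identical(r$sirna_total, b$designs$sirna_total[i])
    expect_identical(r$sirna_on_target, b$designs$sirna_on_target[i])
    expect_identical(r$sirna_off_target, b$designs$sirna_off_target[i])
    expect_identical(r$sirna_no_target, b$designs$sirna_no_target[i])
    expect_equal(r$mean_efficiency, b$designs$mean_efficiency[i])
    expect_identical(r$efficient_sirnas, b$designs$efficient_sirnas[i])
    expect_identical(r$can_repeats, b$designs$can_repeats[i])
    expect_identical(r$low_complexity_regions, b$designs$low_complexity_regions[i])
    expect_equal(r$intended_genes, b$designs$target_gene[i])
  }
})

test_that("a reagent without transcript hits has no intended target", {
  b <- design_bundle()
  # random sequence almost surely shares no 19-mer with the fixture
  set.seed(71)
  r <- evaluate_reagent(list(reagent_id = "rx", sequence = random_dna(100)),
                        b$index, b$opts)
  expect_length(r$intended_genes, 0L)
  expect_equal(r$sirna_no_target, r$sirna_total)
  expect_equal(r$sirna_on_target, 0L)

  expect_error(evaluate_reagent(list(reagent_id = "short", sequence = "ACGT"),
                                b$index, b$opts), "shorter than")
})

test_that("intended target is the argmax of per-transcript siRNA hits", {
  b <- design_bundle()
  tA <- b$fix$transcripts$residues[b$fix$transcripts$id == "g006.t1"]
  tB <- b$fix$transcripts$residues[b$fix$transcripts$id == "g001.t1"]
  # chimeric reagent: 150 nt of geneA, 30 nt of geneB
  reagent <- list(reagent_id = "chim",
                  sequence = paste0(substr(tA, 1, 150), substr(tB, 1, 30)))
  r <- evaluate_reagent(reagent, b$index, b$opts)
  expect_equal(r$intended_genes, "g006")
  expect_false(r$multi_intended)
  expect_true("g001" %in% r$unintended_genes)
  # the 12 geneB-only siRNAs are off-target relative to the intended set
  expect_equal(r$sirna_off_target, 12L)
  expect_equal(r$sirna_total, r$sirna_on_target + r$sirna_off_target +
                 r$sirna_no_target)
})

test_that("homology scan finds self-matches and respects the threshold", {
  b <- design_bundle()
  db <- b$fix$transcripts
  full <- list(reagent_id = "full", sequence = db$residues[1])
  hits <- homology_scan(full, db, 1e-10)
  skip_if(is.null(hits), "BLAST not available")
  expect_true(db$id[1] %in% hits$transcript_id)
  expect_equal(nrow(homology_scan(full, db, 1e-10, exclude = db$id)), 0L)
  expect_equal(nrow(homology_scan(full, db, 0)), 0L)

  # unrelated random sequence vs a ~1 kb database: nothing below 1e-10
  set.seed(72)
  rnd <- list(reagent_id = "rnd", sequence = random_dna(200))
  small_db <- data.frame(id = c("x1", "x2"), description = "",
                         residues = c(random_dna(500), random_dna(500)),
                         stringsAsFactors = FALSE)
  expect_equal(nrow(homology_scan(rnd, small_db, 1e-10)), 0L)
})

test_that("feature overlap distinguishes missing tables from zero overlap", {
  fp <- list(t1 = data.frame(start0 = 100L, end0 = 200L))
  utr <- data.frame(sequence_id = "t1", start0 = 150L, end0 = 300L)
  snp <- data.frame(sequence_id = "t1", position0 = c(119L, 249L))
  ov <- overlap_features(fp, utr, snp)
  expect_equal(ov$utr_overlap_bases, 50L)
  expect_true(ov$utr_overlap_flag)
  expect_equal(ov$snp_overlap, 1L)

  ov2 <- overlap_features(fp, NULL, NULL)
  expect_true(is.na(ov2$utr_overlap_bases))
  expect_true(is.na(ov2$snp_overlap))

  ov3 <- overlap_features(list(), utr, snp)
  expect_equal(ov3$utr_overlap_bases, 0L)
  expect_equal(ov3$note, "unmapped")
})

test_that("library comparison counts common and independent genes", {
  mkrec <- function(id, gene, start0, end0, tx = paste0(gene, ".t1")) {
    structure(list(reagent_id = id, intended_genes = gene,
                   footprints = setNames(list(data.frame(start0 = start0,
                                                         end0 = end0)), tx)),
              class = "evaluation_record")
  }
  # disjoint gene sets
  cmp <- compare_libraries(list(mkrec("a1", "g1", 0L, 100L)),
                           list(mkrec("b1", "g2", 0L, 100L)))
  expect_equal(c(cmp$genes_common, cmp$genes_independent), c(0L, 0L))

  # same gene, disjoint regions
  cmp <- compare_libraries(list(mkrec("a1", "g1", 0L, 100L)),
                           list(mkrec("b1", "g1", 200L, 300L)))
  expect_equal(c(cmp$genes_common, cmp$genes_independent), c(1L, 1L))

  # same gene, all pairs overlapping by >= 1 base
  cmp <- compare_libraries(list(mkrec("a1", "g1", 0L, 100L)),
                           list(mkrec("b1", "g1", 99L, 180L)))
  expect_equal(c(cmp$genes_common, cmp$genes_independent), c(1L, 0L))

  # independent never exceeds common
  cmp <- compare_libraries(list(mkrec("a1", "g1", 0L, 100L),
                                mkrec("a2", "g2", 0L, 50L)),
                           list(mkrec("b1", "g1", 50L, 150L),
                                mkrec("b2", "g2", 60L, 120L)))
  expect_lte(cmp$genes_independent, cmp$genes_common)
})

test_that("perturbed libraries match their manifest expectations", {
  b <- design_bundle()
  d <- b$designs
  rl <- setNames(nchar(b$regions$sequence), b$regions$region_id)[d$region_id]
  shift <- max(d$amplicon_length)
  d <- d[d$region_offset0 + shift + d$amplicon_length <= rl, , drop = FALSE]
  expect_gt(nrow(d), 1L)

  ev0 <- evaluate_library(generate_library(d, b$regions, "none")$library,
                          b$index, b$opts)
  evs <- evaluate_library(generate_library(d, b$regions, "shift",
                                           shift = shift)$library,
                          b$index, b$opts)
  cmp <- compare_libraries(ev0, evs)
  # shift >= amplicon length: zero overlap, every common gene independent
  expect_equal(cmp$genes_common, length(unique(d$target_gene)))
  expect_equal(cmp$genes_independent, cmp$genes_common)

  # self-comparison never yields independent designs
  cmp_self <- compare_libraries(ev0, ev0)
  expect_equal(cmp_self$genes_independent, 0L)

  # a point mutation at the centre destroys exactly k on-target 19-mers
  evm <- evaluate_library(generate_library(d, b$regions, "mutate")$library,
                          b$index, b$opts)
  for (i in seq_len(nrow(d))) {
    expect_equal(d$sirna_on_target[i] - evm[[i]]$sirna_on_target, b$opts$k)
  }

  # shifting beyond the region bounds is an error
  expect_error(generate_library(d, b$regions, "shift", shift = 10000L),
               "beyond region bounds")
})
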