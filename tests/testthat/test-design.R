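no_mask <- function() data.frame(start0 = integer(0), end0 = integer(0),
                                 cause = character(0), stringsAsFactors = FALSE)

passing_cands <- function(region, k = 19L) {
  d <- dice(region, k)
  d$in_masked <- FALSE
  d$specificity <- "1"
  d
}

test_that("optimal regions are maximal unmasked runs above the window minimum", {
  opts <- design_options()
  r <- toy_region(random_dna(200))
  cands <- passing_cands(r)
  out <- find_optimal_regions(r, cands, no_mask(), opts)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start0, out$end0), c(0L, 200L))

  # one failing siRNA at start 90 masks [90,109): runs of 90 and 91 nt
  cands2 <- cands
  cands2$specificity[cands2$start0 == 90L] <- "0"
  out <- find_optimal_regions(r, cands2, no_mask(), opts)
  expect_equal(out$start0, c(0L, 109L))
  expect_equal(out$end0, c(90L, 200L))
  expect_equal(out$length, c(90L, 91L))

  # failing siRNAs tiled across the query leave nothing
  cands3 <- cands
  cands3$specificity <- "0"
  expect_equal(nrow(find_optimal_regions(r, cands3, no_mask(), opts)), 0L)
})

test_that("redesign merges nearest regions first and stops at the target length", {
  # 60 and 70 nt regions, 10-nt gap: one merge gives 140 nt
  regs <- data.frame(start0 = c(0L, 70L), end0 = c(60L, 140L))
  out <- redesign_merge(regs, 80L)
  expect_null(out$failure)
  expect_equal(c(out$region$start0, out$region$end0), c(0L, 140L))
  expect_equal(out$region$length, 140L)

  # 30/30/30 with gaps 5 and 50: nearest-gap pair merges first (65 nt),
  # then the second merge is needed -> 145 nt
  regs <- data.frame(start0 = c(0L, 35L, 115L), end0 = c(30L, 65L, 145L))
  out <- redesign_merge(regs, 80L)
  expect_equal(c(out$region$start0, out$region$end0), c(0L, 145L))

  # a single short region cannot reach the target
  out <- redesign_merge(data.frame(start0 = 0L, end0 = 40L), 80L)
  expect_equal(out$failure, "insufficient optimal sequence")

  # each merge strictly grows a region; termination <= n-1 merges is
  # implied by reaching the spanning interval
  regs <- data.frame(start0 = c(0L, 25L, 50L, 75L), end0 = c(20L, 45L, 70L, 95L))
  out <- redesign_merge(regs, 90L)
  expect_equal(c(out$region$start0, out$region$end0), c(0L, 95L))
})

test_that("primer pairs respect the product window and sort by penalty", {
  opts <- design_options(window_min = 80L, window_max = 250L)
  expect_error(design_primers(random_dna(50), opts), "shorter than")

  set.seed(61)
  for (i in 1:5) {
    tmpl <- random_dna(sample(90:400, 1))
    p <- design_primers(tmpl, opts, n_pairs = 10L)
    if (!nrow(p)) next
    expect_true(all(p$product_length >= 80 & p$product_length <= 250))
    expect_true(all(diff(p$pair_penalty) >= 0))
    # primers actually flank the product
    for (j in seq_len(nrow(p))) {
      expect_equal(substr(tmpl, p$product_start0[j] + 1,
                          p$product_start0[j] + nchar(p$left[j])), p$left[j])
      expect_equal(revcomp(substr(tmpl, p$product_end0[j] - nchar(p$right[j]) + 1,
                                  p$product_end0[j])), p$right[j])
    }
  }
})

test_that("primer engine is deterministic on a pinned template (golden pair)", {
  set.seed(7)
  tmpl <- random_dna(200)
  p <- design_primers(tmpl, design_options(), n_pairs = 1L)
  expect_equal(p$left, "CGGTGCGCCTTGTTCGTGCTGT")
  expect_equal(p$right, "CGCCCTGCTGCGTAAGATAACGAG")
  expect_equal(c(p$product_start0, p$product_end0), c(0L, 155L))
  expect_equal(p$pair_penalty, 1.6, tolerance = 1e-6)
})

test_that("ranking is lexicographic: specificity, then efficiency, then penalty", {
  d <- data.frame(design_id = c("A", "B"),
                  sirna_off_target = c(0L, 2L),
                  efficient_sirnas = c(5L, 9L),
                  mean_efficiency = c(70, 90),
                  primer_pair_penalty = c(1, 0.5),
                  stringsAsFactors = FALSE)
  out <- rank_designs(d, "dsrna")
  expect_equal(out$design_id, c("A", "B"))  # specificity before efficiency

  d2 <- data.frame(design_id = c("C", "D"),
                   sirna_off_target = 0L,
                   efficient_sirnas = c(9L, 12L),
                   mean_efficiency = c(95, 60),
                   primer_pair_penalty = 1,
                   stringsAsFactors = FALSE)
  expect_equal(rank_designs(d2, "dsrna")$design_id, c("D", "C"))

  # identical metrics preserve input order (stability)
  d3 <- data.frame(design_id = c("E", "F", "G"), sirna_off_target = 1L,
                   efficient_sirnas = 3L, mean_efficiency = 50,
                   primer_pair_penalty = 2, stringsAsFactors = FALSE)
  expect_equal(rank_designs(d3, "dsrna")$design_id, c("E", "F", "G"))

  s <- data.frame(design_id = c("H", "I", "J"),
                  specificity_bit = c(1L, 1L, 0L),
                  efficiency = c(70, 90, 99),
                  seed_frequency = c(10L, 500L, 1L),
                  stringsAsFactors = FALSE)
  expect_equal(rank_designs(s, "sirna")$design_id, c("I", "H", "J"))
})

test_that("design_for_target composes the stages and honours n_designs", {
  b <- design_bundle()
  region <- b$regions[1, , drop = FALSE]
  res <- design_for_target(region, b$index, b$opts)
  expect_null(res$failure)
  expect_gte(nrow(res$designs), 1L)
  expect_equal(res$designs$sirna_off_target[1], 0L)
  # total siRNA count law for every emitted dsRNA
  expect_equal(res$designs$sirna_total,
               res$designs$amplicon_length - b$opts$k + 1L)

  # a query that is one long CAN repeat fails with a low-complexity cause
  can_region <- toy_region(strrep("CAT", 80))
  res2 <- design_for_target(can_region, b$index, b$opts)
  expect_equal(nrow(res2$designs), 0L)
  expect_equal(res2$failure$reason, "low complexity")

  # n designs capped and ranked 1..n
  opts3 <- design_options(n_designs = 3L, allow_overlap = TRUE)
  res3 <- design_for_target(b$regions[2, , drop = FALSE], b$index, opts3)
  expect_lte(nrow(res3$designs), 3L)
  expect_equal(res3$designs$rank, seq_len(nrow(res3$designs)))

  # non-overlapping designs by default
  opts4 <- design_options(n_designs = 3L)
  res4 <- design_for_target(b$regions[2, , drop = FALSE], b$index, opts4)
  if (nrow(res4$designs) > 1L) {
    s <- res4$designs$region_offset0
    e <- s + res4$designs$amplicon_length
    for (i in 2:nrow(res4$designs)) {
      expect_true(all(e[seq_len(i - 1)] <= s[i] | s[seq_len(i - 1)] >= e[i]))
    }
  }
})

test_that("no emitted amplicon overlaps a masked base", {
  b <- design_bundle()
  d <- b$designs
  seq_of <- setNames(b$regions$sequence, b$regions$region_id)
  for (i in seq_len(nrow(d))) {
    amp <- d$sequence[i]
    expect_equal(nrow(find_can_repeats(amp)), 0L)
    expect_equal(nrow(dust_mask(amp)), 0L)
    # every siRNA of the amplicon is specific for the target gene
    cands <- dice(toy_region(amp), 19L)
    cl <- classify_specificity(cands, b$index)
    expect_true(all(cl$specificity != "0"))
  }
})

test_that("repeated runs produce byte-identical result tables", {
  b <- design_bundle()
  run_once <- function(dir) {
    res <- rnaidesign:::design_all(b$regions, b$index, b$opts)
    suppressWarnings(write_design_outputs(res$designs, res$failed, dir))
  }
  f1 <- run_once(tempfile()); f2 <- run_once(tempfile())
  expect_identical(readLines(f1[["tab"]]), readLines(f2[["tab"]]))
  expect_identical(readLines(f1[["gff"]]), readLines(f2[["gff"]]))
})

test_that("redesign rescues a fragmented query", {
  b <- design_bundle()
  # fragment a clean region with unspecific siRNAs planted every 60 nt:
  # insert 19-mers from another gene so optimal runs are < 80 nt
  # the paralog-shared 19-mer hits two genes, so planting it creates
  # failing (unspecific) siRNAs that fragment the query
  shared <- b$fix$manifest$detail[b$fix$manifest$feature == "shared_19mer"][1]
  seqv <- strsplit(substr(b$regions$sequence[6], 1, 200), "")[[1]]
  for (at in c(60L, 130L)) {
    seqv[(at + 1):(at + 19)] <- strsplit(shared, "")[[1]]
  }
  # unmasked runs are now 60, 51 and 51 nt: none reaches the 80-nt window
  frag <- toy_region(paste(seqv, collapse = ""), gene_id = "g006",
                     region_id = "frag_r1")
  res_no <- design_for_target(frag, b$index, design_options(redesign = FALSE))
  expect_equal(res_no$failure$reason, "optimal regions too short")
  res_yes <- design_for_target(frag, b$index, design_options(redesign = TRUE))
  expect_null(res_yes$failure)
  expect_gte(nrow(res_yes$designs), 1L)
})
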