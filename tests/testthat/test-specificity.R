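tx_df <- function(ids, seqs) {
  data.frame(id = ids, description = "", residues = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

tg_df <- function(tx, gene) {
  data.frame(transcript_id = tx, gene_id = gene, stringsAsFactors = FALSE)
}

test_that("index postings cover every k-mer start position", {
  set.seed(41)
  one <- random_dna(19)
  idx <- build_index(tx_df("t1", one), tg_df("t1", "g1"), 19L)
  expect_equal(nrow(idx$postings), 1L)
  expect_equal(idx$postings$pos0, 0L)

  shared <- random_dna(19)
  db <- tx_df(c("t1", "t2"), c(paste0(random_dna(10), shared),
                               paste0(shared, random_dna(12))))
  idx <- build_index(db, tg_df(c("t1", "t2"), c("g1", "g2")), 19L)
  expect_equal(nrow(query_index(idx, shared)), 2L)

  idx <- build_index(tx_df("t1", random_dna(25)), tg_df("t1", "g1"), 19L)
  expect_equal(nrow(idx$postings), 7L)  # 25 - 19 + 1

  # completeness: sum of postings == sum over sequences of L - k + 1
  db <- tx_df(c("a", "b", "c"), c(random_dna(40), random_dna(19), random_dna(100)))
  idx <- build_index(db, tg_df(c("a", "b", "c"), c("g1", "g2", "g3")), 19L)
  expect_equal(nrow(idx$postings), sum(db$length - 19L + 1L))

  # N windows skipped; short sequences warn and contribute nothing
  db <- tx_df("n1", paste0(strrep("A", 10), "N", strrep("C", 10)))
  idx <- build_index(db, tg_df("n1", "g1"), 19L)
  expect_equal(nrow(idx$postings), 0L)
  expect_warning(build_index(tx_df("s1", "ACGT"), tg_df("s1", "g1"), 19L),
                 "shorter than k")
  expect_warning(build_index(tx_df("t1", random_dna(30)),
                             tg_df("zz", "g1"), 19L), "singleton")
})

test_that("specificity classes follow the single-gene rule", {
  set.seed(42)
  core <- random_dna(19)
  # two isoforms of geneA contain the siRNA; geneB does not
  db <- tx_df(c("a1", "a2", "b1"),
              c(paste0(random_dna(5), core, random_dna(5)),
                paste0(core, random_dna(8)), random_dna(40)))
  tg <- tg_df(c("a1", "a2", "b1"), c("geneA", "geneA", "geneB"))
  idx <- build_index(db, tg, 19L)
  cands <- data.frame(sense = core, stringsAsFactors = FALSE)
  out <- classify_specificity(cands, idx)
  expect_equal(out$specificity, "1")
  expect_equal(out$hit_genes, "geneA")

  # also present in geneB -> unspecific
  db$residues[3] <- paste0(random_dna(3), core, random_dna(3))
  db$length <- nchar(db$residues)
  idx <- build_index(db, tg, 19L)
  expect_equal(classify_specificity(cands, idx)$specificity, "0")

  # absent entirely -> no_target
  absent <- data.frame(sense = strrep("A", 19), stringsAsFactors = FALSE)
  expect_equal(classify_specificity(absent, idx)$specificity, "no_target")

  # reverse-complement matches count when both strands are queried
  rc_cand <- data.frame(sense = revcomp(core), stringsAsFactors = FALSE)
  expect_equal(classify_specificity(rc_cand, idx, both_strands = TRUE)$specificity, "0")
  expect_equal(classify_specificity(rc_cand, idx, both_strands = FALSE)$specificity,
               "no_target")
})

test_that("index classification agrees with brute-force substring search", {
  fix <- default_fixture()
  tx2gene <- setNames(fix$transcript_gene$gene_id, fix$transcript_gene$transcript_id)
  idx <- build_index(fix$transcripts, fix$transcript_gene, 19L)
  set.seed(43)
  # all siRNAs of two transcripts plus random probes
  queries <- character(0)
  for (i in sample(nrow(fix$transcripts), 2)) {
    queries <- c(queries, kmer_windows <- rnaidesign:::kmer_windows(
      fix$transcripts$residues[i], 19L))
  }
  queries <- c(sample(queries, 150), vapply(1:30, function(i) random_dna(19),
                                            character(1)))
  got <- classify_specificity(data.frame(sense = queries,
                                         stringsAsFactors = FALSE), idx)
  want <- vapply(queries, brute_specificity, character(1),
                 transcripts = fix$transcripts, tx2gene = tx2gene,
                 USE.NAMES = FALSE)
  expect_equal(got$specificity, want)
})

test_that("seed complement frequency counts overlapping sites of the seed complement", {
  utr <- tx_df("u1", paste0(random_dna(10), "TTTAAAC", random_dna(10),
                            "TTTAAAC", random_dna(5)))
  # guide seed whose reverse complement is TTTAAAC
  seed <- revcomp("TTTAAAC")
  tab <- seed_frequency_table(seed, utr)
  expect_equal(unname(tab[seed]), 2L)
  expect_equal(unname(seed_frequency_table("ACGTCCA", tx_df("u1", "GGGG"))), 0L)

  # overlapping occurrences all count: AAAAAA complement in a poly-A stretch
  utr2 <- tx_df("u2", strrep("A", 10))
  tab2 <- seed_frequency_table("TTTTTT", utr2)
  expect_equal(unname(tab2), 5L)  # 10 - 6 + 1

  # orientation: db AAAAAA, guide seed TTTTTT -> site AAAAAA present once
  expect_equal(unname(seed_frequency_table("TTTTTT", tx_df("u3", "AAAAAA"))), 1L)

  # equals a naive count on the concatenated-with-separator database
  set.seed(44)
  utr3 <- tx_df(c("a", "b"), c(random_dna(300), random_dna(200)))
  seeds <- vapply(1:10, function(i) random_dna(7), character(1))
  tab3 <- seed_frequency_table(seeds, utr3)
  concat <- paste(utr3$residues, collapse = "X")
  for (s in seeds) {
    site <- revcomp(s)
    naive <- length(gregexpr(paste0("(?=", site, ")"), concat, perl = TRUE)[[1]])
    if (gregexpr(paste0("(?=", site, ")"), concat, perl = TRUE)[[1]][1] == -1) naive <- 0L
    expect_equal(unname(tab3[s]), naive)
  }
})

test_that("candidate annotation inherits the frequency of its seed", {
  utr <- tx_df("u1", strrep("A", 50))
  cands <- data.frame(region_id = "r", start0 = 0L,
                      sense = strrep("A", 19), guide = strrep("T", 19),
                      contains_n = FALSE, stringsAsFactors = FALSE)
  out <- seed_frequency(cands, utr, "7mer", threshold = 1000L)
  expect_equal(out$seed_frequency, 44L)  # 50 - 7 + 1
  expect_true(out$seed_low_frequency)
  out2 <- seed_frequency(cands, utr, "7mer", threshold = 10L)
  expect_false(out2$seed_low_frequency)
})
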