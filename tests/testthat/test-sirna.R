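test_that("dicing enumerates L-k+1 windows in order", {
  expect_equal(nrow(dice(toy_region(random_dna(19)), 19L)), 1L)
  expect_equal(nrow(dice(toy_region(random_dna(18)), 19L)), 0L)
  d <- dice(toy_region(random_dna(221)), 19L)
  expect_equal(nrow(d), 203L)
  expect_equal(d$start0, 0:202)
  # guide is the exact reverse complement of the sense window
  expect_equal(d$guide, revcomp(d$sense))

  set.seed(21)
  for (i in 1:20) {
    k <- sample(5:25, 1)
    L <- sample(k:300, 1)
    expect_equal(nrow(dice(toy_region(random_dna(L)), k)), L - k + 1L)
  }
})

test_that("N-containing windows are flagged", {
  d <- dice(toy_region(paste0(strrep("A", 20), "N", strrep("C", 20))), 19L)
  expect_true(any(d$contains_n))
  expect_equal(sum(d$contains_n), 19L)  # every window covering the N
})

test_that("CAN detection finds maximal runs in all three frames", {
  expect_equal(find_can_repeats(strrep("CAT", 6))$start0, 0L)
  expect_equal(find_can_repeats(strrep("CAT", 6))$end0, 18L)
  expect_equal(nrow(find_can_repeats(strrep("CAT", 5))), 0L)
  # frame 2
  m <- find_can_repeats(paste0("GG", strrep("CAA", 6), "TT"))
  expect_equal(c(m$start0, m$end0), c(2L, 20L))
  # frame 1 and mixed units
  m <- find_can_repeats(paste0("T", "CAACAGCATCACCAACAT", "G"))
  expect_equal(c(m$start0, m$end0), c(1L, 19L))
  # configurable threshold
  expect_equal(nrow(find_can_repeats(strrep("CAT", 5), min_units = 5L)), 1L)
})

test_that("CAN detection is strand-specific (sense strand only)", {
  run <- strrep("CAT", 6)
  expect_equal(nrow(find_can_repeats(run)), 1L)
  # the reverse complement (ATG-type run) is deliberately not masked
  expect_equal(nrow(find_can_repeats(revcomp(run))), 0L)
})

test_that("DUST masks homopolymers but not triplet-diverse sequence", {
  m <- dust_mask(strrep("A", 64))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start0, m$end0), c(0L, 64L))

  # a sequence in which every triplet occurs once has score 0: greedy
  # de Bruijn construction (append the first base not repeating a triplet)
  s <- "TT"; used <- character(0)
  while (nchar(s) < 64) {
    for (b in c("A", "C", "G", "T")) {
      tri <- paste0(substr(s, nchar(s) - 1L, nchar(s)), b)
      if (!(tri %in% used)) { used <- c(used, tri); s <- paste0(s, b); break }
    }
  }
  expect_false(anyDuplicated(substring(s, 1:62, 3:64)) > 0)
  expect_equal(nrow(dust_mask(s)), 0L)

  # four distinct triplets repeated ~16x score well below the cutoff
  expect_equal(nrow(dust_mask(strrep("ACGT", 16))), 0L)
})

test_that("DUST agrees with a direct recount of the triplet statistic", {
  # independent oracle: recompute the windowed score naively
  naive_score <- function(s) {
    tri <- substring(s, 1:(nchar(s) - 2), 3:nchar(s))
    counts <- table(tri)
    sum(counts * (counts - 1) / 2) / (length(tri) - 1)
  }
  set.seed(32)
  runs <- c(strrep("A", 70), strrep("AT", 35), strrep("T", 66),
            strrep("AAG", 25), strrep("GC", 35))
  for (i in seq_along(runs)) {
    s <- paste0(random_dna(20), runs[i], random_dna(20))
    m <- dust_mask(s)
    L <- nchar(s)
    wlen <- min(64L, L)
    flagged <- vapply(1:(L - wlen + 1), function(p)
      naive_score(substr(s, p, p + wlen - 1)) > 28, logical(1))
    if (any(flagged)) {
      expect_gt(nrow(m), 0L)
      expect_equal(min(m$start0), min(which(flagged)) - 1L)
      expect_equal(max(m$end0), max(which(flagged)) - 1L + wlen)
    } else {
      expect_equal(nrow(m), 0L)
    }
  }
})

test_that("masked intervals are reproducible on the masked substring", {
  s <- paste0(random_dna(30), strrep("CAG", 7), random_dna(30))
  m <- find_can_repeats(s)
  expect_equal(nrow(m), 1L)
  sub <- substr(s, m$start0 + 1, m$end0)
  m2 <- find_can_repeats(sub)
  expect_equal(c(m2$start0, m2$end0), c(0L, nchar(sub)))
})

test_that("miRNA seed flags use guide positions 2-8 (or 2-7), guide strand only", {
  cands <- data.frame(region_id = "r", start0 = 0L,
                      sense = revcomp("AACCGGTTACGTACGTACG"),
                      guide = "AACCGGTTACGTACGTACG",
                      contains_n = FALSE, stringsAsFactors = FALSE)
  out <- flag_mirna_seeds(cands, "ACCGGTT", "7mer")
  expect_true(out$has_mirna_seed)
  out <- flag_mirna_seeds(cands, "ACCGGT", "6mer")
  expect_true(out$has_mirna_seed)
  expect_false(flag_mirna_seeds(cands, character(0), "7mer")$has_mirna_seed)
  # a seed matching the sense but not the guide does not flag
  sense_seed <- substr(cands$sense, 2, 8)
  expect_false(flag_mirna_seeds(cands, sense_seed, "7mer")$has_mirna_seed)
  # RNA alphabet is normalized
  expect_true(flag_mirna_seeds(cands, "ACCGGUU", "7mer")$has_mirna_seed)
  expect_error(flag_mirna_seeds(cands, "ACCGGTT", "6mer"), "wrong length")
})

test_that("seed lists load from plain text and from mature-miRNA FASTA", {
  tf <- tempfile()
  writeLines(c("# comment", "ACCGGUU", "TTTTTTT"), tf)
  expect_equal(read_mirna_seeds(tf, "7mer"), c("ACCGGTT", "TTTTTTT"))
  writeLines(c(">mir-1", "UGGAAUGUAAAGAAGUAUGUAU"), tf)
  expect_equal(read_mirna_seeds(tf, "7mer"), "GGAATGT")
})
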