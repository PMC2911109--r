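# siRNA enumeration ("dicing") and sequence-level filters: CAN tandem
# trinucleotide repeats, DUST low-complexity masking, miRNA-seed matches.

#' Dice a target sequence into candidate siRNAs
#'
#' Enumerates every k-mer window of the region sequence (default 19 nt at an
#' offset of 1 nt), simulating Dicer cleavage of a long dsRNA. The guide
#' strand is the exact reverse complement of the sense window. Windows
#' containing N are flagged and excluded from all downstream passes.
#'
#' @param region one-row region table (or any list with `region_id` and
#'   `sequence`).
#' @param k siRNA length, nt.
#' @param offset dicing step, nt.
#' @return data.frame of candidates: `region_id`, `start0` (offset within
#'   the region), `sense`, `guide`, `contains_n`.
#' @export
dice <- function(region, k = 19L, offset = 1L) {
  stopifnot(k >= 1L, offset >= 1L)
  seq <- region$sequence
  L <- nchar(seq)
  if (L < k) {
    return(data.frame(region_id = character(0), start0 = integer(0),
                      sense = character(0), guide = character(0),
                      contains_n = logical(0), stringsAsFactors = FALSE))
  }
  starts0 <- seq.int(0L, L - k, by = offset)
  sense <- substring(seq, starts0 + 1L, starts0 + k)
  data.frame(region_id = region$region_id, start0 = starts0, sense = sense,
             guide = revcomp(sense), contains_n = grepl("N", sense, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Find tandem CAN trinucleotide repeats
#'
#' Scans all three reading frames of the sense strand for maximal runs of at
#' least `min_units` consecutive trinucleotides each matching CA[ACGT].
#' Such runs exert promiscuous off-target effects and are excluded from
#' designs. Detection is strand-specific: the reverse-strand equivalent
#' ([ACGT]TG runs) is deliberately not searched, mirroring a filter applied
#' to the target template as written.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param min_units minimum number of tandem units (default 6).
#' @return data.frame of masked intervals: `start0`, `end0`, `cause`
#'   (`"CAN"`), 0-based half-open within `seq`.
#' @export
find_can_repeats <- function(seq, min_units = 6L) {
  L <- nchar(seq)
  res <- list()
  for (frame in 0:2) {
    n_units <- (L - frame) %/% 3L
    if (n_units < min_units) next
    starts0 <- frame + 3L * (seq_len(n_units) - 1L)
    units <- substring(seq, starts0 + 1L, starts0 + 3L)
    is_can <- grepl("^CA[ACGT]$", units)
    r <- rle(is_can)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    keep <- r$values & r$lengths >= min_units
    for (j in which(keep)) {
      res[[length(res) + 1L]] <- c(starts0[starts_idx[j]],
                                   starts0[ends_idx[j]] + 3L)
    }
  }
  if (!length(res)) {
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      cause = character(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, res)
  out <- data.frame(start0 = m[, 1], end0 = m[, 2], cause = "CAN",
                    stringsAsFactors = FALSE)
  out <- unique(out[order(out$start0, out$end0), , drop = FALSE])
  rownames(out) <- NULL
  out
}

# base -> 0..3 code; N -> NA
base_codes <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  codes
}

#' DUST low-complexity masking
#'
#' Implements the DUST triplet-counting statistic: within each sliding
#' window the score is \eqn{\sum_t c_t (c_t - 1) / 2} over the counts
#' \eqn{c_t} of the 64 possible triplets, normalized by (number of triplet
#' words in the window - 1). Positions of every window whose score exceeds
#' `cutoff` are merged into maximal masked intervals. Triplets containing N
#' do not contribute to the counts.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param window sliding window length, nt (default 64).
#' @param word word length, nt (default 3).
#' @param cutoff score threshold (default 28).
#' @return data.frame of masked intervals: `start0`, `end0`, `cause`
#'   (`"DUST"`).
#' @export
dust_mask <- function(seq, window = 64L, word = 3L, cutoff = 28) {
  L <- nchar(seq)
  if (L < word + 1L) {
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      cause = character(0), stringsAsFactors = FALSE))
  }
  wlen <- min(window, L)
  codes <- base_codes(seq)
  n_words <- L - word + 1L
  # integer code of each word, NA when it contains N
  wcode <- integer(n_words)
  for (i in seq_len(word)) {
    wcode <- wcode * 4L + codes[i:(i + n_words - 1L)]
  }
  words_per_win <- wlen - word + 1L
  if (words_per_win < 2L) {
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      cause = character(0), stringsAsFactors = FALSE))
  }
  counts <- integer(4L^word)
  pair_sum <- 0
  flagged <- logical(L - wlen + 1L)
  add_word <- function(w) {
    if (is.na(w)) return(invisible())
    c0 <- counts[w + 1L]
    pair_sum <<- pair_sum + c0
    counts[w + 1L] <<- c0 + 1L
  }
  drop_word <- function(w) {
    if (is.na(w)) return(invisible())
    c0 <- counts[w + 1L]
    pair_sum <<- pair_sum - (c0 - 1L)
    counts[w + 1L] <<- c0 - 1L
  }
  for (j in seq_len(words_per_win)) add_word(wcode[j])
  for (s in seq_len(L - wlen + 1L)) {
    if (s > 1L) {
      drop_word(wcode[s - 1L])
      add_word(wcode[s + words_per_win - 1L])
    }
    flagged[s] <- (pair_sum / (words_per_win - 1)) > cutoff
  }
  if (!any(flagged)) {
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      cause = character(0), stringsAsFactors = FALSE))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = which(flagged),
                                         width = wlen))
  data.frame(start0 = IRanges::start(ir) - 1L,
             end0 = pmin(IRanges::end(ir), L),
             cause = "DUST", stringsAsFactors = FALSE)
}

#' Extract the guide-strand seed of an siRNA
#'
#' The seed is the guide strand's positions 2-8 (7-mer mode, default) or
#' 2-7 (6-mer mode), numbered 1-based 5' to 3' on the guide.
#'
#' @param guide guide-strand sequence(s).
#' @param mode `"7mer"` or `"6mer"`.
#' @return character vector of seeds.
#' @export
guide_seed <- function(guide, mode = c("7mer", "6mer")) {
  mode <- match.arg(mode)
  substr(guide, 2L, if (mode == "7mer") 8L else 7L)
}

#' Flag siRNAs carrying listed miRNA seeds
#'
#' Marks each candidate whose guide-strand seed (positions 2-8 in 7-mer
#' mode, 2-7 in 6-mer mode) exactly equals a listed seed. Seeds are
#' normalized from RNA to DNA alphabet (U to T) and uppercased. A match is
#' tested on the guide strand only: a seed occurring in the sense strand
#' does not flag the candidate.
#'
#' @param cands candidate table from [dice()].
#' @param seeds character vector of seeds (6- or 7-mers, RNA or DNA).
#' @param mode `"7mer"` or `"6mer"`.
#' @return `cands` with a logical column `has_mirna_seed`.
#' @export
flag_mirna_seeds <- function(cands, seeds, mode = c("7mer", "6mer")) {
  mode <- match.arg(mode)
  want <- if (mode == "7mer") 7L else 6L
  seeds <- toupper(chartr("U", "T", seeds))
  if (length(seeds) && any(nchar(seeds) != want)) {
    stop(sprintf("seed(s) of wrong length for %s mode: %s", mode,
                 paste(seeds[nchar(seeds) != want], collapse = ", ")))
  }
  cands$has_mirna_seed <- guide_seed(cands$guide, mode) %in% seeds
  cands
}

#' Extract seeds from mature miRNA sequences
#'
#' Reads a seed list either from a one-column text/tab file of seeds or from
#' a FASTA of mature miRNAs, in which case the seed is taken as positions
#' 2-8 (or 2-7) of the mature sequence, U converted to T.
#'
#' @param path file path (FASTA if the first non-empty character is `>`).
#' @param mode `"7mer"` or `"6mer"`.
#' @return character vector of unique DNA seeds.
#' @export
read_mirna_seeds <- function(path, mode = c("7mer", "6mer")) {
  mode <- match.arg(mode)
  want <- if (mode == "7mer") 8L else 7L
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(trimws(first), ">")) {
    set <- Biostrings::readBStringSet(path)
    mature <- toupper(chartr("Uu", "TT", as.character(set)))
    seeds <- substr(mature, 2L, want)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    lines <- lines[lines != "seed"]  # tolerate a header row
    seeds <- toupper(chartr("Uu", "TT", lines))
  }
  unique(seeds)
}
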