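# Design engine: optimal-region finding over filtered siRNA candidates,
# iterative redesign (merging nearby optimal regions), primer design for
# dsRNA amplicons, ranking, and the per-target composition.

# Per-candidate pass/fail under the active filters. A failing siRNA masks
# its full k-nt span of the query.
candidate_fails <- function(cands, opts) {
  fail <- cands$contains_n
  if (!is.null(cands$in_masked)) fail <- fail | cands$in_masked
  fail <- fail | (cands$specificity == "0")
  if (opts$mirna_seed_filter && !is.null(cands$has_mirna_seed)) {
    fail <- fail | cands$has_mirna_seed
  }
  if (isTRUE(opts$efficiency_filter) && !is.null(cands$efficiency)) {
    fail <- fail | (!is.na(cands$efficiency) & cands$efficiency < opts$efficiency_cutoff)
  }
  if (opts$seed_frequency_filter && !is.null(cands$seed_frequency)) {
    fail <- fail | (!cands$seed_low_frequency)
  }
  fail
}

# logical mask over the query: TRUE = excluded base
query_mask <- function(L, k, cands, masks) {
  m <- logical(L)
  if (nrow(masks)) {
    for (i in seq_len(nrow(masks))) {
      m[(masks$start0[i] + 1L):min(masks$end0[i], L)] <- TRUE
    }
  }
  fail_starts <- cands$start0[cands$fails]
  for (s in fail_starts) m[(s + 1L):min(s + k, L)] <- TRUE
  m
}

# maximal unmasked runs as a data.frame(start0, end0, length)
unmasked_runs <- function(mask) {
  r <- rle(!mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start0 = starts[keep] - 1L, end0 = ends[keep],
             length = r$lengths[keep])
}

#' Find optimal target regions within a query
#'
#' Masks the full k-nt span of every siRNA failing the active filters
#' (low complexity, multi-gene perfect homology, optional efficiency /
#' seed-frequency / miRNA-seed cutoffs) together with the CAN/DUST masked
#' intervals, and returns the maximal unmasked intervals at least
#' `opts$window_min` nt long. Intervals longer than `opts$window_max` are
#' reported whole; the primer product window enforces the length cap.
#'
#' @param region one-row region table.
#' @param cands fully annotated candidate table (flags, specificity and —
#'   if the corresponding filters are on — efficiency and seed frequency).
#' @param masks CAN/DUST interval table for the region sequence.
#' @param opts [design_options()].
#' @return data.frame of optimal regions: `start0`, `end0`, `length`
#'   (0-based half-open within the query).
#' @export
find_optimal_regions <- function(region, cands, masks, opts = design_options()) {
  cands$fails <- candidate_fails(cands, opts)
  L <- nchar(region$sequence)
  runs <- unmasked_runs(query_mask(L, opts$k, cands, masks))
  runs[runs$length >= opts$window_min, , drop = FALSE]
}

#' Iteratively merge nearby optimal regions (redesign)
#'
#' When every optimal region is individually too short for primer design,
#' the pair of regions with the smallest intervening gap (ties: leftmost
#' pair) is merged into one region spanning both plus the "suboptimal" gap
#' between them. Merging repeats until a region of at least `min_len` nt
#' exists or a single region remains.
#'
#' @param regions data.frame of regions (`start0`, `end0`), all shorter
#'   than `min_len`.
#' @param min_len target length, nt.
#' @return list with either `region` (one-row data.frame reaching
#'   `min_len`) or `failure` (reason string).
#' @export
redesign_merge <- function(regions, min_len) {
  regions <- regions[order(regions$start0), , drop = FALSE]
  if (nrow(regions) == 0L) {
    return(list(failure = "insufficient optimal sequence"))
  }
  span <- regions$end0[nrow(regions)] - regions$start0[1]
  if (span < min_len) return(list(failure = "insufficient optimal sequence"))
  repeat {
    len <- regions$end0 - regions$start0
    if (any(len >= min_len)) {
      i <- which(len >= min_len)[1]
      return(list(region = data.frame(start0 = regions$start0[i],
                                      end0 = regions$end0[i],
                                      length = len[i])))
    }
    if (nrow(regions) == 1L) {
      return(list(failure = "insufficient optimal sequence"))
    }
    gaps <- regions$start0[-1] - regions$end0[-nrow(regions)]
    j <- which.min(gaps)  # smallest gap; which.min takes the leftmost tie
    regions$end0[j] <- regions$end0[j + 1L]
    regions <- regions[-(j + 1L), , drop = FALSE]
  }
}

# melting temperature of a primer with g GC bases and length n
# (GC-content formula; adequate for 18-24-mers)
primer_tm <- function(n_gc, len) {
  64.9 + 41 * (n_gc - 16.4) / len
}

# best primer (over lengths) anchored at each template position
# side "left": primer = template[s, s+len); side "right": primer =
# revcomp(template[e-len, e)) for product end e
primer_profiles <- function(template, lengths, opt_tm = 60) {
  L <- nchar(template)
  gc_cum <- c(0L, cumsum(strsplit(template, "", fixed = TRUE)[[1]] %in% c("G", "C")))
  best <- function(anchor, side) {
    # anchor: left -> product start s (0-based); right -> product end e
    n <- length(anchor)
    best_pen <- rep(Inf, n); best_len <- rep(NA_integer_, n)
    best_tm <- rep(NA_real_, n); best_gc <- rep(NA_real_, n)
    for (len in lengths) {
      if (side == "left") {
        s0 <- anchor; e0 <- anchor + len
      } else {
        s0 <- anchor - len; e0 <- anchor
      }
      ok <- s0 >= 0L & e0 <= L
      s0c <- pmax(s0, 0L); e0c <- pmin(e0, L)
      n_gc <- ifelse(ok, gc_cum[e0c + 1L] - gc_cum[s0c + 1L], NA)
      tm <- primer_tm(n_gc, len)
      gc <- n_gc / len
      pen <- abs(tm - opt_tm) + ifelse(gc < 0.35 | gc > 0.65, 2, 0)
      upd <- ok & !is.na(pen) & pen < best_pen
      best_pen[upd] <- pen[upd]; best_len[upd] <- len
      best_tm[upd] <- tm[upd]; best_gc[upd] <- gc[upd]
    }
    data.frame(anchor = anchor, penalty = best_pen, len = best_len,
               tm = best_tm, gc = best_gc)
  }
  list(left = best(0:(L - min(lengths)), "left"),
       right = best(min(lengths):L, "right"))
}

#' Design primer pairs for a dsRNA amplicon template
#'
#' A self-contained primer-design engine: enumerates left/right primers of
#' 18-24 nt anchored at every possible product start/end, scores each
#' primer by deviation of its melting temperature (GC-content formula) from
#' 60 degrees C plus a GC-fraction term, and combines them into pairs whose
#' product length lies within the options window. Pairs are returned sorted
#' by pair penalty (sum of the primer penalties plus the Tm difference);
#' lower is better.
#'
#' @param template template DNA sequence (an optimal region).
#' @param opts [design_options()]; `window_min`/`window_max` bound the
#'   product length.
#' @param n_pairs maximum number of pairs returned.
#' @return data.frame of pairs: `product_start0`, `product_end0`,
#'   `product_length`, `left`, `right`, `left_tm`, `right_tm`, `left_gc`,
#'   `right_gc`, `pair_penalty`; zero rows when no pair fits.
#' @export
design_primers <- function(template, opts = design_options(), n_pairs = 5L) {
  L <- nchar(template)
  if (L < opts$window_min) {
    stop("template shorter than the minimum product length (",
         opts$window_min, " nt)")
  }
  lengths <- 18:24
  lengths <- lengths[lengths <= L]
  prof <- primer_profiles(template, lengths)
  lp <- prof$left[is.finite(prof$left$penalty), , drop = FALSE]
  rp <- prof$right[is.finite(prof$right$penalty), , drop = FALSE]
  if (!nrow(lp) || !nrow(rp)) return(empty_primer_table())
  pairs <- vector("list", nrow(lp))
  for (i in seq_len(nrow(lp))) {
    s <- lp$anchor[i]
    e_min <- s + opts$window_min
    e_max <- min(s + opts$window_max, L)
    if (e_min > e_max) next
    sel <- rp$anchor >= e_min & rp$anchor <= e_max
    if (!any(sel)) next
    rr <- rp[sel, , drop = FALSE]
    pen <- lp$penalty[i] + rr$penalty + abs(lp$tm[i] - rr$tm)
    j <- which.min(pen)
    pairs[[i]] <- data.frame(product_start0 = s, product_end0 = rr$anchor[j],
                             left_len = lp$len[i], right_len = rr$len[j],
                             left_tm = lp$tm[i], right_tm = rr$tm[j],
                             left_gc = lp$gc[i], right_gc = rr$gc[j],
                             pair_penalty = pen[j])
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || !nrow(pairs)) return(empty_primer_table())
  pairs <- pairs[order(pairs$pair_penalty, pairs$product_start0), , drop = FALSE]
  pairs <- utils::head(pairs, n_pairs)
  pairs$product_length <- pairs$product_end0 - pairs$product_start0
  pairs$left <- substring(template, pairs$product_start0 + 1L,
                          pairs$product_start0 + pairs$left_len)
  pairs$right <- revcomp(substring(template, pairs$product_end0 - pairs$right_len + 1L,
                                   pairs$product_end0))
  rownames(pairs) <- NULL
  pairs[, c("product_start0", "product_end0", "product_length", "left",
            "right", "left_tm", "right_tm", "left_gc", "right_gc",
            "pair_penalty")]
}

empty_primer_table <- function() {
  data.frame(product_start0 = integer(0), product_end0 = integer(0),
             product_length = integer(0), left = character(0),
             right = character(0), left_tm = numeric(0),
             right_tm = numeric(0), left_gc = numeric(0),
             right_gc = numeric(0), pair_penalty = numeric(0),
             stringsAsFactors = FALSE)
}

#' Rank reagent designs
#'
#' Lexicographic, stable ranking. dsRNA designs: off-target siRNA count
#' ascending, efficient-siRNA count descending, mean efficiency descending,
#' primer pair penalty ascending. siRNA designs: specificity bit
#' descending, efficiency descending, seed complement frequency ascending.
#'
#' @param designs design table (dsRNA: columns `sirna_off_target`,
#'   `efficient_sirnas`, `mean_efficiency`, `primer_pair_penalty`; siRNA:
#'   `specificity_bit`, `efficiency`, `seed_frequency`).
#' @param type `"dsrna"` or `"sirna"`.
#' @return the table reordered with a `rank` column (1 = best); full ties
#'   keep input order.
#' @export
rank_designs <- function(designs, type = c("dsrna", "sirna")) {
  type <- match.arg(type)
  if (!nrow(designs)) { designs$rank <- integer(0); return(designs) }
  ord <- if (type == "dsrna") {
    order(designs$sirna_off_target, -designs$efficient_sirnas,
          -designs$mean_efficiency,
          designs$primer_pair_penalty, seq_len(nrow(designs)))
  } else {
    order(-as.integer(designs$specificity_bit), -designs$efficiency,
          designs$seed_frequency, seq_len(nrow(designs)))
  }
  designs <- designs[ord, , drop = FALSE]
  designs$rank <- seq_len(nrow(designs))
  rownames(designs) <- NULL
  designs
}

# count of intervals in `masks` overlapping [s0, e0)
count_overlapping <- function(masks, s0, e0, cause = NULL) {
  if (!nrow(masks)) return(0L)
  m <- masks
  if (!is.null(cause)) m <- m[m$cause == cause, , drop = FALSE]
  sum(m$start0 < e0 & m$end0 > s0)
}

# annotate one amplicon [s0, e0) of a region with its reagent-quality metrics
amplicon_metrics <- function(cands, masks, s0, e0, k, eff_cutoff) {
  sub <- cands[cands$start0 >= s0 & cands$start0 <= e0 - k, , drop = FALSE]
  scored <- sub$efficiency[!is.na(sub$efficiency)]
  list(sirna_total = nrow(sub),
       sirna_on_target = sum(sub$specificity == "1"),
       sirna_off_target = sum(sub$specificity == "0"),
       sirna_no_target = sum(sub$specificity == "no_target"),
       efficient_sirnas = if (length(scored)) sum(scored >= eff_cutoff) else 0L,
       mean_efficiency = if (length(scored)) mean(scored) else NA_real_,
       can_repeats = count_overlapping(masks, s0, e0, "CAN"),
       low_complexity_regions = count_overlapping(masks, s0, e0, "DUST"),
       mirna_seeds = if (!is.null(sub$has_mirna_seed)) sum(sub$has_mirna_seed) else NA_integer_,
       seed_low_frequency = if (!is.null(sub$seed_low_frequency))
         sum(sub$seed_low_frequency, na.rm = TRUE) else NA_integer_)
}

# annotate candidates with all flags/scores needed by the filters
annotate_candidates <- function(region, opts, index = NULL, seeds = NULL,
                                utr_db = NULL, weight_table = NULL) {
  masks <- find_can_repeats(region$sequence, opts$can_min_units)
  if (opts$dust) {
    masks <- rbind(masks, dust_mask(region$sequence, opts$dust_window,
                                    opts$dust_word, opts$dust_cutoff))
  }
  cands <- dice(region, opts$k, opts$offset)
  if (nrow(cands)) {
    cands$in_masked <- vapply(seq_len(nrow(cands)), function(i) {
      count_overlapping(masks, cands$start0[i], cands$start0[i] + opts$k) > 0L
    }, logical(1))
  } else {
    cands$in_masked <- logical(0)
  }
  if (!is.null(index) && nrow(cands)) {
    cands <- classify_specificity(cands, index, opts$both_strands)
  } else {
    cands$specificity <- rep("no_target", nrow(cands))
    cands$n_hit_genes <- rep(0L, nrow(cands))
  }
  cands <- if (nrow(cands)) {
    score_efficiency(cands, opts$efficiency_method, weight_table)
  } else { cands$efficiency <- numeric(0); cands }
  if (!is.null(seeds)) cands <- flag_mirna_seeds(cands, seeds, opts$seed_mode)
  if (!is.null(utr_db)) {
    cands <- seed_frequency(cands, utr_db, opts$seed_mode,
                            opts$seed_frequency_threshold)
  }
  list(cands = cands, masks = masks)
}

#' Design ranked dsRNA reagents for one target region
#'
#' Composes the whole per-target pipeline: dicing, low-complexity flags,
#' specificity classification, efficiency scoring, optional miRNA-seed and
#' seed-frequency annotation, optimal-region finding, optional iterative
#' redesign, primer design and ranking. Off-target specificity is computed
#' relative to the target's own gene: an siRNA whose perfect matches all
#' fall in isoforms of `region$gene_id` is on-target.
#'
#' @param region one-row region table (a common region).
#' @param index `offtarget_index` over the transcriptome.
#' @param opts [design_options()].
#' @param seeds optional miRNA seed vector.
#' @param utr_db optional UTR sequence data.frame (enables seed
#'   frequencies).
#' @param weight_table optional weight table for the weighted method.
#' @return list with `designs` (ranked data.frame, up to `opts$n_designs`
#'   rows) and `failure` (NULL or data.frame `target_id`, `stage`,
#'   `reason`).
#' @export
design_for_target <- function(region, index, opts = design_options(),
                              seeds = NULL, utr_db = NULL,
                              weight_table = NULL) {
  fail_rec <- function(stage, reason) {
    list(designs = empty_design_table(),
         failure = data.frame(target_id = region$region_id, stage = stage,
                              reason = reason, stringsAsFactors = FALSE))
  }
  L <- nchar(region$sequence)
  if (L < opts$k) return(fail_rec("dicing", "query shorter than siRNA length"))
  ann <- annotate_candidates(region, opts, index, seeds, utr_db, weight_table)
  cands <- ann$cands; masks <- ann$masks
  cands$fails <- candidate_fails(cands, opts)
  mask <- query_mask(L, opts$k, cands, masks)
  runs <- unmasked_runs(mask)
  runs <- runs[runs$length >= opts$k, , drop = FALSE]
  if (!nrow(runs)) {
    reason <- if (all(cands$in_masked | cands$contains_n)) "low complexity"
              else if (all(cands$fails) && any(cands$specificity == "0"))
                "off-target homology" else "no optimal sequence"
    return(fail_rec("optimal_region", reason))
  }
  optimal <- runs[runs$length >= opts$window_min, , drop = FALSE]
  if (!nrow(optimal)) {
    if (!opts$redesign) return(fail_rec("optimal_region", "optimal regions too short"))
    merged <- redesign_merge(runs, opts$window_min)
    if (!is.null(merged$failure)) return(fail_rec("redesign", merged$failure))
    optimal <- merged$region
  }
  # candidate amplicons: primer products over every optimal region
  amps <- list()
  for (i in seq_len(nrow(optimal))) {
    tmpl <- subseq0(region$sequence, optimal$start0[i], optimal$end0[i])
    pairs <- design_primers(tmpl, opts, n_pairs = max(opts$n_designs * 3L, 5L))
    if (!nrow(pairs)) next
    pairs$product_start0 <- pairs$product_start0 + optimal$start0[i]
    pairs$product_end0 <- pairs$product_end0 + optimal$start0[i]
    amps[[length(amps) + 1L]] <- pairs
  }
  amps <- do.call(rbind, amps)
  if (is.null(amps) || !nrow(amps)) {
    return(fail_rec("primer_design", "no primer pair within the product window"))
  }
  rows <- vector("list", nrow(amps))
  for (i in seq_len(nrow(amps))) {
    met <- amplicon_metrics(cands, masks, amps$product_start0[i],
                            amps$product_end0[i], opts$k,
                            opts$efficiency_cutoff)
    rows[[i]] <- data.frame(
      design_id = NA_character_, target_gene = region$gene_id,
      region_id = region$region_id, rank = NA_integer_,
      sequence_id = region$sequence_id,
      start0 = if (!is.na(region$start0)) region$start0 + amps$product_start0[i] else NA_integer_,
      end0 = if (!is.na(region$start0)) region$start0 + amps$product_end0[i] else NA_integer_,
      strand = region$strand, amplicon_length = amps$product_length[i],
      sirna_total = met$sirna_total, sirna_on_target = met$sirna_on_target,
      sirna_off_target = met$sirna_off_target,
      sirna_no_target = met$sirna_no_target,
      efficient_sirnas = met$efficient_sirnas,
      mean_efficiency = met$mean_efficiency, can_repeats = met$can_repeats,
      low_complexity_regions = met$low_complexity_regions,
      mirna_seeds = met$mirna_seeds,
      seed_low_frequency = met$seed_low_frequency,
      utr_overlap_bases = NA_integer_, snp_overlap = NA_integer_,
      homology_hits = NA_integer_,
      primer_left = amps$left[i], primer_right = amps$right[i],
      primer_left_tm = amps$left_tm[i], primer_right_tm = amps$right_tm[i],
      primer_left_gc = amps$left_gc[i], primer_right_gc = amps$right_gc[i],
      primer_pair_penalty = amps$pair_penalty[i],
      sequence = subseq0(region$sequence, amps$product_start0[i],
                         amps$product_end0[i]),
      region_offset0 = amps$product_start0[i],
      stringsAsFactors = FALSE)
  }
  designs <- do.call(rbind, rows)
  designs <- rank_designs(designs, "dsrna")
  # keep top n, non-overlapping within the region unless allowed
  picked <- integer(0)
  for (i in seq_len(nrow(designs))) {
    if (length(picked) >= opts$n_designs) break
    if (!opts$allow_overlap && length(picked)) {
      s <- designs$region_offset0[i]; e <- s + designs$amplicon_length[i]
      ps <- designs$region_offset0[picked]
      pe <- ps + designs$amplicon_length[picked]
      if (any(ps < e & pe > s)) next
    }
    picked <- c(picked, i)
  }
  designs <- designs[picked, , drop = FALSE]
  if (!nrow(designs)) {
    return(fail_rec("primer_design", "no non-overlapping amplicon"))
  }
  designs$rank <- seq_len(nrow(designs))
  designs$design_id <- sprintf("%s_d%d", region$region_id, designs$rank)
  rownames(designs) <- NULL
  list(designs = designs, failure = NULL)
}

#' Design ranked single siRNAs for one target region
#'
#' Filters candidates as in dsRNA design and ranks the survivors by
#' specificity bit (descending), efficiency (descending) and seed
#' complement frequency (ascending), returning the top `opts$n_designs`.
#'
#' @inheritParams design_for_target
#' @return list with `designs` (data.frame: `design_id`, `target_gene`,
#'   `region_id`, `rank`, `start0` within region, `sense`, `guide`,
#'   `specificity_bit`, `efficiency`, `seed_frequency`) and `failure`.
#' @export
design_sirnas_for_target <- function(region, index, opts = design_options(),
                                     seeds = NULL, utr_db = NULL,
                                     weight_table = NULL) {
  opts2 <- opts
  opts2$both_strands <- FALSE
  ann <- annotate_candidates(region, opts2, index, seeds, utr_db, weight_table)
  cands <- ann$cands
  if (!nrow(cands)) {
    return(list(designs = NULL,
                failure = data.frame(target_id = region$region_id,
                                     stage = "dicing",
                                     reason = "query shorter than siRNA length",
                                     stringsAsFactors = FALSE)))
  }
  cands$fails <- candidate_fails(cands, opts2)
  keep <- cands[!cands$fails, , drop = FALSE]
  if (!nrow(keep)) {
    return(list(designs = NULL,
                failure = data.frame(target_id = region$region_id,
                                     stage = "filter",
                                     reason = "no candidate passed the filters",
                                     stringsAsFactors = FALSE)))
  }
  keep$specificity_bit <- as.integer(keep$specificity == "1")
  if (is.null(keep$seed_frequency)) keep$seed_frequency <- NA_integer_
  sf <- keep$seed_frequency
  sf[is.na(sf)] <- .Machine$integer.max  # unknown frequency ranks last
  keep$seed_frequency_rankkey <- sf
  ranked <- keep[order(-keep$specificity_bit, -keep$efficiency,
                       keep$seed_frequency_rankkey, seq_len(nrow(keep))), ,
                 drop = FALSE]
  ranked <- utils::head(ranked, opts$n_designs)
  ranked$rank <- seq_len(nrow(ranked))
  out <- data.frame(design_id = sprintf("%s_s%d", region$region_id, ranked$rank),
                    target_gene = region$gene_id, region_id = region$region_id,
                    rank = ranked$rank, start0 = ranked$start0,
                    sense = ranked$sense, guide = ranked$guide,
                    specificity_bit = ranked$specificity_bit,
                    efficiency = ranked$efficiency,
                    seed_frequency = ranked$seed_frequency,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(designs = out, failure = NULL)
}
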