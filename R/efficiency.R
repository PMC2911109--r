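# Predicted siRNA silencing efficiency: the "rational" rule set (eight
# position/composition criteria, raw score in [-2, 10]) and a "weighted"
# position-base scheme driven by a tab-delimited weight table. Both are
# normalized affinely to a 0-100 scale; the conventional cutoffs for an
# "efficient" siRNA are 66.7 (rational) and 63 (weighted). T is treated as
# U throughout (DNA input, RNA rules).

# longest internal reverse-complement stem >= stem_len?
has_internal_stem <- function(sense, stem_len = 4L) {
  L <- nchar(sense)
  if (L < stem_len) return(FALSE)
  starts <- seq_len(L - stem_len + 1L)
  subs <- substring(sense, starts, starts + stem_len - 1L)
  rcs <- revcomp(subs)
  for (i in seq_along(subs)) {
    hits <- gregexpr(rcs[i], sense, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    if (any(hits != i)) return(TRUE)
  }
  FALSE
}

#' Rational siRNA efficiency score
#'
#' Applies the eight-criterion rational rule set to a 19-nt sense strand:
#' \itemize{
#'   \item I: G+C content within 30-52\% (+1)
#'   \item II: +1 for each A/T at sense positions 15-19 when at least 3 of
#'     those positions are A/T (0 otherwise; maximum +5)
#'   \item III: absence of internal repeats, i.e. the longest internal
#'     reverse-complement stem is shorter than `stem_len` bp (+1)
#'   \item IV: A at sense position 19 (+1)
#'   \item V: A at sense position 3 (+1)
#'   \item VI: T at sense position 10 (+1)
#'   \item VII: G or C at sense position 19 (-1)
#'   \item VIII: G at sense position 13 (-1)
#' }
#' The raw score lies in [-2, 10] and is normalized affinely to 0-100 by
#' (raw + 2) / 12 * 100, which places the conventional raw efficiency
#' cutoff of 6 exactly at 66.7.
#'
#' @param sense 19-nt DNA sense strand, no N.
#' @param stem_len internal-repeat stem threshold, bp (default 4).
#' @return list of class `rational_score`: per-criterion `contributions`
#'   (named I..VIII), `raw`, `normalized`.
#' @export
score_rational <- function(sense, stem_len = 4L) {
  if (nchar(sense) != 19L) stop("rational score requires a 19-nt sense strand")
  if (grepl("[^ACGT]", sense)) stop("rational score requires A/C/G/T only")
  b <- strsplit(sense, "", fixed = TRUE)[[1]]
  gc_pct <- 100 * sum(b %in% c("G", "C")) / 19
  at_tail <- sum(b[15:19] %in% c("A", "T"))
  contrib <- c(
    I    = as.numeric(gc_pct >= 30 && gc_pct <= 52),
    II   = if (at_tail >= 3) at_tail else 0,
    III  = as.numeric(!has_internal_stem(sense, stem_len)),
    IV   = as.numeric(b[19] == "A"),
    V    = as.numeric(b[3] == "A"),
    VI   = as.numeric(b[10] == "T"),
    VII  = -as.numeric(b[19] %in% c("G", "C")),
    VIII = -as.numeric(b[13] == "G")
  )
  raw <- sum(contrib)
  structure(list(contributions = contrib, raw = raw,
                 normalized = (raw + 2) / 12 * 100),
            class = "rational_score")
}

#' @export
print.rational_score <- function(x, ...) {
  cat(sprintf("rational efficiency score: raw %g, normalized %.2f\n",
              x$raw, x$normalized))
  cat("  contributions:",
      paste(sprintf("%s=%g", names(x$contributions), x$contributions),
            collapse = " "), "\n")
  invisible(x)
}

#' Load a weight table for the weighted efficiency method
#'
#' The weight table is a tab-delimited file with header
#' `feature  position  base  weight` and rows of kinds `position_base`
#' (weight applies when the sense base at `position` equals `base`),
#' `gc_window` (weight when G+C content is within 30-52\%), `at_15_19`
#' (weight per A/T at sense positions 15-19) and `no_internal_repeat`
#' (weight when no internal reverse-complement stem of >= 4 bp exists),
#' plus footer rows `min_raw` / `max_raw` giving the affine normalization
#' range. The package ships a versioned default table
#' (`inst/extdata/weight_table_v1.tsv`); users may substitute their own.
#'
#' @param path table path; default the shipped table.
#' @return list of class `weight_table`.
#' @export
load_weight_table <- function(path = system.file("extdata", "weight_table_v1.tsv",
                                                 package = "rnaidesign")) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  req <- c("feature", "position", "base", "weight")
  if (!all(req %in% names(tab))) {
    stop("weight table must have columns: ", paste(req, collapse = ", "))
  }
  min_raw <- tab$weight[tab$feature == "min_raw"]
  max_raw <- tab$weight[tab$feature == "max_raw"]
  if (length(min_raw) != 1L || length(max_raw) != 1L) {
    stop("weight table needs exactly one min_raw and one max_raw row")
  }
  if (min_raw == max_raw) stop("degenerate weight table: min_raw == max_raw")
  rules <- tab[!(tab$feature %in% c("min_raw", "max_raw")), , drop = FALSE]
  structure(list(rules = rules, min_raw = min_raw, max_raw = max_raw),
            class = "weight_table")
}

#' Weighted siRNA efficiency score
#'
#' Sums the weights of all satisfied features of the weight table and maps
#' the raw sum affinely onto 0-100 (`min_raw` to 0, `max_raw` to 100,
#' clamped).
#'
#' @param sense 19-nt DNA sense strand, no N.
#' @param table a `weight_table` from [load_weight_table()].
#' @return normalized score in [0, 100].
#' @export
score_weighted <- function(sense, table = load_weight_table()) {
  if (nchar(sense) != 19L) stop("weighted score requires a 19-nt sense strand")
  if (grepl("[^ACGT]", sense)) stop("weighted score requires A/C/G/T only")
  stopifnot(inherits(table, "weight_table"))
  b <- strsplit(sense, "", fixed = TRUE)[[1]]
  gc_pct <- 100 * sum(b %in% c("G", "C")) / 19
  raw <- 0
  for (i in seq_len(nrow(table$rules))) {
    r <- table$rules[i, ]
    raw <- raw + switch(r$feature,
      position_base = if (b[r$position] == r$base) r$weight else 0,
      gc_window = if (gc_pct >= 30 && gc_pct <= 52) r$weight else 0,
      at_15_19 = r$weight * sum(b[15:19] %in% c("A", "T")),
      no_internal_repeat = if (!has_internal_stem(sense)) r$weight else 0,
      stop("unknown weight-table feature: ", r$feature))
  }
  norm <- (raw - table$min_raw) / (table$max_raw - table$min_raw) * 100
  min(100, max(0, norm))
}

#' Score a candidate table
#'
#' Adds an `efficiency` column (0-100) to a candidate table using the
#' selected method; candidates containing N get `NA`.
#'
#' @param cands candidate table from [dice()].
#' @param method `"rational"` or `"weighted"`.
#' @param weight_table weight table for the weighted method.
#' @return `cands` with an `efficiency` column.
#' @export
score_efficiency <- function(cands, method = c("rational", "weighted"),
                             weight_table = NULL) {
  method <- match.arg(method)
  if (method == "weighted" && is.null(weight_table)) {
    weight_table <- load_weight_table()
  }
  cands$efficiency <- vapply(seq_len(nrow(cands)), function(i) {
    if (cands$contains_n[i]) return(NA_real_)
    if (method == "rational") score_rational(cands$sense[i])$normalized
    else score_weighted(cands$sense[i], weight_table)
  }, numeric(1))
  cands
}

#' Summarize efficiency over the siRNAs of a reagent
#'
#' @param scores numeric vector of per-siRNA efficiency scores (0-100).
#' @param cutoff scores at or above this count as efficient.
#' @return list with `mean_efficiency` and `efficient_count`.
#' @export
summarize_efficiency <- function(scores, cutoff) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no scored siRNAs to summarize")
  list(mean_efficiency = mean(scores),
       efficient_count = sum(scores >= cutoff))
}
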