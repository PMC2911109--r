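#' Design options
#'
#' Container for every tunable parameter of the design and evaluation
#' pipeline, with the pipeline defaults: 19-nt siRNAs diced at an offset of
#' 1 nt, CAN repeat filter at 6 tandem units, DUST low-complexity filter
#' (window 64, word 3, cutoff 28), efficiency scoring by the "rational"
#' rule set (cutoff 66.7 on the normalized 0-100 scale; the "weighted"
#' method uses 63), a seed-complement-frequency threshold of 1000, an
#' amplicon length window of 80-250 nt, a common-region split threshold of
#' 700 nt, and a homology E-value threshold of 1e-10.
#'
#' @param k siRNA length in nt.
#' @param offset dicing step in nt.
#' @param can_min_units minimum number of tandem CA[ACGT] trinucleotide
#'   units for the CAN filter.
#' @param dust logical, apply the DUST low-complexity filter.
#' @param dust_window,dust_word,dust_cutoff DUST parameters.
#' @param mirna_seed_filter logical, exclude siRNAs whose guide seed matches
#'   a listed miRNA seed.
#' @param seed_mode `"7mer"` (guide positions 2-8, default) or `"6mer"`
#'   (positions 2-7).
#' @param efficiency_method `"rational"` or `"weighted"`.
#' @param efficiency_cutoff efficiency score (0-100) at or above which an
#'   siRNA counts as efficient; defaults to 66.7 for the rational method and
#'   63 for the weighted method when `NULL`.
#' @param efficiency_filter logical, also use the efficiency cutoff as an
#'   exclusion filter on candidate siRNAs (off by default: the cutoff then
#'   only drives the efficient-siRNA count used in ranking).
#' @param seed_frequency_filter logical, apply the seed-complement-frequency
#'   cutoff (requires a UTR database).
#' @param seed_frequency_threshold counts below this are "low frequency".
#' @param window_min,window_max amplicon (primer product) length window, nt.
#' @param redesign logical, enable the iterative merge of nearby optimal
#'   regions when none is long enough for primer design.
#' @param n_designs maximum number of ranked designs returned per target.
#' @param evalue_max homology-scan E-value threshold.
#' @param split_threshold common regions longer than this are split into two
#'   equal halves, nt.
#' @param both_strands logical, query both orientations of each siRNA
#'   against the off-target database (dsRNA mode); `FALSE` restricts to the
#'   guide-matching orientation for single-siRNA design.
#' @param allow_overlap logical, allow the top-n designs of one target to
#'   overlap each other.
#' @return an object of class `design_options` (a named list).
#' @export
design_options <- function(k = 19L,
                           offset = 1L,
                           can_min_units = 6L,
                           dust = TRUE,
                           dust_window = 64L,
                           dust_word = 3L,
                           dust_cutoff = 28,
                           mirna_seed_filter = FALSE,
                           seed_mode = c("7mer", "6mer"),
                           efficiency_method = c("rational", "weighted"),
                           efficiency_cutoff = NULL,
                           efficiency_filter = FALSE,
                           seed_frequency_filter = FALSE,
                           seed_frequency_threshold = 1000L,
                           window_min = 80L,
                           window_max = 250L,
                           redesign = TRUE,
                           n_designs = 1L,
                           evalue_max = 1e-10,
                           split_threshold = 700L,
                           both_strands = TRUE,
                           allow_overlap = FALSE) {
  seed_mode <- match.arg(seed_mode)
  efficiency_method <- match.arg(efficiency_method)
  if (is.null(efficiency_cutoff)) {
    efficiency_cutoff <- if (efficiency_method == "rational") 200 / 3 else 63
  }
  k <- as.integer(k); offset <- as.integer(offset)
  stopifnot(k >= 1L, offset >= 1L, can_min_units >= 1L,
            window_min <= window_max, n_designs >= 1L,
            efficiency_cutoff >= 0, efficiency_cutoff <= 100,
            split_threshold >= 1L)
  opts <- list(k = k, offset = offset, can_min_units = as.integer(can_min_units),
               dust = isTRUE(dust), dust_window = as.integer(dust_window),
               dust_word = as.integer(dust_word), dust_cutoff = dust_cutoff,
               mirna_seed_filter = isTRUE(mirna_seed_filter),
               seed_mode = seed_mode,
               efficiency_method = efficiency_method,
               efficiency_cutoff = efficiency_cutoff,
               efficiency_filter = isTRUE(efficiency_filter),
               seed_frequency_filter = isTRUE(seed_frequency_filter),
               seed_frequency_threshold = as.integer(seed_frequency_threshold),
               window_min = as.integer(window_min),
               window_max = as.integer(window_max),
               redesign = isTRUE(redesign),
               n_designs = as.integer(n_designs),
               evalue_max = evalue_max,
               split_threshold = as.integer(split_threshold),
               both_strands = isTRUE(both_strands),
               allow_overlap = isTRUE(allow_overlap))
  structure(opts, class = "design_options")
}

#' @export
print.design_options <- function(x, ...) {
  cat("RNAi design options:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = " ")))
  invisible(x)
}

# Keys accepted by an options file, mapped to design_options arguments.
OPTIONS_FILE_KEYS <- c(
  sirna_length = "k", offset = "offset", can_min_units = "can_min_units",
  dust = "dust", dust_window = "dust_window", dust_word = "dust_word",
  dust_cutoff = "dust_cutoff", mirna_seed_filter = "mirna_seed_filter",
  seed_mode = "seed_mode", efficiency_method = "efficiency_method",
  efficiency_cutoff = "efficiency_cutoff",
  efficiency_filter = "efficiency_filter",
  seed_frequency_filter = "seed_frequency_filter",
  seed_frequency_threshold = "seed_frequency_threshold",
  window_min = "window_min", window_max = "window_max",
  redesign = "redesign", n_designs = "n_designs",
  evalue_max = "evalue_max", split_threshold = "split_threshold",
  both_strands = "both_strands", allow_overlap = "allow_overlap")

# Path-valued / run-control keys an options file may also carry.
OPTIONS_FILE_PATH_KEYS <- c("mode", "query_fasta", "exon_table",
                            "transcript_gene", "offtarget_fasta", "utr_fasta",
                            "utr_table", "snp_table", "seed_list",
                            "library_fasta", "library_fasta_b", "out_dir")

#' Parse an options file
#'
#' Reads a `key=value` file (`#` starts a comment) into a validated options
#' profile: a [design_options()] object plus any file paths and the run mode.
#' Unset keys take the documented defaults.
#'
#' @param path options file path.
#' @return a list with elements `options` (class `design_options`), `paths`
#'   (named list of path-valued keys) and `mode`.
#' @export
parse_options <- function(path) {
  if (!file.exists(path)) stop("options file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("options file line %d is not key=value: '%s'", i, ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!(key %in% names(OPTIONS_FILE_KEYS)) && !(key %in% OPTIONS_FILE_PATH_KEYS)) {
      stop(sprintf("unknown options key '%s'; valid keys: %s", key,
                   paste(c(names(OPTIONS_FILE_KEYS), OPTIONS_FILE_PATH_KEYS),
                         collapse = ", ")))
    }
    kv[[key]] <- list(value = val, line = i)
  }
  args <- list()
  numeric_keys <- c("k", "offset", "can_min_units", "dust_window", "dust_word",
                    "dust_cutoff", "efficiency_cutoff",
                    "seed_frequency_threshold", "window_min", "window_max",
                    "n_designs", "evalue_max", "split_threshold")
  logical_keys <- c("dust", "mirna_seed_filter", "efficiency_filter",
                    "seed_frequency_filter",
                    "redesign", "both_strands", "allow_overlap")
  for (key in intersect(names(kv), names(OPTIONS_FILE_KEYS))) {
    arg <- OPTIONS_FILE_KEYS[[key]]
    raw <- kv[[key]]$value
    line <- kv[[key]]$line
    if (arg %in% numeric_keys) {
      val <- suppressWarnings(as.numeric(raw))
      if (is.na(val)) stop(sprintf("line %d: value for '%s' is not numeric: '%s'",
                                   line, key, raw))
    } else if (arg %in% logical_keys) {
      val <- toupper(raw) %in% c("TRUE", "T", "1", "YES", "ON")
      if (!(toupper(raw) %in% c("TRUE", "T", "1", "YES", "ON",
                                "FALSE", "F", "0", "NO", "OFF"))) {
        stop(sprintf("line %d: value for '%s' is not logical: '%s'", line, key, raw))
      }
    } else {
      val <- raw
    }
    args[[arg]] <- val
  }
  paths <- lapply(kv[intersect(names(kv), OPTIONS_FILE_PATH_KEYS)],
                  function(x) x$value)
  mode <- paths$mode %||% "design_dsrna"
  paths$mode <- NULL
  valid_modes <- c("design_dsrna", "design_sirna", "evaluate", "compare")
  if (!(mode %in% valid_modes)) {
    stop("unknown run mode '", mode, "'; valid modes: ",
         paste(valid_modes, collapse = ", "))
  }
  list(options = do.call(design_options, args), paths = paths, mode = mode)
}
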