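# End-to-end run modes over the file-based interface: dsRNA design, siRNA
# design, library evaluation and pairwise library comparison, with the
# tab/FASTA/GFF3/AFF writers, a failed-designs report and a static HTML
# summary.

#' Spliced transcript sequences from a genome and exon table
#'
#' @param genome data.frame from [read_fasta()].
#' @param exons exon table (internal coordinates).
#' @return data.frame of transcript sequences (id, residues, length).
#' @export
spliced_transcripts <- function(genome, exons) {
  gseq <- stats::setNames(genome$residues, genome$id)
  ids <- unique(exons$transcript_id)
  res <- vapply(ids, function(tx) {
    e <- exons[exons$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start0), , drop = FALSE]
    paste(substring(gseq[[e$sequence_id[1]]], e$start0 + 1L, e$end0),
          collapse = "")
  }, character(1))
  data.frame(id = ids, description = "", residues = unname(res),
             length = nchar(unname(res)), stringsAsFactors = FALSE)
}

# design all regions of a prepared region table against an index
design_all <- function(regions, index, opts, seeds = NULL, utr_db = NULL,
                       weight_table = NULL, mode = c("dsrna", "sirna")) {
  mode <- match.arg(mode)
  designs <- list(); failures <- list()
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, , drop = FALSE]
    res <- if (mode == "dsrna") {
      design_for_target(region, index, opts, seeds, utr_db, weight_table)
    } else {
      design_sirnas_for_target(region, index, opts, seeds, utr_db, weight_table)
    }
    if (!is.null(res$failure)) {
      failures[[length(failures) + 1L]] <- res$failure
    }
    if (!is.null(res$designs) && nrow(res$designs)) {
      designs[[length(designs) + 1L]] <- res$designs
    }
  }
  list(designs = if (length(designs)) do.call(rbind, designs) else NULL,
       failed = if (length(failures)) do.call(rbind, failures) else NULL)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# static HTML summary equivalent in content to the main tab file
write_html_summary <- function(designs, failed, out_dir, mode) {
  n_ok <- if (is.null(designs)) 0L else nrow(designs)
  n_fail <- if (is.null(failed)) 0L else nrow(failed)
  n_targets <- length(unique(c(if (n_ok) designs$region_id,
                               if (n_fail) failed$target_id)))
  rows <- ""
  if (n_ok) {
    cols <- intersect(c("design_id", "target_gene", "region_id", "rank",
                        "sirna_total", "sirna_on_target", "sirna_off_target",
                        "sirna_no_target", "efficient_sirnas",
                        "mean_efficiency", "primer_pair_penalty",
                        "specificity_bit", "efficiency", "seed_frequency"),
                      names(designs))
    hdr <- paste0("<tr>", paste0("<th>", cols, "</th>", collapse = ""), "</tr>")
    body <- apply(designs[, cols, drop = FALSE], 1, function(r) {
      paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                            collapse = ""), "</tr>")
    })
    rows <- paste0("<table border='1'>", hdr, paste(body, collapse = ""),
                   "</table>")
  }
  frows <- ""
  if (n_fail) {
    body <- apply(failed, 1, function(r) {
      paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                            collapse = ""), "</tr>")
    })
    frows <- paste0("<table border='1'><tr><th>target</th><th>stage</th>",
                    "<th>reason</th></tr>", paste(body, collapse = ""),
                    "</table>")
  }
  html <- paste0(
    "<html><head><title>RNAi design report</title></head><body>",
    "<h1>RNAi ", html_escape(mode), " report</h1>",
    sprintf("<p>Queried targets: %d; successful designs: %d; failed targets: %d</p>",
            n_targets, n_ok, n_fail),
    "<h2>Designs</h2>", rows,
    "<h2>Failed designs</h2>", frows,
    "</body></html>")
  path <- file.path(out_dir, "summary.html")
  writeLines(html, path)
  path
}

#' Run the pipeline for an options profile
#'
#' Executes the selected run mode end-to-end from the files named in the
#' profile (see [parse_options()]) and writes the result files, the
#' failed-designs report and a static HTML summary into the output
#' directory. A stage error on a single target is logged and the run
#' continues; only configuration errors abort.
#'
#' @param profile list from [parse_options()] (or built by hand: `options`,
#'   `paths`, `mode`).
#' @param out_dir output directory (defaults to `profile$paths$out_dir`).
#' @return list: `mode`, `designs`, `failed`, `files`, plus
#'   mode-specific results (`evaluations`, `comparison`).
#' @export
run_pipeline <- function(profile, out_dir = NULL) {
  opts <- profile$options
  paths <- profile$paths
  mode <- profile$mode
  out_dir <- out_dir %||% paths$out_dir %||% stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  log_line("mode %s", mode)

  tg <- if (!is.null(paths$transcript_gene)) {
    read_feature_table(paths$transcript_gene, "transcript_gene")
  } else NULL
  seeds <- if (!is.null(paths$seed_list)) {
    read_mirna_seeds(paths$seed_list, opts$seed_mode)
  } else NULL
  utr_db <- if (!is.null(paths$utr_fasta)) read_fasta(paths$utr_fasta) else NULL

  if (mode %in% c("design_dsrna", "design_sirna")) {
    if (is.null(tg)) stop("design modes require a transcript_gene table")
    if (!is.null(paths$exon_table)) {
      genome <- read_fasta(paths$query_fasta)
      exons <- read_feature_table(paths$exon_table, "exon")
      models <- gene_models(exons, tg)
      regions <- do.call(rbind, lapply(models, common_regions, genome = genome))
      transcripts <- spliced_transcripts(genome, exons)
    } else {
      transcripts <- read_fasta(paths$query_fasta)
      regions <- transcript_regions(transcripts, tg)
    }
    regions <- split_regions(regions, opts$split_threshold)
    log_line("%d query regions after splitting at %d nt", nrow(regions),
             opts$split_threshold)
    db <- if (!is.null(paths$offtarget_fasta)) read_fasta(paths$offtarget_fasta)
          else transcripts
    index <- build_index(db, tg, opts$k)
    res <- design_all(regions, index, opts, seeds, utr_db,
                      mode = if (mode == "design_dsrna") "dsrna" else "sirna")
    designs <- res$designs; failed <- res$failed
    if (mode == "design_dsrna") {
      files <- write_design_outputs(designs, failed, out_dir)
    } else {
      # siRNA designs: tab + FASTA only (no genome footprint by default)
      files <- c(tab = file.path(out_dir, "results.tab"))
      utils::write.table(designs %||% data.frame(), files[["tab"]],
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(designs) && nrow(designs)) {
        files[["fasta"]] <- file.path(out_dir, "designs.fasta")
        write_fasta(data.frame(id = designs$design_id,
                               residues = designs$sense,
                               stringsAsFactors = FALSE), files[["fasta"]])
      }
      if (!is.null(failed)) {
        files[["failed"]] <- file.path(out_dir, "failed.tab")
        utils::write.table(failed, files[["failed"]], sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
    files[["html"]] <- write_html_summary(designs, failed, out_dir, mode)
    log_line("%d designs, %d failures",
             if (is.null(designs)) 0L else nrow(designs),
             if (is.null(failed)) 0L else nrow(failed))
    return(list(mode = mode, designs = designs, failed = failed,
                files = files))
  }

  if (mode == "evaluate") {
    if (is.null(tg)) stop("evaluate mode requires a transcript_gene table")
    db <- read_fasta(paths$offtarget_fasta)
    index <- build_index(db, tg, opts$k)
    lib <- read_fasta(paths$library_fasta)
    features <- list(
      utr = if (!is.null(paths$utr_table)) read_feature_table(paths$utr_table, "utr") else NULL,
      snp = if (!is.null(paths$snp_table)) read_feature_table(paths$snp_table, "snp") else NULL)
    evals <- evaluate_library(lib, index, opts, library_id = "library",
                              seeds = seeds, utr_db = utr_db,
                              features = features, homology_db = db)
    tab <- evaluation_table(evals)
    path <- file.path(out_dir, "evaluation.tab")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    log_line("%d reagents evaluated", length(evals))
    return(list(mode = mode, evaluations = evals, files = c(tab = path)))
  }

  # compare
  db <- read_fasta(paths$offtarget_fasta)
  if (is.null(tg)) stop("compare mode requires a transcript_gene table")
  index <- build_index(db, tg, opts$k)
  libA <- read_fasta(paths$library_fasta)
  libB <- read_fasta(paths$library_fasta_b)
  evalsA <- evaluate_library(libA, index, opts, library_id = "A")
  evalsB <- evaluate_library(libB, index, opts, library_id = "B")
  cmp <- compare_libraries(evalsA, evalsB, "A", "B")
  tab <- data.frame(libA = cmp$libA, libB = cmp$libB,
                    genes_common = cmp$genes_common,
                    genes_independent = cmp$genes_independent)
  path <- file.path(out_dir, "comparison.tab")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("comparison: %d common, %d independent", cmp$genes_common,
           cmp$genes_independent)
  list(mode = mode, comparison = cmp, files = c(tab = path))
}

#' Flatten evaluation records to a table
#'
#' @param evals list of `evaluation_record`s.
#' @return data.frame with one row per reagent.
#' @export
evaluation_table <- function(evals) {
  rows <- lapply(evals, function(r) {
    data.frame(
      reagent_id = r$reagent_id,
      library_id = r$library_id,
      length = r$length,
      intended_genes = if (length(r$intended_genes))
        paste(r$intended_genes, collapse = ",") else "NA",
      unintended_genes = if (length(r$unintended_genes))
        paste(r$unintended_genes, collapse = ",") else "NA",
      sirna_total = r$sirna_total, sirna_on_target = r$sirna_on_target,
      sirna_off_target = r$sirna_off_target,
      sirna_no_target = r$sirna_no_target,
      can_repeats = r$can_repeats,
      low_complexity_regions = r$low_complexity_regions,
      mirna_seeds = r$mirna_seeds,
      mean_efficiency = r$mean_efficiency,
      efficient_sirnas = r$efficient_sirnas,
      utr_overlap_bases = r$utr_overlap_bases %||% NA_integer_,
      utr_overlap_flag = r$utr_overlap_flag %||% NA,
      snp_overlap = r$snp_overlap %||% NA_integer_,
      homology_hits = r$homology_hits %||% NA_integer_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
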