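## Pipeline orchestration and report generation (cli_report).
##
## Reports always carry counts next to every percentage so that any printed
## number can be recomputed from the same report (audited by
## audit_run_report()).

#' Assemble a pipeline run configuration
#'
#' Inputs may be given as loaded objects or file paths (BED12 for the
#' model, VCF-like tab file for markers, FASTA for the element library).
#'
#' @param bam path to the aligned, RQ-tagged BAM.
#' @param model `transcript_model` or BED12 path.
#' @param amplicon an `amplicon`, a length-2 integer vector
#'   `c(first_exon, last_exon)`, or `NULL` for the full exon range.
#' @param markers marker data.frame, path, or `NULL` to skip phasing.
#' @param elements element library ([Biostrings::DNAStringSet]), FASTA
#'   path, or `NULL` to skip insertion identification.
#' @param outdir output directory.
#' @param rq_threshold,tol,min_insertion_len,display_min_coverage,min_support
#'   stage thresholds (see the stage functions).
#' @param insertion_mode `"cdna"` or `"genomic"`.
#' @param alpha significance level for the allelic-depletion test.
#' @param transcript_id transcript selector when `model` is a file.
#' @param seed RNG seed recorded for provenance (the analysis stages are
#'   deterministic; the seed covers any future resampling extension).
#' @return list of class `run_config`.
#' @export
run_config <- function(bam, model, amplicon = NULL, markers = NULL,
                       elements = NULL, outdir = tempfile("ampliSplice_"),
                       rq_threshold = 0.99, tol = 5, min_insertion_len = 50,
                       display_min_coverage = 0, min_support = 10,
                       insertion_mode = c("cdna", "genomic"), alpha = 0.01,
                       transcript_id = NULL, seed = 1) {
  insertion_mode <- match.arg(insertion_mode)
  if (!file.exists(bam)) stopf("config error: no such BAM: %s", bam)
  if (is.character(model))
    model <- load_transcript_model(model, "BED12", transcript_id)
  if (!is.null(amplicon) && !inherits(amplicon, "amplicon"))
    amplicon <- amplicon(model, amplicon[1], amplicon[2])
  if (is.null(amplicon)) amplicon <- amplicon(model, 1L, n_exons(model))
  if (is.character(markers)) markers <- load_markers(markers, amplicon)
  if (is.character(elements)) elements <- load_element_library(elements)
  for (v in c(rq_threshold)) if (v < 0 || v > 1)
    stopf("config error: rq_threshold outside [0, 1]")
  if (tol < 0 || min_insertion_len < 1 || min_support < 1 ||
      display_min_coverage < 0)
    stopf("config error: threshold outside its documented range")
  structure(list(bam = bam, model = model, amplicon = amplicon,
                 markers = markers, elements = elements, outdir = outdir,
                 rq_threshold = rq_threshold, tol = tol,
                 min_insertion_len = min_insertion_len,
                 display_min_coverage = display_min_coverage,
                 min_support = min_support, insertion_mode = insertion_mode,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes filter -> extract/classify -> quantify -> phase (if markers are
#' configured) -> insertion analysis (if an element library is configured)
#' and writes junction/isoform/allele tables (TSV), an insertion report
#' (JSON), a machine-readable summary (JSON), a text Sashimi rendering and
#' the resolved configuration (YAML) into `config$outdir`. Idempotent for
#' fixed inputs. A stage error is surfaced with the stage name after a
#' partial report has been written.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: list with `counts` (per-stage read
#'   counts), `junction_table`, `allele_summary`, `depletion`,
#'   `insertion_events`, `files`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$counts <- list(input = 0L, rq_pass = 0L, classified = 0L,
                       rejected = 0L, phased_defined = NA_integer_,
                       undefined = NA_integer_, unphaseable = NA_integer_)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      write_partial_summary(config, state, name, conditionMessage(e))
      stopf("stage '%s': %s", name, conditionMessage(e))
    })
  }

  reads <- stage("filter", {
    r <- read_alignments(config$bam)
    state$counts$input <- length(r)
    r <- suppressWarnings(filter_by_rq(r, config$rq_threshold))
    state$counts$rq_pass <- length(r)
    state$counts$rq_missing <- attr(r, "rq_missing")
    if (length(r) == 0L) stopf("no reads after filtering")
    r
  })

  calls <- stage("classify", {
    cl <- classify_reads(reads, config$model, config$amplicon,
                         tol = config$tol,
                         min_insertion_len = config$min_insertion_len)
    state$counts$classified <- nrow(cl)
    state$counts$rejected <- nrow(attr(cl, "rejected"))
    if (nrow(cl) == 0L) stopf("no reads overlap the amplicon")
    cl
  })

  jt <- stage("quantify",
    build_junction_table(calls, reads, config$display_min_coverage))

  asum <- NULL; depletion <- NULL
  if (!is.null(config$markers) && nrow(config$markers) > 0L) {
    phased <- stage("phase", {
      assn <- assign_alleles(reads, config$markers)
      s <- allele_summary(assn, calls)
      state$counts$phased_defined <- s$n_defined
      state$counts$undefined <- s$undefined
      state$counts$unphaseable <- s$unphaseable
      list(summary = s,
           depletion = detect_allelic_depletion(s, alpha = config$alpha))
    })
    asum <- phased$summary
    depletion <- phased$depletion
  }

  events <- list()
  if (!is.null(config$elements)) {
    events <- stage("insertion", {
      ev <- collect_insertion_reads(reads,
                                    min_insertion_len = config$min_insertion_len,
                                    min_support = config$min_support)
      lapply(ev, function(e) {
        e$element_hit <- identify_element(e$consensus, config$elements)
        e$donor_sites <- if (nchar(e$consensus) >= 9L)
          score_donor_sites(e$consensus, top_k = 3) else NULL
        e
      })
    })
  }

  report <- structure(list(counts = state$counts, junction_table = jt,
                           allele_summary = asum, depletion = depletion,
                           insertion_events = events,
                           config = config), class = "run_report")
  report$files <- write_run_report(report, config)
  report$provenance <- report$files$provenance
  report
}

write_partial_summary <- function(config, state, failed_stage, msg) {
  path <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(list(status = "error", failed_stage = failed_stage,
                            error = msg, counts = state$counts),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

write_run_report <- function(report, config) {
  out <- config$outdir
  jt <- report$junction_table
  jx <- jt$junctions
  jx_out <- data.frame(donor_last_base = jx$donor_end,      # 1-based inclusive
                       acceptor_first_base = jx$acceptor_start + 1L,
                       count = jx$count, percentage = jx$percentage,
                       hidden = jx$hidden)
  write.table(jx_out, file.path(out, "junctions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(jt$isoforms, file.path(out, "isoforms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(render_sashimi_counts(jt), file.path(out, "sashimi.txt"))
  files <- list(junctions = "junctions.tsv", isoforms = "isoforms.tsv",
                sashimi = "sashimi.txt")
  if (!is.null(report$allele_summary)) {
    al <- report$allele_summary
    write.table(al$alleles, file.path(out, "alleles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(alleles = al$alleles, undefined = al$undefined,
                              unphaseable = al$unphaseable,
                              n_defined = al$n_defined,
                              wt_split = al$wt_split,
                              by_isoform = al$by_isoform,
                              depletion = report$depletion),
                         file.path(out, "alleles.json"),
                         auto_unbox = TRUE, digits = NA)
    files$alleles <- "alleles.tsv"
  }
  if (length(report$insertion_events)) {
    ev_json <- lapply(report$insertion_events, function(e) {
      h <- e$element_hit
      list(anchor_1based = to1(e$anchor),
           supporting_reads = e$supporting_reads,
           length_stats = as.list(e$length_stats),
           consensus = e$consensus,
           element_hit = if (h$hit) h[c("element", "percent_identity",
                                        "element_span", "consensus_span",
                                        "orientation", "score")]
                         else list(hit = FALSE),
           donor_sites = e$donor_sites)
    })
    jsonlite::write_json(ev_json, file.path(out, "insertions.json"),
                         auto_unbox = TRUE, digits = NA)
    files$insertions <- "insertions.json"
  }
  cfg_list <- list(bam = config$bam,
                   transcript_id = config$model$transcript_id,
                   amplicon = c(config$amplicon$first_exon,
                                config$amplicon$last_exon),
                   rq_threshold = config$rq_threshold, tol = config$tol,
                   min_insertion_len = config$min_insertion_len,
                   display_min_coverage = config$display_min_coverage,
                   min_support = config$min_support,
                   insertion_mode = config$insertion_mode,
                   alpha = config$alpha, seed = config$seed)
  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(cfg_list, cfg_path)
  provenance <- list(package = "ampliSplice",
                     version = as.character(utils::packageVersion("ampliSplice")),
                     config_md5 = unname(tools::md5sum(cfg_path)),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  summary <- list(status = "ok", counts = report$counts,
                  total_reads = jt$total_reads,
                  isoforms = jt$isoforms,
                  junctions = jx_out,
                  alleles = if (!is.null(report$allele_summary))
                    report$allele_summary$alleles,
                  n_insertion_events = length(report$insertion_events),
                  provenance = provenance)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  files$summary <- "summary.json"
  files$config <- "config.yaml"
  files$provenance <- provenance
  files
}

#' @export
print.run_report <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf("<run_report> input %d | RQ-pass %d | classified %d (rejected %d)\n",
              c0$input, c0$rq_pass, c0$classified, c0$rejected))
  top <- head(x$junction_table$isoforms, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-28s %8d  %6.2f%%\n", top$isoform_key[i], top$count[i],
                top$percentage[i]))
  if (!is.null(x$allele_summary)) print(x$allele_summary)
  invisible(x)
}

#' Render junction counts as a text Sashimi summary
#'
#' One arc line per junction at or above `min_coverage`; junctions below
#' the threshold are suppressed from the rendering (they stay in the TSV)
#' and summarized in a trailing line. Rendering is deterministic.
#'
#' @param table a `junction_table`.
#' @param min_coverage display threshold; defaults to the table's.
#' @return character vector of lines (class `sashimi_text`).
#' @export
render_sashimi_counts <- function(table, min_coverage = NULL) {
  if (is.null(min_coverage)) min_coverage <- table$display_min_coverage
  jx <- table$junctions
  header <- sprintf("sashimi junction counts (total reads: %d; min coverage: %d)",
                    table$total_reads, min_coverage)
  shown <- jx[jx$count >= min_coverage, , drop = FALSE]
  lines <- if (nrow(shown)) sprintf(
    "  %9d )~~~~[ %9s reads, %6.2f%% ]~~~~( %-9d",
    shown$donor_end, format(shown$count, big.mark = ","),
    shown$percentage, shown$acceptor_start + 1L) else "  (no junctions to show)"
  hidden <- sum(jx$count < min_coverage)
  structure(c(header, lines,
              if (hidden > 0) sprintf("  [%d junction(s) below min coverage not shown]",
                                      hidden)),
            class = c("sashimi_text", "character"))
}

#' @export
print.sashimi_text <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Audit a run report for internal consistency
#'
#' Verifies that every percentage in the report is reproducible from counts
#' present in the same report and that stage counts are monotone along the
#' filter chain.
#'
#' @param report a `run_report`.
#' @return `TRUE` invisibly, or an error describing the first inconsistency.
#' @export
audit_run_report <- function(report) {
  c0 <- report$counts
  if (!(c0$input >= c0$rq_pass && c0$rq_pass >= c0$classified))
    stopf("stage counts not monotone along the filter chain")
  jt <- report$junction_table
  if (sum(jt$isoforms$count) != jt$total_reads)
    stopf("isoform counts do not sum to the classified total")
  if (any(abs(jt$isoforms$percentage -
                100 * jt$isoforms$count / jt$total_reads) > 1e-9))
    stopf("isoform percentages not reproducible from counts")
  if (nrow(jt$junctions) &&
      any(abs(jt$junctions$percentage -
                100 * jt$junctions$count / jt$total_reads) > 1e-9))
    stopf("junction percentages not reproducible from counts")
  if (!is.null(report$allele_summary)) {
    al <- report$allele_summary
    if (abs(sum(al$alleles$percentage) - 100) > 1e-9)
      stopf("allele percentages do not sum to 100 over defined reads")
    if (any(abs(al$alleles$percentage -
                  100 * al$alleles$count / al$n_defined) > 1e-9))
      stopf("allele percentages not reproducible from counts")
  }
  invisible(TRUE)
}
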