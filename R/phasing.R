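## Allele phasing via in-amplicon heterozygous markers, with the
## artifact-base ("undefined") exclusion rule: reads whose marker base
## matches neither REF nor ALT are reported but never enter allele
## denominators.

#' Assign reads to alleles from marker bases
#'
#' Per marker, a read's observed base votes for the REF-carrying allele,
#' the ALT-carrying allele, or — when it matches neither — an artifact.
#' Reads with unanimous non-artifact votes get that allele; conflicting
#' votes or artifact-only observations yield `undefined`; reads covering no
#' marker are `unphaseable` (kept distinct from `undefined`: absence of an
#' informative variant is not a sequencing artifact).
#'
#' @param reads a `read_set`.
#' @param markers marker data.frame (see [variant_marker()]); at least one.
#' @return object of class `allele_assignments`: data.frame with `read_id`,
#'   `label`, and one observed-base column per marker.
#' @export
assign_alleles <- function(reads, markers) {
  if (is.null(markers) || nrow(markers) == 0L)
    stopf("at least one marker is required for phasing")
  mb <- marker_bases(reads, markers)
  n <- length(reads)
  votes <- matrix(NA_character_, n, nrow(markers))
  artifact <- matrix(FALSE, n, nrow(markers))
  for (t in seq_len(nrow(markers))) {
    b <- mb[, t]
    votes[b == markers$ref_base[t] & !is.na(b), t] <- markers$allele_label_ref[t]
    votes[b == markers$alt_base[t] & !is.na(b), t] <- markers$allele_label_alt[t]
    artifact[, t] <- !is.na(b) & b != markers$ref_base[t] & b != markers$alt_base[t]
  }
  label <- vapply(seq_len(n), function(i) {
    v <- unique(votes[i, !is.na(votes[i, ])])
    if (length(v) == 1L) v
    else if (length(v) > 1L) "undefined"          # conflicting markers
    else if (any(artifact[i, ])) "undefined"      # artifact-only observations
    else "unphaseable"                            # no marker covered
  }, character(1))
  out <- data.frame(read_id = reads$read_id, label = label,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mb, stringsAsFactors = FALSE))
  structure(out, class = c("allele_assignments", "data.frame"),
            allele_labels = sort(unique(c(markers$allele_label_ref,
                                          markers$allele_label_alt))))
}

#' Assign a single read to an allele
#' @param read a `read_set` of length 1.
#' @param markers marker data.frame.
#' @return list of class `allele_assignment` with `read_id`, `label`,
#'   `marker_bases`.
#' @export
assign_allele <- function(read, markers) {
  stopifnot(length(read) == 1L)
  a <- assign_alleles(read, markers)
  structure(list(read_id = a$read_id[1], label = a$label[1],
                 marker_bases = unlist(a[1, -(1:2), drop = FALSE])),
            class = "allele_assignment")
}

#' Summarize allele subpopulations and allele-level splicing
#'
#' Allele percentages are computed over defined reads only (the two allele
#' labels); `undefined` and `unphaseable` reads are reported but excluded
#' from every denominator. Within each allele, isoform keys are partitioned
#' into WT (canonical) versus aberrant splicing.
#'
#' @param assignments an `allele_assignments` object.
#' @param calls an `isoform_calls` object sharing read ids.
#' @return object of class `allele_summary`: list with `alleles`
#'   (data.frame `label`, `count`, `percentage` over defined reads),
#'   `undefined`, `unphaseable` (counts), `by_isoform` (per allele x
#'   isoform key: `count`, `percentage_within_allele`) and `wt_split` (per
#'   allele: WT vs aberrant counts and within-allele percentages).
#' @export
allele_summary <- function(assignments, calls) {
  idx <- match(assignments$read_id, calls$read_id)
  merged <- data.frame(label = assignments$label,
                       isoform_key = calls$isoform_key[idx],
                       canonical = calls$canonical[idx],
                       stringsAsFactors = FALSE)
  merged <- merged[!is.na(merged$isoform_key), , drop = FALSE]
  labels <- attr(assignments, "allele_labels")
  defined <- merged[merged$label %in% labels, , drop = FALSE]
  if (nrow(defined) == 0L)
    stopf("no defined reads: every read is undefined or unphaseable")
  cnt <- vapply(labels, function(l) sum(defined$label == l), integer(1))
  alleles <- data.frame(label = labels, count = cnt,
                        percentage = 100 * cnt / nrow(defined),
                        stringsAsFactors = FALSE)
  by_iso <- as.data.frame(table(label = defined$label,
                                isoform_key = defined$isoform_key),
                          stringsAsFactors = FALSE)
  names(by_iso)[names(by_iso) == "Freq"] <- "count"
  by_iso <- by_iso[by_iso$count > 0L, , drop = FALSE]
  by_iso$percentage_within_allele <-
    100 * by_iso$count / cnt[match(by_iso$label, labels)]
  rownames(by_iso) <- NULL
  wt <- do.call(rbind, lapply(labels, function(l) {
    sub <- defined[defined$label == l, , drop = FALSE]
    data.frame(label = l, wt_count = sum(sub$canonical),
               aberrant_count = sum(!sub$canonical),
               wt_percentage = if (nrow(sub)) 100 * mean(sub$canonical) else NA,
               aberrant_percentage = if (nrow(sub)) 100 * mean(!sub$canonical)
               else NA, stringsAsFactors = FALSE)
  }))
  structure(list(alleles = alleles,
                 undefined = sum(merged$label == "undefined"),
                 unphaseable = sum(merged$label == "unphaseable"),
                 n_defined = nrow(defined),
                 by_isoform = by_iso, wt_split = wt),
            class = "allele_summary")
}

#' @export
print.allele_summary <- function(x, ...) {
  cat(sprintf("<allele_summary> %d defined reads (%s); undefined %d, unphaseable %d\n",
              x$n_defined,
              paste(sprintf("%s %.2f%%", x$alleles$label, x$alleles$percentage),
                    collapse = ", "),
              x$undefined, x$unphaseable))
  invisible(x)
}

#' Flag allelic depletion
#'
#' Compares each allele's defined-read fraction against an expected
#' fraction (default 0.5, the balanced-expression null) with a two-sided
#' exact binomial test and attaches a qualitative flag: `absent` (0 reads),
#' `near_absent` (below `near_absent_frac`, default 1%), `skewed`
#' (`p < alpha`), else `balanced`. The test and the 1% threshold are
#' reporting conveniences of this package, not published cutoffs.
#'
#' @param summary an `allele_summary`.
#' @param expected expected fraction per allele under the null.
#' @param alpha significance level (default 0.01).
#' @param near_absent_frac fraction below which an allele is `near_absent`.
#' @return data.frame `label`, `count`, `fraction`, `p_value`, `flag`.
#' @export
detect_allelic_depletion <- function(summary, expected = 0.5, alpha = 0.01,
                                     near_absent_frac = 0.01) {
  n <- summary$n_defined
  if (n < 1L) stopf("no defined reads")
  out <- summary$alleles
  out$fraction <- out$count / n
  out$p_value <- vapply(out$count, function(k)
    stats::binom.test(k, n, p = expected)$p.value, numeric(1))
  out$flag <- ifelse(out$count == 0L, "absent",
              ifelse(out$fraction < near_absent_frac, "near_absent",
              ifelse(out$p_value < alpha, "skewed", "balanced")))
  out$percentage <- NULL
  out
}
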