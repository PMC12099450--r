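## Splicing deviations: the shared vocabulary between the read generator and
## the classifier. A read's isoform is the (possibly empty) set of deviations
## from the canonical exon chain of the amplicon.

#' Splicing deviation constructors
#'
#' A splicing deviation describes one way a read departs from the canonical
#' exon structure of the transcript amplicon:
#'
#' * `dev_exon_skip(exons)` — one or more *adjacent* exons absent from the
#'   read. Adjacent skipped exons form a single co-skip deviation, so
#'   skipping exons 16 and 17 together is one event, distinct from two
#'   independent single skips.
#' * `dev_pseudoexon(start, end)` — an intron-internal segment included in
#'   the mRNA (cryptic-splice-site activation), given as a 0-based half-open
#'   genomic interval strictly inside an intron.
#' * `dev_exon_truncation(exon, delta_bp, side)` — a junction sharing one
#'   canonical boundary while the other is displaced `delta_bp` *into* the
#'   exon (`side` is `"donor"` or `"acceptor"` in transcript orientation).
#' * `dev_exon_elongation(exon, delta_bp, side)` — as above but displaced
#'   into the intron.
#' * `dev_insertion(anchor, length, payload)` — a novel sequence of
#'   `length` bp inserted at genomic position `anchor` (0-based, the
#'   reference base immediately left of the insertion point). `payload`
#'   optionally names an entry of a scenario's `insertion_payloads` (used by
#'   the generator only).
#'
#' @param exons integer vector of adjacent exon numbers (transcript order).
#' @param start,end 0-based half-open genomic interval.
#' @param exon exon number.
#' @param delta_bp positive displacement in bp.
#' @param side `"donor"` or `"acceptor"`.
#' @param anchor 0-based genomic anchor position.
#' @param length insertion length in bp (may be `NA` in generator specs when
#'   a `payload` determines it).
#' @param payload optional payload name (generator only).
#' @return A list of class `splice_deviation`.
#' @examples
#' dev_exon_skip(c(16, 17))
#' dev_exon_elongation(2, 39, "donor")
#' @name splice_deviation
NULL

new_deviation <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "splice_deviation")
}

#' @rdname splice_deviation
#' @export
dev_exon_skip <- function(exons) {
  exons <- sort(as.integer(exons))
  if (length(exons) == 0L) stopf("exon_skip needs at least one exon")
  if (length(exons) > 1L && any(diff(exons) != 1L))
    stopf("co-skipped exons must be adjacent; got %s",
          paste(exons, collapse = ","))
  new_deviation("exon_skip", exons = exons)
}

#' @rdname splice_deviation
#' @export
dev_pseudoexon <- function(start, end) {
  if (end <= start) stopf("pseudoexon interval is empty")
  new_deviation("pseudoexon", start = as.integer(start), end = as.integer(end))
}

#' @rdname splice_deviation
#' @export
dev_exon_truncation <- function(exon, delta_bp, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  if (delta_bp <= 0) stopf("delta_bp must be positive")
  new_deviation("exon_truncation", exon = as.integer(exon),
                delta_bp = as.integer(delta_bp), side = side)
}

#' @rdname splice_deviation
#' @export
dev_exon_elongation <- function(exon, delta_bp, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  if (delta_bp <= 0) stopf("delta_bp must be positive")
  new_deviation("exon_elongation", exon = as.integer(exon),
                delta_bp = as.integer(delta_bp), side = side)
}

#' @rdname splice_deviation
#' @export
dev_insertion <- function(anchor, length = NA_integer_, payload = NULL) {
  new_deviation("insertion", anchor = as.integer(anchor),
                length = as.integer(length), payload = payload)
}

#' Canonical serialization of a deviation (set)
#'
#' `dev_key()` serializes one deviation; `devs_key()` serializes a set
#' (sorted, `|`-joined), yielding identical keys for identical sets. The
#' empty set serializes to `"canonical"`. Positions in keys are 1-based for
#' readability.
#'
#' @param dev a `splice_deviation`.
#' @param devs a list of `splice_deviation`s (possibly empty).
#' @return character scalar.
#' @export
dev_key <- function(dev) {
  switch(dev$kind,
    exon_skip = paste0("skip:", paste(dev$exons, collapse = "+")),
    pseudoexon = sprintf("pe:%d-%d", to1(dev$start), dev$end),
    exon_truncation = sprintf("trunc:%d:%s:%d", dev$exon, dev$side, dev$delta_bp),
    exon_elongation = sprintf("elong:%d:%s:%d", dev$exon, dev$side, dev$delta_bp),
    insertion = sprintf("ins:%d:%d", to1(dev$anchor), dev$length),
    stopf("unknown deviation kind '%s'", dev$kind))
}

#' @rdname dev_key
#' @export
devs_key <- function(devs) {
  if (length(devs) == 0L) return("canonical")
  paste(sort(vapply(devs, dev_key, character(1))), collapse = "|")
}

#' Human-readable description of a deviation set
#' @param devs list of `splice_deviation`s.
#' @return character scalar.
#' @export
devs_describe <- function(devs) {
  if (length(devs) == 0L) return("canonical (WT) splicing")
  one <- function(d) switch(d$kind,
    exon_skip = if (length(d$exons) > 1L)
      sprintf("co-skipping of exons %s", paste(d$exons, collapse = " and "))
    else sprintf("skipping of exon %d", d$exons),
    pseudoexon = sprintf("pseudoexon inclusion (%d nt, %d-%d)",
                         d$end - d$start, to1(d$start), d$end),
    exon_truncation = sprintf("truncation of exon %d (%d bp, %s side)",
                              d$exon, d$delta_bp, d$side),
    exon_elongation = sprintf("elongation of exon %d (%d bp, %s side)",
                              d$exon, d$delta_bp, d$side),
    insertion = sprintf("insertion of %d nt after position %d",
                        d$length, to1(d$anchor)))
  paste(sort(vapply(devs, one, character(1))), collapse = "; ")
}

#' @export
print.splice_deviation <- function(x, ...) {
  cat("<splice_deviation>", dev_key(x), "\n")
  invisible(x)
}

## Check mutual compatibility of a deviation set (no two deviations claiming
## the same exon); used when validating isoform specs.
check_deviation_compat <- function(devs) {
  claimed <- unlist(lapply(devs, function(d)
    switch(d$kind, exon_skip = d$exons,
           exon_truncation = , exon_elongation = d$exon, integer(0))))
  if (anyDuplicated(claimed))
    stopf("incompatible deviations: exon %d claimed twice",
          claimed[duplicated(claimed)][1])
  invisible(TRUE)
}
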