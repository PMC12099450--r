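## Core splice-analysis engine: classify reads into isoform categories
## against the transcript model and quantify events with the junction-read
## percentage formula.

## Decompose one alignment geometry into splicing deviations.
classify_geom <- function(g, model, amp, tol, min_insertion_len) {
  ex <- amplicon_exons(amp)
  strand <- model$strand
  blocks <- g$blocks
  nb <- nrow(blocks)
  devs <- list()
  add <- function(d) devs[[length(devs) + 1L]] <<- d

  ## exon x block overlaps
  ov_ex <- lapply(seq_len(nrow(ex)), function(i)
    which(blocks[, "start"] < ex$end[i] & blocks[, "end"] > ex$start[i]))
  ov_bl <- lapply(seq_len(nb), function(b)
    which(ex$start < blocks[b, "end"] & ex$end > blocks[b, "start"]))

  ## exon skips: absent exons, adjacent ones merged into one co-skip
  absent <- sort(ex$exon[lengths(ov_ex) == 0L])
  if (length(absent)) {
    runs <- split(absent, cumsum(c(1L, diff(absent) != 1L)))
    for (r in runs) add(dev_exon_skip(r))
  }

  ## pseudoexons: blocks with no exon overlap, fully inside an intron
  span <- amplicon_span(amp)
  for (b in which(lengths(ov_bl) == 0L)) {
    s <- blocks[b, "start"]; e <- blocks[b, "end"]
    if (s >= span["start"] && e <= span["end"]) add(dev_pseudoexon(s, e))
  }

  ## intron retention (a block bridging consecutive exons) is represented as
  ## a donor-side elongation across the full retained intron
  for (b in seq_len(nb)) {
    exs <- ov_bl[[b]]
    if (length(exs) >= 2L) for (j in seq_len(length(exs) - 1L)) {
      i1 <- exs[j]; i2 <- exs[j + 1L]
      donor_exon <- if (strand == "+") ex$exon[i1] else ex$exon[i2]
      add(dev_exon_elongation(donor_exon, ex$start[i2] - ex$end[i1], "donor"))
    }
  }

  ## junction-adjacent block edges vs canonical exon boundaries
  for (b in seq_len(nb)) {
    exs <- ov_bl[[b]]
    if (!length(exs)) next  # pseudoexon block: captured above
    if (b > 1L) {  # left edge faces a junction
      i <- exs[1]
      diff <- blocks[b, "start"] - ex$start[i]
      if (abs(diff) > tol) {
        side <- if (strand == "+") "acceptor" else "donor"
        add(if (diff > 0) dev_exon_truncation(ex$exon[i], diff, side)
            else dev_exon_elongation(ex$exon[i], -diff, side))
      }
    }
    if (b < nb) {  # right edge faces a junction
      i <- exs[length(exs)]
      diff <- blocks[b, "end"] - ex$end[i]
      if (abs(diff) > tol) {
        side <- if (strand == "+") "donor" else "acceptor"
        add(if (diff < 0) dev_exon_truncation(ex$exon[i], -diff, side)
            else dev_exon_elongation(ex$exon[i], diff, side))
      }
    }
  }

  ## insertion operations of at least min_insertion_len; shorter ones are
  ## treated as indel noise and ignored
  if (nrow(g$ins)) for (t in which(g$ins$len >= min_insertion_len))
    add(dev_insertion(g$ins$boundary[t], g$ins$len[t]))

  devs
}

#' Classify reads into isoform calls
#'
#' Each read's alignment geometry is decomposed into splicing deviations
#' jointly: an expected exon with no overlapping aligned block is an exon
#' skip (adjacent skipped exons merge into one co-skip); a block fully
#' inside an intron is a pseudoexon; a junction sharing one canonical
#' boundary with the other end displaced more than `tol` bp into an exon is
#' a truncation, into an intron an elongation; an insertion operation of at
#' least `min_insertion_len` bp is an insertion deviation (shorter ones are
#' ignored as indel noise). Deviation sets compose, so a read may carry e.g.
#' an exon elongation plus an insertion. Reads whose aligned span does not
#' overlap the amplicon are rejected with a counted reason (attribute
#' `rejected`). Classification is a pure function of
#' `(read, model, tol, min_insertion_len)`.
#'
#' @param reads a `read_set`.
#' @param model a `transcript_model`.
#' @param amplicon an `amplicon`; `NULL` means the full exon range.
#' @param tol junction-matching tolerance in bp applied to both junction
#'   ends independently (default 5; absorbs aligner jitter without merging
#'   distinct events).
#' @param min_insertion_len minimal insertion length in bp (default 50).
#' @return object of class `isoform_calls`: a data.frame with columns
#'   `read_id`, `isoform_key`, `canonical`, `n_deviations`; attribute
#'   `deviation_sets` maps each `isoform_key` to its deviation list and
#'   attribute `rejected` lists excluded reads.
#' @export
classify_reads <- function(reads, model, amplicon = NULL, tol = 5,
                           min_insertion_len = 50) {
  if (is.null(amplicon)) amplicon <- amplicon(model, 1L, n_exons(model))
  geometry <- read_geometry(reads)
  span <- amplicon_span(amplicon)
  keys <- character(0); devsets <- list()
  geom_key <- character(length(geometry$geoms))
  geom_reject <- logical(length(geometry$geoms))
  names(geom_key) <- names(geometry$geoms)
  for (k in names(geometry$geoms)) {
    g <- geometry$geoms[[k]]
    lo <- min(g$blocks[, "start"]); hi <- max(g$blocks[, "end"])
    if (hi <= span["start"] || lo >= span["end"]) {
      geom_reject[match(k, names(geometry$geoms))] <- TRUE
      geom_key[k] <- NA_character_
      next
    }
    devs <- classify_geom(g, model, amplicon, tol, min_insertion_len)
    key <- devs_key(devs)
    if (is.null(devsets[[key]])) devsets[[key]] <- devs
    geom_key[k] <- key
  }
  key_per_read <- geom_key[geometry$key]
  rejected <- is.na(key_per_read)
  calls <- data.frame(read_id = reads$read_id[!rejected],
                      isoform_key = unname(key_per_read[!rejected]),
                      stringsAsFactors = FALSE)
  calls$canonical <- calls$isoform_key == "canonical"
  calls$n_deviations <- vapply(devsets[calls$isoform_key], length, integer(1))
  structure(calls, class = c("isoform_calls", "data.frame"),
            deviation_sets = devsets,
            rejected = data.frame(
              read_id = reads$read_id[rejected],
              reason = rep("no_amplicon_overlap", sum(rejected)),
              stringsAsFactors = FALSE))
}

#' Classify a single read
#'
#' @inheritParams classify_reads
#' @param read a `read_set` of length 1.
#' @return list of class `isoform_call` with `read_id`, `deviations`,
#'   `canonical`, `isoform_key`.
#' @export
classify_read <- function(read, model, amplicon = NULL, tol = 5,
                          min_insertion_len = 50) {
  stopifnot(length(read) == 1L)
  calls <- classify_reads(read, model, amplicon, tol, min_insertion_len)
  if (nrow(calls) == 0L)
    stopf("read %s rejected: %s", read$read_id,
          attr(calls, "rejected")$reason[1])
  key <- calls$isoform_key[1]
  structure(list(read_id = calls$read_id[1],
                 deviations = attr(calls, "deviation_sets")[[key]],
                 canonical = calls$canonical[1], isoform_key = key),
            class = "isoform_call")
}

#' @export
print.isoform_call <- function(x, ...) {
  cat(sprintf("<isoform_call> %s: %s\n", x$read_id, x$isoform_key))
  invisible(x)
}

#' Junction-read percentage
#'
#' The quantification formula of the pipeline:
#' `(number of reads covering a specific exon-exon junction / total number
#' of reads) x 100%`.
#'
#' @param junction_reads reads whose junction chain contains the junction.
#' @param total_reads denominator (all classified reads); must be >= 1.
#' @return percentage in `[0, 100]`.
#' @examples
#' junction_percentage(149, 1000)  # 14.9
#' @export
junction_percentage <- function(junction_reads, total_reads) {
  if (total_reads == 0L)
    stopf("undefined junction percentage: total_reads is 0")
  if (total_reads < 0L || junction_reads < 0L || junction_reads > total_reads)
    stopf("need 0 <= junction_reads <= total_reads")
  100 * junction_reads / total_reads
}

#' Tabulate junction coverage and isoform abundances
#'
#' Counts, for every observed junction, the reads whose chain contains that
#' exact junction (Sashimi-arc semantics), and tabulates every isoform key's
#' read count and percentage (denominator: all classified reads). Junctions
#' below `display_min_coverage` are flagged `hidden` — suppressed from
#' Sashimi-style renderings — but retained in the table.
#'
#' @param calls an `isoform_calls` object.
#' @param reads the `read_set` the calls were derived from (same ids).
#' @param display_min_coverage display threshold in reads (default 0).
#' @return object of class `junction_table`: list with `junctions`
#'   (data.frame `donor_end`, `acceptor_start`, `count`, `percentage`,
#'   `hidden`), `isoforms` (data.frame `isoform_key`, `description`,
#'   `count`, `percentage`) and `total_reads`.
#' @export
build_junction_table <- function(calls, reads, display_min_coverage = 0) {
  idx <- match(calls$read_id, reads$read_id)
  if (anyNA(idx)) stopf("calls and reads carry mismatched read ids")
  sub <- reads[idx]
  geometry <- read_geometry(sub)
  tallies <- new.env(parent = emptyenv())
  counts <- table(geometry$key)
  for (k in names(geometry$geoms)) {
    sk <- geometry$geoms[[k]]$skips
    if (!nrow(sk)) next
    w <- counts[[k]]
    for (r in seq_len(nrow(sk))) {
      jk <- sprintf("%d:%d", sk[r, 1], sk[r, 2])
      tallies[[jk]] <- (tallies[[jk]] %||% 0L) + w
    }
  }
  jkeys <- ls(tallies)
  total <- nrow(calls)
  if (length(jkeys)) {
    parts <- do.call(rbind, strsplit(jkeys, ":", fixed = TRUE))
    junctions <- data.frame(donor_end = as.integer(parts[, 1]),
                            acceptor_start = as.integer(parts[, 2]),
                            count = vapply(jkeys, function(k)
                              as.integer(tallies[[k]]), integer(1)))
    junctions <- junctions[order(junctions$donor_end,
                                 junctions$acceptor_start), , drop = FALSE]
    rownames(junctions) <- NULL
    junctions$percentage <- vapply(junctions$count, junction_percentage,
                                   numeric(1), total_reads = total)
    junctions$hidden <- junctions$count < display_min_coverage
  } else {
    junctions <- data.frame(donor_end = integer(0), acceptor_start = integer(0),
                            count = integer(0), percentage = numeric(0),
                            hidden = logical(0))
  }
  iso_counts <- sort(table(calls$isoform_key), decreasing = TRUE)
  devsets <- attr(calls, "deviation_sets")
  isoforms <- data.frame(isoform_key = names(iso_counts),
                         description = vapply(names(iso_counts), function(k)
                           devs_describe(devsets[[k]]), character(1)),
                         count = as.integer(iso_counts),
                         stringsAsFactors = FALSE)
  isoforms$percentage <- 100 * isoforms$count / total
  rownames(isoforms) <- NULL
  structure(list(junctions = junctions, isoforms = isoforms,
                 total_reads = total,
                 display_min_coverage = display_min_coverage),
            class = "junction_table")
}

#' @export
print.junction_table <- function(x, ...) {
  cat(sprintf("<junction_table> %d junctions, %d isoforms, %d reads\n",
              nrow(x$junctions), nrow(x$isoforms), x$total_reads))
  invisible(x)
}

#' Check that a deep-intronic variant rides on pseudoexon reads
#'
#' Among reads that include the given pseudoexon (a block matching the
#' interval within `tol` at both ends), returns the fraction whose base at
#' the variant position is the ALT base. When no read contains the
#' pseudoexon the result is an explicit empty-set record (`fraction = NA`),
#' not zero.
#'
#' @param reads a `read_set`.
#' @param pseudoexon 0-based half-open genomic interval `c(start, end)`.
#' @param variant one-row marker data.frame (see [variant_marker()]); its
#'   position must lie inside the pseudoexon.
#' @param tol boundary tolerance in bp.
#' @return list of class `pe_check`: `n_pseudoexon_reads`, `n_alt`,
#'   `fraction`, `empty`.
#' @export
variant_in_pseudoexon_check <- function(reads, pseudoexon, variant, tol = 5) {
  if (!(variant$pos >= pseudoexon[1] && variant$pos < pseudoexon[2]))
    stopf("variant position is not inside the pseudoexon interval")
  geometry <- read_geometry(reads)
  has_pe <- logical(length(reads))
  for (k in names(geometry$geoms)) {
    g <- geometry$geoms[[k]]
    hit <- any(abs(g$blocks[, "start"] - pseudoexon[1]) <= tol &
                 abs(g$blocks[, "end"] - pseudoexon[2]) <= tol)
    if (hit) has_pe[geometry$key == k] <- TRUE
  }
  n <- sum(has_pe)
  if (n == 0L)
    return(structure(list(n_pseudoexon_reads = 0L, n_alt = 0L,
                          fraction = NA_real_, empty = TRUE),
                     class = "pe_check"))
  bases <- base_at(reads[which(has_pe)], variant$pos)
  n_alt <- sum(bases == variant$alt_base, na.rm = TRUE)
  structure(list(n_pseudoexon_reads = n, n_alt = n_alt,
                 fraction = n_alt / n, empty = FALSE),
            class = "pe_check")
}
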