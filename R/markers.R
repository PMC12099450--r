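## Heterozygous variant markers used for allele phasing, plus the
## mobile-element FASTA library (models_io).

#' Construct a variant marker
#'
#' A single-nucleotide heterozygous marker inside the amplicon, used to
#' assign reads to alleles. `allele_label_ref`/`allele_label_alt` name which
#' allele carries the REF/ALT base.
#'
#' @param chrom chromosome.
#' @param pos 0-based genomic position.
#' @param ref_base,alt_base single characters, distinct.
#' @param allele_label_ref,allele_label_alt allele names.
#' @param hgvs_label display label (e.g. HGVS-style), optional.
#' @return one-row data.frame; marker sets are data.frames with these columns.
#' @export
variant_marker <- function(chrom, pos, ref_base, alt_base,
                           allele_label_ref = "allele2",
                           allele_label_alt = "allele1",
                           hgvs_label = NA_character_) {
  if (nchar(ref_base) != 1L || nchar(alt_base) != 1L || ref_base == alt_base)
    stopf("marker REF/ALT must be distinct single bases")
  data.frame(chrom = chrom, pos = as.integer(pos),
             ref_base = toupper(ref_base), alt_base = toupper(alt_base),
             allele_label_ref = allele_label_ref,
             allele_label_alt = allele_label_alt,
             hgvs_label = hgvs_label, stringsAsFactors = FALSE)
}

#' Load phasing markers from a VCF-like tab file
#'
#' The file is a headerless (or `#`-commented) tab table with columns
#' `CHROM POS ID REF ALT [INFO]`; `POS` is 1-based as in VCF. The INFO key
#' `ALLELES=<label_for_REF>,<label_for_ALT>` names the alleles; it defaults
#' to `allele2,allele1` (ALT marks allele 1, as when the known pathogenic
#' missense variant tags allele 1). Only SNV markers are supported:
#' multi-allelic or indel records are rejected. Markers outside the
#' amplicon's genomic span are dropped with a warning.
#'
#' @param path file path.
#' @param amplicon an `amplicon` (defines the retained genomic span).
#' @return data.frame of markers (see [variant_marker()]), possibly 0-row.
#' @export
load_markers <- function(path, amplicon) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("CHROM", "POS", "ID", "REF", "ALT", "INFO")[1:6],
                    fill = TRUE)
  if (nrow(tab) == 0L) return(variant_marker("x", 0, "A", "C")[0, ])
  bad <- nchar(tab$REF) != 1L | nchar(tab$ALT) != 1L | grepl(",", tab$ALT)
  if (any(bad))
    stopf("marker %s %d %s>%s rejected: SNV markers only (single REF/ALT base)",
          tab$CHROM[bad][1], tab$POS[bad][1], tab$REF[bad][1], tab$ALT[bad][1])
  info <- as.character(tab$INFO %||% "")
  lab <- regmatches(info, regexec("ALLELES=([^;,]+),([^;]+)", info))
  ref_lab <- vapply(lab, function(m) if (length(m) == 3L) m[2] else "allele2",
                    character(1))
  alt_lab <- vapply(lab, function(m) if (length(m) == 3L) m[3] else "allele1",
                    character(1))
  mk <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    variant_marker(tab$CHROM[i], tab$POS[i] - 1L, tab$REF[i], tab$ALT[i],
                   ref_lab[i], alt_lab[i], tab$ID[i])))
  span <- amplicon_span(amplicon)
  inside <- mk$chrom == amplicon$model$chrom &
    mk$pos >= span["start"] & mk$pos < span["end"]
  if (any(!inside))
    warnf("%d marker(s) outside the amplicon span dropped", sum(!inside))
  mk[inside, , drop = FALSE]
}

#' Write markers to the VCF-like tab format read by [load_markers()]
#' @param markers marker data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\tALLELES=%s,%s",
                   markers$chrom, to1(markers$pos),
                   ifelse(is.na(markers$hgvs_label), ".", markers$hgvs_label),
                   markers$ref_base, markers$alt_base,
                   markers$allele_label_ref, markers$allele_label_alt)
  writeLines(c("#CHROM\tPOS\tID\tREF\tALT\tINFO", lines), path)
  invisible(path)
}

#' Load a mobile-element library from FASTA
#'
#' Sequences are upper-cased and validated against the `{A,C,G,T,N}`
#' alphabet; duplicate entry names are rejected.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
load_element_library <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lib <- Biostrings::readDNAStringSet(path)
  if (length(lib) == 0L) stopf("empty element library: %s", path)
  names(lib) <- sub("\\s.*$", "", names(lib))
  if (anyDuplicated(names(lib)))
    stopf("duplicate element name '%s'", names(lib)[duplicated(names(lib))][1])
  lib <- Biostrings::DNAStringSet(toupper(lib))
  if (any(Biostrings::width(lib) == 0L)) stopf("empty element sequence")
  bad <- Biostrings::alphabetFrequency(lib, baseOnly = TRUE)[, "other"] -
    Biostrings::letterFrequency(lib, "N")
  if (any(bad > 0)) stopf("element sequences must use alphabet {A,C,G,T,N}")
  lib
}
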