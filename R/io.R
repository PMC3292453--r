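# Readers and writers for the pipeline's external formats. Coordinates are
# 0-based half-open internally; BED exports keep that convention, GFF3 and the
# RepeatMasker-style .out table are 1-based inclusive.

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings with the package's conventions (no line
#' wrapping surprises, names kept verbatim).
#'
#' @param file path.
#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @return `read_fasta` returns a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(file) Biostrings::readDNAStringSet(file)

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, file) {
  Biostrings::writeXStringSet(as_dna_set(seqs), file)
  invisible(file)
}

#' Write a TE family library as FASTA
#'
#' Headers carry the class and provenance:
#' `>RS0001 class=LTR source=de_novo`.
#'
#' @param library a `te_library`.
#' @param file path.
#' @export
write_library_fasta <- function(library, file) {
  seqs <- Biostrings::DNAStringSet(library$consensus)
  names(seqs) <- sprintf("%s class=%s source=%s", library$family_id,
                         library$te_class, library$source)
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' Read a TE family library from FASTA
#'
#' Accepts plain headers (first word = family id) or the annotated headers of
#' [write_library_fasta()]; `class=`/`source=` tags are parsed when present.
#'
#' @param file path.
#' @param default_source provenance for entries without a `source=` tag.
#' @return a `te_library`.
#' @export
read_library_fasta <- function(file, default_source = "known") {
  seqs <- Biostrings::readDNAStringSet(file)
  hdr <- names(seqs)
  id <- sub("\\s.*$", "", hdr)
  grab <- function(tag, default) {
    m <- regmatches(hdr, regexpr(paste0(tag, "=\\S+"), hdr))
    out <- rep(default, length(hdr))
    hit <- grepl(paste0(tag, "="), hdr)
    out[hit] <- sub(paste0("^.*", tag, "="), "",
                    regmatches(hdr, regexpr(paste0(tag, "=\\S+"), hdr)))
    out
  }
  lib <- data.frame(family_id = id,
                    te_class = grab("class", NA_character_),
                    source = grab("source", default_source),
                    consensus = unname(as.character(seqs)),
                    stringsAsFactors = FALSE)
  rownames(lib) <- NULL
  class(lib) <- c("te_library", "data.frame")
  lib
}

#' Write / read annotations as a RepeatMasker-style .out table
#'
#' Tab-separated with one header line; `begin`/`end` are 1-based inclusive
#' genome coordinates, `cons_begin`/`cons_end` 1-based consensus coordinates,
#' `div_pct` is `100 * (1 - identity)`. Alignments are not carried in this
#' table (see [write_alignments()]).
#'
#' @param hits annotation data frame.
#' @param file path.
#' @param library optional `te_library` for the class column.
#' @export
write_rm_out <- function(hits, file, library = NULL) {
  cls <- if (!is.null(library))
    library$te_class[match(hits$family_id, library$family_id)]
  else rep(NA_character_, nrow(hits))
  out <- data.frame(score = hits$score,
                    div_pct = round(100 * (1 - hits$identity), 2),
                    contig = hits$contig, begin = hits$start + 1L,
                    end = hits$end, strand = hits$strand,
                    family = hits$family_id, te_class = cls,
                    cons_begin = hits$cons_start, cons_end = hits$cons_end,
                    copy_id = hits$copy_id, stringsAsFactors = FALSE)
  data.table::fwrite(out, file, sep = "\t", quote = FALSE)
  invisible(file)
}

#' @rdname write_rm_out
#' @return `read_rm_out` returns a data frame with internal 0-based half-open
#'   `start`/`end`.
#' @export
read_rm_out <- function(file) {
  d <- as.data.frame(data.table::fread(file, sep = "\t", header = TRUE))
  if (!all(c("score", "contig", "begin", "end") %in% names(d)))
    stop("malformed .out table: ", file)
  data.frame(copy_id = d$copy_id, contig = d$contig,
             start = d$begin - 1L, end = d$end, strand = d$strand,
             family_id = d$family, te_class = d$te_class, score = d$score,
             identity = 1 - d$div_pct / 100,
             cons_start = d$cons_begin, cons_end = d$cons_end,
             stringsAsFactors = FALSE)
}

annotations_granges <- function(hits) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$contig,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand)
  S4Vectors::mcols(gr)$name <- hits$copy_id
  S4Vectors::mcols(gr)$score <- as.numeric(hits$score %||% 0)
  gr
}

#' Export annotations as BED6 (0-based half-open)
#'
#' @param hits annotation (or truth) data frame with `contig`, `start`, `end`,
#'   `strand` and an id column (`copy_id`).
#' @param file path.
#' @export
write_bed <- function(hits, file) {
  if (!"score" %in% names(hits)) hits$score <- 0
  rtracklayer::export(annotations_granges(hits), file, format = "BED")
  invisible(file)
}

#' Export annotations as GFF3 (1-based inclusive, class in attributes)
#'
#' @param hits annotation data frame.
#' @param file path.
#' @param library optional `te_library` for the class attribute.
#' @export
write_gff3 <- function(hits, file, library = NULL) {
  if (!"score" %in% names(hits)) hits$score <- 0
  gr <- annotations_granges(hits)
  S4Vectors::mcols(gr)$type <- "dispersed_repeat"
  S4Vectors::mcols(gr)$ID <- hits$copy_id
  S4Vectors::mcols(gr)$family <- hits$family_id
  if (!is.null(library))
    S4Vectors::mcols(gr)$te_class <-
      library$te_class[match(hits$family_id, library$family_id)]
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' Write / read per-copy gapped alignments
#'
#' Plain-text blocks, one per copy:
#' a `#` header line with copy id, genome, contig, coordinates, strand, family
#' and consensus interval, followed by the gapped consensus row and the gapped
#' copy row.
#'
#' @param hits annotation data frame with `aln_cons`/`aln_copy`.
#' @param file path.
#' @export
write_alignments <- function(hits, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(hits))) {
    writeLines(sprintf("# %s %s %s %d %d %s %s %d %d",
                       hits$copy_id[i], hits$genome_id[i], hits$contig[i],
                       hits$start[i], hits$end[i], hits$strand[i],
                       hits$family_id[i], hits$cons_start[i],
                       hits$cons_end[i]), con)
    writeLines(c(hits$aln_cons[i], hits$aln_copy[i]), con)
  }
  invisible(file)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^# ", lines)
  if (!length(hdr)) return(empty_annotations())
  parts <- strsplit(sub("^# ", "", lines[hdr]), " ")
  bad <- which(lengths(parts) != 9L)
  if (length(bad))
    stop("malformed alignment header at line ", hdr[bad[1]])
  d <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(d) <- c("copy_id", "genome_id", "contig", "start", "end", "strand",
                "family_id", "cons_start", "cons_end")
  for (cl in c("start", "end", "cons_start", "cons_end"))
    d[[cl]] <- as.integer(d[[cl]])
  d$aln_cons <- lines[hdr + 1L]
  d$aln_copy <- lines[hdr + 2L]
  d$score <- NA_real_
  d$identity <- vapply(seq_len(nrow(d)), function(i)
    alignment_identity(d$aln_cons[i], d$aln_copy[i]), 0)
  d
}

#' Packaged transcriptions of the published comparison tables
#'
#' `"table1"`: per-class copy numbers, densities and genome percentages for
#' the two real genomes (selfing *A. thaliana* vs outcrossing *A. lyrata*),
#' 4 class rows plus one Total row per genome. `"partition"`: the
#' shared/unique/absent family partition. `"genome_sizes"`: assembly lengths
#' consistent with the densities (derived, see the fixture comments).
#'
#' @param which fixture name.
#' @return a data frame.
#' @export
read_table_fixture <- function(which = c("table1", "partition",
                                         "genome_sizes")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(switch(which,
         table1 = "table1_copy_numbers", partition = "family_partition",
         genome_sizes = "genome_sizes"), ".tsv"), package = "tedyn",
       mustWork = TRUE)
  utils::read.delim(f, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a truth table TSV
#' @param truth truth data frame from [simulate_two_lineages()].
#' @param file path.
#' @export
write_truth <- function(truth, file) {
  data.table::fwrite(truth, file, sep = "\t", quote = FALSE)
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  as.data.frame(data.table::fread(file, sep = "\t", header = TRUE,
                                  colClasses = list(character = c(
                                    "copy_id", "lineage", "contig", "strand",
                                    "family_id", "parent_copy_id"))))
}
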