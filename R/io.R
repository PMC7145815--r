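## File-format boundary. Internal coordinates are 0-based half-open
## everywhere; GFF3 is 1-based inclusive and BED 0-based half-open, and the
## conversion lives only in these functions.

#' Read and write FASTA
#'
#' @param path File path.
#' @return `read_fasta`: a named character vector of uppercase sequences
#'   (softmasked input is uppercased with a warning).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  ## read as plain strings first: DNAStringSet would silently uppercase and
  ## hide softmasking from the caller
  x <- Biostrings::readBStringSet(path)
  s <- as.character(x)
  if (any(grepl("[a-z]", s))) {
    warning("lower-case bases in ", path, " uppercased")
    s <- toupper(s)
  }
  Biostrings::DNAStringSet(s)  # validates the alphabet
  stats::setNames(s, names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read and write feature tables as GFF3
#'
#' Internal features (0-based half-open) are written as GFF3 (1-based
#' inclusive) and converted back on reading.
#'
#' @param path File path.
#' @param seqid Sequence id restriction for `read_gff3` (`NULL` = all).
#' @return `read_gff3`: a feature data.frame (`type`, `start`, `end`,
#'   `strand`, `name`), 0-based half-open.
#' @export
read_gff3 <- function(path, seqid = NULL) {
  if (!file.exists(path)) stop("missing input file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(seqid)) gr <- gr[as.character(GenomicRanges::seqnames(gr)) == seqid]
  nm <- if ("ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$ID)
  } else rep(NA_character_, length(gr))
  data.frame(type = as.character(S4Vectors::mcols(gr)$type),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             name = nm, stringsAsFactors = FALSE)
}

#' @rdname read_gff3
#' @param genome An [annotated_genome()] whose features are exported.
#' @export
write_gff3 <- function(genome, path) {
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- f$type
  S4Vectors::mcols(gr)$ID <- f$name
  S4Vectors::mcols(gr)$source <- "plastoflux"
  ## planted CDS always start in frame
  S4Vectors::mcols(gr)$phase <- ifelse(f$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read and write 0-based half-open intervals as BED
#'
#' @param path File path.
#' @return `read_bed`: data.frame `chrom`, `start`, `end`, `name` (0-based
#'   half-open, as in the BED standard).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if ("name" %in% names(S4Vectors::mcols(gr))) {
               as.character(S4Vectors::mcols(gr)$name)
             } else rep(NA_character_, length(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param intervals Data.frame with `chrom`, `start`, `end` and optionally
#'   `name` (0-based half-open).
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
  if (!is.null(intervals$name)) S4Vectors::mcols(gr)$name <- intervals$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read and write tab-separated tables
#'
#' Thin wrappers fixing the dialect (tab separator, header row, no quoting,
#' no row names) used by every TSV the pipeline emits.
#'
#' @param path File path.
#' @return `read_tsv`: a data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param x Data.frame to write.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write genotype tables
#'
#' TSV layout: header `collection  label  <marker1> <marker2> ...`, one row
#' per collection, calls in `{target, off, missing, both}`.
#'
#' @param path File path.
#' @return `read_genotype_table`: a `genotype_table`.
#' @export
read_genotype_table <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("collection", "label"))) {
    stop("malformed genotype table ", path,
         ": expected columns collection, label, <markers...>")
  }
  genotype_table(as.matrix(df[, -(1:2), drop = FALSE]),
                 labels = df$label, ids = df$collection)
}

#' @rdname read_genotype_table
#' @param table A `genotype_table`.
#' @export
write_genotype_table <- function(table, path) {
  df <- data.frame(collection = table$collections$id,
                   label = table$collections$label,
                   table$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write an annotated genome (FASTA + GFF3) and read it back
#'
#' @param genome An [annotated_genome()].
#' @param fasta,gff Paths for the sequence and the features.
#' @return `read_annotated_genome`: the reconstructed [annotated_genome()].
#' @export
write_annotated_genome <- function(genome, fasta, gff) {
  write_fasta(stats::setNames(genome$sequence, genome$id), fasta)
  write_gff3(genome, gff)
  invisible(genome)
}

#' @rdname write_annotated_genome
#' @param id Record to read (default: first FASTA record).
#' @export
read_annotated_genome <- function(fasta, gff, id = NULL) {
  seqs <- read_fasta(fasta)
  if (is.null(id)) id <- names(seqs)[1]
  feats <- read_gff3(gff, seqid = id)
  annotated_genome(id, seqs[[id]], feats)
}
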