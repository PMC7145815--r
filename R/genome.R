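#' Annotated organelle genome
#'
#' Constructs the basic container used throughout the package: one DNA
#' sequence plus a table of typed features. Coordinates are 0-based,
#' half-open (`start` inclusive, `end` exclusive); conversion to the 1-based
#' inclusive convention happens only at the GFF3 boundary
#' (see [read_gff3()] / [write_gff3()]).
#'
#' @param id Single character identifier for the sequence.
#' @param sequence Character scalar over the DNA alphabet `A`, `C`, `G`, `T`.
#'   Lower-case (softmasked) input is uppercased with a warning.
#' @param features A `data.frame` with columns `type` (one of `CDS`, `gene`,
#'   `tRNA`, `rRNA`), `start`, `end` (0-based half-open), `strand`
#'   (`"+"`/`"-"`) and `name`. May be empty.
#' @return An object of class `AnnotatedGenome`: a list with elements `id`,
#'   `sequence` and `features`.
#' @examples
#' g <- annotated_genome("chr", "ATGAAATAA",
#'   data.frame(type = "CDS", start = 0, end = 9, strand = "+", name = "g1"))
#' genome_length(g)
#' @export
annotated_genome <- function(id, sequence, features = empty_features()) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  if (grepl("[acgtn]", sequence)) {
    warning("lower-case bases in '", id, "' uppercased")
    sequence <- toupper(sequence)
  }
  bad <- gregexpr("[^ACGTRYSWKMBDHVN]", sequence)[[1]]
  if (bad[1] != -1L) {
    stop("non-IUPAC character in sequence '", id, "' at position ", bad[1])
  }
  features <- as.data.frame(features)
  req <- c("type", "start", "end", "strand", "name")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  features <- features[, req, drop = FALSE]
  L <- nchar(sequence)
  if (nrow(features)) {
    features$start <- as.integer(features$start)
    features$end   <- as.integer(features$end)
    if (any(features$start < 0L) || any(features$end > L) ||
        any(features$start >= features$end)) {
      stop("feature coordinates must satisfy 0 <= start < end <= ", L)
    }
    if (!all(features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  structure(list(id = id, sequence = sequence, features = features),
            class = "AnnotatedGenome")
}

#' @rdname annotated_genome
#' @export
empty_features <- function() {
  data.frame(type = character(), start = integer(), end = integer(),
             strand = character(), name = character(),
             stringsAsFactors = FALSE)
}

#' @rdname annotated_genome
#' @param x An `AnnotatedGenome`.
#' @export
genome_length <- function(x) nchar(x$sequence)

#' @export
print.AnnotatedGenome <- function(x, ...) {
  cat("AnnotatedGenome", x$id, "-", genome_length(x), "bp,",
      nrow(x$features), "features\n")
  if (nrow(x$features)) print(utils::head(x$features, 10))
  invisible(x)
}

## ---- low-level sequence helpers -------------------------------------------
## DNA is held as character scalars at the interface; hot loops work on
## integer vectors in 0:3 (A,C,G,T). Ambiguity codes map to NA_integer_ and
## never match a seed or count as identity.

.BASE2INT <- {
  v <- rep(NA_integer_, 127L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("T")] <- 3L
  v
}
.INT2BASE <- c("A", "C", "G", "T")

dna_to_int <- function(s) .BASE2INT[utf8ToInt(s)]

int_to_dna <- function(v) paste(.INT2BASE[v + 1L], collapse = "")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## substring by 0-based half-open interval
subseq0 <- function(s, start, end) substr(s, start + 1L, end)

translate_cds <- function(cds) {
  aa <- Biostrings::GENETIC_CODE[codons_of(cds)]
  aa[is.na(aa)] <- "X"   # ambiguity codes
  paste(aa, collapse = "")
}

## split a CDS string into codon triplets
codons_of <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character())
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

has_internal_stop <- function(cds) {
  aa <- translate_cds(cds)
  n <- nchar(aa)
  n > 1L && grepl("\\*", substr(aa, 1L, n - 1L))
}
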