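#' Project per-species MTPT segments onto a reference plastid backbone
#'
#' Builds the depth profile used to survey MTPT prevalence across species:
#' `depth[i]` is the number of distinct species with at least one segment
#' covering backbone position `i` (multiple overlapping segments from one
#' species count once).
#'
#' @param per_species_segments Named list (one element per species) of
#'   `mtpt_segments` data.frames indexed to the backbone.
#' @param backbone The backbone [annotated_genome()].
#' @return A list of class `depth_profile`: `backbone_id`, `length`, `depth`
#'   (integer vector of length `length`), `n_species`, and `species_cov`
#'   (per-species merged plastid intervals, used for gene-frequency counts).
#' @export
project_to_backbone <- function(per_species_segments, backbone) {
  stopifnot(inherits(backbone, "AnnotatedGenome"),
            is.list(per_species_segments))
  L <- genome_length(backbone)
  depth <- integer(L)
  species_cov <- lapply(per_species_segments, function(seg) {
    if (nrow(seg) == 0L) return(data.frame(start = integer(), end = integer()))
    if (any(seg$plastid_end > L) || any(seg$plastid_start < 0L)) {
      stop("segment beyond backbone length ", L)
    }
    merge_intervals0(seg$plastid_start, seg$plastid_end)
  })
  for (cov in species_cov) {
    for (i in seq_len(nrow(cov))) {
      idx <- (cov$start[i] + 1L):cov$end[i]
      depth[idx] <- depth[idx] + 1L
    }
  }
  structure(list(backbone_id = backbone$id, length = L, depth = depth,
                 n_species = length(per_species_segments),
                 species_cov = species_cov),
            class = "depth_profile")
}

## number of species whose merged coverage overlaps >= min_overlap of
## [start, end)
.species_count_over <- function(profile, start, end, min_overlap = 0.5) {
  span <- end - start
  sum(vapply(profile$species_cov, function(cov) {
    if (nrow(cov) == 0L) return(FALSE)
    ov <- pmax(0L, pmin(end, cov$end) - pmax(start, cov$start))
    sum(ov) >= min_overlap * span
  }, logical(1)))
}

.frequency_class <- function(count, most_frequent_above = 20L,
                             moderate_above = 10L) {
  ifelse(count > most_frequent_above, "most_frequent",
         ifelse(count > moderate_above, "moderate", "rare"))
}

#' Classify backbone genes by MTPT frequency across species
#'
#' A gene's frequency is the number of species whose MTPT coverage overlaps
#' at least half of the gene span. Genes found in more than
#' `most_frequent_above` species are `most_frequent`, in more than
#' `moderate_above` species `moderate`, otherwise `rare`.
#'
#' @param profile A [project_to_backbone()] result.
#' @param genes Feature data.frame (0-based half-open `start`/`end`, `name`)
#'   of genes on the backbone; defaults apply to surveys of dozens of
#'   species, matching the ">20" / ">10" frequency classes.
#' @param most_frequent_above,moderate_above Class thresholds (species
#'   counts).
#' @param min_overlap Fraction of the gene span that must be covered for a
#'   species to count.
#' @return A data.frame `name`, `count`, `class`.
#' @export
classify_gene_frequency <- function(profile, genes,
                                    most_frequent_above = 20L,
                                    moderate_above = 10L,
                                    min_overlap = 0.5) {
  stopifnot(inherits(profile, "depth_profile"))
  genes <- as.data.frame(genes)
  if (nrow(genes) && any(genes$end > profile$length)) {
    stop("gene beyond backbone length")
  }
  count <- vapply(seq_len(nrow(genes)), function(i) {
    .species_count_over(profile, genes$start[i], genes$end[i], min_overlap)
  }, numeric(1))
  data.frame(name = genes$name, count = as.integer(count),
             class = .frequency_class(count, most_frequent_above,
                                      moderate_above),
             stringsAsFactors = FALSE)
}

#' MTPT frequency of barcoding regions
#'
#' Per named barcode region on the backbone, the number of species whose
#' MTPT coverage overlaps at least half the region, and its frequency class.
#' This is the machine-readable form of the observation that some genic
#' barcodes (e.g. rbcL, rpoB) are frequent MTPTs while intergenic barcode
#' regions are seldom transferred.
#'
#' @inheritParams classify_gene_frequency
#' @param barcode_regions Feature data.frame of named barcode regions.
#' @return A data.frame `name`, `count`, `class`.
#' @export
barcode_overlap_report <- function(profile, barcode_regions,
                                   most_frequent_above = 20L,
                                   moderate_above = 10L,
                                   min_overlap = 0.5) {
  classify_gene_frequency(profile, barcode_regions,
                          most_frequent_above, moderate_above, min_overlap)
}
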