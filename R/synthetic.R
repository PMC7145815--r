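#' Flux scenario: the study conditions for a simulated species pair
#'
#' Bundles the parameters of the two-rate organelle molecular clock used by
#' [simulate_flux_scenario()]: a plastid-to-mitochondrion transfer (MTPT
#' insertion) in the common ancestor at `t_flux` years before present, a
#' species split at `t_split`, and compartment-specific synonymous
#' substitution rates. Default rates are the conventional organelle clocks
#' (2e-9 substitutions/synonymous site/year for plastid, 0.6e-9 for
#' mitochondrion); the default transferred fraction of 0.35 reflects the
#' scale of flux reported for medicinal *Cynanchum* herbs.
#'
#' @param t_split Years since the two species diverged.
#' @param t_flux Years since the MTPT insertion (must be >= `t_split`).
#' @param lambda_pt,lambda_mt Synonymous substitution rates per site per year
#'   for the plastid and mitochondrial compartments (`lambda_mt <= lambda_pt`).
#' @param plastid_length Length (bp) of the simulated ancestral plastid.
#' @param n_genes Number of protein-coding genes planted in the plastid.
#' @param mtpt_fraction Target fraction (0-1) of the plastid copied into the
#'   mitochondrial genome at `t_flux`.
#' @param copy_fraction_pt Expected fraction of organelle reads of plastid
#'   origin (used by [simulate_allele_depths()]).
#' @param n_mtpt_blocks Number of contiguous plastid blocks making up the
#'   transfer (MTPTs are typically multi-fragment).
#' @param gene_codons Either `NULL` (gene lengths sampled 100-300 codons) or
#'   a fixed codon count for every gene.
#' @param seed Integer RNG seed; all randomness in the scenario flows from it.
#' @return A list of class `flux_scenario`.
#' @export
flux_scenario <- function(t_split = 2e6, t_flux = 1e7,
                          lambda_pt = 2e-9, lambda_mt = 0.6e-9,
                          plastid_length = 60000L, n_genes = 20L,
                          mtpt_fraction = 0.35, copy_fraction_pt = 0.88,
                          n_mtpt_blocks = 5L, gene_codons = NULL,
                          seed = 1L) {
  stopifnot(t_flux >= t_split, t_split >= 0,
            lambda_pt > 0, lambda_mt > 0, lambda_mt <= lambda_pt,
            mtpt_fraction >= 0, mtpt_fraction <= 1,
            copy_fraction_pt >= 0, copy_fraction_pt <= 1,
            plastid_length >= 1000, n_genes >= 1, n_mtpt_blocks >= 1)
  structure(list(t_split = t_split, t_flux = t_flux,
                 lambda_pt = lambda_pt, lambda_mt = lambda_mt,
                 plastid_length = as.integer(plastid_length),
                 n_genes = as.integer(n_genes),
                 mtpt_fraction = mtpt_fraction,
                 copy_fraction_pt = copy_fraction_pt,
                 n_mtpt_blocks = as.integer(n_mtpt_blocks),
                 gene_codons = gene_codons,
                 seed = as.integer(seed)),
            class = "flux_scenario")
}

## random sense codon (never a stop), random non-ATG-specific
.random_sense_codons <- function(n) {
  sample(.SENSE_CODONS, n, replace = TRUE)
}

#' Simulate an ancestral plastid genome
#'
#' Generates a uniform-random DNA sequence and plants `n_genes`
#' non-overlapping protein-coding genes (ATG start, random sense codons, one
#' stop codon; no premature stop), plus one tRNA- and one rRNA-typed feature.
#' Roughly half the genes are placed on the minus strand. Deterministic for
#' a fixed seed.
#'
#' @param length Genome length in bp (>= 1000).
#' @param n_genes Number of CDS to plant (>= 1).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param gene_codons `NULL` (codon counts sampled uniformly 100-300, shrunk
#'   to fit) or a fixed codon count per gene.
#' @return An [annotated_genome()] whose CDS features include the stop codon.
#' @export
simulate_ancestral_plastid <- function(length, n_genes, seed = NULL,
                                       gene_codons = NULL) {
  length <- as.integer(length); n_genes <- as.integer(n_genes)
  stopifnot(length >= 1000L, n_genes >= 1L)
  trna_len <- 72L; rrna_len <- 300L; spacer_min <- 10L
  budget <- (length - trna_len - rrna_len -
             (n_genes + 3L) * spacer_min) %/% n_genes
  max_codons <- min(300L, budget %/% 3L - 1L)  # one extra codon for the stop
  if (!is.null(gene_codons)) {
    if (gene_codons + 1L > budget %/% 3L) {
      stop("genes of ", gene_codons, " codons cannot fit: ", n_genes,
           " genes in ", length, " bp")
    }
  } else if (max_codons < 34L) {
    stop("cannot fit ", n_genes, " genes in ", length, " bp")
  }
  with_seed(seed, {
    n_codons <- if (is.null(gene_codons)) {
      sample(100:max(100L, max_codons), n_genes, replace = TRUE)
    } else rep(as.integer(gene_codons), n_genes)
    n_codons <- pmin(n_codons, max_codons)
    gene_len <- 3L * (n_codons + 1L)
    feat_len <- c(gene_len, trna_len, rrna_len)
    n_feat <- length(feat_len)
    free <- length - sum(feat_len)
    # distribute free space over n_feat + 1 gaps, each >= spacer_min
    w <- as.vector(stats::rmultinom(1, free - (n_feat + 1L) * spacer_min,
                                    rep(1, n_feat + 1L)))
    gaps <- w + spacer_min
    ord <- sample.int(n_feat)  # shuffle feature order along the genome
    starts <- integer(n_feat)
    pos <- 0L
    for (i in seq_len(n_feat)) {
      pos <- pos + gaps[i]
      starts[ord[i]] <- pos
      pos <- pos + feat_len[ord[i]]
    }
    seq_int <- sample(0:3, length, replace = TRUE)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    for (g in seq_len(n_genes)) {
      body <- paste(.random_sense_codons(n_codons[g] - 1L), collapse = "")
      cds <- paste0("ATG", body, sample(.STOP_CODONS, 1))
      if (strands[g] == "-") cds <- revcomp(cds)
      seq_int[(starts[g] + 1L):(starts[g] + gene_len[g])] <- dna_to_int(cds)
    }
    feats <- data.frame(
      type = c(rep("CDS", n_genes), "tRNA", "rRNA"),
      start = starts,
      end = starts + feat_len,
      strand = c(strands, "+", "+"),
      name = c(sprintf("gene%02d", seq_len(n_genes)), "trnX", "rrnX"),
      stringsAsFactors = FALSE)
    annotated_genome("ancestral_plastid", int_to_dna(seq_int), feats)
  })
}

#' Evolve a coding sequence by synonymous substitutions only
#'
#' Draws a Poisson number of substitution events with mean
#' `rate * years * S`, where `S` is the NG86 synonymous site count of the
#' input, and applies each event as one random synonymous single-nucleotide
#' change (codon chosen proportional to its synonymous site count, position
#' within the codon proportional to its synonymous fraction, target base
#' uniform among synonymous alternatives). The translation is invariant, so
#' the realized divergence is directly comparable to `rate * years` on the
#' NG86 scale.
#'
#' @param cds Coding sequence, length divisible by 3, no internal stop.
#' @param rate Synonymous substitutions per synonymous site per year.
#' @param years Elapsed time.
#' @param seed Integer seed or `NULL` (current RNG stream).
#' @return The mutated coding sequence (same length).
#' @export
evolve_synonymous <- function(cds, rate, years, seed = NULL) {
  stopifnot(nchar(cds) %% 3L == 0L, rate >= 0, years >= 0)
  if (has_internal_stop(cds)) stop("internal stop codon in CDS")
  if (rate == 0 || years == 0 || nchar(cds) == 0L) return(cds)
  with_seed(seed, {
    cods <- codons_of(cds)
    n <- length(cods)
    terminal_stop <- is_stop_codon(cods[n])
    idx <- if (terminal_stop) seq_len(n - 1L) else seq_len(n)
    s_c <- vapply(cods[idx], function(cd) ng86_codon_info(cd)$s_sites,
                  numeric(1))
    n_events <- stats::rpois(1, rate * years * sum(s_c))
    for (e in seq_len(n_events)) {
      ci <- sample(idx, 1, prob = s_c)
      info <- ng86_codon_info(cods[ci])
      pos <- sample(1:3, 1, prob = info$f)
      alt <- info$syn_alts[[pos]]
      cods[ci] <- if (length(alt) == 1L) alt else sample(alt, 1)
      s_c[ci] <- ng86_codon_info(cods[ci])$s_sites
    }
    paste(cods, collapse = "")
  })
}

## Jukes-Cantor-style neutral substitution over arbitrary positions: Poisson
## number of events, each replacing one random position by a random
## different base. Used for non-coding sequence at 3x the synonymous rate.
evolve_neutral_positions <- function(seq_int, positions, rate, years) {
  if (length(positions) == 0L || rate == 0 || years == 0) return(seq_int)
  n_events <- stats::rpois(1, rate * years * length(positions))
  if (n_events == 0L) return(seq_int)
  at <- sample(positions, n_events, replace = TRUE)
  for (p in at) {
    cur <- seq_int[p]
    if (is.na(cur)) next
    seq_int[p] <- sample((0:3)[-(cur + 1L)], 1)
  }
  seq_int
}

#' Evolve an annotated genome under the two-regime neutral model
#'
#' CDS features accumulate synonymous-only substitutions at `rate` (see
#' [evolve_synonymous()]); all other positions evolve under a Jukes-Cantor
#' process at `intergenic_factor * rate` (default 3x, a neutral proxy that
#' keeps non-coding identity comparable to coding identity without modeling
#' selection). Feature coordinates are unchanged (substitution-only model).
#'
#' @param genome An [annotated_genome()].
#' @param rate Synonymous substitution rate per site per year.
#' @param years Branch length in years.
#' @param seed Integer seed or `NULL`.
#' @param intergenic_factor Multiplier for the non-coding substitution rate.
#' @return The evolved `AnnotatedGenome` (same id, same features).
#' @export
evolve_genome <- function(genome, rate, years, seed = NULL,
                          intergenic_factor = 3) {
  stopifnot(inherits(genome, "AnnotatedGenome"), rate >= 0, years >= 0)
  if (rate == 0 || years == 0) return(genome)
  with_seed(seed, {
    seq_int <- dna_to_int(genome$sequence)
    cds <- genome$features[genome$features$type == "CDS", , drop = FALSE]
    in_cds <- rep(FALSE, genome_length(genome))
    for (i in seq_len(nrow(cds))) {
      s <- cds$start[i]; e <- cds$end[i]
      in_cds[(s + 1L):e] <- TRUE
      block <- int_to_dna(seq_int[(s + 1L):e])
      if (cds$strand[i] == "-") block <- revcomp(block)
      block <- evolve_synonymous(block, rate, years)
      if (cds$strand[i] == "-") block <- revcomp(block)
      seq_int[(s + 1L):e] <- dna_to_int(block)
    }
    seq_int <- evolve_neutral_positions(seq_int, which(!in_cds),
                                        rate * intergenic_factor, years)
    annotated_genome(genome$id, int_to_dna(seq_int), genome$features)
  })
}

## pick n_blocks non-overlapping source intervals in [0, L) with given sizes
.place_blocks <- function(sizes, L) {
  nb <- length(sizes)
  for (attempt in 1:200) {
    sizes_o <- if (nb > 1L) sample(sizes) else sizes
    starts <- sort(sample.int(L - max(sizes), nb) - 1L)
    ends <- starts + sizes_o
    if (all(ends <= L) &&
        (nb == 1L || all(utils::head(ends, -1) <= utils::tail(starts, -1)))) {
      return(data.frame(start = starts, end = ends))
    }
  }
  # deterministic fallback: even spacing
  gap <- (L - sum(sizes)) %/% (length(sizes) + 1L)
  if (gap < 0L) stop("MTPT blocks do not fit in the plastid")
  starts <- cumsum(c(gap, utils::head(sizes, -1) + gap))
  data.frame(start = as.integer(starts), end = as.integer(starts + sizes))
}

#' Simulate a species pair with planted MTPTs
#'
#' Builds an ancestral plastid, copies contiguous plastid blocks totaling
#' about `mtpt_fraction` of the plastid into a random mitochondrial
#' background (the MTPT insertion, at `t_flux` years ago), then evolves the
#' four genomes along the tree `((A,B):t_split)` rooted at `t_flux`: plastid
#' lineages at `lambda_pt`, mitochondrial lineages (including the MTPTs) at
#' `lambda_mt`. Plastid genes falling inside a transferred block are carried
#' over as CDS features of the mitochondrial genomes, so their MTPT copies
#' can be paired with the plastid originals for Ks dating.
#'
#' @param scenario A [flux_scenario()].
#' @return A list of class `species_pair` with elements `species_a`,
#'   `species_b` (each `list(plastid =, mito =)`), `truth` (the scenario) and
#'   `mtpt_truth` (a data.frame of planted mito intervals and their plastid
#'   source intervals, 0-based half-open, recorded at insertion time).
#' @export
simulate_flux_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "flux_scenario"))
  with_seed(scenario$seed, {
    anc_pt <- simulate_ancestral_plastid(scenario$plastid_length,
                                         scenario$n_genes,
                                         gene_codons = scenario$gene_codons)
    L <- genome_length(anc_pt)

    ## choose MTPT source blocks (sizes log-uniform 0.3-20 kb, rescaled to
    ## the target total fraction)
    blocks <- data.frame(start = integer(), end = integer())
    if (scenario$mtpt_fraction > 0) {
      nb <- scenario$n_mtpt_blocks
      target <- scenario$mtpt_fraction * L
      raw <- exp(stats::runif(nb, log(300), log(20000)))
      sizes <- pmax(50L, as.integer(round(raw * target / sum(raw))))
      if (sum(sizes) > 0.9 * L) stop("mtpt_fraction too large for genome")
      blocks <- .place_blocks(sizes, L)
    }

    ## ancestral mitochondrial genome: random background with the plastid
    ## blocks spliced in between random spacer pieces
    bg_len <- max(20000L, as.integer(round(0.8 * L)))
    bg <- sample(0:3, bg_len, replace = TRUE)
    nb <- nrow(blocks)
    cuts <- sort(sample.int(bg_len - 1L, nb))
    prev <- 0L
    mt_seq <- integer(0)
    mt_feats <- empty_features()
    truth <- data.frame(mito_start = integer(), mito_end = integer(),
                        plastid_start = integer(), plastid_end = integer())
    pt_int <- dna_to_int(anc_pt$sequence)
    for (i in seq_len(nb)) {
      mt_seq <- c(mt_seq, bg[(prev + 1L):cuts[i]])
      prev <- cuts[i]
      ins_at <- length(mt_seq)
      blk <- pt_int[(blocks$start[i] + 1L):blocks$end[i]]
      mt_seq <- c(mt_seq, blk)
      truth <- rbind(truth, data.frame(
        mito_start = ins_at, mito_end = ins_at + length(blk),
        plastid_start = blocks$start[i], plastid_end = blocks$end[i]))
      ## carry over CDS features fully inside the block
      f <- anc_pt$features
      inside <- f$type == "CDS" & f$start >= blocks$start[i] &
        f$end <= blocks$end[i]
      if (any(inside)) {
        fi <- f[inside, , drop = FALSE]
        off <- ins_at - blocks$start[i]
        fi$start <- fi$start + off
        fi$end <- fi$end + off
        mt_feats <- rbind(mt_feats, fi)
      }
    }
    mt_seq <- c(mt_seq, bg[(prev + 1L):bg_len])
    anc_mt <- annotated_genome("ancestral_mito", int_to_dna(mt_seq), mt_feats)

    stem <- scenario$t_flux - scenario$t_split
    pt_stem <- evolve_genome(anc_pt, scenario$lambda_pt, stem)
    mt_stem <- evolve_genome(anc_mt, scenario$lambda_mt, stem)
    mk <- function(g, id) annotated_genome(id, g$sequence, g$features)
    pt_a <- mk(evolve_genome(pt_stem, scenario$lambda_pt, scenario$t_split), "A_pt")
    pt_b <- mk(evolve_genome(pt_stem, scenario$lambda_pt, scenario$t_split), "B_pt")
    mt_a <- mk(evolve_genome(mt_stem, scenario$lambda_mt, scenario$t_split), "A_mt")
    mt_b <- mk(evolve_genome(mt_stem, scenario$lambda_mt, scenario$t_split), "B_mt")

    structure(list(
      species_a = list(plastid = pt_a, mito = mt_a),
      species_b = list(plastid = pt_b, mito = mt_b),
      truth = scenario,
      mtpt_truth = truth,
      ancestral_plastid = anc_pt), class = "species_pair")
  })
}

#' Simulate allele depths at plastid/MTPT diagnostic sites
#'
#' At a site whose plastid and MTPT copies carry different alleles, reads of
#' plastid origin support one allele and reads of mitochondrial origin the
#' other; the plastid-allele depth is binomial in the total depth with the
#' plastid copy fraction as success probability.
#'
#' @param copy_fraction_pt Expected fraction of reads of plastid origin (0-1).
#' @param total_depth Total read depth per site (>= 1).
#' @param n_sites Number of diagnostic sites.
#' @param seed Integer seed or `NULL`.
#' @return A data.frame with columns `site`, `depth_pt`, `depth_mt`
#'   (`depth_pt + depth_mt == total_depth` at every site).
#' @export
simulate_allele_depths <- function(copy_fraction_pt, total_depth, n_sites,
                                   seed = NULL) {
  stopifnot(copy_fraction_pt >= 0, copy_fraction_pt <= 1, total_depth >= 1,
            n_sites >= 1)
  with_seed(seed, {
    d_pt <- stats::rbinom(n_sites, total_depth, copy_fraction_pt)
    data.frame(site = seq_len(n_sites), depth_pt = d_pt,
               depth_mt = as.integer(total_depth) - d_pt)
  })
}

#' Simulate a collections-by-markers genotype table
#'
#' Emits allele calls for `n_target` collections of the target species and
#' `n_other` collections of a related (off-target) species, with truth labels
#' attached. Target collections carry the off-type allele at marker `j`
#' independently with probability `offtype_freq[j]` (intraspecies plastid
#' diversity); "other" collections carry the target allele with probability
#' `target_in_other_freq[j]`. Exact counts of mixed collections can be forced
#' for constructing tables that match observed error patterns.
#'
#' @param n_target,n_other Numbers of collections per truth class.
#' @param n_markers Number of markers (>= 1).
#' @param offtype_freq Per-marker probability (recycled) that a target
#'   collection shows the off-type allele.
#' @param target_in_other_freq Per-marker probability (recycled) that an
#'   "other" collection shows the target allele.
#' @param force_n_offtype If not `NULL`, exactly this many target collections
#'   carry at least one off-type allele (each gets one random off call; the
#'   rest are pure target).
#' @param force_n_target_in_other If not `NULL`, exactly this many "other"
#'   collections carry at least one target allele.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `genotype_table`: `collections` (data.frame `id`,
#'   `label`), `markers` (character) and `calls` (character matrix,
#'   collections x markers, values `"target"`/`"off"`/`"missing"`).
#' @export
simulate_genotype_table <- function(n_target, n_other = 0L, n_markers = 3L,
                                    offtype_freq = 0, target_in_other_freq = 0,
                                    force_n_offtype = NULL,
                                    force_n_target_in_other = NULL,
                                    seed = NULL) {
  stopifnot(n_markers >= 1, n_target >= 0, n_other >= 0)
  offtype_freq <- rep_len(offtype_freq, n_markers)
  target_in_other_freq <- rep_len(target_in_other_freq, n_markers)
  with_seed(seed, {
    n <- n_target + n_other
    calls <- matrix("target", nrow = n, ncol = n_markers)
    if (n_target > 0) {
      if (is.null(force_n_offtype)) {
        for (j in seq_len(n_markers)) {
          hit <- stats::runif(n_target) < offtype_freq[j]
          calls[seq_len(n_target)[hit], j] <- "off"
        }
      } else {
        stopifnot(force_n_offtype <= n_target)
        mixed <- sample.int(n_target, force_n_offtype)
        for (i in mixed) calls[i, sample.int(n_markers, 1)] <- "off"
      }
    }
    if (n_other > 0) {
      rows <- n_target + seq_len(n_other)
      calls[rows, ] <- "off"
      if (is.null(force_n_target_in_other)) {
        for (j in seq_len(n_markers)) {
          hit <- stats::runif(n_other) < target_in_other_freq[j]
          calls[rows[hit], j] <- "target"
        }
      } else {
        stopifnot(force_n_target_in_other <= n_other)
        mixed <- sample(rows, force_n_target_in_other)
        for (i in mixed) calls[i, sample.int(n_markers, 1)] <- "target"
      }
    }
    markers <- sprintf("M%d", seq_len(n_markers))
    colnames(calls) <- markers
    collections <- data.frame(
      id = c(sprintf("T%02d", seq_len(n_target)),
             sprintf("O%02d", seq_len(n_other))),
      label = c(rep("target", n_target), rep("other", n_other)),
      stringsAsFactors = FALSE)
    rownames(calls) <- collections$id
    structure(list(collections = collections, markers = markers,
                   calls = calls), class = "genotype_table")
  })
}
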