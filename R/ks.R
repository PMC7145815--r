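#' Compartment-specific synonymous clock rates
#'
#' Default rates: 2e-9 synonymous substitutions per site per year for the
#' plastid genome and 0.6e-9 for the mitochondrial genome, the conventional
#' organelle clocks used for dating.
#'
#' @param lambda_pt,lambda_mt Rates (substitutions/synonymous site/year).
#' @return A list of class `rate_model`.
#' @export
rate_model <- function(lambda_pt = 2e-9, lambda_mt = 0.6e-9) {
  stopifnot(lambda_pt > 0, lambda_mt > 0)
  structure(list(lambda_pt = lambda_pt, lambda_mt = lambda_mt),
            class = "rate_model")
}

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Globally aligns the translated sequences (log-odds amino-acid scoring,
#' affine gaps) and back-projects the alignment onto the nucleotides, so all
#' gaps are codon multiples. Terminal stop codons, if present on both
#' sequences, are carried through as a final aligned codon column (and
#' removed again by [trim_alignment()]).
#'
#' @param cds_a,cds_b Coding sequences: length divisible by 3, no internal
#'   stop codon.
#' @param substitution_matrix Amino-acid scoring matrix name (default
#'   `"BLOSUM62"`; the choice is immaterial for near-identical organelle
#'   genes).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A list of class `codon_alignment` with elements `a` and `b`
#'   (gapped nucleotide strings of equal length, gaps as `-`) and attribute
#'   `score` (the amino-acid alignment score).
#' @export
codon_align <- function(cds_a, cds_b, substitution_matrix = "BLOSUM62",
                        gap_open = 10, gap_extend = 1) {
  for (s in list(a = cds_a, b = cds_b)) {
    if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
  }
  check_stop <- function(cds, which) {
    aa <- translate_cds(cds)
    internal <- regexpr("\\*", substr(aa, 1L, max(0L, nchar(aa) - 1L)))
    if (internal > 0) {
      stop("internal stop codon in sequence ", which, " at codon ", internal)
    }
  }
  check_stop(cds_a, "a"); check_stop(cds_b, "b")
  strip1 <- function(cds) {
    cods <- codons_of(cds)
    n <- length(cods)
    if (n && is_stop_codon(cods[n])) {
      list(cds = paste(cods[-n], collapse = ""), stop = cods[n])
    } else list(cds = cds, stop = NULL)
  }
  sa <- strip1(cds_a); sb <- strip1(cds_b)
  aa_a <- translate_cds(sa$cds); aa_b <- translate_cds(sb$cds)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cods_a <- codons_of(sa$cds); cods_b <- codons_of(sb$cds)
  ia <- 0L; ib <- 0L
  nt_a <- character(length(al_a)); nt_b <- character(length(al_b))
  for (k in seq_along(al_a)) {
    if (al_a[k] == "-") nt_a[k] <- "---" else {
      ia <- ia + 1L; nt_a[k] <- cods_a[ia]
    }
    if (al_b[k] == "-") nt_b[k] <- "---" else {
      ib <- ib + 1L; nt_b[k] <- cods_b[ib]
    }
  }
  if (!is.null(sa$stop) && !is.null(sb$stop)) {
    nt_a <- c(nt_a, sa$stop); nt_b <- c(nt_b, sb$stop)
  } else if (!is.null(sa$stop)) {
    nt_a <- c(nt_a, sa$stop); nt_b <- c(nt_b, "---")
  } else if (!is.null(sb$stop)) {
    nt_a <- c(nt_a, "---"); nt_b <- c(nt_b, sb$stop)
  }
  structure(list(a = paste(nt_a, collapse = ""),
                 b = paste(nt_b, collapse = "")),
            score = Biostrings::score(pa), class = "codon_alignment")
}

#' Trim a codon alignment for Ks estimation
#'
#' Removes every codon column containing a gap and every column containing a
#' stop codon (terminal stops included), leaving an ungapped, stop-free
#' codon alignment.
#'
#' @param aln A [codon_align()] result.
#' @return A `codon_alignment`; its `a`/`b` are empty strings (and attribute
#'   `empty` is `TRUE`) when nothing survives trimming.
#' @export
trim_alignment <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  ca <- codons_of(aln$a); cb <- codons_of(aln$b)
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE) &
    !(ca %in% .STOP_CODONS) & !(cb %in% .STOP_CODONS)
  structure(list(a = paste(ca[keep], collapse = ""),
                 b = paste(cb[keep], collapse = "")),
            empty = !any(keep), class = "codon_alignment")
}

#' NG86 synonymous substitution estimate
#'
#' Nei-Gojobori (1986) counting on a trimmed codon alignment: synonymous
#' site counts averaged over the two sequences, synonymous differences
#' averaged over all minimal substitution paths per codon pair, and the
#' Jukes-Cantor multiple-hit correction
#' `Ks = -(3/4) * log(1 - (4/3) * pS)`. The estimate is flagged `saturated`
#' when `pS >= 3/4`, where the correction is undefined.
#'
#' @param aln A trimmed `codon_alignment` (see [trim_alignment()]); an
#'   untrimmed alignment is trimmed first.
#' @param gene_id Optional identifier carried into the result.
#' @return A one-row data.frame: `gene_id`, `ks`, `s_sites`, `sd`,
#'   `saturated`.
#' @export
ks_ng86 <- function(aln, gene_id = NA_character_) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (grepl("-", aln$a, fixed = TRUE) || grepl("-", aln$b, fixed = TRUE) ||
      isTRUE(attr(aln, "empty"))) {
    aln <- trim_alignment(aln)
  }
  ca <- codons_of(aln$a); cb <- codons_of(aln$b)
  if (length(ca) == 0L) stop("empty alignment: no codon columns to compare")
  usable <- ca %in% .SENSE_CODONS & cb %in% .SENSE_CODONS
  ca <- ca[usable]; cb <- cb[usable]
  if (length(ca) == 0L) stop("no unambiguous codon columns to compare")
  s_a <- sum(vapply(ca, function(x) ng86_codon_info(x)$s_sites, numeric(1)))
  s_b <- sum(vapply(cb, function(x) ng86_codon_info(x)$s_sites, numeric(1)))
  s_sites <- (s_a + s_b) / 2
  sd_tot <- 0
  diff <- which(ca != cb)
  for (i in diff) {
    sd_tot <- sd_tot + ng86_pair_diffs(ca[i], cb[i])[["sd"]]
  }
  ps <- if (s_sites > 0) sd_tot / s_sites else NaN
  saturated <- !is.finite(ps) || ps >= 0.75
  ks <- if (saturated) NA_real_ else -0.75 * log(1 - ps * 4 / 3) + 0
  data.frame(gene_id = gene_id, ks = ks, s_sites = s_sites, sd = sd_tot,
             saturated = saturated, stringsAsFactors = FALSE)
}

#' Mode of a Ks distribution
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a fixed grid; returns the grid argmax (ties broken toward
#' the smallest value). With fewer than 5 finite values the median is
#' returned with a warning.
#'
#' @param values Numeric Ks values (non-finite values dropped).
#' @param grid_step Grid spacing (default 5e-4).
#' @param bandwidth Kernel bandwidth; default Silverman (`stats::bw.nrd0`).
#' @return The mode (numeric scalar).
#' @export
ks_mode <- function(values, grid_step = 5e-4, bandwidth = NULL) {
  x <- values[is.finite(values)]
  if (length(x) < 5L) {
    warning("fewer than 5 finite Ks values; returning the median")
    return(stats::median(x))
  }
  if (max(x) - min(x) < grid_step) return(min(x))
  h <- if (is.null(bandwidth)) stats::bw.nrd0(x) else bandwidth
  if (!is.finite(h) || h <= 0) return(min(x))
  grid <- seq(min(x), max(x), by = grid_step)
  dens <- vapply(grid, function(g) sum(stats::dnorm((g - x) / h)), numeric(1))
  top <- max(dens)
  # ties (within numerical noise) break toward the smallest Ks
  grid[which(dens >= top - 1e-9 * top)[1]]
}

#' Divergence time from a synonymous distance
#'
#' `T = Ks / (2 * lambda)`: both lineages accumulate synonymous changes at
#' `lambda` after the split.
#'
#' @param ks Synonymous substitutions per synonymous site (>= 0); `NA` for a
#'   saturated estimate.
#' @param lam Synonymous substitution rate per site per year.
#' @return Years (NA with a warning if `ks` is NA/saturated).
#' @export
divergence_time <- function(ks, lam) {
  stopifnot(lam > 0)
  if (any(is.na(ks))) warning("saturated/undefined Ks: time undefined")
  ks / (2 * lam)
}

#' Flux (MTPT insertion) time from plastid-vs-MTPT divergence
#'
#' After insertion, the plastid copy keeps evolving at the plastid rate and
#' the MTPT copy at the mitochondrial rate, so their synonymous distance
#' grows at `lambda_pt + lambda_mt` per year (`clock = "sum"`, the default).
#' The single-compartment readings `Ks/(2*lambda_pt)` and
#' `Ks/(2*lambda_mt)` are also available.
#'
#' @param ks_pt_vs_mtpt Synonymous distance between a plastid gene and its
#'   MTPT counterpart.
#' @param rates A [rate_model()].
#' @param clock One of `"sum"`, `"2pt"`, `"2mt"`.
#' @return Years.
#' @export
flux_time <- function(ks_pt_vs_mtpt, rates = rate_model(),
                      clock = c("sum", "2pt", "2mt")) {
  clock <- match.arg(clock)
  if (any(is.na(ks_pt_vs_mtpt))) {
    warning("saturated/undefined Ks: time undefined")
  }
  denom <- switch(clock,
                  sum = rates$lambda_pt + rates$lambda_mt,
                  `2pt` = 2 * rates$lambda_pt,
                  `2mt` = 2 * rates$lambda_mt)
  ks_pt_vs_mtpt / denom
}

## ---- convenience: Ks over homologous gene sets ------------------------------

#' Extract a CDS by feature name
#'
#' Returns the coding-strand sequence of the named CDS feature.
#'
#' @param genome An [annotated_genome()].
#' @param name Feature name.
#' @return Character CDS.
#' @export
extract_cds <- function(genome, name) {
  f <- genome$features
  i <- which(f$type == "CDS" & f$name == name)
  if (length(i) == 0L) stop("no CDS named '", name, "'")
  i <- i[1]
  s <- subseq0(genome$sequence, f$start[i], f$end[i])
  if (f$strand[i] == "-") s <- revcomp(s)
  s
}

#' Ks table for homologous genes of two genomes
#'
#' For every CDS name present in both genomes: codon-align, trim and
#' estimate Ks.
#'
#' @param genome_a,genome_b [annotated_genome()] objects whose homologous
#'   CDS share feature names.
#' @return A data.frame, one row per shared gene (see [ks_ng86()]).
#' @export
ks_table <- function(genome_a, genome_b) {
  shared <- intersect(
    genome_a$features$name[genome_a$features$type == "CDS"],
    genome_b$features$name[genome_b$features$type == "CDS"])
  do.call(rbind, lapply(shared, function(g) {
    aln <- trim_alignment(codon_align(extract_cds(genome_a, g),
                                      extract_cds(genome_b, g)))
    ks_ng86(aln, gene_id = g)
  }))
}

#' Date a simulated species pair from its gene content
#'
#' Runs the dating chain on a [simulate_flux_scenario()] result: Ks between
#' the two species' plastid gene copies dates the split
#' (`T = Ks / (2 * lambda_pt)`), and Ks between each species' MTPT gene
#' copies and their own plastid counterparts dates the insertion
#' (`T = Ks / (lambda_pt + lambda_mt)`). Per-gene Ks values are summarized
#' by their mean (`estimator = "mean"`, stable for small gene sets where the
#' Ks distribution is nearly discrete) or by the kernel-density mode
#' (`"mode"`, matching how multi-gene Ks distributions are usually read).
#'
#' @param pair A `species_pair`.
#' @param rates A [rate_model()].
#' @param estimator `"mean"` or `"mode"`.
#' @return A list: `t_split_hat`, `t_flux_hat`, `ks_split` (per-gene table),
#'   `ks_flux` (per-gene table, both species pooled).
#' @export
date_species_pair <- function(pair, rates = rate_model(),
                              estimator = c("mean", "mode")) {
  estimator <- match.arg(estimator)
  summarize <- function(v) {
    v <- v[is.finite(v)]
    if (estimator == "mean") mean(v) else ks_mode(v)
  }
  ks_split <- ks_table(pair$species_a$plastid, pair$species_b$plastid)
  flux_a <- ks_table(pair$species_a$plastid, pair$species_a$mito)
  flux_b <- ks_table(pair$species_b$plastid, pair$species_b$mito)
  ks_flux <- rbind(flux_a, flux_b)
  list(t_split_hat = divergence_time(summarize(ks_split$ks),
                                     rates$lambda_pt),
       t_flux_hat = flux_time(summarize(ks_flux$ks), rates, "sum"),
       ks_split = ks_split, ks_flux = ks_flux)
}
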