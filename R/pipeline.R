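#' Run the full simulate-scan-date-markers-authenticate workflow
#'
#' Executes the pipeline stages on a simulated species pair and writes
#' per-stage outputs plus a machine-readable summary. Stages: simulate the
#' scenario; scan each species' mitochondrial genome against its plastid;
#' project both species onto the plastid of species A as a backbone; date
#' the species split and the flux episode from Ks; call inter-species
#' plastid variants and design markers; classify each marker as
#' SAFE/PARADOX; simulate allele depths and estimate the copy fraction;
#' simulate a genotype table and evaluate both authentication rules.
#'
#' One global `seed` fans out to per-stage seeds by fixed offsets, so a
#' rerun with the same configuration is byte-identical and individual
#' stages can be reproduced in isolation.
#'
#' @param scenario A [flux_scenario()] (its `seed` is the global seed).
#' @param out_dir Output directory (`NULL` = no files written).
#' @param params A [scan_params()].
#' @param rates A [rate_model()].
#' @param total_depth Read depth for the simulated diagnostic sites.
#' @param genotype Options for the genotype stage: list with `n_target`,
#'   `n_other`, `n_markers`, `offtype_freq`, `target_in_other_freq`.
#' @return The summary list (also written as `summary.json` when `out_dir`
#'   is set): coverage fractions, dated times, marker safety classes and
#'   rule metrics.
#' @export
run_pipeline <- function(scenario = flux_scenario(), out_dir = NULL,
                         params = scan_params(), rates = rate_model(),
                         total_depth = 1000L,
                         genotype = list(n_target = 27L, n_other = 26L,
                                         n_markers = 3L,
                                         offtype_freq = 0.2,
                                         target_in_other_freq = 0.02)) {
  seed <- scenario$seed
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(x, name, writer = write_tsv) {
    if (!is.null(out_dir)) writer(x, file.path(out_dir, name))
    x
  }

  ## stage 1: simulate
  pair <- simulate_flux_scenario(scenario)
  if (!is.null(out_dir)) {
    write_fasta(c(A_pt = pair$species_a$plastid$sequence,
                  A_mt = pair$species_a$mito$sequence,
                  B_pt = pair$species_b$plastid$sequence,
                  B_mt = pair$species_b$mito$sequence),
                file.path(out_dir, "genomes.fasta"))
    write_gff3(pair$species_a$plastid, file.path(out_dir, "A_pt.gff3"))
    write_gff3(pair$species_a$mito, file.path(out_dir, "A_mt.gff3"))
    write_bed(data.frame(chrom = "A_mt",
                         start = pair$mtpt_truth$mito_start,
                         end = pair$mtpt_truth$mito_end,
                         name = sprintf("mtpt%d",
                                        seq_len(nrow(pair$mtpt_truth)))),
              file.path(out_dir, "mtpt_truth.bed"))
  }

  ## stage 2: scan both species
  seg_a <- find_mtpt_segments(pair$species_a$mito, pair$species_a$plastid,
                              params)
  seg_b <- find_mtpt_segments(pair$species_b$mito, pair$species_b$plastid,
                              params)
  emit(seg_a, "segments_A.tsv"); emit(seg_b, "segments_B.tsv")
  cov_a <- coverage_fraction(seg_a, genome_length(pair$species_a$plastid))
  cov_b <- coverage_fraction(seg_b, genome_length(pair$species_b$plastid))

  ## stage 3: backbone projection (plastid A as backbone; B's segments are
  ## indexed to B's plastid, which shares coordinates in this
  ## substitution-only simulation)
  profile <- project_to_backbone(list(A = seg_a, B = seg_b),
                                 pair$species_a$plastid)
  genes <- pair$species_a$plastid$features
  genes <- genes[genes$type == "CDS", , drop = FALSE]
  gene_freq <- classify_gene_frequency(profile, genes,
                                       most_frequent_above = 1L,
                                       moderate_above = 0L)
  emit(gene_freq, "gene_frequency.tsv")
  emit(data.frame(position = seq_len(profile$length) - 1L,
                  depth = profile$depth), "depth_profile.tsv")

  ## stage 4: Ks dating
  dating <- date_species_pair(pair, rates)
  emit(dating$ks_split, "ks_split.tsv")
  emit(dating$ks_flux, "ks_flux.tsv")

  ## stage 5: markers and co-amplification
  sites <- call_variants(pair$species_a$plastid, pair$species_b$plastid)
  sites_f <- filter_promiscuous(sites, het_a = 0, het_b = 0)
  markers <- design_markers(sites_f, pair$species_a$plastid)
  emit(markers, "markers.tsv")
  coamp <- lapply(seq_len(nrow(markers)), function(i) {
    assess_coamplification(markers[i, ], pair$species_a$plastid,
                           pair$species_a$mito, seg_a)
  })
  marker_classes <- vapply(coamp, `[[`, character(1), "classification")

  ## stage 6: copy fraction from simulated depths
  depths <- simulate_allele_depths(scenario$copy_fraction_pt, total_depth,
                                   n_sites = 4L, seed = seed + 1001L)
  emit(depths, "allele_depths.tsv")
  cf <- copy_fraction(sum(depths$depth_pt), sum(depths$depth_mt))

  ## stage 7: authentication
  gt <- simulate_genotype_table(
    n_target = genotype$n_target, n_other = genotype$n_other,
    n_markers = genotype$n_markers, offtype_freq = genotype$offtype_freq,
    target_in_other_freq = genotype$target_in_other_freq,
    seed = seed + 1002L)
  if (!is.null(out_dir)) {
    write_genotype_table(gt, file.path(out_dir, "genotypes.tsv"))
  }
  metrics <- evaluate_rules(gt)
  emit(metrics, "rule_metrics.tsv")

  summary <- list(
    seed = seed,
    coverage_fraction = list(A = cov_a, B = cov_b),
    n_segments = list(A = nrow(seg_a), B = nrow(seg_b)),
    t_split_hat = dating$t_split_hat,
    t_flux_hat = dating$t_flux_hat,
    marker_classes = as.list(stats::setNames(marker_classes, markers$name)),
    copy_fraction_pt_percent = cf$percent_pt,
    rule_metrics = metrics)
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary
}
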