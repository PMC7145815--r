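make_genome <- function(seq, feats = empty_features(), id = "g") {
  annotated_genome(id, seq, feats)
}

test_that("variant calling finds planted SNPs and InDels at their coordinates", {
  set.seed(20)
  a <- random_dna(20000)
  g_a <- make_genome(a, id = "a")
  expect_equal(nrow(call_variants(g_a, make_genome(a, id = "b"))), 0L)
  ## one substitution
  pos <- 12345
  b <- a
  old <- substr(b, pos + 1, pos + 1)
  substr(b, pos + 1, pos + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
  v <- call_variants(g_a, make_genome(b, id = "b"))
  expect_equal(nrow(v), 1L)
  expect_equal(v$type, "SNP")
  expect_equal(v$pos, pos)
  expect_equal(v$allele_a, old)
  ## a 348 bp deletion in b
  b2 <- paste0(substr(a, 1, 8000), substr(a, 8349, 20000))
  v2 <- call_variants(g_a, make_genome(b2, id = "b"))
  expect_equal(nrow(v2), 1L)
  expect_equal(v2$type, "InDel")
  expect_equal(v2$indel_length, 348L)
  expect_equal(nchar(v2$allele_a) - nchar(v2$allele_b), 348L)
})

test_that("variant calling is symmetric up to allele swapping", {
  set.seed(21)
  a <- random_dna(8000)
  b <- mutate_dna(a, 0.002)
  v_ab <- call_variants(make_genome(a, id = "a"), make_genome(b, id = "b"))
  v_ba <- call_variants(make_genome(b, id = "b"), make_genome(a, id = "a"))
  expect_equal(nrow(v_ab), nrow(v_ba))
  expect_equal(v_ab$allele_a, v_ba$allele_b)
  expect_equal(v_ab$allele_b, v_ba$allele_a)
  expect_equal(v_ab$pos, v_ba$pos)  # identical coordinates: no indels planted
})

test_that("unrelated sequences are rejected as non-homologous", {
  set.seed(22)
  expect_error(call_variants(make_genome(random_dna(5000), id = "a"),
                             make_genome(random_dna(5000), id = "b")),
               "homologous")
})

test_that("heterogeneous-depth sites are eliminated above 3 percent only", {
  sites <- data.frame(pos = c(10, 20, 30, 40), type = "SNP",
                      allele_a = "A", allele_b = "G", indel_length = 0L)
  out <- filter_promiscuous(sites, het_a = c(0.12, 0, 0.03, 0.031),
                            het_b = 0)
  expect_equal(out$pos, c(20, 30))  # 12% and 3.1% dropped; exactly 3% kept
  ## either accession can disqualify a site
  out2 <- filter_promiscuous(sites, het_a = 0, het_b = c(0, 0.5, 0, 0))
  expect_equal(out2$pos, c(10, 30, 40))
  expect_warning(out3 <- filter_promiscuous(sites, het_a = NA, het_b = 0),
                 "without read support")
  expect_equal(nrow(out3), 4L)
  expect_true(all(out3$depth_missing))
})

test_that("marker design applies the InDel-length and SNP-spacing rules", {
  set.seed(23)
  a <- random_dna(20000)
  g_a <- make_genome(a, id = "a")
  ## 348 bp deletion in b -> codominant InDel marker, products differ by 348
  b <- paste0(substr(a, 1, 9000), substr(a, 9349, 20000))
  v <- call_variants(g_a, make_genome(b, id = "b"))
  mk <- design_markers(v, g_a)
  expect_equal(nrow(mk), 1L)
  expect_equal(mk$mode, "codominant_InDel")
  expect_equal(abs(mk$amplicon_a - mk$amplicon_b), 348L)
  ## the predicted product sizes are real: amplify both genomes in silico
  amp_a <- in_silico_pcr(mk$forward, mk$reverse, g_a)
  amp_b <- in_silico_pcr(mk$forward, mk$reverse, make_genome(b, id = "b"))
  expect_equal(amp_a$length, mk$amplicon_a)
  expect_equal(amp_b$length, mk$amplicon_b)
  ## a 15 bp InDel yields no marker
  b15 <- paste0(substr(a, 1, 9000), substr(a, 9016, 20000))
  v15 <- call_variants(g_a, make_genome(b15, id = "b"))
  expect_equal(v15$indel_length, 15L)
  expect_equal(nrow(design_markers(v15, g_a)), 0L)
  ## two SNPs 100 bp apart are both excluded
  b2 <- a
  for (p in c(5001, 5101)) {
    old <- substr(b2, p, p)
    substr(b2, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  v2 <- call_variants(g_a, make_genome(b2, id = "b"))
  expect_equal(nrow(v2), 2L)
  expect_equal(nrow(design_markers(v2, g_a)), 0L)
  ## one isolated SNP yields a codominant SNP marker in the amplicon range
  b3 <- a
  substr(b3, 5001, 5001) <- setdiff(c("A", "C", "G", "T"),
                                    substr(a, 5001, 5001))[1]
  v3 <- call_variants(g_a, make_genome(b3, id = "b"))
  mk3 <- design_markers(v3, g_a)
  expect_equal(nrow(mk3), 1L)
  expect_equal(mk3$mode, "codominant_SNP")
  expect_gte(mk3$amplicon_a, 100L)
  expect_lte(mk3$amplicon_a, 150L)
  amp3 <- in_silico_pcr(mk3$forward, mk3$reverse, g_a)
  expect_equal(nrow(amp3), 1L)
  ## the target SNP lies inside the product
  expect_true(amp3$start < 5000 && amp3$end > 5001)
})

test_that("in-silico PCR finds convergent primer pairs and respects the 3' end", {
  set.seed(24)
  templ <- random_dna(3000)
  fwd <- substr(templ, 1001, 1020)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(templ, 1181, 1200))))
  amp <- in_silico_pcr(fwd, rev, templ)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 1000L)
  expect_equal(amp$end, 1200L)
  expect_equal(amp$length, 200L)
  ## absent reverse primer: nothing
  expect_equal(nrow(in_silico_pcr(fwd, random_dna(20), templ)), 0L)
  ## a mismatch at the 3' terminal trimer kills the binding site
  fwd_bad <- fwd
  substr(fwd_bad, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                     substr(fwd, 20, 20))[1]
  expect_equal(nrow(in_silico_pcr(fwd_bad, rev, templ)), 0L)
  ## up to two internal mismatches are tolerated
  fwd_mm <- fwd
  substr(fwd_mm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 5, 5))[1]
  substr(fwd_mm, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(fwd, 9, 9))[1]
  amp_mm <- in_silico_pcr(fwd_mm, rev, templ)
  expect_equal(nrow(amp_mm), 1L)
  expect_equal(amp_mm$mismatches, 2L)
  ## strand symmetry: reverse-complementing the template mirrors products
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(templ)))
  amp_rc <- in_silico_pcr(fwd, rev, rc)
  expect_equal(nrow(amp_rc), 1L)
  expect_equal(amp_rc$length, amp$length)
  expect_equal(amp_rc$start, 3000L - amp$end)
})

test_that("a template with an MTPT copy of the locus yields two products", {
  set.seed(25)
  plast <- random_dna(5000)
  locus <- substr(plast, 2001, 2200)
  mito <- paste0(random_dna(1000), locus, random_dna(1000))
  fwd <- substr(locus, 1, 20)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(locus, 181, 200))))
  both <- rbind(in_silico_pcr(fwd, rev, make_genome(plast, id = "pt")),
                in_silico_pcr(fwd, rev, make_genome(mito, id = "mt")))
  expect_equal(nrow(both), 2L)
  expect_setequal(both$template_id, c("pt", "mt"))
})

test_that("markers inside planted MTPT blocks are PARADOX, outside are SAFE", {
  sc <- flux_scenario(t_split = 0, t_flux = 0, plastid_length = 30000,
                      n_genes = 8, mtpt_fraction = 0.3, seed = 31)
  pair <- simulate_flux_scenario(sc)
  plast <- pair$species_a$plastid
  mito <- pair$species_a$mito
  seg <- find_mtpt_segments(mito, plast)
  tr <- pair$mtpt_truth
  inside <- function(p) any(p >= tr$plastid_start + 100 &
                              p <= tr$plastid_end - 300)
  pick_pos <- function(want_inside) {
    for (p in seq(500, 29000, by = 97)) {
      if (want_inside == inside(p)) {
        ## avoid annotated features so primers sit in neutral sequence
        f <- plast$features
        if (!any(p + 250 > f$start & p < f$end)) return(p)
      }
    }
    NA
  }
  make_marker <- function(p) {
    locus <- substr(plast$sequence, p + 1, p + 220)
    list(name = sprintf("m%d", p),
         forward = substr(locus, 1, 20),
         reverse = as.character(Biostrings::reverseComplement(
           Biostrings::DNAString(substr(locus, 201, 220)))))
  }
  p_in <- pick_pos(TRUE); p_out <- pick_pos(FALSE)
  expect_false(is.na(p_in)); expect_false(is.na(p_out))
  res_in <- assess_coamplification(make_marker(p_in), plast, mito, seg)
  expect_equal(res_in$classification, "PARADOX")
  expect_gte(length(res_in$mito_bands), 1L)
  res_out <- assess_coamplification(make_marker(p_out), plast, mito, seg)
  expect_equal(res_out$classification, "SAFE")
  expect_equal(length(res_out$mito_bands), 0L)
})

test_that("copy fractions reproduce read-depth arithmetic with integer percents", {
  cf <- copy_fraction(1045, 141)
  expect_equal(cf$percent_pt, 88L)
  expect_equal(cf$percent_mt, 12L)
  cf2 <- copy_fraction(1889, 297)
  expect_equal(cf2$percent_pt, 86L)
  expect_equal(cf2$percent_mt, 14L)
  cf3 <- copy_fraction(100, 0)
  expect_equal(cf3$percent_pt, 100L)
  expect_equal(cf3$fraction_mt, 0)
  expect_error(copy_fraction(0, 0), "positive")
  ## percentages reconcile to 100 for arbitrary depths
  set.seed(26)
  for (i in 1:50) {
    d <- sample(1:5000, 2)
    cf <- copy_fraction(d[1], d[2])
    expect_equal(cf$percent_pt + cf$percent_mt, 100L)
  }
})

test_that("band visibility is monotone and minor templates need extra cycles", {
  expect_false(band_visibility(0, 60, threshold = 1e6))
  set.seed(27)
  for (i in 1:20) {
    copies <- runif(1, 1, 100); cycles <- sample(0:40, 1); thr <- 10^runif(1, 3, 9)
    v <- band_visibility(copies, cycles, thr)
    expect_true(!v || band_visibility(copies * 2, cycles, thr))
    expect_true(!v || band_visibility(copies, cycles + 1, thr))
  }
  ## 88:12 template ratio: with threshold 88*2^10 the major template shows at
  ## 10 cycles and the minor needs ceiling(log2(88/12)) = 3 extra
  thr <- 88 * 2^10
  expect_equal(min_cycles_visible(88, thr), 10)
  expect_equal(min_cycles_visible(12, thr) - min_cycles_visible(88, thr),
               ceiling(log2(88 / 12)))
})
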