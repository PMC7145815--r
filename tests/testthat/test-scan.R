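make_genome <- function(seq, feats = empty_features(), id = "g") {
  annotated_genome(id, seq, feats)
}

test_that("feature masks merge overlapping and adjacent intervals", {
  f <- data.frame(type = c("tRNA", "rRNA"), start = c(100, 150),
                  end = c(180, 400), strand = "+", name = c("t", "r"))
  g <- make_genome(random_dna(500), f)
  m <- mask_features(g)
  expect_equal(m, data.frame(start = 100L, end = 400L))
  ## adjacent half-open intervals merge
  f2 <- data.frame(type = c("tRNA", "tRNA"), start = c(10, 20),
                   end = c(20, 30), strand = "+", name = c("a", "b"))
  g2 <- make_genome(random_dna(100), f2)
  expect_equal(mask_features(g2), data.frame(start = 10L, end = 30L))
  ## no masked features -> empty mask
  g3 <- make_genome(random_dna(100))
  expect_equal(nrow(mask_features(g3)), 0L)
  expect_warning(mask_features(g3, types = "promoter"), "unknown")
})

test_that("E-value follows the Karlin-Altschul form", {
  expect_equal(evalue(0, 100, 200, 1.33, 0.621), 0.621 * 100 * 200)
  expect_equal(evalue(50, 1e5, 1e5, 1.33, 0.621),
               0.621 * 1e10 * exp(-66.5))
  ## enormous scores underflow cleanly to zero
  expect_identical(evalue(1e6, 10, 10, 1.33, 0.621), 0)
})

test_that("a genome scanned against itself yields one full-length segment", {
  set.seed(42)
  g <- make_genome(random_dna(8000))
  seg <- find_mtpt_segments(make_genome(g$sequence, id = "m"), g,
                            mask_types = NULL)
  plus <- seg[seg$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$plastid_start, 0L)
  expect_equal(plus$plastid_end, 8000L)
  expect_equal(plus$identity, 1.0)
  expect_equal(coverage_fraction(seg, 8000), 1.0)
})

test_that("a planted diverged block is recovered with tight coordinates", {
  set.seed(7)
  plast <- random_dna(6000)
  block <- substr(plast, 2001, 2500)            # 500 bp source
  block_mut <- mutate_dna(block, 0.10)          # ~90% identity
  mito <- paste0(random_dna(1500), block_mut, random_dna(1500))
  seg <- find_mtpt_segments(make_genome(mito, id = "m"), make_genome(plast),
                            mask_types = NULL)
  expect_gte(nrow(seg), 1L)
  best <- seg[which.max(seg$score), ]
  expect_lte(abs(best$plastid_start - 2000), 5)
  expect_lte(abs(best$plastid_end - 2500), 5)
  expect_lte(abs(best$mito_start - 1500), 5)
  expect_gte(best$identity, 0.85)
})

test_that("a 25 bp perfect block fails the 30 bp length filter", {
  set.seed(9)
  plast <- random_dna(4000)
  block <- substr(plast, 1001, 1025)
  mito <- paste0(random_dna(800), block, random_dna(800))
  seg <- find_mtpt_segments(make_genome(mito, id = "m"), make_genome(plast),
                            mask_types = NULL)
  covering <- seg$plastid_start <= 1000 & seg$plastid_end >= 1025
  expect_false(any(covering))
})

test_that("segments overlapping the tRNA/rRNA mask are dropped or trimmed", {
  set.seed(11)
  plast_seq <- random_dna(5000)
  ## plant a copy of [1000,1600) in the mito; mask [1000,1400) (>50% of span)
  mito <- paste0(random_dna(500), substr(plast_seq, 1001, 1600),
                 random_dna(500))
  f <- data.frame(type = "rRNA", start = 1000, end = 1400, strand = "+",
                  name = "rrn")
  plast <- make_genome(plast_seq, f)
  seg_masked <- find_mtpt_segments(make_genome(mito, id = "m"), plast)
  seg_open <- find_mtpt_segments(make_genome(mito, id = "m"), plast,
                                 mask_types = NULL)
  expect_true(any(seg_open$plastid_start <= 1000 & seg_open$plastid_end >= 1600))
  ## with the mask, nothing may cover the masked interval
  if (nrow(seg_masked)) {
    ov <- pmin(seg_masked$plastid_end, 1400) -
      pmax(seg_masked$plastid_start, 1000)
    expect_true(all(ov <= 0.5 * (seg_masked$plastid_end -
                                   seg_masked$plastid_start)))
  }
  ## mask on a minority of the span: segment survives, trimmed
  f2 <- data.frame(type = "rRNA", start = 1000, end = 1100, strand = "+",
                   name = "rrn")
  plast2 <- make_genome(plast_seq, f2)
  seg2 <- find_mtpt_segments(make_genome(mito, id = "m"), plast2)
  hit <- seg2[seg2$plastid_end >= 1500, ]
  expect_gte(nrow(hit), 1L)
  expect_gte(min(hit$plastid_start), 1100)
})

test_that("scanning against the reverse-complemented plastid flips strands", {
  set.seed(13)
  plast_seq <- random_dna(4000)
  block <- substr(plast_seq, 1501, 2200)
  mito <- paste0(random_dna(600), mutate_dna(block, 0.05), random_dna(600))
  m <- make_genome(mito, id = "m")
  seg_fwd <- find_mtpt_segments(m, make_genome(plast_seq), mask_types = NULL)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plast_seq)))
  seg_rc <- find_mtpt_segments(m, make_genome(rc), mask_types = NULL)
  expect_equal(nrow(seg_fwd), nrow(seg_rc))
  L <- 4000
  mirrored <- data.frame(
    plastid_start = L - seg_rc$plastid_end,
    plastid_end = L - seg_rc$plastid_start,
    strand = ifelse(seg_rc$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$plastid_start), ]
  expect_equal(mirrored$plastid_start, seg_fwd$plastid_start)
  expect_equal(mirrored$plastid_end, seg_fwd$plastid_end)
  expect_equal(mirrored$strand, seg_fwd$strand)
  expect_equal(sort(seg_rc$score), sort(seg_fwd$score))
})

test_that("tightening any filter never adds a segment", {
  set.seed(17)
  key <- function(seg) {
    paste(seg$plastid_start, seg$plastid_end, seg$mito_start, seg$strand)
  }
  for (rep in 1:5) {
    plast <- random_dna(3000)
    mito <- paste0(random_dna(400),
                   mutate_dna(substr(plast, 501, 900), 0.12),
                   random_dna(200),
                   mutate_dna(substr(plast, 1501, 1700), 0.05),
                   random_dna(400))
    m <- make_genome(mito, id = "m"); p <- make_genome(plast)
    base <- scan_params(min_identity = 0.70, min_length = 30,
                        max_evalue = 1e-8)
    loose <- find_mtpt_segments(m, p, base, mask_types = NULL)
    for (tight in list(scan_params(min_identity = 0.85, min_length = 30,
                                   max_evalue = 1e-8),
                       scan_params(min_identity = 0.70, min_length = 120,
                                   max_evalue = 1e-8),
                       scan_params(min_identity = 0.70, min_length = 30,
                                   max_evalue = 1e-14))) {
      seg <- find_mtpt_segments(m, p, tight, mask_types = NULL)
      expect_true(all(key(seg) %in% key(loose)))
    }
  }
})

test_that("coverage fraction is a union and ignores segment order/splits", {
  seg <- data.frame(plastid_start = c(0, 50), plastid_end = c(100, 150))
  expect_equal(coverage_fraction(seg, 1000), 0.15)
  expect_equal(coverage_fraction(seg[2:1, ], 1000), 0.15)
  split3 <- data.frame(plastid_start = c(0, 40, 50),
                       plastid_end = c(40, 100, 150))
  expect_equal(coverage_fraction(split3, 1000), 0.15)
  expect_equal(coverage_fraction(seg[0, ], 1000), 0)
})

test_that("backbone depth counts each species at most once per position", {
  bb <- make_genome(random_dna(100), id = "bb")
  seg1 <- data.frame(plastid_start = c(0, 5), plastid_end = c(10, 8))
  seg2 <- data.frame(plastid_start = 0, plastid_end = 10)
  seg3 <- data.frame(plastid_start = 0, plastid_end = 10)
  prof <- project_to_backbone(list(a = seg1, b = seg2, c = seg3), bb)
  expect_equal(prof$depth[1:10], rep(3L, 10))
  expect_equal(prof$depth[11:100], rep(0L, 90))
  expect_equal(prof$n_species, 3L)
  expect_true(all(prof$depth <= prof$n_species))
  bad <- data.frame(plastid_start = 90, plastid_end = 120)
  expect_error(project_to_backbone(list(a = bad), bb), "beyond")
})

test_that("gene frequency classes follow the >20 / >10 species thresholds", {
  bb <- make_genome(random_dna(1000), id = "bb")
  gene <- data.frame(type = "CDS", start = 100, end = 200, strand = "+",
                     name = "rbcL")
  cover <- data.frame(plastid_start = 100, plastid_end = 200)
  none <- data.frame(plastid_start = 500, plastid_end = 600)
  make_prof <- function(n_cover, n_total) {
    segs <- c(replicate(n_cover, cover, simplify = FALSE),
              replicate(n_total - n_cover, none, simplify = FALSE))
    names(segs) <- sprintf("sp%02d", seq_len(n_total))
    project_to_backbone(segs, bb)
  }
  expect_equal(classify_gene_frequency(make_prof(25, 40), gene)$class,
               "most_frequent")
  expect_equal(classify_gene_frequency(make_prof(12, 40), gene)$class,
               "moderate")
  expect_equal(classify_gene_frequency(make_prof(3, 40), gene)$class, "rare")
  ## a species covering less than half the gene does not count
  partial <- data.frame(plastid_start = 100, plastid_end = 140)
  prof <- project_to_backbone(list(a = partial, b = cover), bb)
  expect_equal(classify_gene_frequency(prof, gene)$count, 1L)
  ## barcode report inherits the same counting
  rep <- barcode_overlap_report(make_prof(25, 40), gene)
  expect_equal(rep$count, 25L)
  expect_equal(rep$class, "most_frequent")
  outside <- data.frame(type = "region", start = 800, end = 900,
                        strand = "+", name = "trnH-psbA")
  expect_equal(barcode_overlap_report(make_prof(25, 40), outside)$count, 0L)
})
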