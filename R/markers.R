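## ---- variant calling between two plastid genomes ---------------------------

## collinear anchor chain of shared unique k-mers (longest increasing
## subsequence on the b-side); anchors are (apos, bpos) 0-based
.anchor_chain <- function(a_int, b_int, k = 25L) {
  ca <- kmer_codes(a_int, k)
  cb <- kmer_codes(b_int, k)
  ua <- which(!is.na(ca) & !(ca %in% ca[duplicated(ca)]))
  ub <- which(!is.na(cb) & !(cb %in% cb[duplicated(cb)]))
  common <- intersect(ca[ua], cb[ub])
  if (length(common) == 0L) {
    return(data.frame(apos = integer(), bpos = integer()))
  }
  apos <- ua[match(common, ca[ua])]
  bpos <- ub[match(common, cb[ub])]
  o <- order(apos)
  apos <- apos[o]; bpos <- bpos[o]
  ## longest strictly increasing subsequence of bpos
  n <- length(bpos)
  tails <- integer(0); tail_idx <- integer(0); prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(bpos[i] - 1L, tails) + 1L
    prev[i] <- if (j > 1L) tail_idx[j - 1L] else 0L
    tails[j] <- bpos[i]
    tail_idx[j] <- i
    length(tails) <- j      # truncate stale tails above j
    length(tail_idx) <- j
  }
  path <- integer(0)
  cur <- tail_idx[length(tail_idx)]
  while (cur > 0L) { path <- c(cur, path); cur <- prev[cur] }
  out <- data.frame(apos = apos[path] - 1L, bpos = bpos[path] - 1L)
  ## drop anchors overlapping the previous one (possible at indel junctions
  ## where a k-mer spans the breakpoint); overlap would let one base be
  ## "matched" twice and corrupt slice lengths
  keep <- logical(nrow(out))
  last_a <- -k; last_b <- -k
  for (i in seq_len(nrow(out))) {
    if (out$apos[i] >= last_a + k && out$bpos[i] >= last_b + k) {
      keep[i] <- TRUE
      last_a <- out$apos[i]; last_b <- out$bpos[i]
    }
  }
  out[keep, , drop = FALSE]
}

## parse one aligned slice (equal-length gapped strings, 0-based offset of
## the slice start on genome a) into SNP / InDel records
.slice_variants <- function(al_a, al_b, a_off) {
  va <- strsplit(al_a, "")[[1]]
  vb <- strsplit(al_b, "")[[1]]
  n <- length(va)
  apos <- cumsum(va != "-") + a_off  # 1-based a coordinate per column
  out <- list(); m <- 0L
  i <- 1L
  while (i <= n) {
    if (va[i] == vb[i] || (va[i] != "-" && vb[i] != "-")) {
      if (va[i] != vb[i]) {  # SNP column
        m <- m + 1L
        out[[m]] <- data.frame(pos = apos[i] - 1L, type = "SNP",
                               allele_a = va[i], allele_b = vb[i],
                               indel_length = 0L, stringsAsFactors = FALSE)
      }
      i <- i + 1L
    } else {
      ## gap run (in either sequence)
      j <- i
      while (j <= n && (va[j] == "-" || vb[j] == "-")) j <- j + 1L
      run <- i:(j - 1L)
      aa <- paste(va[run][va[run] != "-"], collapse = "")
      bb <- paste(vb[run][vb[run] != "-"], collapse = "")
      m <- m + 1L
      out[[m]] <- data.frame(
        pos = if (va[i] == "-") apos[i] - 1L else apos[i] - 1L,
        type = "InDel", allele_a = aa, allele_b = bb,
        indel_length = abs(nchar(aa) - nchar(bb)),
        stringsAsFactors = FALSE)
      i <- j
    }
  }
  if (m == 0L) return(NULL)
  do.call(rbind, out[seq_len(m)])
}

#' Call variants between two homologous plastid genomes
#'
#' Anchored global comparison: collinear unique-`k`-mer anchors partition the
#' genomes into short inter-anchor slices; equal-length slices are compared
#' column-wise and unequal slices are globally aligned, yielding SNPs and
#' InDels (gap-run length = `indel_length`). Positions are reported on
#' genome `a`, 0-based.
#'
#' @param plastid_a,plastid_b [annotated_genome()] objects.
#' @param anchor_k Anchor k-mer size.
#' @param min_alignable Reject as non-homologous when the anchored fraction
#'   of genome `a` falls below this value.
#' @return A data.frame of class `variant_sites`: `pos`, `type`
#'   (`SNP`/`InDel`), `allele_a`, `allele_b`, `indel_length`.
#' @export
call_variants <- function(plastid_a, plastid_b, anchor_k = 25L,
                          min_alignable = 0.5) {
  stopifnot(inherits(plastid_a, "AnnotatedGenome"),
            inherits(plastid_b, "AnnotatedGenome"))
  a_int <- dna_to_int(plastid_a$sequence)
  b_int <- dna_to_int(plastid_b$sequence)
  empty <- data.frame(pos = integer(), type = character(),
                      allele_a = character(), allele_b = character(),
                      indel_length = integer(), stringsAsFactors = FALSE)
  if (identical(plastid_a$sequence, plastid_b$sequence)) {
    class(empty) <- c("variant_sites", "data.frame")
    return(empty)
  }
  anch <- .anchor_chain(a_int, b_int, anchor_k)
  La <- length(a_int); Lb <- length(b_int)
  anchored <- nrow(anch) * anchor_k
  if (anchored < min_alignable * min(La, Lb)) {
    stop("genomes do not appear homologous (anchored fraction ",
         sprintf("%.2f", anchored / min(La, Lb)), " < ", min_alignable, ")")
  }
  ## slice boundaries: anchor midpoints are trusted matches
  bounds_a <- c(0L, anch$apos + anchor_k, La)
  bounds_b <- c(0L, anch$bpos + anchor_k, Lb)
  starts_a <- c(0L, anch$apos + anchor_k)
  starts_b <- c(0L, anch$bpos + anchor_k)
  ends_a <- c(anch$apos, La)
  ends_b <- c(anch$bpos, Lb)
  out <- list(); m <- 0L
  for (i in seq_along(starts_a)) {
    sa <- starts_a[i]; ea <- ends_a[i]
    sb <- starts_b[i]; eb <- ends_b[i]
    if (ea <= sa && eb <= sb) next
    slice_a <- subseq0(plastid_a$sequence, sa, max(ea, sa))
    slice_b <- subseq0(plastid_b$sequence, sb, max(eb, sb))
    if (nchar(slice_a) == 0L || nchar(slice_b) == 0L) {
      ## pure insertion/deletion between two anchors
      m <- m + 1L
      out[[m]] <- data.frame(
        pos = if (nchar(slice_a)) sa else max(sa - 1L, 0L),
        type = "InDel", allele_a = slice_a, allele_b = slice_b,
        indel_length = abs(nchar(slice_a) - nchar(slice_b)),
        stringsAsFactors = FALSE)
      next
    }
    if (nchar(slice_a) == nchar(slice_b)) {
      if (identical(slice_a, slice_b)) next
      al_a <- slice_a; al_b <- slice_b
    } else {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(slice_a), Biostrings::DNAString(slice_b),
        type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -2, baseOnly = TRUE),
        gapOpening = 5, gapExtension = 2)
      al_a <- as.character(Biostrings::alignedPattern(pa))
      al_b <- as.character(Biostrings::alignedSubject(pa))
    }
    v <- .slice_variants(al_a, al_b, sa)
    if (!is.null(v)) { m <- m + 1L; out[[m]] <- v }
  }
  res <- if (m) do.call(rbind, out[seq_len(m)]) else empty
  res <- res[order(res$pos), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("variant_sites", "data.frame")
  res
}

#' Drop variant sites with heterogeneous read support
#'
#' A diagnostic site whose reads are not near-homogeneous within an
#' accession indicates co-mapping reads from an MTPT copy of the locus.
#' Sites with a minor-allele read fraction of more than `max_het` (default
#' 3%) in either accession are eliminated; the boundary value is retained
#' (strictly "more than").
#'
#' @param sites A `variant_sites` data.frame.
#' @param het_a,het_b Per-site minor-allele read fractions in accessions a
#'   and b (recycled; `NA` = depth unavailable, site retained and flagged).
#' @param max_het Elimination threshold (exclusive).
#' @return The surviving sites, with a logical `depth_missing` column.
#' @export
filter_promiscuous <- function(sites, het_a, het_b, max_het = 0.03) {
  n <- nrow(sites)
  het_a <- rep_len(het_a, n); het_b <- rep_len(het_b, n)
  missing <- is.na(het_a) | is.na(het_b)
  if (any(missing)) {
    warning(sum(missing), " site(s) without read support retained unchecked")
  }
  drop <- !missing & (het_a > max_het | het_b > max_het)
  out <- sites[!drop, , drop = FALSE]
  out$depth_missing <- missing[!drop]
  rownames(out) <- NULL
  out
}

## ---- marker design ----------------------------------------------------------

.gc_fraction <- function(s) {
  v <- dna_to_int(s)
  mean(v == 1L | v == 2L)
}

## pick a primer_len-mer inside window [lo, hi) (0-based, on the plus strand
## of `genome_seq`) with GC in range and a unique occurrence in the genome;
## scans from the window edge nearest the target
.pick_primer <- function(genome_seq, lo, hi, primer_len, gc_range,
                         from_right) {
  starts <- lo:(hi - primer_len)
  if (from_right) starts <- rev(starts)
  for (s in starts) {
    p <- subseq0(genome_seq, s, s + primer_len)
    gc <- .gc_fraction(p)
    if (gc < gc_range[1] || gc > gc_range[2]) next
    hits <- length(Biostrings::matchPattern(p, Biostrings::DNAString(genome_seq)))
    if (hits == 1L) return(list(seq = p, start = s))
  }
  NULL
}

#' Design authentication markers from filtered variant sites
#'
#' Applies the marker-design rules: InDel sites longer than `min_indel` bp
#' become codominant InDel markers; SNP sites with no other variant within
#' `snp_spacing` bp become codominant SNP markers with an amplicon of
#' `amplicon_range` bp. Primers are unique `primer_len`-mers flanking the
#' target with GC content in `gc_range` (simple rule-based design; no
#' thermodynamics).
#'
#' @param sites Filtered `variant_sites` (see [filter_promiscuous()]).
#' @param plastid The [annotated_genome()] of accession a (primer template).
#' @param min_indel Minimum InDel length, exclusive (default: longer than
#'   20 bp).
#' @param snp_spacing A SNP is excluded if any other variant lies within
#'   this many bp (exclusive).
#' @param amplicon_range Target amplicon length range for SNP markers.
#' @param primer_len Primer length (nt).
#' @param gc_range Allowed primer GC fraction.
#' @return A data.frame of class `marker_defs`: `name`, `mode`, `forward`,
#'   `reverse`, `target_pos`, `indel_length`, `amplicon_a`, `amplicon_b`
#'   (expected product lengths per species).
#' @export
design_markers <- function(sites, plastid, min_indel = 20L,
                           snp_spacing = 150L, amplicon_range = c(100L, 150L),
                           primer_len = 20L, gc_range = c(0.40, 0.60)) {
  stopifnot(inherits(plastid, "AnnotatedGenome"))
  gseq <- plastid$sequence
  L <- nchar(gseq)
  empty <- data.frame(name = character(), mode = character(),
                      forward = character(), reverse = character(),
                      target_pos = integer(), indel_length = integer(),
                      amplicon_a = integer(), amplicon_b = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) {
    class(empty) <- c("marker_defs", "data.frame")
    return(empty)
  }
  out <- list(); m <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (s$type == "InDel") {
      if (s$indel_length <= min_indel) next
      span_a <- max(nchar(s$allele_a), 1L)  # site footprint on genome a
      flank <- 60L
      f_lo <- max(0L, s$pos - flank - primer_len)
      fwd <- .pick_primer(gseq, f_lo, s$pos, primer_len, gc_range,
                          from_right = TRUE)
      r_lo <- s$pos + span_a
      rev_ <- .pick_primer(gseq, r_lo, min(L, r_lo + flank + primer_len),
                           primer_len, gc_range, from_right = FALSE)
      if (is.null(fwd) || is.null(rev_)) {
        message("no primer window for InDel at ", s$pos, "; skipped")
        next
      }
      amp_a <- rev_$start + primer_len - fwd$start
      amp_b <- amp_a - nchar(s$allele_a) + nchar(s$allele_b)
      m <- m + 1L
      out[[m]] <- data.frame(
        name = sprintf("indel_%d", s$pos), mode = "codominant_InDel",
        forward = fwd$seq, reverse = revcomp(rev_$seq),
        target_pos = s$pos, indel_length = s$indel_length,
        amplicon_a = amp_a, amplicon_b = amp_b, stringsAsFactors = FALSE)
    } else {
      other <- sites$pos[-i]
      if (length(other) && any(abs(other - s$pos) < snp_spacing)) next
      half <- (amplicon_range[1] + amplicon_range[2]) %/% 4L
      f_hi <- max(0L, s$pos - half)
      fwd <- .pick_primer(gseq, max(0L, f_hi - 40L), max(primer_len, f_hi + 20L),
                          primer_len, gc_range, from_right = TRUE)
      if (is.null(fwd)) {
        message("no forward primer window for SNP at ", s$pos, "; skipped")
        next
      }
      ## choose the reverse primer so the product lands in amplicon_range
      rev_ <- NULL
      for (amp in amplicon_range[1]:amplicon_range[2]) {
        r_end <- fwd$start + amp
        if (r_end > L || r_end - primer_len <= s$pos) next
        p <- subseq0(gseq, r_end - primer_len, r_end)
        gc <- .gc_fraction(p)
        if (gc < gc_range[1] || gc > gc_range[2]) next
        hits <- length(Biostrings::matchPattern(
          p, Biostrings::DNAString(gseq)))
        if (hits == 1L) { rev_ <- list(seq = p, end = r_end); break }
      }
      if (is.null(rev_)) {
        message("no reverse primer window for SNP at ", s$pos, "; skipped")
        next
      }
      amp <- rev_$end - fwd$start
      m <- m + 1L
      out[[m]] <- data.frame(
        name = sprintf("snp_%d", s$pos), mode = "codominant_SNP",
        forward = fwd$seq, reverse = revcomp(rev_$seq),
        target_pos = s$pos, indel_length = 0L,
        amplicon_a = amp, amplicon_b = amp, stringsAsFactors = FALSE)
    }
  }
  res <- if (m) do.call(rbind, out[seq_len(m)]) else empty
  rownames(res) <- NULL
  class(res) <- c("marker_defs", "data.frame")
  res
}

## ---- in-silico PCR ----------------------------------------------------------

## binding sites of `primer` on `template_int` with <= max_mismatch
## mismatches and an exact 3' terminal 3-mer. Returns 0-based starts of the
## primer footprint on the plus strand plus the mismatch count.
## orientation "fwd": primer as given, 3' end on the right;
## orientation "rev": reverse complement laid on the plus strand, 3' end on
## the left.
.primer_sites <- function(template_int, primer, max_mismatch, orientation) {
  p <- if (orientation == "fwd") primer else revcomp(primer)
  pv <- dna_to_int(p)
  k <- length(pv)
  n <- length(template_int) - k + 1L
  if (n < 1L) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  mm <- integer(n)
  for (j in seq_len(k)) {
    x <- template_int[j:(j + n - 1L)]
    mm <- mm + as.integer(is.na(x) | x != pv[j])
  }
  three_prime <- if (orientation == "fwd") (k - 2L):k else 1L:3L
  exact3 <- rep(TRUE, n)
  for (j in three_prime) {
    x <- template_int[j:(j + n - 1L)]
    exact3 <- exact3 & !is.na(x) & x == pv[j]
  }
  hit <- which(mm <= max_mismatch & exact3)
  data.frame(start = hit - 1L, mismatches = mm[hit])
}

#' Predict PCR amplicons on a template
#'
#' Finds all binding sites of both primers on both strands (allowing up to
#' `max_mismatch` mismatches but requiring an exact 3' terminal 3-mer, a
#' permissive model of lab PCR) and reports every convergent
#' forward/reverse site pair within `max_len` bp. With MTPT copies of a
#' marker locus present, the same primer pair yields products in both
#' organelle compartments - the mechanism of the barcoding paradox.
#'
#' @param forward,reverse Primer sequences (5'->3', >= 15 nt).
#' @param template An [annotated_genome()] or a DNA string.
#' @param max_mismatch Mismatch tolerance per primer (default 2).
#' @param max_len Maximum product length (default 5000).
#' @return A data.frame of class `amplicons`: `template_id`, `start`, `end`
#'   (0-based half-open product span), `length`, `mismatches` (sum over both
#'   primers), ordered by `start`.
#' @export
in_silico_pcr <- function(forward, reverse, template, max_mismatch = 2L,
                          max_len = 5000L) {
  stopifnot(nchar(forward) >= 15L, nchar(reverse) >= 15L)
  if (inherits(template, "AnnotatedGenome")) {
    id <- template$id
    tseq <- template$sequence
  } else {
    id <- "template"
    tseq <- toupper(as.character(template))
  }
  t_int <- dna_to_int(tseq)
  ## plus-strand-anchored sites (3' pointing right) from either primer, and
  ## minus-strand-anchored sites (3' pointing left)
  tag <- function(sites, primer, len) {
    sites$primer <- rep(primer, nrow(sites))
    sites$len <- rep(len, nrow(sites))
    sites
  }
  plus <- rbind(
    tag(.primer_sites(t_int, forward, max_mismatch, "fwd"), "F",
        nchar(forward)),
    tag(.primer_sites(t_int, reverse, max_mismatch, "fwd"), "R",
        nchar(reverse)))
  minus <- rbind(
    tag(.primer_sites(t_int, forward, max_mismatch, "rev"), "F",
        nchar(forward)),
    tag(.primer_sites(t_int, reverse, max_mismatch, "rev"), "R",
        nchar(reverse)))
  out <- list(); m <- 0L
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      if (plus$primer[i] == minus$primer[j]) next  # need both primers
      s <- plus$start[i]
      e <- minus$start[j] + minus$len[j]
      if (e <= s + plus$len[i]) next  # must be convergent
      if (e - s > max_len) next
      m <- m + 1L
      out[[m]] <- data.frame(
        template_id = id, start = s, end = e, length = e - s,
        mismatches = plus$mismatches[i] + minus$mismatches[j],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (m) do.call(rbind, out[seq_len(m)]) else data.frame(
    template_id = character(), start = integer(), end = integer(),
    length = integer(), mismatches = integer(), stringsAsFactors = FALSE)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("amplicons", "data.frame")
  res
}

#' Classify a marker as SAFE or PARADOX against the MTPT landscape
#'
#' A marker is `PARADOX` when its primers are predicted to amplify from the
#' mitochondrial genome, or when its plastid amplicon overlaps a detected
#' MTPT segment (so the mitochondrial copy of the locus can co-amplify);
#' otherwise it is `SAFE`.
#'
#' @param marker One row of a [design_markers()] result (or a list with
#'   `forward`, `reverse`, `name`).
#' @param plastid,mito [annotated_genome()] objects of one species.
#' @param segments `mtpt_segments` for that species (plastid-side
#'   coordinates).
#' @param max_mismatch,max_len Passed to [in_silico_pcr()].
#' @return A list: `name`, `classification` (`"SAFE"`/`"PARADOX"`),
#'   `plastid_bands`, `mito_bands` (product lengths), `overlaps_mtpt`.
#' @export
assess_coamplification <- function(marker, plastid, mito, segments,
                                   max_mismatch = 2L, max_len = 5000L) {
  amp_pt <- in_silico_pcr(marker$forward, marker$reverse, plastid,
                          max_mismatch, max_len)
  amp_mt <- in_silico_pcr(marker$forward, marker$reverse, mito,
                          max_mismatch, max_len)
  overlaps <- FALSE
  if (nrow(amp_pt) && nrow(segments)) {
    for (i in seq_len(nrow(amp_pt))) {
      ov <- pmin(amp_pt$end[i], segments$plastid_end) -
        pmax(amp_pt$start[i], segments$plastid_start)
      if (any(ov > 0L)) { overlaps <- TRUE; break }
    }
  }
  paradox <- nrow(amp_mt) > 0L || overlaps
  list(name = if (!is.null(marker$name)) marker$name else NA_character_,
       classification = if (paradox) "PARADOX" else "SAFE",
       plastid_bands = amp_pt$length, mito_bands = amp_mt$length,
       overlaps_mtpt = overlaps)
}

## ---- copy fraction and band visibility --------------------------------------

#' Organelle copy fractions from diagnostic-site read depths
#'
#' At a site whose plastid and MTPT copies differ, the fraction of reads
#' supporting the plastid allele estimates the plastid share of organelle
#' DNA. Percentages are rounded to integers with largest-remainder
#' reconciliation so they always sum to 100.
#'
#' @param d_pt,d_mt Read depths of the plastid and mitochondrial alleles
#'   (non-negative, sum > 0).
#' @return A list of class `copy_fraction`: `d_pt`, `d_mt`, `fraction_pt`,
#'   `fraction_mt`, `percent_pt`, `percent_mt`.
#' @export
copy_fraction <- function(d_pt, d_mt) {
  stopifnot(length(d_pt) == 1L, length(d_mt) == 1L, d_pt >= 0, d_mt >= 0)
  if (d_pt + d_mt <= 0) stop("total depth must be positive")
  f_pt <- d_pt / (d_pt + d_mt)
  pct <- percent_largest_remainder(c(f_pt, 1 - f_pt))
  structure(list(d_pt = d_pt, d_mt = d_mt,
                 fraction_pt = f_pt, fraction_mt = 1 - f_pt,
                 percent_pt = pct[1], percent_mt = pct[2]),
            class = "copy_fraction")
}

#' @export
print.copy_fraction <- function(x, ...) {
  cat(sprintf("plastid %d%% (%g reads) / mitochondrial %d%% (%g reads)\n",
              x$percent_pt, x$d_pt, x$percent_mt, x$d_mt))
  invisible(x)
}

#' Semi-quantitative PCR band visibility
#'
#' A deliberately minimal model of why MTPT-derived bands appear only at
#' high cycle numbers or template amounts: the product grows as
#' `copies * 2^cycles`, capped at a plateau, and a band is visible once the
#' product reaches a detection threshold. Visibility is monotone
#' non-decreasing in both copies and cycles.
#'
#' @param copies Relative template copy number (>= 0).
#' @param cycles PCR cycles (>= 0).
#' @param threshold Detection threshold in product units.
#' @param plateau Saturation cap on the product (default `Inf`).
#' @return Logical: band visible.
#' @export
band_visibility <- function(copies, cycles, threshold, plateau = Inf) {
  stopifnot(all(copies >= 0), all(cycles >= 0), threshold > 0)
  pmin(copies * 2^cycles, plateau) >= threshold
}

#' Cycles needed for a template to reach the detection threshold
#'
#' Closed form of the visibility model: the least integer `c` with
#' `copies * 2^c >= threshold`. The extra cycles a minor template needs over
#' a major one approximate `log2(copies_major / copies_minor)`.
#'
#' @inheritParams band_visibility
#' @return Integer cycle count (0 when already visible; `Inf` for 0 copies).
#' @export
min_cycles_visible <- function(copies, threshold) {
  stopifnot(all(copies >= 0), threshold > 0)
  ifelse(copies == 0, Inf, pmax(0, ceiling(log2(threshold / copies))))
}
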