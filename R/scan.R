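#' Parameters of the MTPT homology scan
#'
#' The biological filters (identity, length, E-value) are the thresholds the
#' scan exists to apply: segments must show more than `min_identity`
#' identity over at least `min_length` bp with an E-value at most
#' `max_evalue`. The remaining fields parameterize the seed-and-extend
#' search itself (conventional nucleotide-search settings: 11-bp exact
#' seeds, +1/-2 match/mismatch, affine gaps -5/-2, ungapped
#' Karlin-Altschul constants lambda = 1.33, K = 0.621 for the +1/-2 scheme,
#' X-drop 20) and are exposed so the thresholds can be exercised
#' independently of the search heuristics.
#'
#' @param min_identity Minimum alignment identity (fraction, default 0.70).
#' @param min_length Minimum aligned length in bp (default 30).
#' @param max_evalue Maximum Karlin-Altschul E-value (default 1e-10).
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @param word_size Exact seed length in bp.
#' @param ka_lambda,ka_K Karlin-Altschul statistics for the scoring scheme.
#' @param x_drop Ungapped extension termination: stop when the running score
#'   falls more than `x_drop` below its maximum.
#' @param chain_band Maximum diagonal offset (bp) when chaining HSPs into a
#'   gapped segment.
#' @param chain_gap Maximum plastid-side gap (bp) bridged when chaining.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(min_identity = 0.70, min_length = 30L,
                        max_evalue = 1e-10, match = 1L, mismatch = -2L,
                        gap_open = -5L, gap_extend = -2L, word_size = 11L,
                        ka_lambda = 1.33, ka_K = 0.621, x_drop = 20L,
                        chain_band = 100L, chain_gap = 300L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_length >= word_size, max_evalue > 0, word_size >= 4)
  structure(list(min_identity = min_identity,
                 min_length = as.integer(min_length),
                 max_evalue = max_evalue,
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size),
                 ka_lambda = ka_lambda, ka_K = ka_K,
                 x_drop = as.integer(x_drop),
                 chain_band = as.integer(chain_band),
                 chain_gap = as.integer(chain_gap)),
            class = "scan_params")
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of local
#' alignments of score at least `S` between random sequences of lengths `m`
#' and `n`.
#'
#' @param score Alignment raw score.
#' @param m,n Sequence lengths (bp), both >= 1.
#' @param ka_lambda,ka_K Karlin-Altschul constants for the scoring scheme.
#' @return The expectation value (numeric; underflows to 0 for huge scores).
#' @export
evalue <- function(score, m, n, ka_lambda = 1.33, ka_K = 0.621) {
  stopifnot(m >= 1, n >= 1)
  ka_K * as.numeric(m) * as.numeric(n) * exp(-ka_lambda * score)
}

#' Interval mask from annotated features
#'
#' Returns the merged, sorted, 0-based half-open intervals of all features of
#' the requested types. tRNA and rRNA genes are conserved in both organelle
#' compartments, so plastid regions matching them are excluded from MTPT
#' calling by default.
#'
#' @param genome An [annotated_genome()].
#' @param types Feature types to mask (default `c("tRNA", "rRNA")`).
#' @return A data.frame with columns `start`, `end` (merged intervals).
#' @export
mask_features <- function(genome, types = c("tRNA", "rRNA")) {
  stopifnot(inherits(genome, "AnnotatedGenome"))
  known <- unique(genome$features$type)
  unknown <- setdiff(types, c("CDS", "gene", "tRNA", "rRNA", known))
  if (length(unknown)) {
    warning("unknown feature type(s) requested: ",
            paste(unknown, collapse = ", "))
  }
  f <- genome$features[genome$features$type %in% types, , drop = FALSE]
  merge_intervals0(f$start, f$end)
}

## ---- seed-and-extend internals ---------------------------------------------

## numeric codes of all word_size-mers (NA where the window has an ambiguous
## base); exact as doubles up to word_size 26, integer below 16
kmer_codes <- function(v, w) {
  n <- length(v) - w + 1L
  if (n < 1L) return(integer(0))
  code <- numeric(n)
  for (j in seq_len(w)) {
    code <- code * 4 + v[j:(j + n - 1L)]
  }
  if (w <= 15L) as.integer(code) else code
}

## X-drop ungapped extension along one diagonal, vectorized in chunks.
## a, b: integer sequence vectors; ai, bi: 1-based start offsets of the first
## compared position; dir: +1L/-1L. Returns steps taken to the best-scoring
## endpoint, the score gained and the matches gained.
xdrop_extend <- function(a, b, ai, bi, dir, params) {
  best <- 0L; best_steps <- 0L; best_matches <- 0L
  cur <- 0; matches <- 0L; steps <- 0L
  chunk <- 2048L
  repeat {
    if (dir > 0L) {
      na <- length(a) - (ai + steps) + 1L
      nb <- length(b) - (bi + steps) + 1L
    } else {
      na <- ai - steps
      nb <- bi - steps
    }
    k <- min(chunk, na, nb)
    if (k <= 0L) break
    ia <- ai + dir * (steps + seq_len(k) - 1L)
    ib <- bi + dir * (steps + seq_len(k) - 1L)
    m <- !is.na(a[ia]) & !is.na(b[ib]) & a[ia] == b[ib]
    v <- ifelse(m, params$match, params$mismatch)
    cum <- cur + cumsum(v)
    cmm <- cummax(c(best, cum))[-1]
    stop_at <- which(cmm - cum > params$x_drop)
    lim <- if (length(stop_at)) stop_at[1] else k
    seg <- seq_len(lim)
    mx <- which.max(cum[seg])
    if (cum[mx] > best) {
      best <- cum[mx]
      best_steps <- steps + mx
      best_matches <- matches + sum(m[seq_len(mx)])
    }
    if (length(stop_at) || k < chunk) break
    steps <- steps + k
    cur <- cum[k]
    matches <- matches + sum(m)
  }
  list(steps = best_steps, score = best, matches = best_matches)
}

## ungapped HSPs from seeds shared by integer sequences a (mito) and b
## (plastid strand view); returns data.frame with 0-based half-open coords
## on both, score and matches
.ungapped_hsps <- function(a, b, params) {
  w <- params$word_size
  ca <- kmer_codes(a, w)
  cb <- kmer_codes(b, w)
  dtb <- data.table::data.table(code = cb,
                                bpos = seq_along(cb))[!is.na(code)]
  dta <- data.table::data.table(code = ca,
                                apos = seq_along(ca))[!is.na(code)]
  seeds <- merge(dta, dtb, by = "code", allow.cartesian = TRUE)
  if (nrow(seeds) == 0L) {
    return(data.frame(astart = integer(), aend = integer(),
                      bstart = integer(), bend = integer(),
                      score = integer(), matches = integer()))
  }
  seeds[, diag := apos - bpos]
  data.table::setorder(seeds, diag, apos)
  out <- vector("list", 64L); n_out <- 0L
  cur_diag <- NA_integer_; covered_to <- -1L
  for (r in seq_len(nrow(seeds))) {
    d <- seeds$diag[r]; ap <- seeds$apos[r]; bp <- seeds$bpos[r]
    if (!identical(d, cur_diag)) { cur_diag <- d; covered_to <- -1L }
    if (ap <= covered_to) next
    base_score <- w * params$match
    right <- xdrop_extend(a, b, ap + w, bp + w, +1L, params)
    left <- xdrop_extend(a, b, ap - 1L, bp - 1L, -1L, params)
    astart <- ap - left$steps; aend <- ap + w - 1L + right$steps
    hsp <- data.frame(
      astart = astart - 1L, aend = aend,
      bstart = bp - left$steps - 1L, bend = bp + w - 1L + right$steps,
      score = base_score + left$score + right$score,
      matches = w + left$matches + right$matches)
    n_out <- n_out + 1L
    if (n_out > length(out)) out <- c(out, vector("list", length(out)))
    out[[n_out]] <- hsp
    covered_to <- aend
  }
  do.call(rbind, out[seq_len(n_out)])
}

## greedy chaining of same-strand HSPs whose diagonals differ by at most
## chain_band and whose plastid gap is at most chain_gap; the bridged region
## is scored as a gap plus mismatches
.chain_hsps <- function(h, params) {
  if (nrow(h) <= 1L) return(h)
  h <- h[order(h$bstart, h$astart), , drop = FALSE]
  res <- h[1, , drop = FALSE]
  for (i in 2:nrow(h)) {
    cur <- res[nrow(res), ]
    nxt <- h[i, ]
    dd <- (nxt$astart - nxt$bstart) - (cur$astart - cur$bstart)
    bgap <- nxt$bstart - cur$bend
    agap <- nxt$astart - cur$aend
    if (abs(dd) <= params$chain_band && bgap <= params$chain_gap &&
        agap <= params$chain_gap && bgap >= 0L && agap >= 0L) {
      gap_pen <- if (dd == 0L) 0L else
        params$gap_open + params$gap_extend * (abs(dd) - 1L)
      bridge <- min(agap, bgap)
      merged_score <- cur$score + nxt$score + gap_pen +
        bridge * params$mismatch
      if (merged_score > max(cur$score, nxt$score)) {
        res[nrow(res), ] <- data.frame(
          astart = cur$astart, aend = nxt$aend,
          bstart = cur$bstart, bend = nxt$bend,
          score = merged_score, matches = cur$matches + nxt$matches)
        next
      }
    }
    res <- rbind(res, nxt)
  }
  res
}

## drop or trim segments against a plastid-side mask: a segment is dropped if
## more than half of its plastid span is masked; otherwise masked overhang at
## either end is trimmed off (same amount on the mito side: ends are
## diagonal-consistent) and the segment is re-scored by recounting matches
.apply_mask <- function(seg, mask, a, b, params) {
  if (nrow(seg) == 0L || nrow(mask) == 0L) return(seg)
  keep <- logical(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    s <- seg$bstart[i]; e <- seg$bend[i]
    ov <- pmax(0L, pmin(e, mask$end) - pmax(s, mask$start))
    if (sum(ov) > 0.5 * (e - s)) { keep[i] <- FALSE; next }
    ## trim masked overhang at the ends
    lt <- max(0L, max(c(0L, mask$end[mask$start <= s & mask$end > s])) - s)
    rt <- max(0L, e - min(c(e, mask$start[mask$end >= e & mask$start < e])))
    if (lt + rt > 0L) {
      seg$bstart[i] <- s + lt; seg$bend[i] <- e - rt
      seg$astart[i] <- seg$astart[i] + lt; seg$aend[i] <- seg$aend[i] - rt
      len <- seg$bend[i] - seg$bstart[i]
      if (len < params$min_length) { keep[i] <- FALSE; next }
      ia <- (seg$astart[i] + 1L):seg$aend[i]
      ib <- (seg$bstart[i] + 1L):seg$bend[i]
      if (length(ia) == length(ib)) {
        mm <- sum(!is.na(a[ia]) & !is.na(b[ib]) & a[ia] == b[ib])
        seg$matches[i] <- mm
        seg$score[i] <- mm * params$match + (len - mm) * params$mismatch
      }
    }
    keep[i] <- TRUE
  }
  seg[keep, , drop = FALSE]
}

#' Find MTPT segments between a mitochondrial and a plastid genome
#'
#' Seed-and-extend local alignment on both strands: exact `word_size` seeds,
#' ungapped X-drop extension, greedy chaining of near-diagonal HSPs into
#' gapped segments, then the three biological filters (identity > 70%,
#' length >= 30 bp, E-value <= 1e-10 by default) and the plastid tRNA/rRNA
#' mask.
#'
#' @param mito,plastid [annotated_genome()] objects (mitochondrial query,
#'   plastid subject).
#' @param params A [scan_params()].
#' @param mask_types Plastid feature types masked out (default tRNA/rRNA);
#'   `NULL` disables masking.
#' @return A data.frame of class `mtpt_segments` with columns `mito_id`,
#'   `mito_start`, `mito_end`, `plastid_id`, `plastid_start`, `plastid_end`
#'   (0-based half-open), `strand`, `aligned_length`, `identity`, `score`,
#'   `evalue`, sorted by `plastid_start`.
#' @export
find_mtpt_segments <- function(mito, plastid, params = scan_params(),
                               mask_types = c("tRNA", "rRNA")) {
  stopifnot(inherits(mito, "AnnotatedGenome"),
            inherits(plastid, "AnnotatedGenome"),
            genome_length(mito) > 0L, genome_length(plastid) > 0L)
  a <- dna_to_int(mito$sequence)
  Lp <- genome_length(plastid)
  mask <- if (is.null(mask_types)) {
    data.frame(start = integer(), end = integer())
  } else {
    mask_features(plastid, mask_types)
  }
  out <- list()
  for (strand in c("+", "-")) {
    bseq <- if (strand == "+") plastid$sequence else revcomp(plastid$sequence)
    b <- dna_to_int(bseq)
    smask <- mask
    if (strand == "-" && nrow(mask)) {
      smask <- data.frame(start = Lp - mask$end, end = Lp - mask$start)
      smask <- smask[order(smask$start), , drop = FALSE]
    }
    h <- .ungapped_hsps(a, b, params)
    if (nrow(h) == 0L) next
    h <- .chain_hsps(h, params)
    h <- .apply_mask(h, smask, a, b, params)
    if (nrow(h) == 0L) next
    len <- h$bend - h$bstart
    identity <- h$matches / pmax(len, h$aend - h$astart)
    ev <- evalue(h$score, genome_length(mito), Lp,
                 params$ka_lambda, params$ka_K)
    pass <- len >= params$min_length & identity >= params$min_identity &
      ev <= params$max_evalue
    h <- h[pass, , drop = FALSE]
    if (nrow(h) == 0L) next
    ps <- if (strand == "+") h$bstart else Lp - h$bend
    pe <- if (strand == "+") h$bend else Lp - h$bstart
    out[[strand]] <- data.frame(
      mito_id = mito$id, mito_start = h$astart,
      mito_end = h$aend, plastid_id = plastid$id,
      plastid_start = ps, plastid_end = pe, strand = strand,
      aligned_length = h$bend - h$bstart,
      identity = identity[pass], score = h$score,
      evalue = ev[pass], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    mito_id = character(), mito_start = integer(), mito_end = integer(),
    plastid_id = character(), plastid_start = integer(),
    plastid_end = integer(), strand = character(),
    aligned_length = integer(), identity = numeric(), score = integer(),
    evalue = numeric(), stringsAsFactors = FALSE)
  res <- res[order(res$plastid_start, res$plastid_end), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("mtpt_segments", "data.frame")
  res
}

#' Fraction of the plastid genome covered by MTPT segments
#'
#' Union length of the plastid-side intervals divided by the plastid length.
#'
#' @param segments An `mtpt_segments` data.frame (one plastid backbone).
#' @param plastid_length Plastid genome length in bp.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(segments, plastid_length) {
  stopifnot(plastid_length >= 1)
  if (nrow(segments) == 0L) return(0)
  union_length0(segments$plastid_start, segments$plastid_end) / plastid_length
}
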