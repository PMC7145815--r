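## Independent oracles used to cross-check the package's own estimators.
## These are written against the definitions, not against the package code.

## random CDS: ATG + random sense codons + stop
random_cds <- function(n_codons, seed = NULL) {
  gen <- function() {
    codons <- names(Biostrings::GENETIC_CODE)
    sense <- codons[Biostrings::GENETIC_CODE != "*"]
    paste0("ATG",
           paste(sample(sense, n_codons - 1L, replace = TRUE), collapse = ""),
           sample(c("TAA", "TAG", "TGA"), 1))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## mutate a DNA string at a given per-base substitution probability
mutate_dna <- function(s, p) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

## ---- oracle 1: optimal local alignment score via Biostrings DP --------------
local_dp_score <- function(a, b, match = 1, mismatch = -2,
                           gap_opening = 30, gap_extension = 30) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE),
    gapOpening = gap_opening, gapExtension = gap_extension)
  Biostrings::score(pa)
}

## ---- oracle 2: NG86 per-codon sites and per-pair differences ----------------
## Coded independently: explicit permutation enumeration over differing
## positions; stop-passing paths excluded unless all paths pass a stop, in
## which case all paths count with stop steps as nonsynonymous.
oracle_codon_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  total <- 0
  for (pos in 1:3) {
    neighbours <- character(0)
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      x <- codon
      substr(x, pos, pos) <- b
      neighbours <- c(neighbours, x)
    }
    keep <- neighbours[gc[neighbours] != "*"]
    if (length(keep)) {
      total <- total + sum(gc[keep] == gc[codon]) / length(keep)
    }
  }
  total
}

oracle_pair_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  pos <- which(v1 != v2)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  rows <- lapply(perms(pos), function(ord) {
    cur <- c1; sd <- 0; nd <- 0; stopped <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[nxt] == "*" && nxt != c2) stopped <- TRUE
      if (gc[cur] == "*" || gc[nxt] == "*") nd <- nd + 1
      else if (gc[cur] == gc[nxt]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, stopped)
  })
  m <- do.call(rbind, rows)
  valid <- m[m[, 3] == 0, , drop = FALSE]
  if (nrow(valid) == 0L) valid <- m
  c(sd = mean(valid[, 1]), nd = mean(valid[, 2]))
}

## ---- oracle 3: global affine alignment score (Gotoh), for codon_align ------
## Gap of length L costs gap_opening + gap_extension * L, matching the
## convention of the implementation's aligner.
global_affine_score <- function(a, b, submat, gap_opening = 10,
                                gap_extension = 1) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  NEG <- -1e9
  open <- -(gap_opening + gap_extension); ext <- -gap_extension
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in seq_len(m)) Y[1, j + 1] <- open + ext * (j - 1)
  for (i in seq_len(n)) X[i + 1, 1] <- open + ext * (i - 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[va[i], vb[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + open, X[i, j + 1] + ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + open, Y[i + 1, j] + ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## all sense codons, shared by several suites
sense_codons <- function() {
  codons <- names(Biostrings::GENETIC_CODE)
  codons[Biostrings::GENETIC_CODE != "*"]
}
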