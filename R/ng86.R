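## Nei-Gojobori (1986) codon bookkeeping.
##
## Synonymous site counts: at each codon position the proportion of possible
## single-nucleotide changes that are synonymous, with changes creating a stop
## codon excluded from the proportion (nonsense mutations are ignored, as in
## the original counting method). Pairwise synonymous/nonsynonymous
## differences are averaged over all minimal substitution paths between the
## two codons; paths passing through a stop codon are excluded, unless every
## path does, in which case all paths are used with steps to/from stops
## counted as nonsynonymous.

.ng86 <- new.env(parent = emptyenv())

.ALL_CODONS <- {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}
.STOP_CODONS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

is_stop_codon <- function(codon) codon %in% .STOP_CODONS

## per-codon table: synonymous-site fractions per position and the list of
## synonymous single-nucleotide alternatives (used by the simulator)
.codon_info <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- codon_aa(codon)
  f <- numeric(3)
  syn_alts <- vector("list", 3)
  for (pos in 1:3) {
    alts <- vapply(setdiff(bases, substr(codon, pos, pos)), function(b) {
      x <- codon
      substr(x, pos, pos) <- b
      x
    }, character(1))
    alts <- alts[!is_stop_codon(alts)]
    syn <- alts[codon_aa(alts) == aa]
    f[pos] <- if (length(alts)) length(syn) / length(alts) else 0
    syn_alts[[pos]] <- unname(syn)
  }
  list(s_sites = sum(f), f = f, syn_alts = syn_alts)
}

ng86_codon_info <- function(codon) {
  if (is.null(.ng86$info)) {
    .ng86$info <- lapply(stats::setNames(.SENSE_CODONS, .SENSE_CODONS),
                         .codon_info)
  }
  .ng86$info[[codon]]
}

#' NG86 synonymous site count of a coding sequence
#'
#' Sums, over codons, the per-position fractions of possible changes that are
#' synonymous (nonsense changes excluded). Used both by the Ks estimator and
#' by the synonymous-evolution simulator, so simulated divergence and
#' estimated divergence are expressed on the same site scale.
#'
#' @param cds Coding sequence (length divisible by 3, no internal stop).
#'   A terminal stop codon is allowed and contributes no sites.
#' @return Numeric synonymous site count.
#' @export
ng86_sites <- function(cds) {
  cods <- codons_of(cds)
  n <- length(cods)
  if (n && is_stop_codon(cods[n])) cods <- cods[-n]
  if (any(is_stop_codon(cods))) stop("internal stop codon in CDS")
  sum(vapply(cods, function(cd) {
    if (!cd %in% .SENSE_CODONS) return(NA_real_)  # ambiguity codes
    ng86_codon_info(cd)$s_sites
  }, numeric(1)), na.rm = TRUE)
}

## ---- pairwise codon differences -------------------------------------------

.PERMS <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

## returns c(sd, nd) for one ordered sense-codon pair
.pair_path_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  walk <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0; through_stop <- FALSE
    for (p in pos[order]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (is_stop_codon(nxt) && nxt != c2) through_stop <- TRUE
      if (is_stop_codon(cur) || is_stop_codon(nxt)) {
        nd <- nd + 1          # fallback accounting only
      } else if (codon_aa(cur) == codon_aa(nxt)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd, nd, through_stop)
  }
  res <- t(vapply(.PERMS[[as.character(k)]], walk, numeric(3)))
  ok <- res[, 3] == 0
  if (any(ok)) res <- res[ok, , drop = FALSE]
  c(sd = mean(res[, 1]), nd = mean(res[, 2]))
}

ng86_pair_diffs <- function(c1, c2) {
  if (is.null(.ng86$pairs)) .ng86$pairs <- new.env(parent = emptyenv())
  key <- paste0(c1, c2)
  hit <- .ng86$pairs[[key]]
  if (!is.null(hit)) return(hit)
  val <- .pair_path_counts(c1, c2)
  assign(key, val, envir = .ng86$pairs)
  val
}
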