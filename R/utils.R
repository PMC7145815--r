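## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream. seed = NULL means "use the current stream" (the caller controls
## reproducibility), which is how nested simulator calls share one seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  expr
}

## merged, sorted 0-based half-open intervals from start/end vectors
merge_intervals0 <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

## total length of the union of 0-based half-open intervals
union_length0 <- function(start, end) {
  m <- merge_intervals0(start, end)
  sum(m$end - m$start)
}

## round a vector of proportions to integer percentages that sum to 100
## (largest-remainder reconciliation)
percent_largest_remainder <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  raw <- p * 100
  fl <- floor(raw)
  short <- as.integer(round(100 - sum(fl)))
  if (short > 0L) {
    take <- order(raw - fl, decreasing = TRUE)[seq_len(short)]
    fl[take] <- fl[take] + 1
  }
  as.integer(fl)
}
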