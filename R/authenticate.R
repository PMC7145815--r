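#' Classify collections under the positive or negative detection rule
#'
#' The two multi-marker decision rules trade detection power against
#' false-positive rate. Positive rule: a collection is genuine if at least
#' one marker shows the target allele (heterogeneous genotypes are accepted
#' as the target species). Negative rule: a collection is counterfeit if at
#' least one marker shows an off-type allele (heterogeneous genotypes are
#' rejected). Missing calls are ignored by default; `strict_missing` counts
#' them as off-type. The call value `"both"` (mixed bands at one locus)
#' counts as target-present and off-present simultaneously.
#'
#' @param table A `genotype_table` (see [simulate_genotype_table()] /
#'   [read_genotype_table()]).
#' @param rule `"positive"` or `"negative"`.
#' @param strict_missing Treat missing calls as off-type.
#' @return Character vector (`"genuine"`/`"counterfeit"`, `NA` for
#'   collections with all calls missing), named by collection id.
#' @export
classify <- function(table, rule = c("positive", "negative"),
                     strict_missing = FALSE) {
  rule <- match.arg(rule)
  stopifnot(inherits(table, "genotype_table"))
  calls <- table$calls
  if (strict_missing) calls[calls == "missing"] <- "off"
  has_target <- apply(calls, 1, function(r) any(r %in% c("target", "both")))
  has_off <- apply(calls, 1, function(r) any(r %in% c("off", "both")))
  all_missing <- apply(calls, 1, function(r) all(r == "missing"))
  out <- if (rule == "positive") {
    ifelse(has_target, "genuine", "counterfeit")
  } else {
    ifelse(has_off, "counterfeit", "genuine")
  }
  out[all_missing] <- NA_character_
  if (any(all_missing)) {
    warning(sum(all_missing), " collection(s) with all calls missing: ",
            paste(table$collections$id[all_missing], collapse = ", "))
  }
  stats::setNames(out, table$collections$id)
}

#' Detection power and false-positive rate of both rules
#'
#' Power: fraction of truly "other" collections flagged counterfeit.
#' False-positive rate (type I error): fraction of truly "target"
#' collections flagged counterfeit. The negative rule's counterfeit set
#' always contains the positive rule's, so
#' `power(negative) >= power(positive)` and `fpr(negative) >= fpr(positive)`
#' - the power/false-positive tradeoff between the two rules.
#'
#' @param table A `genotype_table` with truth labels.
#' @param strict_missing Passed to [classify()].
#' @return A data.frame with one row per rule: `rule`,
#'   `n_flagged_counterfeit`, `power`, `fpr` (a metric is `NA` when its
#'   truth class is absent).
#' @export
evaluate_rules <- function(table, strict_missing = FALSE) {
  stopifnot(inherits(table, "genotype_table"))
  lab <- table$collections$label
  one <- function(rule) {
    cl <- classify(table, rule, strict_missing)
    flagged <- !is.na(cl) & cl == "counterfeit"
    n_other <- sum(lab == "other")
    n_target <- sum(lab == "target")
    data.frame(
      rule = rule,
      n_flagged_counterfeit = sum(flagged),
      power = if (n_other) sum(flagged & lab == "other") / n_other
              else NA_real_,
      fpr = if (n_target) sum(flagged & lab == "target") / n_target
            else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- rbind(one("positive"), one("negative"))
  if (!all(c("target", "other") %in% lab)) {
    warning("a truth class is absent; its metric is NA")
  }
  out
}

#' Construct a genotype table from explicit calls
#'
#' @param calls Character matrix (collections x markers) of
#'   `"target"`/`"off"`/`"missing"`/`"both"` calls.
#' @param labels Truth labels (`"target"`/`"other"`), one per row.
#' @param ids Collection ids (default generated).
#' @return A `genotype_table`.
#' @export
genotype_table <- function(calls, labels, ids = NULL) {
  calls <- as.matrix(calls)
  stopifnot(nrow(calls) >= 1L, ncol(calls) >= 1L,
            length(labels) == nrow(calls),
            all(labels %in% c("target", "other")),
            all(calls %in% c("target", "off", "missing", "both")))
  if (is.null(ids)) ids <- sprintf("C%02d", seq_len(nrow(calls)))
  markers <- colnames(calls)
  if (is.null(markers)) markers <- sprintf("M%d", seq_len(ncol(calls)))
  colnames(calls) <- markers
  rownames(calls) <- ids
  structure(list(collections = data.frame(id = ids, label = labels,
                                          stringsAsFactors = FALSE),
                 markers = markers, calls = calls),
            class = "genotype_table")
}
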