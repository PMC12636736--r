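#' Percent reduction of a group mean relative to a reference
#'
#' `100 * (reference - test) / reference`, rounded half-away-from-zero to
#' the nearest integer percent — the convention used for reporting
#' behavioral declines (e.g. open-field distance, rotarod latency).
#'
#' @param reference reference (e.g. wild-type) group mean; must be > 0.
#' @param test test (e.g. mutant) group mean.
#' @return integer-valued percentage.
#' @examples
#' percent_reduction(4190, 1846)   # 56
#' percent_reduction(134.6, 73.97) # 45
#' @export
percent_reduction <- function(reference, test) {
  if (!is.numeric(reference) || reference <= 0) {
    stop_with("trioscan_domain_error", "reference mean must be positive")
  }
  round_half_away(100 * (reference - test) / reference)
}

#' Difference of two group means
#'
#' @inheritParams percent_reduction
#' @return `reference - test`, in the input units.
#' @examples
#' mean_difference(4190, 1846) # 2344
#' @export
mean_difference <- function(reference, test) {
  reference - test
}

#' Percent cell loss from a count pair
#'
#' `100 * (wt_count - mut_count) / wt_count`, rounded half-away-from-zero
#' to one decimal — the convention used for Purkinje-cell loss figures.
#'
#' @param wt_count wild-type cell count; must be > 0.
#' @param mut_count mutant cell count.
#' @return percentage with one decimal place.
#' @examples
#' cell_loss_percent(200, 94) # 53.0
#' @export
cell_loss_percent <- function(wt_count, mut_count) {
  if (!is.numeric(wt_count) || wt_count <= 0) {
    stop_with("trioscan_domain_error", "wild-type count must be positive")
  }
  round_half_away(100 * (wt_count - mut_count) / wt_count, digits = 1)
}

#' Summarize a two-group behavioral comparison
#'
#' Takes a group-summary table (TSV path or data.frame with columns
#' `label`, `mean`, `n`) containing exactly one reference and one test
#' group and returns the percent reduction and mean difference.
#'
#' @param groups path to a TSV or a data.frame with columns `label`,
#'   `mean`, `n`.
#' @param reference_label label of the reference group (default: the first
#'   row).
#' @return data.frame with columns `comparison` and `value`.
#' @export
summarize_behavior <- function(groups, reference_label = NULL) {
  if (is.character(groups) && length(groups) == 1) {
    groups <- utils::read.delim(groups, stringsAsFactors = FALSE)
  }
  if (!all(c("label", "mean", "n") %in% names(groups))) {
    stop_with("trioscan_schema_error",
              "group summary needs columns label, mean, n")
  }
  if (nrow(groups) != 2) {
    stop_with("trioscan_validation_error", "exactly two groups required")
  }
  stopifnot(all(groups$n >= 1))
  if (is.null(reference_label)) reference_label <- groups$label[1]
  i <- match(reference_label, groups$label)
  if (is.na(i)) {
    stop_with("trioscan_lookup_error", "no group labelled '%s'", reference_label)
  }
  ref <- groups$mean[i]
  test <- groups$mean[-i]
  data.frame(
    comparison = c("percent_reduction", "mean_difference"),
    value = c(percent_reduction(ref, test), mean_difference(ref, test)),
    stringsAsFactors = FALSE
  )
}
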