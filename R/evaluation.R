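#' Switch-aware haplotagging accuracy
#'
#' Compares a predicted read tagging against a truth tagging. Haplotag
#' labels are arbitrary within each phase set, so reads are grouped by
#' predicted phase set and, per group, the orientation (identity or 1-2
#' swap) agreeing best with truth is chosen before counting matches. Reads
#' untagged in either input are excluded from the compared set and
#' reported separately; because the right normalization is debatable, the
#' result carries both `accuracy` (correct / compared) and
#' `accuracy_vs_truth_tagged` (correct / truth-tagged, untagged predictions
#' counting against).
#'
#' @param predicted tibble with `read_id`, `tag` (1/2/0) and `phase_set`;
#'   e.g. the output of [run_haplotag()] or [read_tags_bam()].
#' @param truth tibble with `read_id` and `tag` (1/2), e.g. a simulation's
#'   `truth` table or a truth-haplotagged BAM read via [read_tags_bam()].
#' @return object of class `tag_comparison` with fields `n_truth_tagged`,
#'   `n_predicted_tagged`, `n_compared`, `n_correct`, `accuracy` (percent),
#'   `accuracy_vs_truth_tagged` (percent), `untagged_fraction` (fraction of
#'   truth-tagged reads the prediction left untagged).
#' @export
haplotag_accuracy <- function(predicted, truth) {
  # a simulator truth table names its column 'haplotype'; accept both
  if (!"tag" %in% names(truth) && "haplotype" %in% names(truth)) {
    truth$tag <- truth$haplotype
  }
  stopifnot(all(c("read_id", "tag") %in% names(predicted)),
            all(c("read_id", "tag") %in% names(truth)))
  if (!"phase_set" %in% names(predicted)) predicted$phase_set <- 1L
  p <- predicted[predicted$tag %in% c(1L, 2L), c("read_id", "tag", "phase_set")]
  t <- truth[truth$tag %in% c(1L, 2L), c("read_id", "tag")]
  j <- dplyr::inner_join(p, t, by = "read_id", suffix = c("_pred", "_truth"))
  n_compared <- nrow(j)
  n_correct <- 0L
  if (n_compared > 0) {
    per_set <- j |>
      dplyr::group_by(.data$phase_set) |>
      dplyr::summarise(
        same = sum(.data$tag_pred == .data$tag_truth),
        swapped = sum(.data$tag_pred != .data$tag_truth), .groups = "drop")
    n_correct <- sum(pmax(per_set$same, per_set$swapped))
  }
  n_truth_tagged <- nrow(t)
  res <- list(
    n_truth_tagged = n_truth_tagged,
    n_predicted_tagged = nrow(p),
    n_compared = n_compared,
    n_correct = n_correct,
    accuracy = if (n_compared > 0) 100 * n_correct / n_compared else NA_real_,
    accuracy_vs_truth_tagged = if (n_truth_tagged > 0)
      100 * n_correct / n_truth_tagged else NA_real_,
    untagged_fraction = if (n_truth_tagged > 0)
      1 - n_compared / n_truth_tagged else NA_real_)
  class(res) <- "tag_comparison"
  res
}

#' @export
print.tag_comparison <- function(x, ...) {
  cat("<tag_comparison>\n")
  cat(sprintf("  compared reads : %d (of %d truth-tagged)\n",
              x$n_compared, x$n_truth_tagged))
  if (is.na(x$accuracy)) {
    cat("  accuracy       : undefined (no reads tagged in both inputs)\n")
  } else {
    cat(sprintf("  accuracy       : %.2f%% (best per-phase-set orientation)\n",
                x$accuracy))
    cat(sprintf("  vs truth-tagged: %.2f%% (untagged predictions count against)\n",
                x$accuracy_vs_truth_tagged))
  }
  invisible(x)
}

#' @rdname haplotag_accuracy
#' @param x a `tag_comparison`.
#' @param ... unused.
#' @export
glance.tag_comparison <- function(x, ...) {
  tibble::tibble(n_truth_tagged = x$n_truth_tagged,
                 n_predicted_tagged = x$n_predicted_tagged,
                 n_compared = x$n_compared, n_correct = x$n_correct,
                 accuracy = x$accuracy,
                 accuracy_vs_truth_tagged = x$accuracy_vs_truth_tagged,
                 untagged_fraction = x$untagged_fraction)
}

#' @rdname haplotag_accuracy
#' @export
tidy.tag_comparison <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "accuracy_vs_truth_tagged", "untagged_fraction"),
    value = c(x$accuracy, x$accuracy_vs_truth_tagged, x$untagged_fraction))
}
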