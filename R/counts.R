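#' Published per-subject detection counts
#'
#' The per-subject true-positive, false-positive and false-negative counts
#' reported for S1, S2 and S1-S2 template matching on the six-subject FCG
#' study (the recordings themselves are not publicly available; only these
#' counts are). Useful for reproducing the aggregate recognition
#' statistics.
#'
#' @return A data frame with columns `label`, `subject`, `tp`, `fp`, `fn`.
#' @export
#' @examples
#' head(detection_counts())
detection_counts <- function() {
  path <- system.file("extdata", "detection_counts.csv", package = "fcghs")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Aggregate recognition statistics per template label
#'
#' Sums the per-subject counts and applies [recognition_stats()], giving
#' the overall sensitivity and positive predictive value per template, and
#' the total number of cardiac cycles (`tp + fn`, identical across
#' templates by construction).
#'
#' @param counts A data frame as returned by [detection_counts()].
#' @return A data frame with one row per label: `tp`, `fp`, `fn`,
#'   `cycles`, `sensitivity`, `ppv` (percent, full precision).
#' @export
#' @examples
#' recognition_summary()
recognition_summary <- function(counts = detection_counts()) {
  out <- do.call(rbind, lapply(split(counts, counts$label), function(d) {
    tot <- list(tp = sum(d$tp), fp = sum(d$fp), fn = sum(d$fn))
    st <- recognition_stats(tot)
    data.frame(label = d$label[1], tp = tot$tp, fp = tot$fp, fn = tot$fn,
               cycles = tot$tp + tot$fn,
               sensitivity = st[["sensitivity"]], ppv = st[["ppv"]])
  }))
  rownames(out) <- NULL
  out[order(match(out$label, c("S1", "S2", "S1S2"))), ]
}
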