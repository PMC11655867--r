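#' Per-class diagnostic performance metrics
#'
#' One-vs-rest precision, recall and specificity for each class of the truth
#' vector, from the standard confusion-matrix definitions. Classes never
#' predicted get precision NA (no positive predictions).
#'
#' @param predicted,truth equal-length label vectors.
#' @return data.frame: class, precision, recall, specificity, n.
#' @export
class_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop_cfg("predicted (%d) and truth (%d) differ in length",
             length(predicted), length(truth))
  }
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  out <- do.call(rbind, lapply(classes, function(cl) {
    pc <- !is.na(predicted) & predicted == cl  # NA = no prediction made
    tp <- sum(pc & truth == cl)
    fp <- sum(pc & truth != cl)
    fn <- sum(!pc & truth == cl)
    tn <- sum(!pc & truth != cl)
    data.frame(class = cl,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / (tp + fn),
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               n = tp + fn,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fowlkes-Mallows index of two partitions
#'
#' Pairwise clustering agreement: over all pairs of samples, with TP the
#' pairs grouped together in both partitions, FP pairs together only in the
#' first and FN pairs together only in the second,
#' FM = TP / sqrt((TP + FP) (TP + FN)) - the geometric mean of pairwise
#' precision and recall. Symmetric and invariant to label renaming.
#'
#' @param partition1,partition2 equal-length label vectors.
#' @return FM index in [0, 1]; 0 when either partition groups no pair
#'   together with the other's pairs.
#' @export
fm_index <- function(partition1, partition2) {
  if (length(partition1) != length(partition2)) {
    stop_cfg("partitions differ in length")
  }
  n <- length(partition1)
  if (n < 2) stop_cfg("FM index needs at least 2 samples")
  tab <- table(partition1, partition2)
  choose2 <- function(x) x * (x - 1) / 2
  tp <- sum(choose2(tab))
  together1 <- sum(choose2(rowSums(tab)))   # TP + FP
  together2 <- sum(choose2(colSums(tab)))   # TP + FN
  if (together1 == 0 || together2 == 0) return(0)
  tp / sqrt(together1 * together2)
}
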