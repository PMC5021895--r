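# Jaccard similarity, optimal cluster-to-truth label matching, and the
# evaluation report.

#' Jaccard similarity between two pixel sets
#'
#' \eqn{JS = |A \cap B| / |A \cup B|}. Arguments may be logical arrays on
#' the same grid or integer index vectors. Two empty sets are defined to
#' have similarity 1 (degenerate convention).
#'
#' @param a,b logical arrays or integer index vectors.
#' @return a scalar in [0, 1].
#' @examples
#' jaccard(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
jaccard <- function(a, b) {
  if (is.logical(a)) a <- which(a)
  if (is.logical(b)) b <- which(b)
  uni <- length(union(a, b))
  if (uni == 0L) return(1)
  length(intersect(a, b)) / uni
}

# all permutations of 1..n (n small)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Match predicted cluster labels to ground-truth labels
#'
#' Cluster indices are arbitrary, so predicted labels are matched to truth
#' labels by the permutation maximizing the total contingency-table
#' intersection (exhaustive search; class counts in this setting are
#' small). Label 0 (masked out) is ignored.
#'
#' @param predicted,truth integer label arrays on the same grid with labels
#'   in \code{0..classes}.
#' @param classes number of classes.
#' @return integer permutation p: predicted label i corresponds to truth
#'   label \code{p[i]}.
#' @export
matchLabels <- function(predicted, truth, classes) {
  if (length(predicted) != length(truth))
    stop("label maps must share the same grid")
  if (max(predicted, truth) > classes)
    stop("labels exceed the stated class count")
  if (classes > 8) stop("exhaustive matching supports up to 8 classes")
  tab <- matrix(0, classes, classes)
  keep <- predicted > 0L & truth > 0L
  tt <- table(factor(predicted[keep], levels = seq_len(classes)),
              factor(truth[keep], levels = seq_len(classes)))
  tab[] <- as.numeric(tt)
  perms <- .permutations(classes)
  scores <- apply(perms, 1, function(p) sum(tab[cbind(seq_len(classes), p)]))
  as.integer(perms[which.max(scores), ])
}

#' Evaluate a segmentation against ground truth
#'
#' Applies optimal label matching, then computes the per-class Jaccard
#' similarity over unmasked pixels. When the ground truth carries a bias
#' field and the result estimated one, also reports the Pearson
#' correlation between the two after mean-one normalization.
#'
#' @param result a [SegmentationResult-class], or an integer label array.
#' @param truth a [PhantomTruth-class], or an integer label array.
#' @param classes number of classes; inferred when S4 objects are given.
#' @return a [JSReport-class].
#' @export
evaluate <- function(result, truth, classes = NULL) {
  pred <- if (is(result, "SegmentationResult")) labelMap(result) else result
  gtLab <- if (is(truth, "PhantomTruth")) labelMap(truth) else truth
  if (is.null(classes)) {
    classes <- if (is(result, "SegmentationResult"))
      length(prototypes(result)) else max(pred, gtLab)
  }
  perm <- matchLabels(pred, gtLab, classes)
  mapped <- ifelse(pred > 0L, perm[pmax(pred, 1L)], 0L)
  keep <- pred > 0L | gtLab > 0L
  js <- vapply(seq_len(classes), function(i)
    jaccard(which(mapped == i & keep), which(gtLab == i & keep)), numeric(1))
  biasCor <- NA_real_
  if (is(result, "SegmentationResult") && is(truth, "PhantomTruth")) {
    bEst <- biasField(result)
    bTrue <- trueBias(truth)
    inside <- labelMap(result) > 0L
    if (stats::sd(bEst[inside]) > 0 && stats::sd(bTrue[inside]) > 0) {
      e <- bEst[inside] / mean(bEst[inside])
      g <- bTrue[inside] / mean(bTrue[inside])
      biasCor <- stats::cor(e, g)
    }
  }
  new("JSReport", js = js, permutation = perm, meanJS = mean(js),
      biasCorrelation = biasCor)
}
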