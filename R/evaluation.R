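#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed exactly from
#' the contingency table under the permutation model. Equals 1 for identical
#' partitions (up to relabeling) and has expectation 0 for independent random
#' labelings.
#'
#' @param y_true,y_pred Label vectors of equal length (>= 2); any atomic type.
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
adjusted_rand_index <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length")
  if (length(y_true) < 2) stop("need at least 2 observations")
  tab <- table(as.character(y_true), as.character(y_pred))
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(as.numeric(tab)))
  a <- sum(ch2(as.numeric(rowSums(tab))))
  b <- sum(ch2(as.numeric(colSums(tab))))
  ntot <- ch2(length(y_true))
  expected <- a * b / ntot
  maxidx <- (a + b) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxidx - expected)
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Clustering accuracy
#'
#' Fraction of spots assigned the correct region. In `"semantic"` mode
#' (default) the predicted class names are compared to the true names
#' directly — appropriate here because predictions inherit the source slice's
#' class names. `"matched"` mode first maps predicted classes to true classes
#' by the accuracy-maximizing bijection (exhaustive over permutations for up
#' to 9 classes, greedy beyond), the convention needed for label-free
#' clusterers.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param mode `"semantic"` or `"matched"`.
#' @return Accuracy in `[0, 1]`. Matched-mode accuracy is always >= semantic.
#' @export
clustering_accuracy <- function(y_true, y_pred,
                                mode = c("semantic", "matched")) {
  mode <- match.arg(mode)
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (mode == "semantic") {
    if (!length(intersect(unique(y_true), unique(y_pred))))
      stop("true and predicted label names are disjoint; semantic accuracy ",
           "is undefined — use mode = 'matched'")
    return(mean(y_true == y_pred))
  }
  classes <- sort(union(unique(y_true), unique(y_pred)))
  k <- length(classes)
  tab <- matrix(0, k, k, dimnames = list(classes, classes))
  cnt <- table(y_true, y_pred)
  tab[rownames(cnt), colnames(cnt)] <- cnt
  n <- length(y_true)
  if (k <= 9) {
    pm <- perms(k)
    best <- 0
    for (r in seq_len(nrow(pm)))
      best <- max(best, sum(tab[cbind(seq_len(k), pm[r, ])]))
    return(best / n)
  }
  # greedy fallback for many classes: repeatedly take the largest cell
  total <- 0
  t2 <- tab
  for (i in seq_len(k)) {
    ij <- arrayInd(which.max(t2), dim(t2))
    total <- total + t2[ij]
    t2[ij[1], ] <- -1
    t2[, ij[2]] <- -1
  }
  total / n
}

#' Confusion matrix report
#'
#' Tabulates predicted versus true region labels and derives the row-normalized
#' matrix, per-class precision and recall, plus ARI and semantic clustering
#' accuracy.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @return An object of class `"eval_report"`: list with `ari`, `ca`,
#'   `confusion` (counts, true classes in rows), `confusion_norm`
#'   (row-normalized), `precision`, `recall`.
#' @export
confusion_report <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(union(unique(y_true), unique(y_pred)))
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, pred = classes))
  cnt <- table(y_true, y_pred)
  conf[rownames(cnt), colnames(cnt)] <- cnt
  rs <- rowSums(conf)
  cs <- colSums(conf)
  norm <- conf / ifelse(rs == 0, 1, rs)
  dg <- diag(conf)
  structure(list(
    ari = adjusted_rand_index(y_true, y_pred),
    ca = if (length(intersect(unique(y_true), unique(y_pred))))
      mean(y_true == y_pred) else NA_real_,
    confusion = conf,
    confusion_norm = norm,
    precision = ifelse(cs == 0, NA_real_, dg / cs),
    recall = ifelse(rs == 0, NA_real_, dg / rs)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("Evaluation report\n")
  cat("  ARI:", format(x$ari, digits = digits),
      " CA:", format(x$ca, digits = digits), "\n")
  cat("  Confusion (true x pred):\n")
  print(x$confusion)
  invisible(x)
}
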