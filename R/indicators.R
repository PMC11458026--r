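# Dufrene-Legendre indicator value analysis on raw-scale cell means:
# specificity A (concentration of a taxon's mean abundance in one cluster),
# fidelity B (fraction of the cluster's cells where it occurs),
# IV = A * B on the 0-1 scale, label-permutation p-values and
# Benjamini-Hochberg correction.

# cluster means / presence fractions for one label permutation, all taxa at
# once; G is the n x k 0/1 cluster indicator matrix.
.indval_iv <- function(X, G, sizes) {
  means <- crossprod(G, X) / sizes               # k x T
  colt <- colSums(means)
  A <- sweep(means, 2, ifelse(colt > 0, colt, 1), `/`)
  A[, colt <= 0] <- 0
  B <- crossprod(G, (X > 0) * 1) / sizes
  A * B
}

#' Indicator values per taxon and cluster
#'
#' `A_tc` = mean abundance of taxon t over cells of cluster c divided by the
#' sum of those cluster means over all clusters; `B_tc` = fraction of the
#' cells of c where t is present (> 0); `IV_tc = A_tc * B_tc`. The best
#' cluster per taxon is the IV argmax (ties to the lowest cluster index).
#' All-zero taxa get IV = 0 and are flagged.
#'
#' @param X non-negative cells x taxa matrix of raw-scale cell means.
#' @param labels integer cluster labels per cell (every cluster non-empty).
#' @return list with matrices `A`, `B`, `IV` (clusters x taxa), data.frame
#'   `best` (`taxon`, `best_cluster`, `A`, `B`, `IV`, `all_zero`).
#' @export
indval <- function(X, labels) {
  X <- as.matrix(X)
  .check(all(X >= 0), "indval requires non-negative abundances")
  labels <- as.integer(labels)
  k <- max(labels)
  sizes <- tabulate(labels, k)
  if (any(sizes == 0)) stop("every cluster must be non-empty", call. = FALSE)
  n <- nrow(X)
  G <- matrix(0, n, k); G[cbind(seq_len(n), labels)] <- 1
  means <- crossprod(G, X) / sizes
  colt <- colSums(means)
  A <- sweep(means, 2, ifelse(colt > 0, colt, 1), `/`)
  A[, colt <= 0] <- 0
  B <- crossprod(G, (X > 0) * 1) / sizes
  IV <- A * B
  best_c <- apply(IV, 2, which.max)
  best <- data.frame(
    taxon = colnames(X),
    best_cluster = as.integer(best_c),
    A = A[cbind(best_c, seq_along(best_c))],
    B = B[cbind(best_c, seq_along(best_c))],
    IV = IV[cbind(best_c, seq_along(best_c))],
    all_zero = colt <= 0,
    stringsAsFactors = FALSE
  )
  list(A = A, B = B, IV = IV, best = best)
}

#' Permutation p-values for indicator values
#'
#' Permutes cell labels uniformly (cluster sizes preserved) and compares
#' each taxon's best-cluster IV with the permutation distribution of the
#' per-permutation maximum-cluster IV:
#' `p_t = (1 + #{IV_perm >= IV_obs}) / (n_perm + 1)`. Deterministic given
#' the seed.
#'
#' @param X non-negative cells x taxa matrix.
#' @param labels integer cluster labels.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return named numeric vector of p-values per taxon.
#' @export
indval_permutation <- function(X, labels, n_perm = 999L, seed = 1L) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  .check(.is_count(n_perm), "n_perm must be a positive integer")
  k <- max(labels)
  sizes <- tabulate(labels, k)
  n <- nrow(X)
  G <- matrix(0, n, k); G[cbind(seq_len(n), labels)] <- 1
  obs <- apply(.indval_iv(X, G, sizes), 2, max)
  exceed <- numeric(ncol(X))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      # permuting labels == permuting rows of X against fixed labels
      IVp <- .indval_iv(X[sample.int(n), , drop = FALSE], G, sizes)
      stat <- apply(IVp, 2, max)
      exceed <- exceed + (stat >= obs - 1e-12)
    }
  })
  stats::setNames((1 + exceed) / (n_perm + 1), colnames(X))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction (`stats::p.adjust` with
#' `method = "BH"`), with input validation.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  .check(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Full indicator table
#'
#' Combines [indval()], [indval_permutation()] and [bh_adjust()]: one row
#' per taxon with its best cluster, A, B, IV, raw and adjusted p-value, and
#' the indicator flag `IV > iv_threshold & p_adj < alpha`.
#'
#' @param X non-negative cells x taxa matrix of raw-scale cell means.
#' @param labels integer cluster labels.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param iv_threshold minimum indicator value (default 0.25, strict).
#' @param alpha adjusted-p cutoff (default 0.05, strict).
#' @return object of class `indicator_table` (a data.frame).
#' @export
indicator_table <- function(X, labels, n_perm = 999L, seed = 1L,
                            iv_threshold = 0.25, alpha = 0.05) {
  iv <- indval(X, labels)
  p <- indval_permutation(X, labels, n_perm = n_perm, seed = seed)
  tab <- iv$best
  tab$p <- as.numeric(p[tab$taxon])
  tab$p_adj <- bh_adjust(tab$p)
  tab$is_indicator <- tab$IV > iv_threshold & tab$p_adj < alpha
  structure(tab, class = c("indicator_table", "data.frame"),
            iv_threshold = iv_threshold, alpha = alpha, n_perm = n_perm)
}

#' @export
print.indicator_table <- function(x, ...) {
  cat(sprintf("indicator_table: %d taxa, %d indicators (IV > %.2f, BH p < %.2f, %d permutations)\n",
              nrow(x), sum(x$is_indicator), attr(x, "iv_threshold"),
              attr(x, "alpha"), attr(x, "n_perm")))
  print.data.frame(x[order(-x$IV), ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-cluster indicator taxa lists
#'
#' Taxa with `IV > iv_threshold` and `p_adj < alpha`, grouped by best
#' cluster, sorted by decreasing IV.
#'
#' @param table an [indicator_table()].
#' @param iv_threshold,alpha override the table's thresholds.
#' @return named list (one element per cluster) of data.frames.
#' @export
indicator_lists <- function(table, iv_threshold = NULL, alpha = NULL) {
  iv_threshold <- iv_threshold %||% attr(table, "iv_threshold")
  alpha <- alpha %||% attr(table, "alpha")
  sel <- table[table$IV > iv_threshold & table$p_adj < alpha, , drop = FALSE]
  sel <- sel[order(-sel$IV), , drop = FALSE]
  split(sel[, c("taxon", "A", "B", "IV", "p", "p_adj")], sel$best_cluster)
}
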