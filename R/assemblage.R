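# Assemblage definition: Hellinger space, fuzzy c-means in dissimilarity
# form (the FANNY objective of Kaufman & Rousseeuw), and the three
# k-selection diagnostics (silhouette, Mantel correlation, KGS penalty).

#' Split taxa into dominant and secondary sets and derive the clustering set
#'
#' A taxon is dominant when its relative abundance (summed cell means over
#' the grand total) exceeds the threshold, secondary otherwise. The
#' clustering set is the dominant set minus the exclusion list (broad
#' aggregate groups); excluded and secondary taxa remain available for the
#' indicator analysis.
#'
#' @param mean_raw cells x taxa matrix of raw-scale cell means.
#' @param threshold dominance fraction (default 0.005 = 0.5%).
#' @param exclusion character vector of taxa excluded from clustering.
#' @return list with `dominant`, `secondary`, `clustering` (character
#'   vectors) and `relative_abundance` (named, sums to 1).
#' @export
split_dominant_secondary <- function(mean_raw, threshold = 0.005,
                                     exclusion = character(0)) {
  .check(ncol(mean_raw) >= 1 && nrow(mean_raw) >= 1, "empty abundance matrix")
  totals <- colSums(mean_raw)
  grand <- sum(totals)
  if (grand <= 0) stop("grand total abundance is zero", call. = FALSE)
  rel <- totals / grand
  dominant <- names(rel)[rel > threshold]
  list(
    dominant = dominant,
    secondary = setdiff(names(rel), dominant),
    clustering = setdiff(dominant, exclusion),
    relative_abundance = rel
  )
}

#' Hellinger transformation
#'
#' `y_ij = sqrt(x_ij / sum_j x_ij)`: the square root of relative abundance
#' per row. Rows summing to zero become all-zero and are flagged in the
#' `zero_rows` attribute.
#'
#' @param X non-negative cells x taxa matrix.
#' @return transformed matrix (rows of unit Euclidean norm, or all zero).
#' @export
hellinger_transform <- function(X) {
  X <- as.matrix(X)
  .check(all(X >= 0), "Hellinger transform requires non-negative entries")
  rs <- rowSums(X)
  Y <- sqrt(sweep(X, 1, ifelse(rs > 0, rs, 1), `/`))
  Y[rs == 0, ] <- 0
  structure(Y, zero_rows = rownames(X)[rs == 0] %||% which(rs == 0))
}

#' Hellinger distance matrix
#'
#' Euclidean distances between Hellinger-transformed rows; bounded by
#' sqrt(2) for unit rows.
#'
#' @param Y Hellinger-transformed matrix (see [hellinger_transform()]).
#' @return symmetric distance matrix with zero diagonal.
#' @export
hellinger_distance <- function(Y) {
  as.matrix(stats::dist(Y))
}

# FANNY objective: sum_c [ sum_{i,j} u_ic^r u_jc^r d_ij ] / [ 2 sum_j u_jc^r ]
fanny_objective <- function(D, U, r) {
  M <- U^r
  P <- colSums(M * (D %*% M))
  S <- colSums(M)
  sum(ifelse(S > 0, P / (2 * S), 0))
}

# Dirichlet(1) initial memberships keyed per row label: row order never
# changes the stream.
.fanny_init <- function(labels, k, seed, restart) {
  U <- t(vapply(labels, function(lb) {
    e <- with_seed(derive_seed(seed, "fanny-init", restart, lb),
                   stats::rexp(k))
    e / sum(e)
  }, numeric(k)))
  matrix(U, ncol = k, dimnames = list(labels, NULL))
}

#' Fuzzy c-means clustering of a dissimilarity matrix (FANNY)
#'
#' Minimizes the Kaufman-Rousseeuw objective
#' `sum_c [ sum_{i,j} u_ic^r u_jc^r d_ij ] / [ 2 sum_j u_jc^r ]`
#' over memberships `u_ic >= 0` with rows summing to 1, by Lagrangian
#' fixed-point updates (`u_ic` proportional to `g_ic^{-1/(r-1)}` where `g`
#' is the partial derivative of the objective in `u^r`). Runs `nstart`
#' restarts from Dirichlet(1) memberships seeded per row label and keeps the
#' best objective; a sweep that would increase the objective is rolled back,
#' so the reported objective trace is non-increasing.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param k number of clusters (2 <= k < n).
#' @param r membership exponent (> 1; default 1.2).
#' @param seed integer seed for the restarts.
#' @param maxit maximum sweeps per restart (default 500).
#' @param tol relative objective decrease declaring convergence (1e-9).
#' @param nstart random restarts (default 5).
#' @return object of class `fanny_membership`: `U` (cells x k), `labels`
#'   and `max_membership` (crisp map), `objective`, `n_iter`, `converged`,
#'   `r`, `k`.
#' @export
fanny_cluster <- function(D, k, r = 1.2, seed = 1L, maxit = 500L, tol = 1e-9,
                          nstart = 5L) {
  D <- as.matrix(D)
  n <- nrow(D)
  .check(isTRUE(all.equal(D, t(D))), "D must be symmetric")
  .check(all(abs(diag(D)) < 1e-12), "D must have a zero diagonal")
  if (k >= n) stop(sprintf("k (%d) must be smaller than the number of cells (%d)", k, n),
                   call. = FALSE)
  .check(k >= 2, "k must be at least 2")
  .check(r > 1, "membership exponent r must exceed 1")
  rn <- rownames(D) %||% as.character(seq_len(n))

  run_one <- function(U) {
    obj <- fanny_objective(D, U, r)
    trace <- obj
    converged <- FALSE
    it <- 0L
    while (it < maxit) {
      it <- it + 1L
      M <- U^r
      S <- colSums(M)
      DM <- D %*% M                       # n x k: sum_j m_jc d_ij
      P <- colSums(M * DM)                # sum_{ij} m m d per cluster
      G <- sweep(DM, 2, S, `/`) -
        matrix(P / (2 * S^2), n, k, byrow = TRUE)
      G <- pmax(G, 1e-12)
      Unew <- G^(-1 / (r - 1))
      Unew <- Unew / rowSums(Unew)
      obj_new <- fanny_objective(D, Unew, r)
      if (obj_new > obj) {                # roll back: objective stays non-increasing
        converged <- TRUE                 # fixed point oscillates at the optimum
        break
      }
      U <- Unew
      drop <- obj - obj_new
      trace <- c(trace, obj_new)
      obj <- obj_new
      if (drop <= tol * max(obj, 1e-300)) { converged <- TRUE; break }
    }
    list(U = U, objective = obj, n_iter = it, converged = converged, trace = trace)
  }

  best <- NULL
  for (s in seq_len(nstart)) {
    res <- run_one(.fanny_init(rn, k, seed, s))
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  rownames(best$U) <- rn
  crisp <- max_membership_map(best$U)
  structure(
    list(U = best$U, labels = crisp$label, max_membership = crisp$membership,
         objective = best$objective, n_iter = best$n_iter,
         converged = best$converged, trace = best$trace, r = r, k = as.integer(k)),
    class = "fanny_membership"
  )
}

#' @export
print.fanny_membership <- function(x, ...) {
  cat(sprintf(
    "fanny_membership: %d cells, k = %d, r = %.2f; objective %.6g (%s in %d sweeps)\n",
    nrow(x$U), x$k, x$r, x$objective,
    if (x$converged) "converged" else "not converged", x$n_iter
  ))
  cat("cluster sizes (crisp):", paste(tabulate(x$labels, x$k), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.fanny_membership <- function(object, ...) {
  cat(sprintf("FANNY memberships (k = %d, r = %.2f)\n", object$k, object$r))
  print(summary(object$max_membership))
  invisible(object)
}

#' Crisp labels and maximum membership per cell
#'
#' Label = argmax over clusters (ties to the lowest cluster index);
#' value = the maximum membership.
#'
#' @param U cells x k membership matrix.
#' @return list with named integer `label` and numeric `membership`.
#' @export
max_membership_map <- function(U) {
  U <- as.matrix(U)
  lab <- max.col(U, ties.method = "first")
  list(
    label = stats::setNames(lab, rownames(U)),
    membership = stats::setNames(U[cbind(seq_len(nrow(U)), lab)], rownames(U))
  )
}

#' Silhouette widths of a crisp partition
#'
#' `a_i` = mean distance to own cluster (excluding self; 0 for singletons),
#' `b_i` = smallest mean distance to another cluster,
#' `s_i = (b_i - a_i) / max(a_i, b_i)`; singletons get `s_i = 0`.
#'
#' @param D symmetric distance matrix.
#' @param labels integer cluster labels (>= 2 non-empty clusters).
#' @return list with `widths` (per cell) and `mean`.
#' @export
silhouette_widths <- function(D, labels) {
  D <- as.matrix(D)
  labels <- as.integer(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("silhouette needs at least 2 clusters", call. = FALSE)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(cl, labels[i]), function(c2) {
      mean(D[i, labels == c2])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  list(widths = stats::setNames(s, rownames(D)), mean = mean(s))
}

#' Mantel correlation between a distance matrix and a crisp partition
#'
#' Pearson correlation between the strict lower triangles of `D` and of the
#' binary model matrix (0 within cluster, 1 between); larger is better.
#'
#' @param D symmetric distance matrix.
#' @param labels integer cluster labels.
#' @return correlation coefficient.
#' @export
mantel_correlation <- function(D, labels) {
  D <- as.matrix(D)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("Mantel needs at least 2 clusters", call. = FALSE)
  lt <- lower.tri(D)
  dv <- D[lt]
  mv <- (outer(labels, labels, `!=`) * 1)[lt]
  if (stats::sd(dv) == 0 || stats::sd(mv) == 0) {
    stop("Mantel correlation undefined: zero variance in a triangle", call. = FALSE)
  }
  stats::cor(dv, mv)
}

#' Kelly-Gardner-Sutcliffe penalty over a range of k
#'
#' Builds an average-linkage tree on `D`; for each k the average cluster
#' spread (mean pairwise distance among members, 0 for singletons) is
#' computed from the k-cut, the spread sequence is linearly rescaled over
#' `k_range` to `[1, max(k_range)]`, and the penalty is the rescaled spread
#' plus k. The minimum marks a candidate k. (Defined on a cluster tree
#' because the criterion requires one; it is reported as one diagnostic
#' among three, alongside silhouette and Mantel.)
#'
#' @param D symmetric distance matrix.
#' @param k_range integer vector within `[2, n - 1]`.
#' @return named numeric penalty per k.
#' @export
kgs_penalty <- function(D, k_range) {
  D <- as.matrix(D)
  n <- nrow(D)
  .check(all(k_range >= 2 & k_range <= n - 1), "k_range must lie in [2, n-1]")
  if (all(D == 0)) {
    warning("all-zero distance matrix: flat KGS penalty = k")
    return(stats::setNames(as.numeric(k_range), k_range))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  # spreads are computed from k = 1 (one all-inclusive cluster) so the large
  # initial drop anchors the rescaling, as in the tree-based original
  ks <- seq_len(max(k_range))
  spread <- vapply(ks, function(k) {
    lab <- stats::cutree(hc, k = k)
    mean(vapply(unique(lab), function(c0) {
      idx <- which(lab == c0)
      if (length(idx) < 2) 0 else mean(D[idx, idx][lower.tri(D[idx, idx])])
    }, numeric(1)))
  }, numeric(1))
  rng <- range(spread)
  rescaled <- if (diff(rng) == 0) {
    rep(1, length(spread))
  } else {
    1 + (spread - rng[1]) / diff(rng) * (max(k_range) - 1)
  }
  stats::setNames(rescaled[k_range] + k_range, k_range)
}

#' k-selection diagnostics table
#'
#' Runs FANNY at each candidate k and reports the mean silhouette width and
#' Mantel correlation of the crisp labels, plus the KGS penalty. The table
#' informs but never auto-selects k: the final number of clusters is a
#' configured judgment call.
#'
#' @param D symmetric distance matrix.
#' @param k_range candidate numbers of clusters.
#' @param r membership exponent.
#' @param seed integer seed.
#' @return object of class `k_selection`: data.frame with `k`,
#'   `mean_silhouette`, `mantel_r`, `kgs_penalty`.
#' @export
select_k_table <- function(D, k_range = 2:8, r = 1.2, seed = 1L) {
  kgs <- kgs_penalty(D, k_range)
  rows <- lapply(k_range, function(k) {
    fm <- fanny_cluster(D, k, r = r, seed = seed)
    lab <- fm$labels
    ok <- length(unique(lab)) >= 2
    data.frame(
      k = k,
      mean_silhouette = if (ok) silhouette_widths(D, lab)$mean else NA_real_,
      mantel_r = if (ok) tryCatch(mantel_correlation(D, lab),
                                  error = function(e) NA_real_) else NA_real_,
      kgs_penalty = kgs[[as.character(k)]]
    )
  })
  structure(do.call(rbind, rows), class = c("k_selection", "data.frame"))
}

#' @export
print.k_selection <- function(x, ...) {
  cat("k-selection diagnostics (higher silhouette/Mantel better, lower KGS better):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  best <- x$k[which.max(x$mean_silhouette)]
  cat(sprintf("silhouette favors k = %d; the final k remains a configured choice\n", best))
  invisible(x)
}
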