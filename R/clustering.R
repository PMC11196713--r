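#' Ward hierarchical clustering of functioning items
#'
#' Agglomerative minimum-variance (Ward) clustering on Euclidean distances
#' (the `ward.D2` convention: heights are Euclidean, the merge criterion is
#' the squared-distance variance increase). Cutting the tree at `k` yields
#' the phenotype labels. Labels are normalized for cross-run comparability:
#' cluster 1 has the lowest mean functioning sum, ascending from there, so
#' cluster numbering is invariant to row order of the input.
#'
#' @param items Participants x items data frame (a `participant_id` column
#'   is carried through) or numeric matrix; no missing values.
#' @param k Number of clusters to cut.
#' @param scale_items Z-score items before clustering (default `TRUE`;
#'   instruments are on heterogeneous scales).
#' @return An object of class `fp_clusters`: `k`, a `labels` tibble,
#'   the `hclust` tree, and the distance/linkage used.
#' @export
ward_cluster <- function(items, k, scale_items = TRUE) {
  X <- as_item_matrix(items)
  if (anyNA(X)) abort("items must not contain missing values")
  if (k < 1 || k > nrow(X)) abort("`k` must lie in 1..n")
  Xc <- if (scale_items) scale(X) else X
  if (scale_items && any(!is.finite(Xc))) {
    abort("constant item column: cannot z-score before clustering")
  }
  hc <- hclust(dist(Xc), method = "ward.D2")
  raw <- cutree(hc, k = k)
  labels <- normalize_cluster_labels(raw, Xc)
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  structure(
    list(k = as.integer(k),
         labels = tibble::tibble(participant_id = ids,
                                 cluster = labels),
         tree = hc,
         distance = "euclidean",
         linkage = "ward.D2",
         scaled = scale_items),
    class = "fp_clusters")
}

# Renumber clusters so cluster 1 has the lowest mean functioning sum,
# ascending. Ties (identical means) break by first occurrence.
normalize_cluster_labels <- function(raw, X) {
  sums <- rowSums(X)
  means <- tapply(sums, raw, mean)
  ord <- order(means)
  map <- integer(length(ord))
  map[as.integer(names(means))[ord]] <- seq_along(ord)
  map[raw]
}

#' @export
print.fp_clusters <- function(x, ...) {
  cat(sprintf("<fp_clusters> Ward (%s) / %s distance, k = %d\n",
              x$linkage, x$distance, x$k))
  print(table(cluster = x$labels$cluster))
  invisible(x)
}

# Total within-cluster sum of squares for a labelling.
within_ss <- function(X, labels) {
  sum(vapply(split(seq_len(nrow(X)), labels), function(idx) {
    Xi <- X[idx, , drop = FALSE]
    sum(sweep(Xi, 2, colMeans(Xi))^2)
  }, 0))
}

# Internal validity indices for one k given the pairwise distances, data
# and labels. Returns a named list; the caller decides each index's
# preference direction.
validity_indices <- function(X, d, dvec, labels, k, W, W_all, n) {
  p <- ncol(X)
  tss <- W_all[["1"]]
  B <- tss - W
  pair_same <- outer(labels, labels, "==")[lower.tri(diag(n))]

  cent <- do.call(rbind, lapply(split(seq_len(n), labels), function(idx) {
    colMeans(X[idx, , drop = FALSE])
  }))
  sizes <- as.vector(table(labels))
  # scatter of each cluster around its centroid (mean distance)
  S <- vapply(seq_len(k), function(g) {
    idx <- which(labels == g)
    mean(sqrt(rowSums(sweep(X[idx, , drop = FALSE], 2, cent[g, ])^2)))
  }, 0)
  M <- as.matrix(dist(cent))

  ch <- (B / (k - 1)) / (W / (n - k))
  sil <- mean(cluster::silhouette(labels, dist = d)[, "sil_width"])

  d_within <- dvec[pair_same]
  d_sorted <- sort(dvec)
  nw <- length(d_within)
  s_min <- sum(d_sorted[seq_len(nw)])
  s_max <- sum(d_sorted[seq(length(d_sorted) - nw + 1L, length(d_sorted))])
  cindex <- (sum(d_within) - s_min) / (s_max - s_min)

  dunn <- min(dvec[!pair_same]) /
    max(vapply(seq_len(k), function(g) {
      dg <- dvec[pair_same & outer(labels == g, labels == g,
                                   "&")[lower.tri(diag(n))]]
      if (length(dg)) max(dg) else 0
    }, 0))

  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (S[i] + S[j]) / M[i, j], 0))
  }, 0))

  hart <- (W / W_all[[as.character(k + 1L)]] - 1) * (n - k - 1)

  kl_diff <- function(kk) {
    (kk - 1)^(2 / p) * W_all[[as.character(kk - 1L)]] -
      kk^(2 / p) * W_all[[as.character(kk)]]
  }
  kl <- abs(kl_diff(k) / kl_diff(k + 1L))

  ballhall_drop <- W_all[[as.character(k - 1L)]] / (k - 1) - W / k

  ptbiserial <- suppressWarnings(cor(dvec, as.numeric(!pair_same)))

  list(calinski_harabasz = ch, silhouette = sil, c_index = cindex,
       dunn = dunn, davies_bouldin = db, hartigan = hart,
       krzanowski_lai = kl, ball_hall = ballhall_drop,
       point_biserial = ptbiserial)
}

#' Select the number of clusters by index vote
#'
#' Computes ten internal cluster-validity indices (Calinski-Harabasz,
#' average silhouette, C-index, Dunn, Davies-Bouldin, gap statistic,
#' Hartigan, Krzanowski-Lai, Ball-Hall difference, point-biserial) on the
#' Ward hierarchy cut at each candidate `k`, records each index's preferred
#' `k`, and reports the majority vote. Ties — within an index and in the
#' final vote — break toward smaller `k` (parsimony).
#'
#' @inheritParams ward_cluster
#' @param k_range Candidate cluster counts (default 2:8), within
#'   \[2, n - 1\].
#' @param n_reference Number of uniform reference datasets for the gap
#'   statistic (default 20).
#' @param seed Seed for the gap-statistic reference draws.
#' @return An object of class `fp_kselect`: `votes` tibble (k, votes),
#'   `winners` tibble (index, best_k), and the majority `winner`.
#' @export
select_k <- function(items, k_range = 2:8, scale_items = TRUE,
                     n_reference = 20L, seed = 1L) {
  X <- as_item_matrix(items)
  if (anyNA(X)) abort("items must not contain missing values")
  n <- nrow(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > n - 1L) {
    abort("`k_range` must lie within [2, n - 1]")
  }
  Xc <- if (scale_items) scale(X) else X
  if (anyNA(Xc) || sum(dist(Xc)) == 0) {
    abort("degenerate input: all rows identical or constant items")
  }
  d <- dist(Xc)
  dvec <- as.vector(d)
  hc <- hclust(d, method = "ward.D2")

  ks_needed <- sort(unique(c(1L, k_range - 1L, k_range, k_range + 1L)))
  W_all <- lapply(ks_needed, function(k) {
    if (k == 1L) sum(scale(Xc, scale = FALSE)^2)
    else within_ss(Xc, cutree(hc, k))
  })
  names(W_all) <- as.character(ks_needed)

  idx_tbl <- lapply(k_range, function(k) {
    validity_indices(Xc, d, dvec, cutree(hc, k), k,
                     W_all[[as.character(k)]], W_all, n)
  })

  gap <- gap_statistic(Xc, k_range, n_reference, seed)

  # preference direction per index
  pick <- function(vals, maximize = TRUE) {
    vals <- if (maximize) vals else -vals
    k_range[which.max(vals)]  # which.max: first (= smallest k) on ties
  }
  get <- function(nm) vapply(idx_tbl, `[[`, 0, nm)
  winners <- c(
    calinski_harabasz = pick(get("calinski_harabasz")),
    silhouette = pick(get("silhouette")),
    c_index = pick(get("c_index"), maximize = FALSE),
    dunn = pick(get("dunn")),
    davies_bouldin = pick(get("davies_bouldin"), maximize = FALSE),
    gap = gap$best_k,
    hartigan = pick(hartigan_drop(get("hartigan"))),
    krzanowski_lai = pick(get("krzanowski_lai")),
    ball_hall = pick(get("ball_hall")),
    point_biserial = pick(get("point_biserial"))
  )
  votes <- vapply(k_range, function(k) sum(winners == k), 0L)
  winner <- k_range[votes == max(votes)][1L]
  structure(
    list(k_range = k_range,
         votes = tibble::tibble(k = k_range, votes = votes),
         winners = tibble::tibble(index = names(winners),
                                  best_k = unname(winners)),
         index_values = idx_tbl,
         gap = gap,
         winner = winner),
    class = "fp_kselect")
}

# Hartigan's rule as a per-k score: the drop H(k-1) - H(k) is largest at
# the knee; the first element has no predecessor within the range and is
# scored -Inf so it can only win if the range has length 1.
hartigan_drop <- function(h) {
  if (length(h) == 1L) return(0)
  c(-Inf, h[-length(h)] - h[-1L])
}

# Tibshirani gap statistic on the Ward hierarchy with the principal-
# component-aligned uniform reference (appropriate for correlated items)
# and the 1-SE rule (smallest k with gap(k) >= gap(k+1) - se(k+1));
# falls back to the global maximum when no k satisfies it in range.
gap_statistic <- function(X, k_range, n_reference, seed) {
  n <- nrow(X)
  hc <- hclust(dist(X), method = "ward.D2")
  logW <- vapply(k_range, function(k) log(within_ss(X, cutree(hc, k))), 0)
  Xc <- scale(X, scale = FALSE)
  V <- svd(Xc, nu = 0)$v
  Xp <- Xc %*% V
  rng <- apply(Xp, 2, range)
  ref <- with_seed(seed, {
    vapply(seq_len(n_reference), function(b) {
      Xr <- apply(rng, 2, function(r) runif(n, r[1L], r[2L])) %*% t(V)
      hcr <- hclust(dist(Xr), method = "ward.D2")
      vapply(k_range, function(k) log(within_ss(Xr, cutree(hcr, k))), 0)
    }, numeric(length(k_range)))
  })
  ref <- matrix(ref, nrow = length(k_range))
  gap <- rowMeans(ref) - logW
  se <- apply(ref, 1, sd) * sqrt(1 + 1 / n_reference)
  best <- NA_integer_
  for (i in seq_along(k_range)[-length(k_range)]) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) {
      best <- k_range[i]
      break
    }
  }
  if (is.na(best)) best <- k_range[which.max(gap)]
  list(k = k_range, gap = gap, se = se, best_k = best)
}

#' @export
print.fp_kselect <- function(x, ...) {
  cat("<fp_kselect> index votes per candidate k\n")
  print(as.data.frame(x$votes), row.names = FALSE)
  cat(sprintf("majority winner: k = %d\n", x$winner))
  invisible(x)
}

#' Bootstrap Jaccard stability of a clustering
#'
#' For each of `n_bootstrap` resamples (rows drawn with replacement), the
#' resampled data are re-clustered with the same Ward/Euclidean procedure
#' and cut at the same `k`. Each reference cluster is scored by its maximum
#' Jaccard similarity with any bootstrap cluster, computed on the resampled
#' points with duplicates counted once; the per-cluster mean over resamples
#' is the stability, and a cluster with mean below 0.5 is flagged
#' dissolved.
#'
#' @inheritParams ward_cluster
#' @param n_bootstrap Number of resamples (default 100).
#' @param seed Integer seed for the resampling.
#' @return An object of class `fp_stability`: tibble `stability`
#'   (cluster, mean_jaccard, dissolved) plus `n_bootstrap`.
#' @export
bootstrap_stability <- function(items, k, n_bootstrap = 100L, seed = 1L,
                                scale_items = TRUE) {
  if (n_bootstrap < 1L) abort("`n_bootstrap` must be at least 1")
  X <- as_item_matrix(items)
  n <- nrow(X)
  ref <- ward_cluster(X, k, scale_items = scale_items)
  ref_sets <- split(seq_len(n), ref$labels$cluster)

  jac <- with_seed(seed, {
    out <- matrix(NA_real_, n_bootstrap, length(ref_sets))
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      bs <- ward_cluster(X[idx, , drop = FALSE], k,
                         scale_items = scale_items)
      bs_sets <- split(idx, bs$labels$cluster)  # original indices, dup-safe
      in_bs <- unique(idx)
      for (a in seq_along(ref_sets)) {
        A <- intersect(ref_sets[[a]], in_bs)
        out[b, a] <- max(vapply(bs_sets, function(B) {
          jaccard_similarity(A, B)
        }, 0))
      }
    }
    out
  })
  mj <- colMeans(jac)
  structure(
    list(stability = tibble::tibble(
           cluster = as.integer(names(ref_sets)),
           mean_jaccard = unname(mj),
           dissolved = unname(mj < 0.5)),
         n_bootstrap = as.integer(n_bootstrap),
         reference = ref),
    class = "fp_stability")
}

#' @export
print.fp_stability <- function(x, ...) {
  cat(sprintf("<fp_stability> %d bootstrap resamples\n", x$n_bootstrap))
  print(as.data.frame(x$stability), row.names = FALSE)
  invisible(x)
}
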