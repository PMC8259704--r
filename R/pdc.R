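#' Delay embedding of a numeric series
#'
#' Embeds a series of length `T` into overlapping windows
#' `(x_j, x_{j+t}, ..., x_{j+(m-1)t})`, yielding `T - (m-1) t` windows.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (>= 2).
#' @param t Delay (>= 1).
#' @return A matrix with one window per row.
#' @export
delay_embed <- function(x, m, t = 1L) {
  m <- as.integer(m); t <- as.integer(t)
  if (m < 2L || t < 1L) stopf("need m >= 2 and t >= 1")
  n_win <- length(x) - (m - 1L) * t
  if (n_win < 1L) {
    stopf("series of length %d too short for (m = %d, t = %d); need >= %d",
          length(x), m, t, (m - 1L) * t + 1L)
  }
  idx <- outer(seq_len(n_win), (0:(m - 1L)) * t, `+`)
  matrix(x[idx], nrow = n_win)
}

#' Codeword (rank pattern) of one embedded window
#'
#' The codeword of a window is the permutation of 0-based indices that
#' sorts the window ascending; ties are broken by original position
#' (stable), so e.g. a constant window maps to the identity codeword.
#'
#' @param window Numeric vector of length `m`.
#' @return Integer vector of 0-based argsort indices.
#' @export
codeword_of_window <- function(window) {
  order(window, method = "radix") - 1L
}

codeword_key <- function(cw) paste(cw, collapse = ",")

#' Construct a codebook object
#'
#' A codebook is the empirical permutation distribution of one series
#' dimension: a table of codeword counts and the number of windows counted.
#' Counts may be non-integer when a codebook is reconstructed from stored
#' frequencies; clustering and assignment only use the frequencies.
#'
#' @param counts Named numeric vector (names are codeword keys such as
#'   `"0,2,1"`).
#' @param total Number of windows counted.
#' @param m,t Embedding parameters the codebook was built with.
#' @return An object of class `codebook`.
#' @export
new_codebook <- function(counts, total, m, t) {
  counts <- counts[order(names(counts))]
  structure(list(counts = counts, total = as.numeric(total),
                 m = as.integer(m), t = as.integer(t)),
            class = "codebook")
}

#' Codeword frequencies of a codebook
#'
#' @param cb A `codebook`.
#' @return Named numeric vector summing to 1 (empty if the codebook is
#'   empty).
#' @export
codebook_frequencies <- function(cb) {
  if (cb$total == 0) return(stats::setNames(numeric(0), character(0)))
  cb$counts / cb$total
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> m = %d, t = %d, %d codeword(s), %g window(s)\n",
              x$m, x$t, length(x$counts), x$total))
  invisible(x)
}

#' Build the permutation-distribution codebook of a series
#'
#' Embeds the series with [delay_embed()], maps each window to its
#' codeword, and counts codeword occurrences.
#'
#' @inheritParams delay_embed
#' @return A [new_codebook()] object with `total = T - (m-1) t`.
#' @export
build_codebook <- function(x, m, t = 1L) {
  emb <- delay_embed(x, m, t)
  keys <- vapply(seq_len(nrow(emb)),
                 function(i) codeword_key(codeword_of_window(emb[i, ])),
                 character(1))
  tab <- table(keys)
  new_codebook(stats::setNames(as.numeric(tab), names(tab)),
               total = nrow(emb), m = m, t = t)
}

#' Normalized permutation entropy of a codebook
#'
#' Shannon entropy of the codeword frequencies divided by its maximum
#' `log(m!)`, hence in `[0, 1]`: 0 for a single recurring rank pattern,
#' 1 for a uniform distribution over all `m!` patterns.
#'
#' @param cb A `codebook`.
#' @return Normalized entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(cb) {
  p <- codebook_frequencies(cb)
  p <- p[p > 0]
  if (length(p) <= 1) return(0)
  -sum(p * log(p)) / lfactorial(cb$m)
}

#' Choose embedding parameters by the entropy heuristic
#'
#' For every candidate `(m, t)` feasible for all supplied series, computes
#' the mean normalized permutation entropy over series (degenerate
#' entropies of exactly 0 or 1 are excluded from the mean, and their count
#' reported) and returns the candidate minimizing it. Ties break towards
#' smaller `m`, then smaller `t`.
#'
#' @param series_list List of numeric series (typically all three
#'   dimensions of every employee).
#' @param ms,ts Candidate embedding dimensions and delays.
#' @return A list with chosen `m`, `t`, the score `trace` (one row per
#'   feasible candidate), and `n_degenerate` excluded at the optimum.
#' @export
entropy_heuristic <- function(series_list, ms = 2:7, ts = 1L) {
  grid <- expand.grid(t = as.integer(ts), m = as.integer(ms))
  grid <- grid[order(grid$m, grid$t), c("m", "t")]
  len_min <- min(vapply(series_list, length, integer(1)))
  feas <- (grid$m - 1L) * grid$t + 1L <= len_min
  if (any(!feas)) {
    message(sum(!feas), " infeasible (m, t) candidate(s) skipped")
  }
  grid <- grid[feas, , drop = FALSE]
  if (nrow(grid) == 0) stopf("no feasible (m, t) candidate")
  score <- numeric(nrow(grid))
  degen <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ent <- vapply(series_list, function(x) {
      permutation_entropy(build_codebook(x, grid$m[i], grid$t[i]))
    }, numeric(1))
    keep <- ent > 1e-12 & ent < 1 - 1e-12
    degen[i] <- sum(!keep)
    score[i] <- if (any(keep)) mean(ent[keep]) else NA_real_
  }
  if (all(is.na(score))) stopf("all candidates degenerate")
  best <- which(score <= min(score, na.rm = TRUE) + 1e-12)[1]
  list(m = grid$m[best], t = grid$t[best],
       trace = data.frame(m = grid$m, t = grid$t, mean_entropy = score,
                          n_degenerate = degen),
       n_degenerate = degen[best])
}

#' Symmetric alpha divergence between two codebooks
#'
#' Amari alpha divergence between the two discrete codeword distributions,
#' evaluated over the union support in sorted codeword order:
#' `D = sum(a p + (1-a) q - p^a q^(1-a)) / (a (1-a))`. At `alpha = 0.5`
#' (the default used throughout) this equals `2 * sum((sqrt(p) -
#' sqrt(q))^2)`, i.e. four times the squared Hellinger distance; it is then
#' symmetric and its square root is a metric.
#'
#' @param p,q `codebook` objects built with the same `m`.
#' @param alpha Divergence order in (0, 1).
#' @return Nonnegative number (4 at `alpha = 0.5` for distributions with
#'   disjoint support).
#' @export
alpha_divergence <- function(p, q, alpha = 0.5) {
  if (p$m != q$m) stopf("codebooks built with different m (%d vs %d)",
                        p$m, q$m)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  fp <- codebook_frequencies(p)
  fq <- codebook_frequencies(q)
  support <- sort(union(names(fp), names(fq)))
  pi <- stats::setNames(numeric(length(support)), support)
  qi <- pi
  pi[names(fp)] <- fp
  qi[names(fq)] <- fq
  val <- sum(alpha * pi + (1 - alpha) * qi - pi^alpha * qi^(1 - alpha)) /
    (alpha * (1 - alpha))
  max(val, 0) # clamp float round-off for near-identical distributions
}

#' Distance between two employees' codebook triples
#'
#' Total distance: the square root of the sum over the three working-hour
#' dimensions of the squared symmetric alpha divergences between the
#' corresponding codebooks.
#'
#' @param a,b Named lists of three `codebook`s (`shift_length`,
#'   `rest_after`, `start_hour`).
#' @param alpha Divergence order, see [alpha_divergence()].
#' @return Nonnegative number.
#' @export
employee_distance <- function(a, b, alpha = 0.5) {
  miss <- setdiff(ws_dims(), intersect(names(a), names(b)))
  if (length(miss)) stopf("missing dimension(s): %s",
                          paste(miss, collapse = ", "))
  d2 <- vapply(ws_dims(),
               function(d) alpha_divergence(a[[d]], b[[d]], alpha)^2,
               numeric(1))
  sqrt(sum(d2))
}

#' Codebook triple of one employee
#'
#' @param ws A `work_series`.
#' @param m,t Embedding parameters.
#' @return Named list of three `codebook`s.
#' @export
employee_codebooks <- function(ws, m, t = 1L) {
  stats::setNames(
    lapply(ws_dims(), function(d) build_codebook(ws[[d]], m, t)),
    ws_dims()
  )
}

#' Pairwise distance matrix of a cohort
#'
#' @param codebooks Named list (by employee id) of codebook triples, as
#'   from [employee_codebooks()].
#' @param alpha Divergence order.
#' @return Symmetric matrix with zero diagonal, dimnames = employee ids.
#' @export
pairwise_distances <- function(codebooks, alpha = 0.5) {
  ids <- names(codebooks)
  n <- length(ids)
  if (n < 2) stopf("need at least 2 employees")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <-
        employee_distance(codebooks[[i]], codebooks[[j]], alpha)
    }
  }
  D
}

#' Complete-linkage agglomeration of a distance matrix
#'
#' @param D Symmetric distance matrix (or `dist`).
#' @return An [stats::hclust] tree (`method = "complete"`).
#' @export
agglomerate_complete <- function(D) {
  stats::hclust(stats::as.dist(D), method = "complete")
}

pool_codebooks <- function(cbs) {
  all_counts <- unlist(lapply(unname(cbs), function(cb) cb$counts))
  tot <- sum(vapply(cbs, function(cb) cb$total, numeric(1)))
  counts <- tapply(all_counts, names(all_counts), sum)
  new_codebook(stats::setNames(as.numeric(counts), names(counts)),
               total = tot, m = cbs[[1]]$m, t = cbs[[1]]$t)
}

#' Information criterion of a cluster partition
#'
#' Scores a partition of the cohort under a per-cluster multinomial model
#' of codeword counts: within a cluster, every employee's codewords in a
#' dimension are draws from the cluster's pooled codeword distribution
#' (its maximum-likelihood estimate). The log-likelihood sums
#' `n_e,d(pi) * log(p_cluster,d(pi))` over employees, dimensions and
#' codewords; the parameter count is `k * sum_d (S_d - 1)` with `S_d` the
#' number of distinct codewords observed cohort-wide in dimension `d`
#' (most of the `m!` patterns never occur, so the nominal support would
#' overstate model size); `N` is the total number of codeword
#' observations. `BIC = -2 LL + params log(N)`;
#' `AIC = -2 LL + 2 params`.
#'
#' @param codebooks Named list of codebook triples.
#' @param labels Cluster labels, named by or aligned with `codebooks`.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @return The criterion value, with attributes `loglik`, `n_params`,
#'   `n_obs`.
#' @export
clustering_bic <- function(codebooks, labels, criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  if (length(labels) != length(codebooks)) {
    stopf("labels (%d) and codebooks (%d) differ in length",
          length(labels), length(codebooks))
  }
  if (!is.null(names(labels))) labels <- labels[names(codebooks)]
  if (anyNA(labels)) stopf("label missing for some employee")
  groups <- split(seq_along(codebooks), labels)
  if (any(lengths(groups) == 0)) stopf("empty cluster in partition")
  ll <- 0
  for (g in groups) {
    for (d in ws_dims()) {
      pooled <- pool_codebooks(lapply(codebooks[g], `[[`, d))
      logp <- log(codebook_frequencies(pooled))
      for (e in g) {
        cnt <- codebooks[[e]][[d]]$counts
        ll <- ll + sum(cnt * logp[names(cnt)])
      }
    }
  }
  s_d <- vapply(ws_dims(), function(d) {
    length(unique(unlist(lapply(codebooks,
                                function(cb) names(cb[[d]]$counts)))))
  }, integer(1))
  n_obs <- sum(vapply(codebooks,
                      function(cb) sum(vapply(cb, `[[`, numeric(1),
                                              "total")),
                      numeric(1)))
  n_params <- length(groups) * sum(s_d - 1L)
  val <- if (criterion == "BIC") -2 * ll + n_params * log(n_obs)
         else -2 * ll + 2 * n_params
  structure(val, loglik = ll, n_params = n_params, n_obs = n_obs)
}

#' Select the number of clusters on a dendrogram
#'
#' Cuts the complete-linkage tree at each candidate `k`, scores each
#' partition with [clustering_bic()], and returns the partition minimizing
#' the criterion (first minimum on ties).
#'
#' @param tree An [stats::hclust] tree over the cohort.
#' @param codebooks Named list of codebook triples, in tree label order.
#' @param ks Candidate numbers of clusters.
#' @param criterion `"BIC"` or `"AIC"`.
#' @return An object of class `cluster_solution`: the tree, chosen `k`,
#'   per-employee `labels`, per-cluster pooled codebooks, and the
#'   criterion `trace`.
#' @export
select_k <- function(tree, codebooks, ks = 1:10,
                     criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  ks <- sort(unique(as.integer(ks)))
  if (any(ks < 1) || any(ks > length(codebooks))) {
    stopf("k range must lie in 1..%d", length(codebooks))
  }
  scores <- numeric(length(ks))
  parts <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    labels <- stats::cutree(tree, k = ks[i])
    parts[[i]] <- labels
    scores[i] <- as.numeric(clustering_bic(codebooks, labels, criterion))
  }
  best <- which.min(scores)
  labels <- parts[[best]]
  pooled <- lapply(split(names(labels), labels), function(ids) {
    stats::setNames(lapply(ws_dims(), function(d) {
      pool_codebooks(lapply(codebooks[ids], `[[`, d))
    }), ws_dims())
  })
  structure(
    list(tree = tree, k = ks[best], labels = labels,
         pooled_codebooks = pooled, criterion = criterion,
         trace = data.frame(k = ks, score = scores)),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d (%s), %d employees; sizes: %s\n",
              x$k, x$criterion, length(x$labels),
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Permutation distribution clustering of a cohort
#'
#' End-to-end PDC: builds the three per-dimension codebooks for every
#' employee, computes the pairwise distance matrix from symmetric alpha
#' divergences, agglomerates with complete linkage, and selects the number
#' of clusters by the information criterion.
#'
#' @param series Named list of `work_series`.
#' @param m,t Embedding parameters (see [entropy_heuristic()] for a
#'   data-driven choice).
#' @param ks Candidate numbers of clusters.
#' @param criterion `"BIC"` or `"AIC"`.
#' @param alpha Divergence order.
#' @return A list with the `solution` (a `cluster_solution`), the
#'   `distances` matrix, the per-employee `codebooks`, and the reference
#'   `store` (a [codebook_store()] holding codebooks and labels).
#' @export
pdc_cluster <- function(series, m, t = 1L, ks = 1:10,
                        criterion = c("BIC", "AIC"), alpha = 0.5) {
  criterion <- match.arg(criterion)
  codebooks <- lapply(series, employee_codebooks, m = m, t = t)
  D <- pairwise_distances(codebooks, alpha = alpha)
  tree <- agglomerate_complete(D)
  sol <- select_k(tree, codebooks, ks = ks, criterion = criterion)
  list(solution = sol, distances = D, codebooks = codebooks,
       store = codebook_store(m, t, codebooks, sol$labels))
}
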