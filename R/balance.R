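# k-nearest-neighbour elimination of the majority (non-succinylated) class.
#
# A negative sample is eliminated when any positive appears among its k
# nearest neighbours; k starts at 10 (the roughly 10:1 class ratio) and grows
# until the retained negatives are close in number to the positives.

# For each negative sample, the rank (1 = nearest) of the closest positive
# among its neighbours (all other samples). A negative is eliminated at a
# given k iff this rank is <= k, which makes the removal set monotone in k by
# construction. Distances are Euclidean on per-feature z-scores computed on
# the dataset being balanced (so surface areas in tens of Angstrom^2 and
# angles in hundreds of degrees do not swamp probability-scale features);
# ties are broken by ascending sample index.
positive_neighbor_rank <- function(X, y) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  Z <- scale(X, center = mu, scale = sd)
  D <- as.matrix(stats::dist(Z))
  neg <- which(y == -1L)
  is_pos <- y == 1L
  n <- nrow(X)
  vapply(neg, function(i) {
    d <- D[i, ]
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i]
    match(TRUE, is_pos[ord])
  }, integer(1))
}

#' Negative samples eliminated by the k-nearest-neighbour rule
#'
#' Each negative sample's k nearest neighbours (excluding itself) are found
#' among all samples of the original dataset, both classes pooled; the
#' negative is marked for removal iff at least one neighbour is positive.
#' Decisions are simultaneous against the unmodified dataset.
#'
#' @param data a `succ_dataset` containing both classes.
#' @param k neighbourhood size (1 <= k < N).
#' @return character vector of ids of negatives to remove.
#' @export
knn_eliminate <- function(data, k) {
  n <- nrow(data$X)
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop("k must be smaller than the number of samples")
  if (!any(data$y == 1L)) stop("no positive samples in dataset")
  if (!any(data$y == -1L)) return(character())
  pr <- positive_neighbor_rank(data$X, data$y)
  data$ids[data$y == -1L][pr <= k]
}

#' Balance a dataset by incremental k-nearest-neighbour elimination
#'
#' Runs the elimination rule of [knn_eliminate()] at k = k_start,
#' k_start + 1, ... (always against the original dataset) and stops at the
#' first k where the retained negatives number at most `ratio_max` times the
#' positives. Because the removal set grows monotonically with k, deciding
#' against the original dataset and shrinking the pool cumulatively give
#' identical results. Positives are never removed. If `k_max` is reached
#' without satisfying the ratio the best-so-far reduction is returned with a
#' warning.
#'
#' @param data a `succ_dataset` with both classes.
#' @param k_start initial neighbourhood size (default 10, matching the
#'   roughly 10:1 negative:positive ratio the rule was designed for).
#' @param ratio_max stop once retained negatives / positives <= this
#'   (default 1.10).
#' @param k_max largest k to try (default 200).
#' @return list with `data` (the balanced `succ_dataset`) and `report`, a
#'   `balance_report` with fields `k_final`, `retained_negatives`,
#'   `removed_per_k` (data frame of k and cumulative removal counts) and
#'   `ratio_final`.
#' @export
balance_dataset <- function(data, k_start = 10, ratio_max = 1.10,
                            k_max = 200) {
  n <- nrow(data$X)
  n_pos <- sum(data$y == 1L)
  n_neg <- sum(data$y == -1L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required for balancing")
  if (k_start >= n) stop("k_start must be smaller than the number of samples")
  pr <- positive_neighbor_rank(data$X, data$y)
  ks <- seq.int(k_start, min(k_max, n - 1L))
  removed <- integer(0)
  k_final <- NA_integer_
  for (k in ks) {
    removed <- c(removed, sum(pr <= k))
    retained <- n_neg - removed[[length(removed)]]
    if (retained <= ratio_max * n_pos) { k_final <- k; break }
  }
  if (is.na(k_final)) {
    k_final <- ks[[length(ks)]]
    warning("balance: ratio ", ratio_max, " not reached by k = ", k_final,
            "; returning best-so-far reduction")
  }
  drop_ids <- data$ids[data$y == -1L][pr <= k_final]
  keep <- !(data$ids %in% drop_ids)
  out <- dataset_subset(data, keep)
  report <- structure(list(
    k_final = k_final,
    retained_negatives = sum(out$y == -1L),
    removed_per_k = data.frame(k = ks[seq_along(removed)], removed = removed),
    ratio_final = sum(out$y == -1L) / n_pos), class = "balance_report")
  list(data = out, report = report)
}
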