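# Shared helpers: tiny in-memory proteins/tracks and brute-force oracles.

make_tracks <- function(L, seed = 1) {
  set.seed(seed)
  pssm_vals <- matrix(runif(L * 20), ncol = 20, dimnames = list(NULL, AA_ORDER))
  pssm_vals <- pssm_vals / rowSums(pssm_vals)
  ss <- matrix(runif(L * 3), ncol = 3, dimnames = list(NULL, c("ph", "pe", "pc")))
  ss <- ss / rowSums(ss)
  list(
    pssm = structure(list(protein_id = "p", values = pssm_vals),
                     class = "pssm_matrix"),
    profile = structure(list(protein_id = "p",
                             asa = abs(rnorm(L, 0, 50)),
                             ss_probs = ss,
                             angles = matrix(runif(L * 4, -180, 180), ncol = 4,
                                             dimnames = list(NULL, c("phi", "psi",
                                                                     "theta", "tau")))),
                        class = "structural_profile"))
}

# naive triple-loop bigram: the independent oracle for bigram_profile()
bigram_naive <- function(track) {
  n <- nrow(track); K <- ncol(track)
  B <- matrix(0, K, K)
  for (p in seq_len(K)) for (q in seq_len(K)) {
    s <- 0
    for (k in seq_len(n - 1)) s <- s + track[k, p] * track[k + 1, q]
    B[p, q] <- s
  }
  B
}

# brute-force k-NN elimination oracle: z-score, full sort per negative
knn_eliminate_naive <- function(X, y, ids, k) {
  sd <- apply(X, 2, sd); sd[sd == 0 | is.na(sd)] <- 1
  Z <- scale(X, scale = sd)
  n <- nrow(X)
  removed <- character()
  for (i in which(y == -1L)) {
    d <- sqrt(colSums((t(Z) - Z[i, ])^2))
    ord <- order(d, seq_len(n))
    nb <- setdiff(ord, i)[seq_len(k)]
    if (any(y[nb] == 1L)) removed <- c(removed, ids[[i]])
  }
  removed
}

# two well-separated Gaussian clouds as a succ_dataset
gaussian_dataset <- function(n_pos, n_neg, p = 5, sep = 5, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_pos * p, mean = sep), ncol = p),
             matrix(rnorm(n_neg * p, mean = 0), ncol = p))
  new_dataset(X, c(rep(1L, n_pos), rep(-1L, n_neg)))
}
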