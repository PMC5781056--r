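# Per-lysine feature construction: bigram transition profiles of the window's
# PSSM and secondary-structure tracks plus the raw structural tracks,
# concatenated into the 657-component descriptor.

#' Bigram transition profile of a window track
#'
#' For a track M with rows indexed by window slot (31 rows by default) and K
#' columns, the bigram profile is the K x K matrix
#' \deqn{B_{p,q} = \sum_{k=1}^{n-1} M_{k,p} M_{k+1,q}}
#' summing over all consecutive slot pairs. It captures ordered pairwise
#' transitions within the window and its dimensionality (K^2) is independent
#' of the window size: a 20-column PSSM track always yields 400 features and
#' a 3-column secondary-structure track always yields 9.
#'
#' @param track numeric matrix with at least 2 rows.
#' @return a `bigram_profile`: list with `B` (K x K matrix) and `F`, its
#'   row-major flattening (first index slowest: B11, B12, ..., BKK).
#' @export
bigram_profile <- function(track) {
  track <- as.matrix(track)
  n <- nrow(track)
  if (n < 2L) stop("bigram profile requires at least 2 window rows")
  B <- crossprod(track[-n, , drop = FALSE], track[-1, , drop = FALSE])
  dimnames(B) <- NULL
  structure(list(B = B, F = as.vector(t(B))), class = "bigram_profile")
}

#' Flatten the structural window tracks into the 248-component block
#'
#' Track-major concatenation: all 31 ASA values (slot -15..+15), then all 31
#' helix probabilities, and so on through ph, pe, pc, phi, psi, theta, tau.
#'
#' @param window_struct the 31 x 8 `struct` matrix from
#'   [extract_window_tracks()].
#' @return numeric vector of length 8 * nrow(window_struct) (248 by default).
#' @export
structural_block <- function(window_struct) {
  window_struct <- as.matrix(window_struct)
  if (ncol(window_struct) != 8L) {
    stop("structural window must have 8 columns, got ", ncol(window_struct))
  }
  as.vector(window_struct)
}

#' Assemble the per-lysine feature vector
#'
#' Block layout (657 components at the default flank of 15):
#' structural tracks 8 x 31 = 248, then the 400-component PSSM bigram block,
#' then the 9-component secondary-structure bigram block. With
#' `bigrams = FALSE` the PSSM and secondary-structure tracks enter raw
#' (track-major, like the structural block) instead of as bigram profiles,
#' giving 31 x 20 + 31 x 3 additional components (961 total) -- the ablation
#' configuration used to quantify what the bigram transformation adds.
#'
#' @param window_struct 31 x 8 structural track matrix.
#' @param window_pssm 31 x 20 PSSM track matrix.
#' @param window_ss 31 x 3 secondary-structure probability matrix.
#' @param bigrams apply the bigram transformation (default TRUE).
#' @return numeric feature vector (length 657, or 961 with `bigrams = FALSE`).
#' @export
assemble_features <- function(window_struct, window_pssm, window_ss,
                              bigrams = TRUE) {
  window_pssm <- as.matrix(window_pssm)
  window_ss <- as.matrix(window_ss)
  if (ncol(window_pssm) != 20L) stop("PSSM window must have 20 columns")
  if (ncol(window_ss) != 3L) stop("secondary-structure window must have 3 columns")
  if (nrow(window_struct) != nrow(window_pssm) ||
      nrow(window_pssm) != nrow(window_ss)) {
    stop("window tracks disagree in row count")
  }
  if (bigrams) {
    c(structural_block(window_struct),
      bigram_profile(window_pssm)$F,
      bigram_profile(window_ss)$F)
  } else {
    c(structural_block(window_struct),
      as.vector(window_pssm),
      as.vector(window_ss))
  }
}

#' Feature vectors for the lysines of one protein
#'
#' In `"sites"` mode one vector is computed per annotated site and labels are
#' carried through; in `"predict"` mode one vector is computed per lysine in
#' the sequence, with label 0 (unlabeled).
#'
#' @param record a `protein_record`.
#' @param pssm matching `pssm_matrix`.
#' @param profile matching `structural_profile`.
#' @param flank window flank (default 15).
#' @param padding passed to [window_indices()].
#' @param mode `"sites"` or `"predict"`.
#' @param bigrams passed to [assemble_features()].
#' @return list with `X` (one row per lysine), `y` (labels) and `meta`
#'   (protein_id, position).
#' @export
featurize_protein <- function(record, pssm, profile, flank = 15,
                              padding = "mirror-terminus",
                              mode = c("sites", "predict"), bigrams = TRUE) {
  mode <- match.arg(mode)
  L <- nchar(record$sequence)
  if (nrow(pssm$values) != L || length(profile$asa) != L) {
    stop("tracks for protein ", record$id,
         " do not match its sequence length ", L)
  }
  if (mode == "sites") {
    positions <- record$sites$position
    labels <- record$sites$label
  } else {
    positions <- which(strsplit(record$sequence, "")[[1]] == "K")
    labels <- rep(0L, length(positions))
  }
  p_feat <- if (bigrams) 8 * (2 * flank + 1) + 400 + 9
            else (8 + 20 + 3) * (2 * flank + 1)
  X <- matrix(NA_real_, nrow = length(positions), ncol = p_feat)
  for (i in seq_along(positions)) {
    w <- window_indices(L, positions[[i]], flank = flank, padding = padding)
    tr <- extract_window_tracks(w, pssm, profile)
    X[i, ] <- assemble_features(tr$struct, tr$pssm, tr$ss, bigrams = bigrams)
  }
  list(X = X, y = labels,
       meta = data.frame(protein_id = rep(record$id, length(positions)),
                         position = as.integer(positions)))
}

#' Build a labeled dataset from a set of proteins and their tracks
#'
#' @param records named list of `protein_record` with sites attached.
#' @param pssms named list of `pssm_matrix` (names matching protein ids).
#' @param profiles named list of `structural_profile`.
#' @inheritParams featurize_protein
#' @return a `succ_dataset`: list with `X` (N x p feature matrix), `y`
#'   (labels in +1/-1), `ids` (unique "protein:position" keys) and `meta`.
#' @export
featurize_dataset <- function(records, pssms, profiles, flank = 15,
                              padding = "mirror-terminus",
                              mode = "sites", bigrams = TRUE) {
  parts <- lapply(records, function(rec) {
    if (is.null(pssms[[rec$id]])) stop("missing PSSM for protein ", rec$id)
    if (is.null(profiles[[rec$id]])) {
      stop("missing structural profile for protein ", rec$id)
    }
    featurize_protein(rec, pssms[[rec$id]], profiles[[rec$id]], flank = flank,
                      padding = padding, mode = mode, bigrams = bigrams)
  })
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  y <- unlist(lapply(parts, `[[`, "y"), use.names = FALSE)
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  rownames(meta) <- NULL
  new_dataset(X, y, meta)
}

#' Construct a labeled dataset object
#'
#' @param X numeric feature matrix, one row per lysine.
#' @param y integer labels (+1/-1, or 0 for unlabeled).
#' @param meta data frame with columns protein_id and position.
#' @return a `succ_dataset`.
#' @export
new_dataset <- function(X, y, meta = NULL) {
  X <- as.matrix(X)
  if (is.null(meta)) {
    meta <- data.frame(protein_id = sprintf("s%d", seq_len(nrow(X))),
                       position = seq_len(nrow(X)))
  }
  ids <- paste(meta$protein_id, meta$position, sep = ":")
  if (nrow(X) != length(y) || nrow(X) != length(ids)) {
    stop("X, y and meta disagree in length")
  }
  if (anyDuplicated(ids)) stop("duplicate sample ids in dataset")
  structure(list(X = X, y = as.integer(y), ids = ids, meta = meta),
            class = "succ_dataset")
}

#' Subset a dataset by row index
#' @param data a `succ_dataset`.
#' @param i row indices (integer or logical).
#' @return the subsetted `succ_dataset`.
#' @export
dataset_subset <- function(data, i) {
  new_dataset(data$X[i, , drop = FALSE], data$y[i],
              data$meta[i, , drop = FALSE])
}
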