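small_cfg <- function(...) {
  synth_config(n_proteins = 12, len_range = c(100, 140), n_pos = 6,
               n_neg = 12, ...)
}

test_that("generation is byte-identical under a fixed seed", {
  g1 <- synth_generate(small_cfg(seed = 7))
  g2 <- synth_generate(small_cfg(seed = 7))
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
  g3 <- synth_generate(small_cfg(seed = 8))
  expect_false(identical(g1$sites, g3$sites))
})

test_that("generated tracks satisfy the input-format invariants", {
  g <- synth_generate(small_cfg(seed = 3, delta = 0.7))
  for (id in names(g$records)) {
    L <- nchar(g$records[[id]]$sequence)
    expect_equal(nrow(g$pssms[[id]]$values), L)
    expect_equal(rowSums(g$pssms[[id]]$values), rep(1, L), tolerance = 1e-9)
    expect_true(all(g$pssms[[id]]$values >= 0))
    expect_equal(rowSums(g$profiles[[id]]$ss_probs), rep(1, L),
                 tolerance = 1e-9)
    expect_true(all(g$profiles[[id]]$asa >= 0))
    expect_true(all(abs(g$profiles[[id]]$angles) <= 180))
  }
  # every site sits on a planted lysine
  res <- mapply(function(id, p) substring(g$records[[id]]$sequence, p, p),
                g$sites$protein_id, g$sites$position)
  expect_true(all(res == "K"))
  expect_equal(sum(g$sites$label == 1L), 6)
  expect_equal(sum(g$sites$label == -1L), 12)
})

test_that("delta = 1 with a one-hot motif pins positive-window PSSM rows", {
  motif <- c(1, rep(0, 19))
  g <- synth_generate(small_cfg(seed = 4, delta = 1, motif = motif))
  pos <- g$sites[g$sites$label == 1L, ]
  for (j in seq_len(nrow(pos))) {
    rows <- (pos$position[j] - 15):(pos$position[j] + 15)
    vals <- g$pssms[[pos$protein_id[j]]]$values[rows, ]
    expect_equal(unname(vals),
                 matrix(motif, nrow = 31, ncol = 20, byrow = TRUE))
  }
})

test_that("delta = 0 leaves the classes distributionally identical", {
  g <- synth_generate(synth_config(n_proteins = 60, len_range = c(100, 160),
                                   n_pos = 40, n_neg = 40, delta = 0,
                                   seed = 5))
  d <- featurize_dataset(g$records, g$pssms, g$profiles)
  # per-feature two-sample tests: at alpha = 0.01 about 1% of 100 random
  # features should reject; require at least 95 non-significant
  set.seed(6)
  feats <- sample(ncol(d$X), 100)
  pvals <- vapply(feats, function(j) {
    suppressWarnings(stats::wilcox.test(d$X[d$y == 1L, j],
                                        d$X[d$y == -1L, j])$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01, na.rm = TRUE), 95)
})

test_that("infeasible site placement is a configuration error", {
  expect_error(synth_generate(synth_config(n_proteins = 2,
                                           len_range = c(40, 50),
                                           n_pos = 30, n_neg = 30)),
               "cannot place")
})

test_that("written fixture trees parse cleanly and round-trip to quantization", {
  g <- synth_generate(small_cfg(seed = 9))
  dir <- withr::local_tempdir()
  expect_no_warning(paths <- write_fixture_set(g, dir))
  expect_no_warning({
    recs <- read_fasta(file.path(dir, "proteins.fasta"))
    sites <- read_sites(file.path(dir, "sites.tsv"))
    recs <- attach_sites(recs, sites)
  })
  expect_equal(sort(names(recs)), sort(names(g$records)))
  for (id in names(recs)[1:3]) {
    p <- read_pssm(file.path(dir, paste0(id, ".pssm")))
    expect_equal(nrow(p$values), nchar(recs[[id]]$sequence))
    expect_lt(max(abs(p$values - g$pssms[[id]]$values)), 0.005 + 1e-9)
    s <- read_structural_profile(file.path(dir, paste0(id, ".spd3")))
    expect_equal(s$asa, g$profiles[[id]]$asa, tolerance = 1e-3)
  }
})

test_that("a terminal site exercises mirror padding end to end", {
  g <- synth_generate(synth_config(n_proteins = 8, len_range = c(60, 80),
                                   n_pos = 4, n_neg = 6, min_margin = 0,
                                   seed = 10))
  # force one annotated site onto position 1
  id <- g$sites$protein_id[[1]]
  seq1 <- g$records[[id]]$sequence
  substr(seq1, 1, 1) <- "K"
  g$records[[id]]$sequence <- seq1
  g$records[[id]]$sites <- data.frame(position = 1L, label = 1L)
  ft <- featurize_protein(g$records[[id]], g$pssms[[id]], g$profiles[[id]])
  expect_equal(dim(ft$X), c(1, 657))
  expect_false(anyNA(ft$X))
  # through the on-disk formats too
  dir <- withr::local_tempdir()
  write_fixture_set(g, dir)
  p <- read_pssm(file.path(dir, paste0(id, ".pssm")))
  s <- read_structural_profile(file.path(dir, paste0(id, ".spd3")))
  ft2 <- featurize_protein(g$records[[id]], p, s)
  expect_equal(dim(ft2$X), c(1, 657))
})
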