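# End-to-end pipeline: read (or generate) inputs, featurize, balance,
# cross-validate, and train a final model, writing versioned artifacts.

#' Run the full prediction pipeline
#'
#' Reads the four input files/directories, builds the per-lysine feature
#' table, reduces the negative class by incremental k-nearest-neighbour
#' elimination, runs stratified n-fold cross-validation, and trains a final
#' model on the balanced data. All artifacts (feature table TSV, balance
#' report JSON, cross-validation report JSON, model JSON) are written under
#' `out_dir`; counts at every stage are logged via `message()` so the
#' imbalance handling is auditable. Deterministic given the inputs and seed.
#'
#' @param fasta path to the protein FASTA file.
#' @param track_dir directory holding `<protein_id>.pssm` and
#'   `<protein_id>.spd3` files for every protein.
#' @param sites path to the site-annotation TSV.
#' @param out_dir output directory.
#' @param flank,padding,pssm_scale feature-extraction settings.
#' @param balance run the k-NN elimination before cross-validation (the
#'   default evaluation design).
#' @param k_start,ratio_max,k_max [balance_dataset()] settings.
#' @param folds,seed,balance_within_folds [cross_validate()] settings.
#' @param C,gamma,tolerance [svm_train()] settings.
#' @return invisibly, a list with the dataset, balance report, `cv_report`
#'   and final model.
#' @export
run_pipeline <- function(fasta, track_dir, sites, out_dir,
                         flank = 15, padding = "mirror-terminus",
                         pssm_scale = "percent",
                         balance = TRUE, k_start = 10, ratio_max = 1.10,
                         k_max = 200,
                         folds = 10, seed = 1, balance_within_folds = FALSE,
                         C = 1, gamma = 0.01, tolerance = 0.001) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_fasta(fasta)
  site_map <- read_sites(sites)
  records <- attach_sites(records, site_map)
  message("pipeline: ", length(records), " proteins, ",
          sum(vapply(records, function(r) nrow(r$sites), integer(1))),
          " annotated sites")
  pssms <- list(); profiles <- list()
  for (id in names(records)) {
    pp <- file.path(track_dir, paste0(id, ".pssm"))
    sp <- file.path(track_dir, paste0(id, ".spd3"))
    if (!file.exists(pp)) stop("missing PSSM file for protein ", id)
    if (!file.exists(sp)) stop("missing structural profile for protein ", id)
    pssms[[id]] <- read_pssm(pp, scale_mode = pssm_scale)
    profiles[[id]] <- read_structural_profile(sp)
  }
  data <- featurize_dataset(records, pssms, profiles, flank = flank,
                            padding = padding)
  message("pipeline: feature table ", nrow(data$X), " x ", ncol(data$X),
          " (", sum(data$y == 1L), " positive / ", sum(data$y == -1L),
          " negative)")
  write_feature_table(data, file.path(out_dir, "features.tsv"))
  bal_report <- NULL
  if (balance && !balance_within_folds) {
    bal <- balance_dataset(data, k_start = k_start, ratio_max = ratio_max,
                           k_max = k_max)
    data <- bal$data
    bal_report <- bal$report
    message("pipeline: balanced at k = ", bal_report$k_final, "; retained ",
            bal_report$retained_negatives, " negatives (ratio ",
            round(bal_report$ratio_final, 3), ")")
    jsonlite::write_json(list(k_final = bal_report$k_final,
                              retained_negatives = bal_report$retained_negatives,
                              ratio_final = bal_report$ratio_final,
                              removed_per_k = bal_report$removed_per_k),
                         file.path(out_dir, "balance_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  cv <- cross_validate(data, n_folds = folds,
                       params = list(C = C, gamma = gamma,
                                     tolerance = tolerance),
                       seed = seed,
                       balance_within_folds = balance_within_folds,
                       balance_params = list(k_start = k_start,
                                             ratio_max = ratio_max,
                                             k_max = k_max))
  message("pipeline: ", folds, "-fold CV mean accuracy ",
          round(cv$means[["accuracy"]], 4), ", MCC ",
          round(cv$means[["mcc"]], 4))
  jsonlite::write_json(list(n_folds = cv$n_folds, seed = cv$seed,
                            per_fold = cv$per_fold,
                            means = as.list(cv$means)),
                       file.path(out_dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  model <- svm_train(data, C = C, gamma = gamma, tolerance = tolerance)
  write_model(model, file.path(out_dir, "model.json"))
  invisible(list(data = data, balance_report = bal_report, cv = cv,
                 model = model))
}

#' Predict succinylation for every lysine of new proteins
#'
#' @param model a `succ_svm` (from [svm_train()] or [read_model()]).
#' @param fasta path to a FASTA file of query proteins.
#' @param track_dir directory with `<id>.pssm` and `<id>.spd3` files.
#' @param flank,padding,pssm_scale feature-extraction settings; must match
#'   those used at training time.
#' @return data frame: protein_id, position, decision value, predicted label.
#' @export
predict_sites <- function(model, fasta, track_dir, flank = 15,
                          padding = "mirror-terminus",
                          pssm_scale = "percent") {
  records <- read_fasta(fasta)
  out <- list()
  for (id in names(records)) {
    pp <- file.path(track_dir, paste0(id, ".pssm"))
    sp <- file.path(track_dir, paste0(id, ".spd3"))
    if (!file.exists(pp)) stop("missing PSSM file for protein ", id)
    if (!file.exists(sp)) stop("missing structural profile for protein ", id)
    ft <- featurize_protein(records[[id]], read_pssm(pp, scale_mode = pssm_scale),
                            read_structural_profile(sp), flank = flank,
                            padding = padding, mode = "predict")
    if (nrow(ft$X) == 0L) next
    sc <- svm_decision(model, ft$X)
    out[[id]] <- data.frame(ft$meta, score = sc,
                            label = ifelse(sc >= 0, 1L, -1L))
  }
  if (length(out) == 0L) {
    return(data.frame(protein_id = character(), position = integer(),
                      score = numeric(), label = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
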