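# RBF-kernel support vector machine for succinylation-site classification.
#
# The decision function is the standard dual expansion
#   y' = sign( sum_i alpha_i y_i K(x_i, x') + beta ),  K(u,v) = exp(-g ||u-v||^2)
# with C = 1, gamma = 0.01 and termination tolerance 0.001 as defaults. The
# dual problem is solved by libsvm (via e1071); prediction evaluates the
# expansion explicitly from the stored support vectors, so a trained model is
# self-contained. Features are z-scored with training-set statistics before
# the kernel: with raw mixed-unit features (Angstrom^2, degrees,
# probabilities) a single shared gamma would be meaningless.

#' Train the RBF-kernel SVM
#'
#' @param data a `succ_dataset` with labels in +1/-1, or a feature matrix
#'   (then `y` must be given).
#' @param y labels, if `data` is a plain matrix.
#' @param C box constraint (default 1).
#' @param gamma RBF kernel width (default 0.01).
#' @param tolerance solver termination tolerance (default 0.001). The
#'   round-off parameter epsilon = 1e-12 of the original formulation has no
#'   direct libsvm analogue; it is recorded on the model for provenance and
#'   the solver tolerance is the operative stopping control.
#' @param epsilon recorded round-off parameter (default 1e-12).
#' @param scale z-score features with training statistics (default TRUE).
#' @return a `succ_svm` model: support vectors (scaled), dual coefficients
#'   alpha_i * y_i, bias, kernel parameters and the feature scaler.
#' @export
svm_train <- function(data, y = NULL, C = 1, gamma = 0.01, tolerance = 0.001,
                      epsilon = 1e-12, scale = TRUE) {
  if (inherits(data, "succ_dataset")) { X <- data$X; y <- data$y }
  else X <- as.matrix(data)
  if (anyNA(X)) stop("feature matrix contains missing values")
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1")
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  if (scale) {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
  } else {
    mu <- rep(0, ncol(X)); sd <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  fit <- e1071::svm(Xs, factor(y, levels = c(-1, 1)), type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma,
                    tolerance = tolerance, scale = FALSE)
  model <- structure(list(
    SV = unname(as.matrix(fit$SV)),
    coefs = as.vector(fit$coefs),       # alpha_i * y_i
    rho = fit$rho,
    orient = 1,
    gamma = gamma, C = C, tolerance = tolerance, epsilon = epsilon,
    scaler = list(center = mu, scale = sd),
    dim = ncol(X)), class = "succ_svm")
  # libsvm orients its decision value toward whichever class it saw first;
  # fix the orientation so positive decision values mean the +1 class
  f <- svm_decision(model, X)
  ref <- as.integer(as.character(stats::predict(fit, Xs)))
  informative <- abs(f) > 1e-9 & !is.na(ref)
  if (any(informative) &&
      mean(sign(f[informative]) == ref[informative]) < 0.5) {
    model$orient <- -1
  }
  model
}

#' Decision values of a trained model
#'
#' Evaluates the dual expansion sum_i (alpha_i y_i) exp(-gamma ||x_i - x||^2)
#' + beta explicitly on the stored (scaled) support vectors.
#'
#' @param model a `succ_svm`.
#' @param X feature matrix (rows) or a single feature vector, on the raw
#'   (unscaled) feature scale.
#' @return numeric vector of real-valued margins; positive means class +1.
#' @export
svm_decision <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$dim) {
    stop("expected ", model$dim, " features, got ", ncol(X))
  }
  Xs <- sweep(sweep(X, 2, model$scaler$center), 2, model$scaler$scale, "/")
  d2 <- outer(rowSums(Xs^2), rowSums(model$SV^2), "+") -
    2 * Xs %*% t(model$SV)
  d2[d2 < 0] <- 0
  K <- exp(-model$gamma * d2)
  model$orient * as.vector(K %*% model$coefs - model$rho)
}

#' Predict class labels
#'
#' `sign(decision value)`, with the tie `sign(0)` resolved to +1.
#'
#' @inheritParams svm_decision
#' @return integer vector of +1/-1 labels.
#' @export
svm_predict <- function(model, X) {
  ifelse(svm_decision(model, X) >= 0, 1L, -1L)
}

#' Serialise a trained model to a portable JSON file
#'
#' The file records a format version, the kernel and solver parameters, the
#' feature scaler, and the support vectors with their dual coefficients --
#' everything [svm_decision()] needs.
#'
#' @param model a `succ_svm`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  obj <- list(format = "succpred-svm-1",
              params = list(C = model$C, gamma = model$gamma,
                            tolerance = model$tolerance,
                            epsilon = model$epsilon),
              scaler = model$scaler,
              SV = model$SV, coefs = model$coefs, rho = model$rho,
              orient = model$orient, dim = model$dim)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path path to the JSON model file.
#' @return a `succ_svm`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "succpred-svm-1")) {
    stop("unrecognised model format in ", path)
  }
  structure(list(SV = as.matrix(obj$SV), coefs = obj$coefs, rho = obj$rho,
                 orient = obj$orient, gamma = obj$params$gamma,
                 C = obj$params$C, tolerance = obj$params$tolerance,
                 epsilon = obj$params$epsilon,
                 scaler = list(center = obj$scaler$center,
                               scale = obj$scaler$scale),
                 dim = obj$dim), class = "succ_svm")
}
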