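#' Baseline classifier configuration
#'
#' Settings for the three reference classifiers trained on the concatenated
#' drug+target feature vector: Gaussian naive Bayes, penalized logistic
#' regression (L1 or L2, strength expressed as the inverse-regularization
#' constant C, so the penalty weight is `1/(C * n)`), and random forest.
#'
#' @param lr_penalty `"L1"` or `"L2"`.
#' @param lr_C inverse regularization strength (> 0); the reference grid is
#'   C in {0.01, 0.1, 1.0}, with L2 at C = 0.1 the pathway-membership
#'   default.
#' @param rf_n_trees number of trees (reference value 10000; desk-scale
#'   profiles use fewer).
#' @param rf_max_features variables tried at each split; `NULL` uses the
#'   square-root-of-feature-count convention.
#' @param nb_variant only `"gaussian"` is defined.
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(lr_penalty = c("L2", "L1"), lr_C = 0.1,
                            rf_n_trees = 10000L, rf_max_features = NULL,
                            nb_variant = "gaussian") {
  lr_penalty <- match.arg(lr_penalty)
  nb_variant <- match.arg(nb_variant, "gaussian")
  if (lr_C <= 0) stop("lr_C must be positive", call. = FALSE)
  if (rf_n_trees < 1L) stop("rf_n_trees must be >= 1", call. = FALSE)
  structure(list(lr_penalty = lr_penalty, lr_C = lr_C,
                 rf_n_trees = as.integer(rf_n_trees),
                 rf_max_features = if (is.null(rf_max_features)) NULL
                                   else as.integer(rf_max_features),
                 nb_variant = nb_variant),
            class = "baseline_config")
}

#' Fit a baseline classifier
#'
#' @param kind `"nb"`, `"lr"` or `"rf"`.
#' @param config a [baseline_config()].
#' @param features numeric matrix (rows = drug-target pairs, columns = the
#'   concatenated drug+target features).
#' @param labels 0/1 labels, both classes present.
#' @param seed seed for the random-forest fit (NB and LR are deterministic).
#' @return An object of class `dti_baseline` (also `dti_model`) with a
#'   [predict()] method returning probability scores.
#' @export
fit_baseline <- function(kind = c("nb", "lr", "rf"), config = baseline_config(),
                         features, labels, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "baseline_config"))
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  y <- factor(labels, levels = c(0, 1))
  fit <- switch(kind,
    nb = e1071::naiveBayes(x = as.data.frame(features), y = y),
    lr = glmnet::glmnet(features, y, family = "binomial",
                        alpha = if (config$lr_penalty == "L1") 1 else 0,
                        lambda = 1 / (config$lr_C * nrow(features)),
                        standardize = TRUE),
    rf = {
      mtry <- config$rf_max_features
      if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
      mtry <- min(mtry, ncol(features))
      ranger::ranger(x = as.data.frame(features), y = y,
                     num.trees = config$rf_n_trees, mtry = mtry,
                     probability = TRUE, seed = seed, num.threads = 1L)
    })
  structure(list(kind = kind, config = config, fit = fit,
                 n_features = ncol(features), trained = TRUE),
            class = c("dti_baseline", "dti_model"))
}

#' @param object a `dti_baseline`.
#' @param features matrix with the training dimensionality.
#' @param ... unused.
#' @rdname fit_baseline
#' @export
predict.dti_baseline <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != object$n_features)
    stop("feature dimensions do not match the trained model", call. = FALSE)
  switch(object$kind,
    nb = as.numeric(predict(object$fit, as.data.frame(features),
                            type = "raw")[, "1"]),
    lr = as.numeric(predict(object$fit, features, type = "response")),
    rf = as.numeric(predict(object$fit, as.data.frame(features),
                            num.threads = 1L)$predictions[, "1"]))
}

#' @export
print.dti_baseline <- function(x, ...) {
  desc <- switch(x$kind,
    nb = sprintf("naive Bayes (%s)", x$config$nb_variant),
    lr = sprintf("logistic regression (%s, C = %g)", x$config$lr_penalty,
                 x$config$lr_C),
    rf = sprintf("random forest (%d trees)", x$config$rf_n_trees))
  cat(sprintf("<dti_baseline> %s on %d features\n", desc, x$n_features))
  invisible(x)
}

#' Score drug-target pairs with any trained model
#'
#' Uniform scoring interface: the two-block network consumes the drug and
#' target blocks separately; baselines consume their concatenation.
#'
#' @param model a `dti_dnn`, a `dti_baseline`, or a plain function
#'   `(drug_x, target_x) -> scores` (useful for reference scorers in
#'   evaluation experiments).
#' @param drug_x,target_x feature matrices (rows = pairs).
#' @return Numeric probability scores between 0 and 1.
#' @export
score_pairs <- function(model, drug_x, target_x) {
  if (is.function(model)) model(drug_x, target_x)
  else if (inherits(model, "dti_dnn")) predict(model, drug_x, target_x)
  else predict(model, cbind(as.matrix(drug_x), as.matrix(target_x)))
}
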