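#' Evaluation configuration
#'
#' @param n_folds cross-validation folds (reference protocol: 10).
#' @param negative_ratio unlabeled negatives sampled per positive (reference
#'   protocol: 1, i.e. balanced).
#' @param k_percent_grid top-k percentages for precision-at-k (reference
#'   range 0.1-20).
#' @param ratio_grid negative:positive ratios for the robustness experiment
#'   (reference range 1-100).
#' @param n_resamples negative redraws per compound and ratio (reference:
#'   100).
#' @param validation_fraction fraction of each training set held out for
#'   the network's early stopping.
#' @param stratify_negatives sample negatives per compound (equal negatives
#'   per drug's positives) rather than uniformly over the whole universe.
#' @param do_cv run the fold loop; `FALSE` evaluates only the held-out test
#'   split (folds are still constructed and checked for disjointness).
#' @param seed seed for sampling and partitioning.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(n_folds = 10L, negative_ratio = 1,
                        k_percent_grid = c(0.1, 0.5, 1, 2, 5, 10, 20),
                        ratio_grid = c(1L, 10L, 50L, 100L),
                        n_resamples = 100L, validation_fraction = 0.15,
                        stratify_negatives = TRUE, do_cv = TRUE,
                        seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (negative_ratio <= 0) stop("negative_ratio must be positive", call. = FALSE)
  if (any(k_percent_grid <= 0 | k_percent_grid > 100))
    stop("k percentages must lie in (0, 100]", call. = FALSE)
  if (any(ratio_grid < 1)) stop("ratios must be >= 1", call. = FALSE)
  structure(list(n_folds = as.integer(n_folds), negative_ratio = negative_ratio,
                 k_percent_grid = k_percent_grid,
                 ratio_grid = as.integer(ratio_grid),
                 n_resamples = as.integer(n_resamples),
                 validation_fraction = validation_fraction,
                 stratify_negatives = isTRUE(stratify_negatives),
                 do_cv = isTRUE(do_cv),
                 seed = as.integer(seed)),
            class = "eval_config")
}

pair_key <- function(drug, target) paste(drug, target, sep = "\r")

#' Sample unlabeled drug-target pairs as presumptive negatives
#'
#' Under the positive-unlabeled assumption (true interactions are sparse),
#' negatives are drawn uniformly without replacement from the drug x target
#' universe minus the known positives and minus any pair already labeled
#' elsewhere (e.g. in another partition), so partitions never share a pair.
#'
#' @param positives data.frame with `drug_id`, `target_id` (the positive
#'   pairs the negatives are matched to).
#' @param drugs,targets character vectors spanning the sampling universe.
#' @param ratio negatives per positive; `floor(ratio * n_positives)` pairs
#'   are drawn.
#' @param seed RNG seed.
#' @param exclude optional data.frame of additional (drug_id, target_id)
#'   pairs to exclude.
#' @return data.frame `drug_id`, `target_id`, `label = "negative"`.
#' @export
sample_negatives <- function(positives, drugs, targets, ratio = 1, seed = 1L,
                             exclude = NULL) {
  n_univ <- length(drugs) * length(targets)
  banned <- pair_key(positives$drug_id, positives$target_id)
  if (!is.null(exclude) && nrow(exclude) > 0)
    banned <- c(banned, pair_key(exclude$drug_id, exclude$target_id))
  n_needed <- floor(ratio * nrow(positives))
  # enumerate the universe; fine at benchmark scale
  univ_drug <- rep(drugs, times = length(targets))
  univ_target <- rep(targets, each = length(drugs))
  free <- !(pair_key(univ_drug, univ_target) %in% banned)
  if (sum(free) < n_needed)
    stop("requested ", n_needed, " negatives but only ", sum(free),
         " unlabeled pairs are available", call. = FALSE)
  set.seed(seed)
  pick <- sample(which(free), n_needed)
  data.frame(drug_id = univ_drug[pick], target_id = univ_target[pick],
             label = "negative", stringsAsFactors = FALSE)
}

#' Compound-stratified negative sampling
#'
#' Calls [sample_negatives()] once per compound so every drug receives
#' `ratio` negatives per positive. Uniform sampling of negatives lets the
#' number of positives per drug act as a label signal (drug-degree leakage),
#' which at small scale dominates and inverts on held-out pairs; matching
#' the per-compound class balance removes that shortcut.
#'
#' @inheritParams sample_negatives
#' @return data.frame `drug_id`, `target_id`, `label = "negative"`.
#' @export
sample_negatives_stratified <- function(positives, targets, ratio = 1,
                                        seed = 1L, exclude = NULL) {
  drugs <- unique(positives$drug_id)
  out <- vector("list", length(drugs))
  for (i in seq_along(drugs)) {
    p <- positives[positives$drug_id == drugs[i], , drop = FALSE]
    out[[i]] <- sample_negatives(p, drugs[i], targets, ratio,
                                 seed = derive_seed(seed, i),
                                 exclude = exclude)
  }
  do.call(rbind, out)
}

#' Leakage-free cross-validation folds over a labeled interaction table
#'
#' Assigns every record with partition `"cv"` to one of `n_folds` folds,
#' stratified by label so each fold holds a balanced share of positives and
#' negatives (sizes within +-1 per class); records with partition `"test"`
#' form the held-out test set. Every (drug, target) pair occurs exactly once
#' across folds and test.
#'
#' @param dti data.frame with `drug_id`, `target_id`, `label` (positive /
#'   negative) and `partition` (cv / test; other partitions are ignored).
#' @param config an [eval_config()].
#' @return List with `folds` (list of integer row-index vectors into `dti`)
#'   and `test` (integer vector). An error is raised if any pair occurs
#'   twice or a fold would have no positive.
#' @export
make_partitions <- function(dti, config = eval_config()) {
  keys <- pair_key(dti$drug_id, dti$target_id)
  if (anyDuplicated(keys))
    stop("interaction table assigns some (drug, target) pair more than once",
         call. = FALSE)
  cv_idx <- which(dti$partition == "cv")
  test_idx <- which(dti$partition == "test")
  n_pos <- sum(dti$label[cv_idx] == "positive")
  if (n_pos < config$n_folds)
    stop("not enough cv positives (", n_pos, ") to populate ",
         config$n_folds, " folds", call. = FALSE)
  set.seed(derive_seed(config$seed, 23L))
  fold_of <- integer(length(keys))
  for (lab in unique(dti$label[cv_idx])) {
    rows <- cv_idx[dti$label[cv_idx] == lab]
    fold_of[sample(rows)] <- rep_len(seq_len(config$n_folds), length(rows))
  }
  folds <- lapply(seq_len(config$n_folds), function(f) which(fold_of == f))
  list(folds = folds, test = test_idx)
}

#' Area under the ROC curve (rank-statistic form)
#'
#' Computed as the probability that a random positive outscores a random
#' negative, ties counted one half -- the Mann-Whitney form of the AUROC,
#' exact for any monotone score.
#'
#' @param scores_pos,scores_neg scores of positive / negative pairs.
#' @return AUROC between 0 and 1.
#' @export
auroc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0L || nn == 0L) stop("both classes must be nonempty", call. = FALSE)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation: pairs are ranked by decreasing score (ties
#' broken by stable input order) and the area is the sum over ranks of
#' `(recall_i - recall_{i-1}) * precision_i`.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUPR between 0 and 1.
#' @export
aupr <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (sum(labels) == 0) stop("no positives", call. = FALSE)
  ord <- order(-scores)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  sum(diff(c(0, recall)) * precision)
}

#' Precision among the top k percent of ranked pairs
#'
#' The top `ceiling(k/100 * n)` pairs by descending score are taken, ties
#' broken by stable input order; the value is the fraction of positives
#' among them. An attribute `tie_at_cut` flags cuts that split a tie group.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param k_percent percentage in (0, 100].
#' @return Precision between 0 and 1.
#' @export
precision_at_k <- function(scores, labels, k_percent) {
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  if (k_percent <= 0 || k_percent > 100)
    stop("k_percent must be in (0, 100]", call. = FALSE)
  m <- ceiling(k_percent / 100 * length(scores))
  ord <- order(-scores)  # stable
  top <- ord[seq_len(m)]
  out <- mean(as.numeric(labels)[top])
  tie <- m < length(scores) && scores[ord[m]] == scores[ord[m + 1]]
  attr(out, "tie_at_cut") <- tie
  out
}

#' Per-compound class-ratio robustness of a scoring model
#'
#' For each novel compound, its positive targets are scored against
#' `n_resamples` independent draws of `ratio * n_positives` unlabeled
#' targets, at every ratio in the grid; the per-draw AUROCs are summarized
#' by their median. Compounds for which a ratio is infeasible (not enough
#' unlabeled targets) are skipped for that ratio with a warning.
#'
#' @param model a trained `dti_model` (scored via [score_pairs()]).
#' @param positives data.frame `drug_id`, `target_id` of each compound's
#'   known targets.
#' @param drug_features,target_features feature matrices with entity row
#'   names; the rownames of `target_features` define the candidate target
#'   universe.
#' @param config an [eval_config()] (fields `ratio_grid`, `n_resamples`,
#'   `seed`).
#' @return data.frame `drug_id`, `ratio`, `median_auroc`, `n_positives`.
#' @export
ratio_robustness <- function(model, positives, drug_features, target_features,
                             config = eval_config()) {
  universe <- rownames(target_features)
  compounds <- unique(positives$drug_id)
  set.seed(derive_seed(config$seed, 31L))
  out <- list()
  for (cmp in compounds) {
    pos_t <- unique(positives$target_id[positives$drug_id == cmp])
    pos_t <- intersect(pos_t, universe)
    if (length(pos_t) == 0L) next
    cand <- setdiff(universe, pos_t)
    # score every candidate pair once; resamples just index into this
    all_t <- c(pos_t, cand)
    sc <- score_pairs(model,
                      drug_features[rep(cmp, length(all_t)), , drop = FALSE],
                      target_features[all_t, , drop = FALSE])
    sc_pos <- sc[seq_along(pos_t)]
    sc_cand <- sc[-seq_along(pos_t)]
    for (ratio in config$ratio_grid) {
      n_neg <- ratio * length(pos_t)
      if (n_neg > length(cand)) {
        warning("compound ", cmp, ": ratio ", ratio,
                " infeasible (needs ", n_neg, " of ", length(cand),
                " unlabeled targets); skipped", call. = FALSE)
        next
      }
      aucs <- vapply(seq_len(config$n_resamples), function(r) {
        auroc(sc_pos, sc_cand[sample(length(cand), n_neg)])
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        drug_id = cmp, ratio = ratio, median_auroc = median(aucs),
        n_positives = length(pos_t), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Correlation between the distance structures of two feature spaces
#'
#' Computes pairwise Euclidean distance matrices over the common genes of
#' two feature sets and returns the Spearman rank correlation of their upper
#' triangles -- a scale- and rotation-invariant measure of how similarly two
#' feature families arrange the target space.
#'
#' @param emb_a,emb_b numeric matrices with gene row names.
#' @return Spearman correlation between -1 and 1.
#' @export
feature_distance_correlation <- function(emb_a, emb_b) {
  common <- intersect(rownames(emb_a), rownames(emb_b))
  if (length(common) < 3L)
    stop("need at least 3 common genes", call. = FALSE)
  da <- as.vector(dist(emb_a[common, , drop = FALSE]))
  db <- as.vector(dist(emb_b[common, , drop = FALSE]))
  cor(da, db, method = "spearman")
}
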