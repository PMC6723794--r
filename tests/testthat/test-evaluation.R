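test_that("auroc equals the pairwise-comparison statistic", {
  expect_equal(auroc(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  expect_equal(auroc(rep(0.5, 4), rep(0.5, 6)), 0.5)
  expect_equal(auroc(c(0.9, 0.8), c(0.2, 0.1)), 1.0)
  expect_error(auroc(numeric(0), 1), "nonempty")
  for (seed in 1:10) {
    set.seed(seed)
    np <- sample(1:15, 1); nn <- sample(1:15, 1)
    # coarse grid forces ties
    pos <- sample(seq(0, 1, 0.25), np, replace = TRUE)
    neg <- sample(seq(0, 1, 0.25), nn, replace = TRUE)
    expect_equal(auroc(pos, neg), bf_auroc(pos, neg))
  }
  # cross-check against an established ROC implementation
  set.seed(99)
  pos <- rnorm(40, 1); neg <- rnorm(60)
  expect_equal(auroc(pos, neg),
               as.numeric(pROC::auc(pROC::roc(
                 response = rep(c(1, 0), c(40, 60)),
                 predictor = c(pos, neg), quiet = TRUE, direction = "<"))))
})

test_that("aupr follows the step-wise interpolation", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # ranking 1,0,1,0: precision at the two positives is 1 and 2/3
  expect_equal(aupr(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_error(aupr(c(0.5), c(0)), "no positives")
})

test_that("precision at top k counts positives above the ceiling cut", {
  scores <- seq(1, 0.1, length.out = 10)
  labels <- c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(as.numeric(precision_at_k(scores, labels, 20)), 1.0)
  expect_equal(as.numeric(precision_at_k(scores, labels, 100)), 0.2)
  perfect <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(as.numeric(precision_at_k(scores, perfect, 30)), 1.0)
  expect_error(precision_at_k(numeric(0), numeric(0), 10), "empty")
  expect_error(precision_at_k(scores, labels, 0), "k_percent")
  tied <- precision_at_k(rep(0.7, 10), labels, 20)
  expect_true(attr(tied, "tie_at_cut"))
})

test_that("negative sampling draws from the unlabeled complement only", {
  pos <- data.frame(drug_id = c("d1", "d2"), target_id = c("t1", "t2"),
                    stringsAsFactors = FALSE)
  neg <- sample_negatives(pos, paste0("d", 1:3), paste0("t", 1:3), ratio = 1,
                          seed = 4)
  expect_equal(nrow(neg), 2)
  expect_true(all(neg$label == "negative"))

  # 3x3 universe, 2 positives, ratio 2: all 4 negatives lie in the 7-pair
  # complement, exhaustively enumerated
  complement <- setdiff(
    as.vector(outer(paste0("d", 1:3), paste0("t", 1:3), paste)),
    paste(pos$drug_id, pos$target_id))
  for (seed in 1:10) {
    n2 <- sample_negatives(pos, paste0("d", 1:3), paste0("t", 1:3), ratio = 2,
                           seed = seed)
    expect_equal(nrow(n2), 4)
    expect_true(all(paste(n2$drug_id, n2$target_id) %in% complement))
    expect_false(any(duplicated(paste(n2$drug_id, n2$target_id))))
  }
  expect_error(sample_negatives(pos, "d1", c("t1", "t2"), ratio = 5, seed = 1),
               "available")
})

test_that("stratified sampling matches each compound's positive count", {
  pos <- data.frame(drug_id = c("d1", "d1", "d1", "d2"),
                    target_id = c("t1", "t2", "t3", "t4"),
                    stringsAsFactors = FALSE)
  neg <- sample_negatives_stratified(pos, paste0("t", 1:20), ratio = 1,
                                     seed = 2)
  expect_equal(unname(table(neg$drug_id)["d1"]), 3L)
  expect_equal(unname(table(neg$drug_id)["d2"]), 1L)
  expect_length(intersect(paste(neg$drug_id, neg$target_id),
                          paste(pos$drug_id, pos$target_id)), 0)
})

test_that("partitioning is balanced, disjoint, exhaustive and seeded", {
  set.seed(10)
  dti <- data.frame(
    drug_id = rep(sprintf("d%03d", 1:50), each = 4),
    target_id = paste0("t", 1:200),
    label = rep(c("positive", "negative"), 100),
    partition = sample(c("cv", "test"), 200, replace = TRUE, prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE)
  cfg <- eval_config(n_folds = 5, seed = 3)
  parts <- make_partitions(dti, cfg)
  all_idx <- c(unlist(parts$folds), parts$test)
  expect_setequal(all_idx, which(dti$partition %in% c("cv", "test")))
  expect_false(any(duplicated(all_idx)))
  pos_counts <- vapply(parts$folds, function(f)
    sum(dti$label[f] == "positive"), integer(1))
  expect_lte(diff(range(pos_counts)), 1)
  expect_identical(parts, make_partitions(dti, cfg))

  hundred <- data.frame(drug_id = paste0("d", 1:100),
                        target_id = paste0("t", 1:100),
                        label = "positive", partition = "cv",
                        stringsAsFactors = FALSE)
  p10 <- make_partitions(hundred, eval_config(n_folds = 10, seed = 1))
  expect_true(all(lengths(p10$folds) == 10))

  dup <- rbind(dti, dti[1, ])
  expect_error(make_partitions(dup, cfg), "more than once")
})

test_that("ratio robustness is exact for a dominance scorer and tight for random scores", {
  set.seed(11)
  targets <- paste0("t", 1:250)
  Tf <- matrix(rnorm(250 * 4), 250, 4, dimnames = list(targets, NULL))
  Df <- matrix(rnorm(3 * 4), 3, 4, dimnames = list(c("c1", "c2", "c3"), NULL))
  # dominance premise requires the scorer to rank the compound's positives
  # above every unlabeled candidate, so use one compound
  pos <- data.frame(drug_id = "c1", target_id = c("t1", "t2"),
                    stringsAsFactors = FALSE)
  cfg <- eval_config(ratio_grid = c(1, 10, 50, 100), n_resamples = 25, seed = 5)

  dominant <- function(dx, tx) as.numeric(rownames(tx) %in% pos$target_id)
  rr <- ratio_robustness(dominant, pos, Df, Tf, cfg)
  expect_true(all(rr$median_auroc == 1))
  expect_setequal(unique(rr$ratio), c(1, 10, 50, 100))

  rnd <- function(dx, tx) runif(nrow(tx))
  rr2 <- ratio_robustness(rnd, pos, Df, Tf,
                          eval_config(ratio_grid = c(1, 10, 50),
                                      n_resamples = 100, seed = 6))
  med <- aggregate(median_auroc ~ ratio, rr2, median)
  expect_true(all(med$median_auroc > 0.3 & med$median_auroc < 0.7))

  # infeasible ratio: compound with 3 positives cannot draw 300 negatives
  pos3 <- data.frame(drug_id = "c3", target_id = c("t5", "t6", "t7"),
                     stringsAsFactors = FALSE)
  expect_warning(
    rr3 <- ratio_robustness(dominant, pos3, Df, Tf,
                            eval_config(ratio_grid = c(1, 100),
                                        n_resamples = 5, seed = 7)),
    "infeasible")
  expect_setequal(unique(rr3$ratio), 1)
})

test_that("distance-structure correlation is isometry-invariant and null-calibrated", {
  set.seed(12)
  A <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(paste0("g", 1:50), NULL))
  expect_equal(feature_distance_correlation(A, A), 1.0)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  expect_equal(feature_distance_correlation(A, A %*% Q), 1.0)
  B <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(paste0("g", 1:50), NULL))
  expect_lt(abs(feature_distance_correlation(A, B)), 0.2)
  expect_error(feature_distance_correlation(A[1:2, ], A[1:2, ]), "3 common")
})
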