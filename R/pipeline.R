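#' Configuration of a full benchmark run
#'
#' Bundles the per-stage configurations for the simulate -> featurize ->
#' embed -> train -> evaluate pipeline. A single global `seed` derives every
#' stage seed, so one config + seed fixes the whole run.
#'
#' @param world a [world_config()].
#' @param families target-feature families to compare: subset of
#'   `"GEP"` (knockdown expression), `"PPI"` (network embedding), `"PM"`
#'   (pathway-membership embedding).
#' @param models subset of `"dnn"`, `"nb"`, `"lr"`, `"rf"`.
#' @param eval an [eval_config()].
#' @param walk a [walk_config()] for the PPI embedding.
#' @param glove a [glove_config()] for the PM embedding.
#' @param dnn_template a [dnn_spec()] whose block widths/optimizer settings
#'   are reused per family; the target block is made pass-through for PPI/PM
#'   and mirrors the drug block for GEP.
#' @param baseline a [baseline_config()].
#' @param standardize column-standardize the drug and target feature
#'   matrices before model fitting (mirrors the z-score scale of the
#'   signature data the pipeline emulates).
#' @param ratio_robustness compute the novel-compound class-ratio-robustness
#'   summary for each family's network model.
#' @param seed global seed.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(world = world_config(),
                             families = c("GEP", "PPI", "PM"),
                             models = c("dnn", "nb", "lr", "rf"),
                             eval = eval_config(),
                             walk = walk_config(embed_dim = 32L),
                             glove = glove_config(embed_dim = 32L,
                                                  epochs = 300L, x_max = 10),
                             dnn_template = dnn_spec(drug_block_layers = 64L,
                                                     joint_layers = 128L,
                                                     activation = "tanh",
                                                     dropout_rate = 0.25,
                                                     max_epochs = 800L,
                                                     early_stop_patience = 100L,
                                                     batch_size = 32L),
                             baseline = baseline_config(rf_n_trees = 200L),
                             standardize = TRUE,
                             ratio_robustness = TRUE,
                             seed = 1L) {
  families <- match.arg(families, c("GEP", "PPI", "PM"), several.ok = TRUE)
  models <- match.arg(models, c("dnn", "nb", "lr", "rf"), several.ok = TRUE)
  stopifnot(inherits(world, "world_config"), inherits(eval, "eval_config"),
            inherits(walk, "walk_config"), inherits(glove, "glove_config"),
            inherits(dnn_template, "dnn_spec"),
            inherits(baseline, "baseline_config"))
  structure(list(world = world, families = families, models = models,
                 eval = eval, walk = walk, glove = glove,
                 dnn_template = dnn_template, baseline = baseline,
                 standardize = isTRUE(standardize),
                 ratio_robustness = isTRUE(ratio_robustness),
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

# Per-family network spec: GEP targets get the drug block mirrored;
# embedding targets are passed through.
family_dnn_spec <- function(template, family, seed) {
  tb <- if (family == "GEP") template$drug_block_layers else integer(0)
  dnn_spec(drug_block_layers = template$drug_block_layers,
           target_block_layers = tb,
           joint_layers = template$joint_layers,
           activation = template$activation,
           dropout_rate = template$dropout_rate,
           learning_rate = template$learning_rate,
           max_epochs = template$max_epochs,
           early_stop_patience = template$early_stop_patience,
           batch_size = template$batch_size, seed = seed)
}

fit_one_model <- function(kind, family, config, drug_X, target_X, rows, seed) {
  Xd <- drug_X[rows$drug_id, , drop = FALSE]
  Xt <- target_X[rows$target_id, , drop = FALSE]
  y <- as.numeric(rows$label == "positive")
  if (kind == "dnn") {
    spec <- family_dnn_spec(config$dnn_template, family, seed)
    model <- build_dnn(spec, ncol(Xd), ncol(Xt))
    train_dnn(model, Xd, Xt, y, config$eval$validation_fraction)
  } else {
    fit_baseline(kind, config$baseline, cbind(Xd, Xt), y, seed = seed)
  }
}

eval_rows <- function(model, drug_X, target_X, rows, k_grid = NULL) {
  sc <- score_pairs(model, drug_X[rows$drug_id, , drop = FALSE],
                    target_X[rows$target_id, , drop = FALSE])
  y <- as.numeric(rows$label == "positive")
  out <- c(auroc = auroc(sc[y == 1], sc[y == 0]), aupr = aupr(sc, y))
  if (!is.null(k_grid)) {
    pk <- vapply(k_grid, function(k) as.numeric(precision_at_k(sc, y, k)),
                 numeric(1))
    names(pk) <- sprintf("precision_at_%g", k_grid)
    out <- c(out, pk)
  }
  out
}

#' Run the full target-feature benchmark
#'
#' Orchestrates the pipeline: generate the synthetic world; build drug and
#' knockdown-consensus expression features; embed the gene network (biased
#' random walks + skip-gram) and the pathway collection (co-occurrence
#' least-squares fit); restrict the comparison to the target genes common to
#' all selected feature families; sample unlabeled negatives and build
#' leakage-free cross-validation/test partitions; train and evaluate every
#' selected model on every family; and (optionally) summarize per-compound
#' AUROC across negative:positive ratios on the held-out novel compounds.
#' Identical config + seed reproduces the report exactly.
#'
#' @param config a [benchmark_config()].
#' @param outdir optional directory; when given, all intermediate artifacts
#'   (world files, features, embeddings, labeled pairs, report) are written
#'   there.
#' @param quiet suppress stage progress messages.
#' @return An object of class `dti_eval_report`: list with `metrics`
#'   (data.frame family/model/split/metric/value; fold-level rows retained),
#'   `ratio` (per-compound median-AUROC data.frame or NULL), `common_targets`,
#'   `config` and `seed`.
#' @export
run_benchmark <- function(config = benchmark_config(), outdir = NULL,
                          quiet = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  seed <- config$seed

  wc <- config$world
  wc$seed <- derive_seed(seed, 1L)
  world <- stage("simulate", generate_world(wc))

  drug_X <- stage("featurize-drugs", drug_feature_matrix(world))
  feats <- list()
  if ("GEP" %in% config$families)
    feats$GEP <- stage("featurize-gep", gep_feature_matrix(world))
  if ("PPI" %in% config$families) {
    walk <- config$walk
    walk$seed <- derive_seed(seed, 2L)
    emb <- stage("embed-network", node2vec_embedding(world$network, walk))
    feats$PPI <- emb[rowSums(abs(emb)) > 0, , drop = FALSE]
  }
  if ("PM" %in% config$families) {
    glove <- config$glove
    glove$seed <- derive_seed(seed, 3L)
    feats$PM <- stage("embed-pathways", {
      X <- suppressMessages(build_cooccurrence(world$pathways,
                                               universe = world$gene_ids))
      fit_glove(X, glove)
    })
  }
  feats <- feats[intersect(c("GEP", "PPI", "PM"), config$families)]

  common <- sort(Reduce(intersect, lapply(feats, rownames)))
  say("[common-space] %d of %d genes common to {%s}", length(common),
      length(world$gene_ids), paste(config$families, collapse = ", "))
  feats <- lapply(feats, function(m) m[common, , drop = FALSE])
  if (config$standardize) {
    std <- function(m) {
      s <- apply(m, 2, sd)
      scale(m, center = colMeans(m), scale = ifelse(s > 0, s, 1))
    }
    drug_X <- std(drug_X)
    feats <- lapply(feats, std)
  }

  dti <- world$dti[world$dti$target_id %in% common, , drop = FALSE]
  cv_pos <- dti[dti$partition == "cv", c("drug_id", "target_id")]
  test_pos <- dti[dti$partition == "test", c("drug_id", "target_id")]
  novel_pos <- dti[dti$partition == "novel", c("drug_id", "target_id")]
  train_drugs <- sort(setdiff(world$drug_ids, world$novel_drugs))

  ev <- config$eval
  ev$seed <- derive_seed(seed, 4L)
  all_pos <- dti[, c("drug_id", "target_id")]
  sampler <- if (ev$stratify_negatives) {
    function(pos, seed, exclude) sample_negatives_stratified(
      pos, common, ev$negative_ratio, seed = seed, exclude = exclude)
  } else {
    function(pos, seed, exclude) sample_negatives(
      pos, train_drugs, common, ev$negative_ratio, seed = seed,
      exclude = exclude)
  }
  cv_neg <- sampler(cv_pos, derive_seed(seed, 5L), all_pos)
  test_neg <- sampler(test_pos, derive_seed(seed, 6L),
                      rbind(all_pos, cv_neg[, 1:2]))
  labeled <- rbind(
    data.frame(cv_pos, label = "positive", partition = "cv"),
    data.frame(cv_neg[, 1:2], label = "negative", partition = "cv"),
    data.frame(test_pos, label = "positive", partition = "test"),
    data.frame(test_neg[, 1:2], label = "negative", partition = "test"))
  parts <- make_partitions(labeled, ev)

  metrics <- list()
  add <- function(family, model, split, vals) {
    metrics[[length(metrics) + 1L]] <<- data.frame(
      family = family, model = model, split = split,
      metric = names(vals), value = unname(vals), stringsAsFactors = FALSE)
  }
  ratio_tabs <- list()
  cv_rows <- labeled[labeled$partition == "cv", ]
  m_i <- 0L
  for (family in names(feats)) {
    Tf <- feats[[family]]
    for (kind in config$models) {
      m_i <- m_i + 1L
      mseed <- derive_seed(seed, 100L + m_i)
      stage(sprintf("train-eval %s/%s", family, kind), {
        if (ev$do_cv) for (f in seq_along(parts$folds)) {
          tr <- labeled[setdiff(unlist(parts$folds[-f]), parts$folds[[f]]), ]
          md <- fit_one_model(kind, family, config, drug_X, Tf, tr,
                              derive_seed(mseed, f))
          add(family, kind, sprintf("fold%02d", f),
              eval_rows(md, drug_X, Tf, labeled[parts$folds[[f]], ]))
        }
        final <- fit_one_model(kind, family, config, drug_X, Tf, cv_rows,
                               mseed)
        add(family, kind, "test",
            eval_rows(final, drug_X, Tf, labeled[parts$test, ],
                      k_grid = ev$k_percent_grid))
        if (config$ratio_robustness && kind == "dnn" && nrow(novel_pos) > 0) {
          rr <- ratio_robustness(final, novel_pos, drug_X, Tf, ev)
          if (!is.null(rr)) ratio_tabs[[family]] <- data.frame(family = family, rr)
        }
        NULL
      })
    }
  }

  report <- structure(
    list(metrics = do.call(rbind, metrics),
         ratio = if (length(ratio_tabs)) do.call(rbind, unname(ratio_tabs)) else NULL,
         common_targets = common,
         n_labeled = nrow(labeled),
         config = config, seed = seed),
    class = "dti_eval_report")
  if (!is.null(outdir)) write_report_artifacts(report, world, drug_X, feats,
                                               labeled, outdir)
  report
}

#' @export
print.dti_eval_report <- function(x, ...) {
  cat("<dti_eval_report>\n")
  cat(sprintf("  %d common target genes, %d labeled pairs, seed %d\n",
              length(x$common_targets), x$n_labeled, x$seed))
  test <- x$metrics[x$metrics$split == "test" &
                    x$metrics$metric %in% c("auroc", "aupr"), ]
  if (nrow(test)) {
    wide <- reshape(test, idvar = c("family", "model"), timevar = "metric",
                    direction = "wide", drop = "split")
    names(wide) <- sub("^value\\.", "", names(wide))
    cat("  held-out test performance:\n")
    for (i in seq_len(nrow(wide)))
      cat(sprintf("    %-4s %-4s AUROC %.3f  AUPR %.3f\n", wide$family[i],
                  wide$model[i], wide$auroc[i], wide$aupr[i]))
  }
  if (!is.null(x$ratio)) {
    agg <- aggregate(median_auroc ~ family + ratio, x$ratio, median)
    cat("  novel-compound median AUROC by negative:positive ratio:\n")
    for (fam in unique(agg$family))
      cat(sprintf("    %-4s %s\n", fam,
                  paste(sprintf("%d:1 %.3f", agg$ratio[agg$family == fam],
                                agg$median_auroc[agg$family == fam]),
                        collapse = "  ")))
  }
  invisible(x)
}

#' Deterministic JSON summary of a benchmark report
#'
#' @param report a [run_benchmark()] result.
#' @param path optional file to write to.
#' @return The JSON string, invisibly if written.
#' @export
report_summary_json <- function(report, path = NULL) {
  test <- report$metrics[report$metrics$split == "test", ]
  test <- test[order(test$family, test$model, test$metric), ]
  summary <- list(
    seed = report$seed,
    config_hash = config_hash(report$config$world),
    n_common_targets = length(report$common_targets),
    n_labeled_pairs = report$n_labeled,
    test_metrics = test[, c("family", "model", "metric", "value")])
  if (!is.null(report$ratio)) {
    agg <- aggregate(median_auroc ~ family + ratio, report$ratio, median)
    summary$novel_median_auroc <- agg[order(agg$family, agg$ratio), ]
  }
  js <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (!is.null(path)) {
    writeLines(as.character(js), path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

write_report_artifacts <- function(report, world, drug_X, feats, labeled,
                                   outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok) stop("cannot create '", outdir, "'", call. = FALSE)
  write_world(world, file.path(outdir, "world"))
  write_features(drug_X, "drug_DEP", file.path(outdir, "features_drug.tsv"))
  for (fam in names(feats))
    write_features(feats[[fam]], paste0("target_", fam),
                   file.path(outdir, sprintf("features_%s.tsv", fam)))
  write.table(labeled, file.path(outdir, "labeled_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$metrics, file.path(outdir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$ratio))
    write.table(report$ratio, file.path(outdir, "ratio_robustness.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  report_summary_json(report, file.path(outdir, "summary.json"))
  invisible(outdir)
}
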