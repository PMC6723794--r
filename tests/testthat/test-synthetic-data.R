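test_that("zero-noise single-target drugs reproduce the expression map exactly", {
  cfg <- world_config(n_genes = 30, n_drugs = 8, n_landmark = 12,
                      latent_dim = 3, n_modules = 4,
                      targets_per_drug = c(1, 1), noise_sd_drug = 0,
                      noise_sd_knockdown = 0, offtarget_rate = 0,
                      n_kd_experiments = 1, seed = 42)
  w <- generate_world(cfg)
  for (p in Filter(function(p) p$kind == "drug", w$profiles)) {
    tgt <- w$drug_targets[[p$perturbagen_id]]
    expect_length(tgt, 1)
    diff <- aggregate_replicates(p$treated) - aggregate_replicates(p$control)
    expected <- as.vector(w$expression_map %*% w$gene_latents[tgt, ])
    expect_equal(unname(diff), expected, tolerance = 1e-12)
  }
})

test_that("same seed and config give identical worlds", {
  cfg <- tiny_world_config(seed = 7)
  expect_identical(generate_world(cfg), generate_world(cfg))
})

test_that("planted positives are exactly the enumerated drug-target pairs", {
  cfg <- world_config(n_genes = 50, n_drugs = 20, n_landmark = 16,
                      latent_dim = 4, n_modules = 5,
                      targets_per_drug = c(2, 2), seed = 3)
  w <- generate_world(cfg)
  expect_equal(nrow(w$dti), 40)
  planted <- sort(unlist(lapply(names(w$drug_targets), function(d)
    paste(d, w$drug_targets[[d]]))))
  recorded <- sort(paste(w$dti$drug_id, w$dti$target_id))
  expect_identical(recorded, planted)
  expect_false(any(duplicated(recorded)))
})

test_that("invalid configurations are rejected", {
  expect_error(world_config(latent_dim = 100, n_landmark = 64), "latent_dim")
  expect_error(world_config(n_genes = 0), "positive count")
  expect_error(world_config(noise_sd_drug = -1), ">= 0")
  expect_error(world_config(targets_per_drug = c(3, 2)), "targets_per_drug")
})

test_that("the gene network is simple, thresholded and homophilous", {
  for (seed in 1:5) {
    w <- generate_world(tiny_world_config(seed = seed))
    e <- w$network$edges
    expect_false(any(e$gene_a == e$gene_b))
    expect_false(any(duplicated(paste(pmin(e$gene_a, e$gene_b),
                                      pmax(e$gene_a, e$gene_b)))))
    expect_true(all(e$weight >= w$network$confidence_threshold))
    d <- as.matrix(dist(w$gene_latents))
    connected <- mean(d[cbind(e$gene_a, e$gene_b)])
    expect_lt(connected, mean(d[upper.tri(d)]))
  }
})

test_that("pathways are nonempty, in-universe and latently coherent", {
  w <- generate_world(tiny_world_config(seed = 11))
  expect_true(all(lengths(w$pathways) > 0))
  expect_true(all(unlist(w$pathways) %in% w$gene_ids))
  d <- as.matrix(dist(w$gene_latents))
  within <- mean(vapply(w$pathways, function(p) {
    if (length(p) < 2) return(NA_real_)
    mean(d[p, p][upper.tri(diag(length(p)))])
  }, numeric(1)), na.rm = TRUE)
  expect_lt(within, mean(d[upper.tri(d)]))
})

test_that("partitions split pairs without overlap", {
  w <- generate_world(tiny_world_config(seed = 5))
  expect_setequal(unique(w$dti$partition), c("cv", "test", "novel"))
  expect_true(all(w$dti$drug_id[w$dti$partition == "novel"] %in% w$novel_drugs))
  expect_false(any(w$dti$drug_id[w$dti$partition != "novel"] %in% w$novel_drugs))
})

test_that("downstream recovery degrades monotonically with the noise knob", {
  # mean held-out AUROC of a fast interaction-capable learner (random
  # forest on pathway-membership features) at low vs high replicate noise
  auroc_at <- function(noise, seed) {
    cfg <- benchmark_config(
      world = tiny_world_config(noise_sd_drug = noise),
      families = "PM", models = "rf",
      eval = eval_config(do_cv = FALSE),
      glove = glove_config(embed_dim = 8L, epochs = 50L, x_max = 10),
      ratio_robustness = FALSE, seed = seed)
    r <- suppressWarnings(run_benchmark(cfg, quiet = TRUE))
    r$metrics$value[r$metrics$split == "test" & r$metrics$metric == "auroc"]
  }
  lo <- vapply(1:10, function(s) auroc_at(0.1, s), numeric(1))
  hi <- vapply(1:10, function(s) auroc_at(2.0, s), numeric(1))
  expect_gte(mean(lo), mean(hi))
})

test_that("a written world round-trips through the plain-text formats", {
  dir <- withr::local_tempdir()
  w <- generate_world(tiny_world_config(seed = 2))
  manifest <- write_world(w, dir)
  expect_setequal(unlist(manifest$files),
                  c("expression.tsv", "samples.tsv", "network.tsv",
                    "pathways.gmt", "dti.tsv"))
  r <- read_world(dir)
  expect_equal(length(r$profiles), length(w$profiles))
  orig <- w$profiles[[3]]
  back <- Filter(function(p) p$perturbagen_id == orig$perturbagen_id,
                 r$profiles)[[1]]
  expect_equal(unname(back$treated), unname(orig$treated), tolerance = 1e-8)
  expect_equal(unname(back$control), unname(orig$control), tolerance = 1e-8)
  expect_equal(back$kind, orig$kind)
  expect_equal(r$network$edges, w$network$edges)
  expect_identical(lapply(r$pathways, sort), lapply(w$pathways, sort))
  expect_equal(r$dti, w$dti)
})

test_that("GMT lines follow the name/description/genes layout", {
  dir <- withr::local_tempdir()
  sets <- list(S1 = c("g1", "g2", "g3"), S2 = c("g9", "g4"))
  write_gmt(sets, file.path(dir, "x.gmt"))
  lines <- readLines(file.path(dir, "x.gmt"))
  expect_length(lines, 2)
  fields <- strsplit(lines, "\t")
  expect_equal(fields[[1]][1], "S1")
  expect_equal(fields[[1]][-(1:2)], c("g1", "g2", "g3"))
  expect_equal(fields[[2]][-(1:2)], c("g9", "g4"))
  expect_identical(lapply(read_gmt(file.path(dir, "x.gmt")), unname), sets)
})

test_that("manifest config hash is sensitive to every config field change", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- tiny_world_config(seed = 9)
  m1 <- write_world(generate_world(cfg), dir1)
  cfg2 <- tiny_world_config(seed = 9, noise_sd_drug = 0.11)
  m2 <- write_world(generate_world(cfg2), dir2)
  expect_false(m1$config_hash == m2$config_hash)
  dir3 <- withr::local_tempdir()
  m3 <- write_world(generate_world(cfg), dir3)
  expect_identical(m1$config_hash, m3$config_hash)
})
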