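test_that("transition distribution matches the hand-derived path and triangle cases", {
  cfg <- walk_config(p = 1, q = 2)
  tw <- transition_weights(path_abc(), "a", "b", cfg)
  expect_equal(tw[["a"]], 2 / 3)
  expect_equal(tw[["c"]], 1 / 3)

  # triangle a-b-c plus edge a-c: c is adjacent to prev a, so alpha(c) = 1
  tri <- make_network(data.frame(gene_a = c("a", "b", "a"),
                                 gene_b = c("b", "c", "c"),
                                 weight = 1, stringsAsFactors = FALSE))
  tw2 <- transition_weights(tri, "a", "b", cfg)
  expect_equal(unname(tw2[c("a", "c")]), c(0.5, 0.5))

  # p = q = 1 on an unweighted graph reduces to a first-order walk
  g <- random_graph(6, seed = 1, weighted = FALSE)
  cfg1 <- walk_config(p = 1, q = 1)
  for (e in seq_len(nrow(g$edges))) {
    prev <- g$edges$gene_a[e]; curr <- g$edges$gene_b[e]
    tw3 <- transition_weights(g, prev, curr, cfg1)
    expect_equal(unname(tw3), rep(1 / length(tw3), length(tw3)))
  }
})

test_that("transition distribution equals exhaustive alpha-enumeration on small graphs", {
  for (seed in 1:6) {
    n <- sample(3:8, 1)
    g <- random_graph(n, seed = seed)
    cfg <- walk_config(p = runif(1, 0.3, 3), q = runif(1, 0.3, 3))
    for (e in seq_len(nrow(g$edges))) {
      for (dir in 1:2) {
        prev <- if (dir == 1) g$edges$gene_a[e] else g$edges$gene_b[e]
        curr <- if (dir == 1) g$edges$gene_b[e] else g$edges$gene_a[e]
        got <- transition_weights(g, prev, curr, cfg)
        want <- bf_transition(g$edges, prev, curr, cfg$p, cfg$q)
        expect_equal(sum(got), 1)
        expect_true(all(got >= 0))
        expect_lt(sum(abs(got[names(want)] - want)), 1e-12)
      }
    }
  }
})

test_that("a huge in-out parameter suppresses outward steps as 1/q", {
  # path a-b-c-d from (b, c): d is not adjacent to b, so
  # weight(d)/weight(b) should equal 1/q
  g <- make_network(data.frame(gene_a = c("a", "b", "c"),
                               gene_b = c("b", "c", "d"),
                               weight = 1, stringsAsFactors = FALSE))
  q <- 1e6
  tw <- transition_weights(g, "b", "c", walk_config(p = 1, q = q))
  expect_equal(tw[["d"]] / tw[["b"]], 1 / q, tolerance = 1e-9)
})

test_that("sampled walks follow the analytic transition distribution", {
  # from (prev = a, curr = b) on a fixed graph, empirical next-step
  # frequencies converge to transition_weights
  g <- make_network(data.frame(
    gene_a = c("a", "b", "b", "b", "c"),
    gene_b = c("b", "c", "d", "e", "e"),
    weight = c(1, 0.9, 0.75, 0.85, 1), stringsAsFactors = FALSE))
  cfg <- walk_config(p = 1, q = 2, walk_length = 3, walks_per_node = 20000,
                     seed = 99)
  walks <- generate_walks(g, cfg)
  from_a <- Filter(function(w) length(w) == 3 && w[1] == "a", walks)
  thirds <- vapply(from_a, function(w) w[3], character(1))
  emp <- table(thirds) / length(thirds)
  want <- transition_weights(g, "a", "b", cfg)
  expect_gt(length(thirds), 1e4)
  expect_lt(sum(abs(emp[names(want)] - want)), 0.02)
})

test_that("walk generation is seeded and handles forced and dead-end cases", {
  g <- random_graph(7, seed = 3)
  cfg <- walk_config(walk_length = 10, walks_per_node = 4, seed = 123)
  expect_identical(generate_walks(g, cfg), generate_walks(g, cfg))

  two <- make_network(data.frame(gene_a = "a", gene_b = "b", weight = 1,
                                 stringsAsFactors = FALSE))
  w2 <- generate_walks(two, walk_config(walk_length = 6, walks_per_node = 1,
                                        seed = 1))
  for (w in w2) expect_true(all(w == rep(c(w[1], setdiff(c("a", "b"), w[1])),
                                         3)))

  iso <- list(nodes = c("a", "b", "x"),
              edges = data.frame(gene_a = "a", gene_b = "b", weight = 1,
                                 stringsAsFactors = FALSE),
              confidence_threshold = 1)
  wi <- generate_walks(iso, walk_config(walk_length = 5, walks_per_node = 1,
                                        seed = 1))
  expect_true(any(vapply(wi, function(w) identical(w, "x"), logical(1))))
})

test_that("skip-gram embeddings separate disconnected cliques", {
  clique <- function(ids) {
    pr <- t(combn(ids, 2))
    data.frame(gene_a = pr[, 1], gene_b = pr[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }
  g <- make_network(rbind(clique(paste0("a", 1:5)), clique(paste0("b", 1:5))))
  cfg <- walk_config(embed_dim = 16, walk_length = 20, walks_per_node = 20,
                     epochs = 5, window = 4, seed = 8)
  emb <- node2vec_embedding(g, cfg)
  cs <- emb / sqrt(rowSums(emb^2))
  S <- cs %*% t(cs)
  a <- grep("^a", rownames(S)); b <- grep("^b", rownames(S))
  within <- mean(c(S[a, a][upper.tri(diag(5))], S[b, b][upper.tri(diag(5))]))
  between <- mean(S[a, b])
  expect_gt(within, between)
})

test_that("zero training epochs return the seeded random initialization", {
  g <- random_graph(6, seed = 2)
  cfg <- walk_config(embed_dim = 8, walks_per_node = 2, walk_length = 5,
                     epochs = 0, seed = 31)
  walks <- generate_walks(g, cfg)
  e1 <- train_skipgram(walks, g$nodes, cfg)
  e2 <- train_skipgram(walks, g$nodes, cfg)
  expect_identical(e1, e2)
  expect_true(any(e1 != 0))
})

test_that("training reduces the sampled skip-gram objective", {
  g <- random_graph(10, seed = 5, p_edge = 0.4)
  cfg0 <- walk_config(embed_dim = 12, walks_per_node = 10, walk_length = 20,
                      epochs = 0, window = 3, seed = 17)
  cfg5 <- walk_config(embed_dim = 12, walks_per_node = 10, walk_length = 20,
                      epochs = 5, window = 3, seed = 17)
  walks <- generate_walks(g, cfg0)
  idx <- seq_along(g$nodes); names(idx) <- g$nodes
  pairs <- do.call(rbind, lapply(walks, function(w) {
    if (length(w) < 2) return(NULL)
    cbind(idx[w[-length(w)]], idx[w[-1]])
  }))
  obj <- function(emb) dtibench:::skipgram_objective(
    emb, attr(emb, "context"), pairs[, 1], pairs[, 2], length(g$nodes),
    seed = 4)
  e0 <- train_skipgram(walks, g$nodes, cfg0)
  e5 <- train_skipgram(walks, g$nodes, cfg5)
  expect_lt(obj(e5), obj(e0))
})

test_that("nodes absent from the walk corpus get zero vectors with a warning", {
  g <- random_graph(5, seed = 6)
  cfg <- walk_config(embed_dim = 4, walks_per_node = 1, walk_length = 4,
                     epochs = 1, seed = 2)
  walks <- generate_walks(g, cfg)
  expect_warning(emb <- train_skipgram(walks, c(g$nodes, "ghost"), cfg),
                 "absent")
  expect_equal(unname(emb["ghost", ]), rep(0, 4))
})

test_that("embeddings round-trip through TSV", {
  dir <- withr::local_tempdir()
  m <- matrix(rnorm(12), 3, dimnames = list(c("g1", "g2", "g3"), NULL))
  write_embedding(m, file.path(dir, "e.tsv"))
  back <- read_embedding(file.path(dir, "e.tsv"))
  expect_equal(unname(back), unname(m), tolerance = 1e-8)
  expect_identical(rownames(back), rownames(m))
})
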