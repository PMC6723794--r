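# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. These deliberately avoid the package's own
# implementation paths.

# unnormalized alpha-weight enumeration for the biased second-order walk
bf_transition <- function(edges, prev, curr, p, q, use_weights = TRUE) {
  nbr_of <- function(v) {
    c(edges$gene_b[edges$gene_a == v], edges$gene_a[edges$gene_b == v])
  }
  wt_of <- function(a, b) {
    i <- which((edges$gene_a == a & edges$gene_b == b) |
               (edges$gene_a == b & edges$gene_b == a))
    if (use_weights) edges$weight[i] else 1
  }
  nbrs <- sort(nbr_of(curr))
  w <- vapply(nbrs, function(x) {
    alpha <- if (is.null(prev)) 1
             else if (x == prev) 1 / p
             else if (x %in% nbr_of(prev)) 1
             else 1 / q
    wt_of(curr, x) * alpha
  }, numeric(1))
  w / sum(w)
}

# pairwise-comparison AUROC, ties counted one half
bf_auroc <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# double-loop pathway co-occurrence counts
bf_cooccurrence <- function(pathways) {
  genes <- sort(unique(unlist(pathways)))
  X <- matrix(0L, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i == j) next
    X[i, j] <- sum(vapply(pathways, function(p)
      genes[i] %in% p && genes[j] %in% p, logical(1)))
  }
  X
}

make_network <- function(edge_df) {
  list(nodes = sort(unique(c(edge_df$gene_a, edge_df$gene_b))),
       edges = edge_df, confidence_threshold = min(edge_df$weight))
}

path_abc <- function() {
  make_network(data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                          weight = c(1, 1), stringsAsFactors = FALSE))
}

# random connected-ish graph on n nodes for exhaustive oracle checks
random_graph <- function(n, seed, p_edge = 0.5, weighted = TRUE) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  ids <- sprintf("n%02d", seq_len(n))
  make_network(data.frame(
    gene_a = ids[pairs[keep, 1]], gene_b = ids[pairs[keep, 2]],
    weight = if (weighted) round(runif(sum(keep), 0.7, 1), 3) else rep(1, sum(keep)),
    stringsAsFactors = FALSE))
}

# small profile builder
toy_profile <- function(id = "d1", kind = "drug", G = 4, n_rep = 2,
                        treated = NULL, control = NULL, target = NA) {
  if (is.null(treated)) treated <- matrix(rnorm(G * n_rep), G, n_rep)
  if (is.null(control)) control <- matrix(rnorm(G * n_rep), G, n_rep)
  perturbation_profile(id, kind, treated, control, target_gene = target)
}

tiny_world_config <- function(...) {
  world_config(n_genes = 60L, n_drugs = 24L, n_landmark = 16L,
               latent_dim = 4L, n_modules = 6L, n_kd_experiments = 1L,
               n_pathways = 40L, pathway_size = c(4L, 10L), ...)
}
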