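#' Configuration for network embedding by biased random walks
#'
#' Hyperparameters of the second-order random-walk + skip-gram embedding.
#' The walk bias follows the standard return/in-out parameterization: from a
#' step (prev -> curr), the unnormalized probability of moving to neighbour x
#' is `edge_weight(curr, x) * alpha`, with `alpha = 1/p` if `x == prev`, `1`
#' if x is adjacent to prev, and `1/q` otherwise. The defaults fix `p = 1`
#' and `q = 2` (mildly outward-exploring walks) and use the walk/skip-gram
#' conventions of the original method for the remaining values.
#'
#' @param p return parameter (> 0).
#' @param q in-out parameter (> 0).
#' @param walk_length steps per walk (>= 2).
#' @param walks_per_node walks started from every node.
#' @param window skip-gram context window.
#' @param embed_dim embedding dimension d (default 256, the feature length
#'   used for PPI/PM target features).
#' @param negative_samples negative samples per (center, context) pair.
#' @param epochs passes over the walk corpus.
#' @param learning_rate initial SGD learning rate (linearly decayed).
#' @param use_weights multiply transition probabilities by edge confidence
#'   weights (set `FALSE` to treat the graph as unweighted).
#' @param seed RNG seed for walks and initialization.
#' @return An object of class `walk_config`.
#' @export
walk_config <- function(p = 1, q = 2, walk_length = 80L, walks_per_node = 10L,
                        window = 10L, embed_dim = 256L, negative_samples = 5L,
                        epochs = 5L, learning_rate = 0.025,
                        use_weights = TRUE, seed = 1L) {
  if (p <= 0 || q <= 0) stop("p and q must be positive", call. = FALSE)
  if (walk_length < 2L) stop("walk_length must be >= 2", call. = FALSE)
  if (embed_dim < 1L) stop("embed_dim must be >= 1", call. = FALSE)
  structure(list(p = p, q = q, walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 window = as.integer(window), embed_dim = as.integer(embed_dim),
                 negative_samples = as.integer(negative_samples),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 use_weights = isTRUE(use_weights), seed = as.integer(seed)),
            class = "walk_config")
}

# Compressed adjacency for a network: sorted 0-based neighbour lists with
# parallel weights.
network_csr <- function(network, use_weights = TRUE) {
  nodes <- network$nodes
  idx <- seq_along(nodes)
  names(idx) <- nodes
  e <- network$edges
  a <- idx[e$gene_a]; b <- idx[e$gene_b]
  if (anyNA(a) || anyNA(b))
    stop("network edges reference unknown nodes", call. = FALSE)
  if (any(a == b)) stop("network contains self-loops", call. = FALSE)
  w <- if (use_weights) e$weight else rep(1, nrow(e))
  src <- c(a, b); dst <- c(b, a); ww <- c(w, w)
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]; ww <- ww[o]
  deg <- tabulate(src, nbins = length(nodes))
  list(off = c(0L, cumsum(deg)), nbr = as.integer(dst - 1L), wts = ww,
       nodes = nodes)
}

#' Second-order transition distribution of the biased walk
#'
#' Returns the exact next-step distribution from `curr` given the previous
#' node `prev` (or `NULL` at the first step of a walk, where plain edge
#' weights are used). This is the contract the walk sampler implements.
#'
#' @param network a network list with `nodes` and an `edges` data.frame
#'   (`gene_a`, `gene_b`, `weight`), as in [generate_world()].
#' @param prev previous node id or `NULL`.
#' @param curr current node id.
#' @param config a [walk_config()].
#' @return Named numeric vector of probabilities over the neighbours of
#'   `curr`, summing to 1.
#' @export
transition_weights <- function(network, prev, curr, config = walk_config()) {
  e <- network$edges
  w <- if (config$use_weights) e$weight else rep(1, nrow(e))
  sel_a <- e$gene_a == curr
  sel_b <- e$gene_b == curr
  nbrs <- c(e$gene_b[sel_a], e$gene_a[sel_b])
  wts <- c(w[sel_a], w[sel_b])
  if (length(nbrs) == 0L)
    stop("node '", curr, "' has no neighbours", call. = FALSE)
  if (!is.null(prev)) {
    if (!prev %in% nbrs)
      stop("'prev' must be a neighbour of 'curr'", call. = FALSE)
    prev_nbrs <- c(e$gene_b[e$gene_a == prev], e$gene_a[e$gene_b == prev])
    alpha <- ifelse(nbrs == prev, 1 / config$p,
                    ifelse(nbrs %in% prev_nbrs, 1, 1 / config$q))
    wts <- wts * alpha
  }
  p <- wts / sum(wts)
  names(p) <- nbrs
  p[order(names(p))]
}

#' Generate the biased random-walk corpus for a network
#'
#' Starts `walks_per_node` walks of length `walk_length` from every node,
#' each step sampled from [transition_weights()]. Walks terminate early at
#' dead ends; isolated nodes yield length-1 walks. Reproducible under
#' `config$seed`.
#'
#' @inheritParams transition_weights
#' @return List of character vectors of node ids.
#' @export
generate_walks <- function(network, config = walk_config()) {
  if (length(network$nodes) == 0L) stop("empty network", call. = FALSE)
  csr <- network_csr(network, config$use_weights)
  set.seed(config$seed)
  walks <- cpp_generate_walks(csr$off, csr$nbr, csr$wts,
                              length(csr$nodes), config$walks_per_node,
                              config$walk_length, config$p, config$q)
  lapply(walks, function(w) csr$nodes[w])
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Skip-gram with negative sampling (negatives drawn from the unigram^0.75
#' distribution, linearly decayed learning rate) over (center, context)
#' pairs within `config$window`. Node order in `nodes` fixes the row order
#' of the result. Nodes absent from the corpus receive zero vectors with a
#' warning. With `epochs = 0` the seeded random initialization is returned.
#'
#' @param walks list of character vectors of node ids (see
#'   [generate_walks()]).
#' @param nodes character vector of all node ids (rows of the result).
#' @param config a [walk_config()].
#' @return An embedding matrix, nodes x `embed_dim`, with the skip-gram
#'   output vectors in attribute `"context"`.
#' @export
train_skipgram <- function(walks, nodes, config = walk_config()) {
  if (length(walks) == 0L) stop("empty walk corpus", call. = FALSE)
  if (config$embed_dim < 1L) stop("embed_dim must be >= 1", call. = FALSE)
  idx <- seq_along(nodes)
  names(idx) <- nodes
  walks_i <- lapply(walks, function(w) as.integer(idx[w]))
  set.seed(derive_seed(config$seed, 7L))
  fit <- cpp_train_skipgram(walks_i, length(nodes), config$embed_dim,
                            config$window, config$negative_samples,
                            config$epochs, config$learning_rate)
  emb <- fit[["in"]]
  ctx <- fit[["out"]]
  seen <- unique(unlist(walks_i, use.names = FALSE))
  missing <- setdiff(idx, seen)
  if (length(missing) > 0L) {
    warning(length(missing), " node(s) absent from walks; zero vectors assigned",
            call. = FALSE)
    emb[missing, ] <- 0
    ctx[missing, ] <- 0
  }
  rownames(emb) <- nodes
  rownames(ctx) <- nodes
  attr(emb, "context") <- ctx
  emb
}

#' Network embedding: walks + skip-gram in one call
#'
#' @inheritParams transition_weights
#' @return Embedding matrix, network nodes x `embed_dim`.
#' @export
node2vec_embedding <- function(network, config = walk_config()) {
  walks <- generate_walks(network, config)
  train_skipgram(walks, network$nodes, config)
}

# Monte-Carlo estimate of the skip-gram objective (negative log-likelihood
# with sampled negatives) on a fixed set of (center, context) index pairs.
skipgram_objective <- function(emb, ctx, centers, contexts, n_nodes,
                               negative = 5L, seed = 1L) {
  set.seed(seed)
  s <- function(x) 1 / (1 + exp(-pmin(pmax(x, -20), 20)))
  pos <- rowSums(emb[centers, , drop = FALSE] * ctx[contexts, , drop = FALSE])
  ll <- sum(log(s(pos)))
  for (k in seq_len(negative)) {
    neg <- sample.int(n_nodes, length(centers), replace = TRUE)
    nd <- rowSums(emb[centers, , drop = FALSE] * ctx[neg, , drop = FALSE])
    ll <- ll + sum(log(s(-nd)))
  }
  -ll / length(centers)
}

#' Write / read an embedding matrix as TSV
#'
#' Columns: `gene_id`, `v1..vd`.
#'
#' @param embedding genes x d numeric matrix with gene row names.
#' @param path TSV path.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(gene_id = rownames(embedding), embedding,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", paste0("v", seq_len(ncol(embedding))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}
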