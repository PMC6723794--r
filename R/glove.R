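#' Pathway co-occurrence counts
#'
#' Counts, for every unordered gene pair, the number of pathways containing
#' both genes: `X[i, j] = |{P : i in P and j in P}|`. Genes belonging to no
#' pathway are excluded (with a message reporting how many). The diagonal is
#' zero by convention.
#'
#' @param pathways named list of gene-id character vectors (a gene-set
#'   collection as in [generate_world()] or [read_gmt()]).
#' @param universe optional gene universe; genes outside it are ignored,
#'   and the count of dropped universe genes is reported.
#' @return A symmetric integer matrix with gene-id dimnames, class
#'   `cooccurrence_matrix`.
#' @export
build_cooccurrence <- function(pathways, universe = NULL) {
  if (length(pathways) == 0L) stop("empty pathway collection", call. = FALSE)
  pathways <- lapply(pathways, unique)
  genes <- sort(unique(unlist(pathways, use.names = FALSE)))
  if (!is.null(universe)) {
    genes <- intersect(genes, universe)
    dropped <- setdiff(universe, genes)
    if (length(dropped) > 0L)
      message(length(dropped), " universe gene(s) in no pathway; excluded")
  }
  n <- length(genes)
  idx <- seq_len(n)
  names(idx) <- genes
  X <- matrix(0L, n, n, dimnames = list(genes, genes))
  for (p in pathways) {
    m <- idx[intersect(p, genes)]
    if (length(m) >= 2L) X[m, m] <- X[m, m] + 1L
  }
  diag(X) <- 0L
  class(X) <- c("cooccurrence_matrix", class(X))
  X
}

#' Configuration for the co-occurrence embedding fit
#'
#' The objective is the standard weighted least squares over nonzero counts:
#' `sum_f(X_ij) (w_i . w~_j + b_i + b~_j - log X_ij)^2` with
#' `f(x) = min((x/x_max)^alpha, 1)`, minimized by per-parameter adaptive
#' (AdaGrad) steps; the returned embedding of gene i is `w_i + w~_i`.
#'
#' @param embed_dim embedding dimension d (default 256, the PM feature
#'   length).
#' @param x_max weighting cap.
#' @param alpha weighting exponent in (0, 1].
#' @param epochs training epochs.
#' @param learning_rate AdaGrad base learning rate.
#' @param seed RNG seed (initialization and pair order).
#' @return An object of class `glove_config`.
#' @export
glove_config <- function(embed_dim = 256L, x_max = 100, alpha = 0.75,
                         epochs = 30L, learning_rate = 0.05, seed = 1L) {
  if (embed_dim < 1L) stop("embed_dim must be >= 1", call. = FALSE)
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (x_max <= 0) stop("x_max must be positive", call. = FALSE)
  structure(list(embed_dim = as.integer(embed_dim), x_max = x_max,
                 alpha = alpha, epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "glove_config")
}

#' Fit co-occurrence embeddings
#'
#' @param X a [build_cooccurrence()] matrix (or any symmetric nonnegative
#'   count matrix with gene dimnames).
#' @param config a [glove_config()].
#' @return Embedding matrix, genes x d (`w + w~`), with the per-epoch mean
#'   weighted squared error in attribute `"loss"` and the raw parameter sets
#'   in attribute `"fit"`. With `epochs = 0` the seeded random initialization
#'   is returned.
#' @export
fit_glove <- function(X, config = glove_config()) {
  genes <- rownames(X)
  ut <- which(upper.tri(X) & X > 0, arr.ind = TRUE)
  if (nrow(ut) == 0L) stop("co-occurrence matrix has no positive entries",
                           call. = FALSE)
  set.seed(config$seed)
  fit <- cpp_fit_glove(as.integer(ut[, 1] - 1L), as.integer(ut[, 2] - 1L),
                       as.numeric(X[ut]), nrow(X), config$embed_dim,
                       config$x_max, config$alpha, config$epochs,
                       config$learning_rate)
  emb <- fit$w + fit$w_context
  rownames(emb) <- genes
  attr(emb, "loss") <- as.numeric(fit$loss)
  attr(emb, "fit") <- fit
  emb
}

#' Write a co-occurrence matrix as a 3-column TSV
#'
#' Columns `gene_a`, `gene_b`, `count`; only nonzero upper-triangle entries.
#'
#' @param X a [build_cooccurrence()] matrix.
#' @param path TSV path.
#' @export
write_cooccurrence <- function(X, path) {
  ut <- which(upper.tri(X) & X > 0, arr.ind = TRUE)
  df <- data.frame(gene_a = rownames(X)[ut[, 1]],
                   gene_b = colnames(X)[ut[, 2]],
                   count = X[ut], stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
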