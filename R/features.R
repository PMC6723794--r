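#' Aggregate expression replicates
#'
#' Collapses replicate landmark vectors into a single vector by the
#' element-wise median, the convention used for multiple untreated controls
#' and for consensus knockdown signatures.
#'
#' @param replicates a landmark x replicate numeric matrix, or a list of
#'   equal-length numeric vectors.
#' @param method aggregation method; only `"median"` is defined.
#' @return A numeric landmark vector.
#' @export
aggregate_replicates <- function(replicates, method = "median") {
  method <- match.arg(method, "median")
  if (is.list(replicates)) {
    if (length(replicates) == 0L)
      stop("no replicates to aggregate", call. = FALSE)
    len <- lengths(replicates)
    if (length(unique(len)) != 1L)
      stop("replicates have unequal lengths", call. = FALSE)
    replicates <- do.call(cbind, replicates)
  }
  replicates <- as.matrix(replicates)
  if (ncol(replicates) == 0L)
    stop("no replicates to aggregate", call. = FALSE)
  if (ncol(replicates) == 1L) return(replicates[, 1])
  apply(replicates, 1L, median)
}

#' Build the concatenated treated+control feature vector for one perturbagen
#'
#' Drug features (family `drug_DEP`) and knockdown expression features
#' (family `target_GEP`) are both the replicate-aggregated treated landmark
#' vector concatenated with the replicate-aggregated control vector, giving a
#' length-2G vector (1956 when G = 978 landmark genes).
#'
#' @param profile a [perturbation_profile()].
#' @return A `feature_vector` object: numeric vector of length 2G with
#'   attributes `entity_id` and `family`.
#' @export
build_feature <- function(profile) {
  stopifnot(inherits(profile, "perturbation_profile"))
  values <- c(aggregate_replicates(profile$treated),
              aggregate_replicates(profile$control))
  family <- if (profile$kind == "drug") "drug_DEP" else "target_GEP"
  entity <- if (profile$kind == "drug") profile$perturbagen_id else profile$target_gene
  feature_vector(entity, values, family)
}

feature_vector <- function(entity_id, values, family) {
  if (!all(is.finite(values)))
    stop("feature values must be finite", call. = FALSE)
  structure(as.numeric(values), entity_id = entity_id, family = family,
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s (%s), length %d\n",
              attr(x, "entity_id"), attr(x, "family"), length(x)))
  invisible(x)
}

#' Consensus knockdown signature for one target gene
#'
#' Aggregates several independent knockdown experiments of the same gene into
#' one consensus `target_GEP` feature: per-experiment features are built with
#' [build_feature()] and combined by the element-wise median, damping
#' experiment-specific off-target signal.
#'
#' @param profiles list of knockdown [perturbation_profile()]s sharing one
#'   target gene.
#' @return A `feature_vector` of family `target_GEP`.
#' @export
consensus_signature <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles given", call. = FALSE)
  genes <- unique(vapply(profiles, function(p) p$target_gene, character(1)))
  if (length(genes) != 1L)
    stop("consensus requires profiles of a single target gene; got: ",
         paste(genes, collapse = ", "), call. = FALSE)
  feats <- lapply(profiles, build_feature)
  values <- aggregate_replicates(lapply(feats, as.numeric))
  feature_vector(genes, values, "target_GEP")
}

#' Feature matrices for all drugs or all knockdown targets in a world
#'
#' `drug_feature_matrix()` returns one `drug_DEP` row per drug;
#' `gep_feature_matrix()` returns one consensus `target_GEP` row per gene
#' with at least one knockdown profile.
#'
#' @param world a [generate_world()] result (or any list of profiles in
#'   `world$profiles`).
#' @return A numeric matrix, entities x 2G.
#' @export
drug_feature_matrix <- function(world) {
  drugs <- Filter(function(p) p$kind == "drug", world$profiles)
  feats <- lapply(drugs, build_feature)
  m <- do.call(rbind, lapply(feats, as.numeric))
  rownames(m) <- vapply(feats, function(f) attr(f, "entity_id"), character(1))
  m
}

#' @rdname drug_feature_matrix
#' @export
gep_feature_matrix <- function(world) {
  kds <- Filter(function(p) p$kind == "knockdown", world$profiles)
  by_gene <- split(kds, vapply(kds, function(p) p$target_gene, character(1)))
  m <- do.call(rbind, lapply(by_gene, function(ps) as.numeric(consensus_signature(ps))))
  rownames(m) <- names(by_gene)
  m
}

#' Write / read a feature table as TSV
#'
#' Rows are entities; columns are `entity_id`, `family`, then `v1..vK`.
#'
#' @param features entities x K numeric matrix with entity row names.
#' @param family feature family label stored with every row.
#' @param path TSV path.
#' @export
write_features <- function(features, family, path) {
  df <- data.frame(entity_id = rownames(features), family = family,
                   features, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("entity_id", "family", paste0("v", seq_len(ncol(features))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$entity_id
  attr(m, "family") <- df$family[1]
  m
}
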