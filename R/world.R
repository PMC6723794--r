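#' Configuration for the synthetic drug-target world
#'
#' Defines the latent-space generative model from which all downstream inputs
#' are drawn: every gene carries a latent functional coordinate, drugs act by
#' perturbing the latent coordinates of their (planted) targets, the
#' PPI-like network connects genes with nearby latents, and pathways are
#' neighbourhoods in latent space. Expression is observed on `n_landmark`
#' measured channels ("landmark genes") through a fixed linear map from
#' latent space.
#'
#' @param n_genes number of genes in the universe.
#' @param n_drugs number of drugs.
#' @param n_landmark number of measured landmark channels G. Desk-scale
#'   default is 64; set 978 to mirror the L1000 landmark panel.
#' @param latent_dim dimension of the latent functional space (must be
#'   <= `n_landmark`).
#' @param n_modules number of functional modules: gene latents are drawn
#'   from a Gaussian mixture with this many centers (standard-normal
#'   centers, within-module spread `module_sd`), emulating the modular
#'   functional organisation that pathway collections and PPI communities
#'   reflect. `0` gives unstructured (iid Gaussian) latents.
#' @param module_sd within-module latent spread.
#' @param targets_per_drug integer vector of length 2, `c(min, max)`: each
#'   drug receives a uniform number of true targets in this range (the
#'   default range brackets the ~9 interactions per compound seen in curated
#'   DTI collections). With modular latents a drug's targets are sampled
#'   within one functional module, reflecting polypharmacology concentrated
#'   in target families; the count is capped at the module size.
#' @param n_kd_experiments independent knockdown experiments per gene (each
#'   with its own replicates); >1 exercises consensus-signature aggregation.
#' @param n_replicates treated and control replicates per experiment.
#' @param noise_sd_drug replicate noise s.d. for drug profiles
#'   (log-expression-like units).
#' @param noise_sd_knockdown replicate noise s.d. for knockdown profiles;
#'   defaults to 1.5x the drug noise.
#' @param offtarget_rate probability that a knockdown experiment additionally
#'   perturbs one random off-target gene.
#' @param mean_degree target mean degree of the gene network; the edge
#'   probability is a logistic function of negative squared latent distance
#'   calibrated to this value.
#' @param noise_edge_rate uniform background edge probability added on top of
#'   the distance-driven edges.
#' @param confidence_threshold minimum edge confidence weight (STRING-like).
#' @param n_pathways number of gene sets.
#' @param pathway_size integer vector `c(min, max)`: set sizes are uniform in
#'   this range; each set is the m nearest genes around a sampled latent
#'   center.
#' @param novel_drug_fraction fraction of drugs held out entirely (all their
#'   pairs in the `novel` partition, for the novel-compound benchmark).
#' @param test_fraction fraction of the remaining (drug, target) pairs
#'   assigned to the held-out `test` partition; the rest are `cv`.
#' @param cell_context identifier of the (single) simulated cell context.
#' @param seed integer seed fixing the whole world.
#'
#' @return An object of class `world_config` (a validated list).
#' @seealso [generate_world()]
#' @export
world_config <- function(n_genes = 200L, n_drugs = 100L, n_landmark = 64L,
                         latent_dim = 8L,
                         n_modules = 16L,
                         module_sd = 0.4,
                         targets_per_drug = c(4L, 8L),
                         n_kd_experiments = 2L,
                         n_replicates = 3L,
                         noise_sd_drug = 0.1,
                         noise_sd_knockdown = 1.5 * noise_sd_drug,
                         offtarget_rate = 0.2,
                         mean_degree = 10,
                         noise_edge_rate = 0.005,
                         confidence_threshold = 0.7,
                         n_pathways = 150L,
                         pathway_size = c(5L, 20L),
                         novel_drug_fraction = 0.1,
                         test_fraction = 0.2,
                         cell_context = "CL1",
                         seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
    n_landmark = as.integer(n_landmark), latent_dim = as.integer(latent_dim),
    n_modules = as.integer(n_modules), module_sd = module_sd,
    targets_per_drug = as.integer(targets_per_drug),
    n_kd_experiments = as.integer(n_kd_experiments),
    n_replicates = as.integer(n_replicates),
    noise_sd_drug = noise_sd_drug,
    noise_sd_knockdown = noise_sd_knockdown,
    offtarget_rate = offtarget_rate,
    mean_degree = mean_degree,
    noise_edge_rate = noise_edge_rate,
    confidence_threshold = confidence_threshold,
    n_pathways = as.integer(n_pathways),
    pathway_size = as.integer(pathway_size),
    novel_drug_fraction = novel_drug_fraction,
    test_fraction = test_fraction,
    cell_context = cell_context,
    seed = as.integer(seed)
  )
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  counts <- c("n_genes", "n_drugs", "n_landmark", "latent_dim",
              "n_kd_experiments", "n_replicates", "n_pathways")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("world_config: '", f, "' must be a positive count", call. = FALSE)
  }
  if (cfg$latent_dim > cfg$n_landmark)
    stop("world_config: latent_dim must not exceed n_landmark", call. = FALSE)
  if (cfg$n_modules < 0L)
    stop("world_config: n_modules must be >= 0", call. = FALSE)
  for (f in c("noise_sd_drug", "noise_sd_knockdown", "offtarget_rate",
              "noise_edge_rate", "module_sd")) {
    if (cfg[[f]] < 0) stop("world_config: '", f, "' must be >= 0", call. = FALSE)
  }
  if (length(cfg$targets_per_drug) != 2L ||
      any(cfg$targets_per_drug < 1L) ||
      diff(cfg$targets_per_drug) < 0L)
    stop("world_config: targets_per_drug must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  if (cfg$targets_per_drug[2] > cfg$n_genes)
    stop("world_config: more targets per drug than genes", call. = FALSE)
  if (length(cfg$pathway_size) != 2L || any(cfg$pathway_size < 1L) ||
      diff(cfg$pathway_size) < 0L || cfg$pathway_size[2] > cfg$n_genes)
    stop("world_config: invalid pathway_size range", call. = FALSE)
  invisible(cfg)
}

#' Construct a perturbation profile
#'
#' A perturbation profile holds the paired treated/control landmark expression
#' replicates for one perturbagen (a drug treatment or a single-gene
#' knockdown) in one cell context.
#'
#' @param perturbagen_id identifier of the drug or knockdown experiment.
#' @param kind `"drug"` or `"knockdown"`.
#' @param treated,control numeric matrices, landmark genes x replicates.
#' @param target_gene for knockdowns, the intended target gene id.
#' @param cell_context cell-context identifier.
#' @return An object of class `perturbation_profile`.
#' @export
perturbation_profile <- function(perturbagen_id, kind = c("drug", "knockdown"),
                                 treated, control, target_gene = NA_character_,
                                 cell_context = "CL1") {
  kind <- match.arg(kind)
  treated <- as.matrix(treated)
  control <- as.matrix(control)
  if (nrow(treated) != nrow(control))
    stop("treated and control replicates must have identical landmark length",
         call. = FALSE)
  if (ncol(treated) < 1L || ncol(control) < 1L)
    stop("need at least one treated and one control replicate", call. = FALSE)
  if (!all(is.finite(treated)) || !all(is.finite(control)))
    stop("replicate values must be finite", call. = FALSE)
  structure(
    list(perturbagen_id = perturbagen_id, kind = kind,
         cell_context = cell_context, target_gene = target_gene,
         treated = treated, control = control),
    class = "perturbation_profile"
  )
}

#' @export
print.perturbation_profile <- function(x, ...) {
  cat(sprintf("<perturbation_profile> %s (%s), G = %d, %d treated / %d control replicates\n",
              x$perturbagen_id, x$kind, nrow(x$treated),
              ncol(x$treated), ncol(x$control)))
  invisible(x)
}

# Calibrate the intercept of the logistic edge model so the expected mean
# degree matches the configured value.
calibrate_edge_intercept <- function(d2, n_genes, mean_degree) {
  target_p <- min(1, mean_degree / (n_genes - 1))
  f <- function(a) mean(plogis(a - d2)) - target_p
  uniroot(f, interval = c(-50, 50), extendInt = "yes")$root
}

#' Generate a synthetic drug-target world
#'
#' Draws a self-consistent synthetic dataset from the latent-space model of
#' [world_config()]: perturbation profiles for drugs and gene knockdowns, a
#' confidence-weighted gene network, a pathway collection, and a table of
#' planted (positive) drug-target interactions with `cv` / `test` / `novel`
#' partitions.
#'
#' Generative model, with `M` the fixed landmark-by-latent expression map and
#' `z_g` the latent coordinate of gene `g`:
#' * drug replicates: `control = b + eps`, `treated = b + sum_{g in targets} M z_g + eps`;
#' * knockdown replicates: `treated = b - M z_g (+ optionally - M z_offtarget) + eps`;
#' * network: edge (i, j) with probability `plogis(a - ||z_i - z_j||^2)`
#'   (intercept `a` calibrated to the configured mean degree) plus a uniform
#'   background rate; weights lie in `[confidence_threshold, 1]` and increase
#'   with latent proximity;
#' * pathways: the m nearest genes around latent centers sampled near random
#'   genes.
#'
#' @param config a [world_config()].
#' @return An object of class `dti_world`: a list with elements `profiles`
#'   (list of [perturbation_profile()]), `network` (list with `nodes`, `edges`
#'   data.frame `gene_a`/`gene_b`/`weight`, `confidence_threshold`),
#'   `pathways` (named list of gene-id vectors), `dti` (data.frame `drug_id`,
#'   `target_id`, `label`, `partition`), plus `gene_ids`, `drug_ids`,
#'   `gene_latents`, `expression_map`, `drug_targets` and the `config`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  validate_world_config(config)
  set.seed(config$seed)
  G <- config$n_landmark
  ng <- config$n_genes
  nd <- config$n_drugs

  gene_ids <- sprintf("g%04d", seq_len(ng))
  drug_ids <- sprintf("d%04d", seq_len(nd))
  landmark_ids <- sprintf("lm%04d", seq_len(G))

  if (config$n_modules > 0L) {
    centers <- matrix(rnorm(config$n_modules * config$latent_dim),
                      config$n_modules, config$latent_dim)
    module_of <- sample.int(config$n_modules, ng, replace = TRUE)
    Z <- centers[module_of, , drop = FALSE] +
      matrix(rnorm(ng * config$latent_dim, sd = config$module_sd),
             ng, config$latent_dim)
    dimnames(Z) <- list(gene_ids, NULL)
  } else {
    module_of <- rep(NA_integer_, ng)
    Z <- matrix(rnorm(ng * config$latent_dim), ng, config$latent_dim,
                dimnames = list(gene_ids, NULL))
  }
  # unit-variance landmark response per unit latent effect
  M <- matrix(rnorm(G * config$latent_dim, sd = 1 / sqrt(config$latent_dim)),
              G, config$latent_dim, dimnames = list(landmark_ids, NULL))

  # planted targets (guard the scalar case of sample()); with modular
  # latents each drug's targets are drawn within one functional module
  # (drug polypharmacology concentrates in target families), capped at the
  # module size
  t_range <- seq(config$targets_per_drug[1], config$targets_per_drug[2])
  n_targets <- if (length(t_range) == 1L) rep(t_range, nd)
               else sample(t_range, nd, replace = TRUE)
  drug_targets <- lapply(n_targets, function(k) {
    if (config$n_modules > 0L) {
      members <- gene_ids[module_of == sample.int(config$n_modules, 1L)]
      while (length(members) == 0L)
        members <- gene_ids[module_of == sample.int(config$n_modules, 1L)]
      sample(members, min(k, length(members)))
    } else {
      sample(gene_ids, k)
    }
  })
  names(drug_targets) <- drug_ids

  nrep <- config$n_replicates
  # cell-context landmark baseline, shared by every profile (one cell line);
  # each experiment adds a small batch offset common to its treated and
  # control arms, plus independent replicate noise
  baseline <- rnorm(G)
  make_reps <- function(base, effect, sd) {
    base + effect + matrix(rnorm(G * nrep, sd = sd), G, nrep,
                           dimnames = list(landmark_ids, NULL))
  }

  profiles <- vector("list", nd + ng * config$n_kd_experiments)
  idx <- 0L
  for (i in seq_len(nd)) {
    base <- baseline + rnorm(G, sd = config$noise_sd_drug)
    effect <- M %*% colSums(rbind(Z[drug_targets[[i]], , drop = FALSE]))
    idx <- idx + 1L
    profiles[[idx]] <- perturbation_profile(
      perturbagen_id = drug_ids[i], kind = "drug",
      treated = make_reps(base, as.vector(effect), config$noise_sd_drug),
      control = make_reps(base, 0, config$noise_sd_drug),
      cell_context = config$cell_context
    )
  }
  for (g in seq_len(ng)) {
    for (e in seq_len(config$n_kd_experiments)) {
      base <- baseline + rnorm(G, sd = config$noise_sd_knockdown)
      effect <- -as.vector(M %*% Z[g, ])
      if (runif(1) < config$offtarget_rate) {
        off <- sample(setdiff(seq_len(ng), g), 1L)
        effect <- effect - as.vector(M %*% Z[off, ])
      }
      idx <- idx + 1L
      profiles[[idx]] <- perturbation_profile(
        perturbagen_id = sprintf("%s_kd%02d", gene_ids[g], e),
        kind = "knockdown", target_gene = gene_ids[g],
        treated = make_reps(base, effect, config$noise_sd_knockdown),
        control = make_reps(base, 0, config$noise_sd_knockdown),
        cell_context = config$cell_context
      )
    }
  }

  # gene network: logistic edge probability in squared latent distance
  d2 <- as.matrix(dist(Z))^2
  ut <- upper.tri(d2)
  a <- calibrate_edge_intercept(d2[ut], ng, config$mean_degree)
  p_edge <- pmin(1, plogis(a - d2[ut]) + config$noise_edge_rate)
  keep <- runif(length(p_edge)) < p_edge
  pairs <- which(ut, arr.ind = TRUE)[keep, , drop = FALSE]
  th <- config$confidence_threshold
  weights <- th + (1 - th) * plogis(a - d2[ut][keep])
  network <- list(
    nodes = gene_ids,
    edges = data.frame(gene_a = gene_ids[pairs[, 1]],
                       gene_b = gene_ids[pairs[, 2]],
                       weight = round(weights, 4)),
    confidence_threshold = th
  )

  # pathways: nearest genes around jittered latent centers
  sizes <- sample(seq(config$pathway_size[1], config$pathway_size[2]),
                  config$n_pathways, replace = TRUE)
  centers <- Z[sample(ng, config$n_pathways, replace = TRUE), , drop = FALSE] +
    matrix(rnorm(config$n_pathways * config$latent_dim, sd = 0.25),
           config$n_pathways, config$latent_dim)
  pathways <- lapply(seq_len(config$n_pathways), function(i) {
    dd <- colSums((t(Z) - centers[i, ])^2)
    gene_ids[order(dd)[seq_len(sizes[i])]]
  })
  names(pathways) <- sprintf("PW%04d", seq_len(config$n_pathways))

  # planted positives with partitions
  dti <- data.frame(
    drug_id = rep(drug_ids, lengths(drug_targets)),
    target_id = unlist(drug_targets, use.names = FALSE),
    label = "positive",
    stringsAsFactors = FALSE
  )
  n_novel <- round(config$novel_drug_fraction * nd)
  novel_drugs <- if (n_novel > 0) sample(drug_ids, n_novel) else character()
  partition <- rep("cv", nrow(dti))
  partition[dti$drug_id %in% novel_drugs] <- "novel"
  non_novel <- which(partition == "cv")
  n_test <- round(config$test_fraction * length(non_novel))
  partition[sample(non_novel, n_test)] <- "test"
  dti$partition <- partition

  structure(
    list(profiles = profiles, network = network, pathways = pathways,
         dti = dti, gene_ids = gene_ids, drug_ids = drug_ids,
         landmark_ids = landmark_ids, gene_latents = Z,
         gene_modules = module_of, expression_map = M,
         drug_targets = drug_targets, novel_drugs = novel_drugs,
         config = config),
    class = "dti_world"
  )
}

#' @export
print.dti_world <- function(x, ...) {
  cfg <- x$config
  cat("<dti_world>\n")
  cat(sprintf("  %d genes, %d drugs, G = %d landmarks, latent dim %d, seed %d\n",
              cfg$n_genes, cfg$n_drugs, cfg$n_landmark, cfg$latent_dim, cfg$seed))
  cat(sprintf("  %d perturbation profiles (%d drug, %d knockdown)\n",
              length(x$profiles),
              sum(vapply(x$profiles, function(p) p$kind == "drug", logical(1))),
              sum(vapply(x$profiles, function(p) p$kind == "knockdown", logical(1)))))
  cat(sprintf("  network: %d edges (mean degree %.1f, weights >= %.2f)\n",
              nrow(x$network$edges),
              2 * nrow(x$network$edges) / length(x$network$nodes),
              x$network$confidence_threshold))
  cat(sprintf("  pathways: %d sets, sizes %d-%d\n", length(x$pathways),
              min(lengths(x$pathways)), max(lengths(x$pathways))))
  tab <- table(x$dti$partition)
  cat(sprintf("  planted positives: %d (%s)\n", nrow(x$dti),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Canonical config hash: md5 of the canonical JSON serialization.
config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

#' Write a synthetic world to plain-text files
#'
#' Serializes a world as the standard interchange formats: a landmark x sample
#' expression TSV plus a sample-annotation TSV, a 3-column edge-list TSV, a
#' GMT pathway file, and a DTI table TSV, with a JSON manifest recording the
#' files, seed and a hash of the generating configuration.
#'
#' @param world a [generate_world()] result.
#' @param directory output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_world <- function(world, directory) {
  stopifnot(inherits(world, "dti_world"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) stop("cannot create directory '", directory, "'", call. = FALSE)

  expr_cols <- list(); ann <- list()
  for (p in world$profiles) {
    for (role in c("treated", "control")) {
      m <- p[[role]]
      for (r in seq_len(ncol(m))) {
        sid <- sprintf("%s.%s.r%d", p$perturbagen_id, role, r)
        expr_cols[[sid]] <- m[, r]
        ann[[sid]] <- data.frame(
          sample_id = sid, perturbagen_id = p$perturbagen_id, kind = p$kind,
          cell_context = p$cell_context, target_gene = p$target_gene,
          role = role, replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  expr <- do.call(cbind, expr_cols)
  rownames(expr) <- world$landmark_ids

  paths <- file.path(directory, c(expression = "expression.tsv",
                                  samples = "samples.tsv",
                                  network = "network.tsv",
                                  pathways = "pathways.gmt",
                                  dti = "dti.tsv",
                                  manifest = "manifest.json"))
  names(paths) <- c("expression", "samples", "network", "pathways", "dti",
                    "manifest")
  write_tsv_checked <- function(df, path, row.names = FALSE) {
    ok <- tryCatch({
      write.table(df, path, sep = "\t", quote = FALSE, row.names = row.names,
                  col.names = if (row.names) NA else TRUE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("failed writing '", path, "': ", conditionMessage(ok), call. = FALSE)
  }
  write_tsv_checked(as.data.frame(expr), paths["expression"], row.names = TRUE)
  write_tsv_checked(do.call(rbind, ann), paths["samples"])
  write_tsv_checked(world$network$edges, paths["network"])
  write_gmt(world$pathways, paths["pathways"])
  write_tsv_checked(world$dti, paths["dti"])

  manifest <- list(
    files = as.list(basename(paths[setdiff(names(paths), "manifest")])),
    seed = world$config$seed,
    config_hash = config_hash(world$config),
    n_genes = world$config$n_genes,
    n_drugs = world$config$n_drugs,
    n_landmark = world$config$n_landmark
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE)
  invisible(manifest)
}

#' Write a gene-set collection in GMT format
#'
#' One line per set: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed writing '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path a GMT file (`name<TAB>description<TAB>genes...`).
#' @return Named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such GMT file: '", path, "'", call. = FALSE)
  fgsea::gmtPathways(path)
}

#' Read a synthetic world back from a directory written by [write_world()]
#'
#' @param directory directory containing the world files and manifest.
#' @return A list with `profiles`, `network`, `pathways`, `dti` and
#'   `manifest` (the configuration-level latent fields are not serialized).
#' @export
read_world <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  expr <- as.matrix(read.delim(file.path(directory, "expression.tsv"),
                               row.names = 1, check.names = FALSE))
  ann <- read.delim(file.path(directory, "samples.tsv"),
                    stringsAsFactors = FALSE)
  profiles <- lapply(split(ann, ann$perturbagen_id)[unique(ann$perturbagen_id)],
    function(a) {
      tr <- expr[, a$sample_id[a$role == "treated"], drop = FALSE]
      ct <- expr[, a$sample_id[a$role == "control"], drop = FALSE]
      perturbation_profile(a$perturbagen_id[1], a$kind[1], tr, ct,
                           target_gene = a$target_gene[1],
                           cell_context = a$cell_context[1])
    })
  edges <- read.delim(file.path(directory, "network.tsv"),
                      stringsAsFactors = FALSE)
  network <- list(nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                  edges = edges, confidence_threshold = min(edges$weight))
  list(profiles = unname(profiles), network = network,
       pathways = read_gmt(file.path(directory, "pathways.gmt")),
       dti = read.delim(file.path(directory, "dti.tsv"),
                        stringsAsFactors = FALSE),
       manifest = manifest)
}
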