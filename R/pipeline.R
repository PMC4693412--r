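# End-to-end pipeline: preprocess -> pairwise IG scan -> percolation
# threshold -> network -> permutation significance -> per-gene dyadicity ->
# centrality report, with a JSON run manifest.

#' Pipeline configuration
#'
#' Collects the analysis constants (MAF cutoff 0.05, LD r^2 cutoff 0.8,
#' 500 kb gene windows, permutation count) plus input paths or a synthetic
#' [sim_config()], and the interpretation flags for the percolation
#' denominator and the dyadicity label universe. Round-trips through YAML
#' via [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param genotype_path,loci_path,phenotype_path,annotation_path input
#'   files; leave `NULL` when `sim` is given.
#' @param sim a [sim_config()] for synthetic mode.
#' @param maf_threshold,r2_threshold,window_pad filter constants.
#' @param permutations permutation replicates R.
#' @param seed root seed (fanned out per stage/replicate).
#' @param percolation_denominator `"all"` or `"present"`, see
#'   [percolation_threshold()].
#' @param label_universe `"network"`, `"snps"` or `"slots"`, see
#'   [dyadicity_report()].
#' @param log_base 2 (bits) or `exp(1)` (nats).
#' @param out_dir output directory (created on demand).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotype_path = NULL, loci_path = NULL,
                            phenotype_path = NULL, annotation_path = NULL,
                            sim = NULL, maf_threshold = 0.05,
                            r2_threshold = 0.8, window_pad = 5e5,
                            permutations = 1000, seed = 1,
                            percolation_denominator = c("all", "present"),
                            label_universe = c("network", "snps", "slots"),
                            log_base = 2, out_dir = "senet-run") {
  if (maf_threshold < 0 || maf_threshold > 0.5) stop("maf_threshold out of [0, 0.5]")
  if (r2_threshold < 0 || r2_threshold > 1) stop("r2_threshold out of [0, 1]")
  if (window_pad < 0) stop("window_pad must be >= 0")
  if (permutations < 1) stop("permutations must be >= 1")
  structure(
    list(genotype_path = genotype_path, loci_path = loci_path,
         phenotype_path = phenotype_path, annotation_path = annotation_path,
         sim = sim, maf_threshold = maf_threshold, r2_threshold = r2_threshold,
         window_pad = window_pad, permutations = as.integer(permutations),
         seed = as.integer(seed),
         percolation_denominator = match.arg(percolation_denominator),
         label_universe = match.arg(label_universe),
         log_base = log_base, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' Simulation settings are restored through [sim_config()] so validation
#' re-runs on load; penetrance tables are stored row-major.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    s <- y$sim
    sim <- sim_config(
      n_individuals = s$n_individuals, n_snps = s$n_snps,
      maf_range = unlist(s$maf_range), ld_block_size = s$ld_block_size,
      ld_rho = s$ld_rho,
      main_effect_snps = if (is.null(s$main_effect_snps)) NULL else
        as.data.frame(lapply(s$main_effect_snps, unlist)),
      epistatic_pairs = if (is.null(s$epistatic_pairs)) NULL else
        lapply(s$epistatic_pairs, function(p) {
          list(snp_a = p$snp_a, snp_b = p$snp_b,
               penetrance = matrix(unlist(p$penetrance), 3, 3, byrow = TRUE))
        }),
      covariate_model = unlist(s$covariate_model),
      missing_rate = s$missing_rate %||% 0.01,
      seed = s$seed %||% 1
    )
  }
  pipeline_config(
    genotype_path = y$genotype_path, loci_path = y$loci_path,
    phenotype_path = y$phenotype_path, annotation_path = y$annotation_path,
    sim = sim, maf_threshold = y$maf_threshold %||% 0.05,
    r2_threshold = y$r2_threshold %||% 0.8, window_pad = y$window_pad %||% 5e5,
    permutations = y$permutations %||% 1000, seed = y$seed %||% 1,
    percolation_denominator = y$percolation_denominator %||% "all",
    label_universe = y$label_universe %||% "network",
    log_base = y$log_base %||% 2, out_dir = y$out_dir %||% "senet-run"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  if (!is.null(y$sim)) {
    s <- unclass(y$sim)
    s$gene_windows <- NULL   # default windows are reconstructed on load
    s$main_effect_snps <- as.list(s$main_effect_snps)
    s$epistatic_pairs <- lapply(s$epistatic_pairs, function(p) {
      list(snp_a = p$snp_a, snp_b = p$snp_b,
           penetrance = as.list(as.data.frame(t(p$penetrance))))
    })
    s$covariate_model <- as.list(s$covariate_model)
    y$sim <- s
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full statistical epistasis network pipeline
#'
#' Executes preprocessing (BMI, dichotomization, covariate adjustment, MAF
#' filter, LD pruning, mode imputation, gene mapping), the pairwise IG
#' scan, percolation-threshold network construction, phenotype-shuffle
#' permutation significance (network sizes, per-SNP MI, per-retained-pair
#' IG), per-gene dyadicity/heterophilicity, and the centrality report on
#' the largest connected component. All artifacts plus a JSON manifest are
#' written to `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a result bundle: `genotypes`, `phenotypes`,
#'   `membership`, `scores`, `threshold`, `network`, `lcc`,
#'   `network_significance`, `score_pvalues`, `dyadicity`, `centrality`,
#'   `top_nodes`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(package_version = as.character(utils::packageVersion("senet")),
                   r_version = R.version.string, seed = config$seed,
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    manifest
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$sim)) {
    cohort <- .stage("simulate", simulate_cohort(config$sim))
    genotypes <- cohort$genotypes
    pheno <- cohort$phenotypes
    ann <- cohort$annotation
    .stage("simulate", {
      write_genotypes(genotypes, out("genotypes.tsv"), out("loci.tsv"))
      write_phenotypes(pheno, out("phenotypes.tsv"))
      write_annotation(ann, out("annotation.tsv"))
    })
    note("simulate", n_individuals = nrow(genotypes$values),
         n_snps = ncol(genotypes$values), sim_seed = config$sim$seed)
  } else {
    for (p in c(config$genotype_path, config$phenotype_path, config$annotation_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop(sprintf("[stage input] required input file missing: %s",
                     if (is.null(p)) "(unset path)" else p), call. = FALSE)
      }
    }
    genotypes <- .stage("input", read_genotypes(config$genotype_path, config$loci_path))
    pheno <- .stage("input", read_phenotypes(config$phenotype_path))
    ann <- .stage("input", read_annotation(config$annotation_path,
                                           window_pad = config$window_pad))
    note("input", n_individuals = nrow(genotypes$values),
         n_snps = ncol(genotypes$values))
  }

  # --- preprocess ---------------------------------------------------------
  pheno <- .stage("preprocess", adjust_and_classify(pheno))
  keep <- genotypes$individual_ids %in% pheno$individual_id
  genotypes <- subset_individuals(genotypes, keep)
  g1 <- .stage("preprocess", filter_maf(genotypes, config$maf_threshold))
  g2 <- .stage("preprocess", ld_prune(g1, config$r2_threshold))
  g3 <- .stage("preprocess", impute_mode(g2))
  membership <- .stage("preprocess", map_snps_to_genes(g3, ann))
  note("preprocess",
       n_individuals = nrow(g3$values),
       concordance = attr(pheno, "concordance"),
       snps_in = ncol(genotypes$values),
       snps_after_maf = ncol(g1$values),
       snps_after_ld = ncol(g2$values),
       snps_labeled = sum(rowSums(membership) > 0))
  status <- pheno$status[match(g3$individual_ids, pheno$individual_id)]

  # --- scan + network -----------------------------------------------------
  scores <- .stage("scan", pairwise_ig_scan(g3, status, log_base = config$log_base))
  write_scores(scores, out("snp_mi.tsv"), out("pair_ig.tsv"))
  threshold <- .stage("network", percolation_threshold(
    scores, denominator = config$percolation_denominator))
  utils::write.table(attr(threshold, "series"), out("threshold_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  net <- .stage("network", build_network(scores, as.numeric(threshold)))
  lcc <- largest_component(net)
  write_graph_file(net, out("network_edges.tsv"), "edgelist")
  write_graph_file(net, out("network.graphml"), "graphml", membership = membership)
  note("network", threshold = as.numeric(threshold),
       n_nodes = igraph::vcount(net$graph), n_edges = igraph::ecount(net$graph),
       lcc_size = igraph::vcount(lcc$graph))

  # --- permutation significance -------------------------------------------
  perm <- .stage("permutation", .pipeline_permutation(
    g3, status, scores, as.numeric(threshold), config$permutations, config$seed))
  utils::write.table(perm$pvalues$mi, out("snp_mi_pvalues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(perm$pvalues$pairs, out("pair_ig_pvalues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(perm$null_sizes, out("null_network_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("permutation", R = config$permutations,
       p_n_nodes = perm$network$n_nodes$p_value,
       p_lcc_size = perm$network$lcc_size$p_value)

  # --- dyadicity + centrality ----------------------------------------------
  dy <- .stage("dyadicity", dyadicity_report(
    net, membership, R = config$permutations,
    seed = fan_seed(config$seed, "pipeline", 1L),
    universe = config$label_universe))
  utils::write.table(as.data.frame(dy), out("dyadicity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cent <- .stage("centrality", centrality_table(lcc))
  utils::write.table(cent, out("centrality.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gene_labels <- apply(membership, 1, function(r) colnames(membership)[r],
                       simplify = FALSE)
  top <- top_k_report(cent, k = min(5, nrow(cent)), gene_labels = gene_labels)
  .write_top_report(top, out("key_nodes.txt"))
  note("report", n_genes = ncol(membership),
       key_nodes_in_all_three = top$in_all_three)

  manifest$config <- .manifest_config(config)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(
    genotypes = g3, phenotypes = pheno, membership = membership,
    scores = scores, threshold = as.numeric(threshold), network = net,
    lcc = lcc, network_significance = perm$network,
    score_pvalues = perm$pvalues, dyadicity = dy, centrality = cent,
    top_nodes = top, manifest = manifest
  ))
}

# One pass over the permutation replicates: exceedance counts for per-SNP
# MI and per-pair IG (pooled per statistic), plus node/LCC size nulls at
# the fixed real-data threshold.
.pipeline_permutation <- function(g, status, scores, threshold, R, seed) {
  m <- length(scores$snp_ids)
  npair <- nrow(scores$pairs)
  mi_count <- integer(m)
  ig_count <- integer(npair)
  nodes_null <- integer(R)
  lcc_null <- integer(R)
  for (r in seq_len(R)) {
    st <- permute_status(status, fan_seed(seed, "permutation", r))
    sc <- pairwise_ig_scan(g, st, log_base = scores$log_base)
    mi_count <- mi_count + (sc$mi >= scores$mi)
    ig_count <- ig_count + (sc$pairs$ig >= scores$pairs$ig)
    net_r <- build_network(sc, threshold)
    comp <- igraph::components(net_r$graph)
    nodes_null[r] <- igraph::vcount(net_r$graph)
    lcc_null[r] <- if (comp$no == 0) 0L else max(comp$csize)
  }
  obs_net <- build_network(scores, threshold)
  comp <- igraph::components(obs_net$graph)
  obs_lcc <- if (comp$no == 0) 0L else max(comp$csize)
  fmt <- function(counts) {
    res <- lapply(counts, format_pvalue, R = R)
    list(p = vapply(res, `[[`, numeric(1), "p"),
         display = vapply(res, `[[`, character(1), "display"))
  }
  pm <- fmt(mi_count)
  pg <- fmt(ig_count)
  list(
    pvalues = list(
      mi = data.frame(snp = scores$snp_ids, mi = unname(scores$mi),
                      p = pm$p, p_display = pm$display),
      pairs = data.frame(snp_a = scores$pairs$snp_a, snp_b = scores$pairs$snp_b,
                         ig = scores$pairs$ig, p = pg$p, p_display = pg$display)
    ),
    network = list(
      n_nodes = permutation_null("n_nodes", igraph::vcount(obs_net$graph),
                                 nodes_null, seed),
      lcc_size = permutation_null("lcc_size", obs_lcc, lcc_null, seed)
    ),
    null_sizes = data.frame(replicate = seq_len(R), n_nodes = nodes_null,
                            lcc_size = lcc_null)
  )
}

.write_top_report <- function(top, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (measure in c("degree", "betweenness", "closeness")) {
    writeLines(sprintf("# top nodes by %s", measure), con)
    tab <- top[[measure]]
    writeLines(sprintf("%s\t%s\t%g", tab$node, tab$gene,
                       tab[[if (measure == "degree") "degree" else measure]]), con)
    writeLines("", con)
  }
  writeLines(paste("# nodes in all three lists:",
                   if (length(top$in_all_three)) paste(top$in_all_three, collapse = ", ")
                   else "(none)"), con)
  invisible(path)
}

.manifest_config <- function(config) {
  y <- unclass(config)
  if (!is.null(y$sim)) {
    y$sim <- list(n_individuals = y$sim$n_individuals, n_snps = y$sim$n_snps,
                  seed = y$sim$seed,
                  n_main_effects = nrow(y$sim$main_effect_snps),
                  n_epistatic_pairs = length(y$sim$epistatic_pairs))
  }
  y
}
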