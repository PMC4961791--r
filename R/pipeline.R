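#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its standard default: the
#' 5/4/5 synteny rule (blocks of >= 5 contiguous orthologous genes,
#' extension across gaps of <= 4 genes, <= 5 inversions per block), the
#' reciprocal-best-hit e-value cutoff 1e-5, Fitch-Margoliash weighting
#' power 2, and the permutation / simulation sizes of the calibration
#' steps.
#'
#' @param seed master seed for every stochastic stage.
#' @param simulate list passed to [sim_config()] plus `n_taxa`,
#'   `crown_age` and `hit_noise`; set to `NULL` to ingest data instead
#'   (see `input_dir`).
#' @param input_dir directory of pre-existing inputs (`genome_<sp>.tsv`,
#'   `hits_<A>__<B>.tsv`, `tree.nwk`); used when `simulate` is NULL.
#' @param evalue_max RBH e-value cutoff (default 1e-5).
#' @param min_genes,max_gap,max_inversions synteny-block rule (5, 4, 5).
#' @param weight_power Fitch-Margoliash weighting power (default 2).
#' @param n_perm family-dynamics permutations (default 1000).
#' @param n_sim phylogenetic-ANOVA simulations (default 1000).
#' @param t_convention divergence-time convention for [loss_rate()]:
#'   `"mrca_age"` (default) or `"path_length"`.
#' @param family_counts optional families x species matrix for the
#'   family-dynamics stage; when `NULL` and simulating, counts are drawn
#'   with [simulate_family_counts()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = list(n_taxa = 6, crown_age = 60,
                                            n_scaffolds = 100, n_genes = 2000,
                                            inversion_rate = 0.5,
                                            translocation_rate = 0.1,
                                            gene_loss_rate = 2e-4,
                                            gene_gain_rate = 0.1,
                                            hit_noise = 0.2),
                            input_dir = NULL,
                            evalue_max = 1e-5,
                            min_genes = 5, max_gap = 4, max_inversions = 5,
                            weight_power = 2, n_perm = 1000, n_sim = 1000,
                            t_convention = "mrca_age",
                            family_counts = NULL) {
  if (min_genes < 1 || max_gap < 0 || max_inversions < 0 ||
      evalue_max <= 0 || n_perm < 100)
    stop_invalid("invalid threshold in pipeline configuration")
  structure(list(seed = as.integer(seed), simulate = simulate,
                 input_dir = input_dir, evalue_max = evalue_max,
                 min_genes = min_genes, max_gap = max_gap,
                 max_inversions = max_inversions,
                 weight_power = weight_power, n_perm = n_perm,
                 n_sim = n_sim, t_convention = t_convention,
                 family_counts = family_counts),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full synteny-decay analysis
#'
#' Stages, in dependency order: (1) simulate genomes, hit tables and tree
#' (or ingest them from `cfg$input_dir`); (2) reciprocal-best-hit
#' orthology for every species pair; (3) syntenic blocks, proportion
#' synteny and loss / rate matrices; (4) least-squares mapping of the loss
#' matrix onto the dated tree and per-branch rates; (5) gene-family
#' dynamics with permutation envelopes (when counts are available).  Every
#' artifact is written under `outdir` with a provenance header (package
#' version, configuration hash, seed), and a machine-readable
#' `report.json` aggregates the results.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return the report, invisibly: list with `p_s`, `loss` and `rate`
#'   matrices, the branch-rate table, the node-dynamics table and the
#'   configuration echo.
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(tool = paste0("syndecay ", packageVersion("syndecay")),
               config = config_hash(unclass(cfg)), seed = cfg$seed)
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    tree <- simulate_tree(s$n_taxa, s$crown_age, seed = cfg$seed)
    scfg <- sim_config(s$n_scaffolds, s$n_genes,
                       inversion_rate = s$inversion_rate %||% 0,
                       translocation_rate = s$translocation_rate %||% 0,
                       gene_loss_rate = s$gene_loss_rate %||% 0,
                       gene_gain_rate = s$gene_gain_rate %||% 0,
                       span_mean = s$span_mean %||% 5, seed = cfg$seed)
    sim <- simulate_genomes(tree, scfg)
    genomes <- sim$genomes
    hits <- simulate_hit_table(genomes, sim$truth,
                               noise = s$hit_noise %||% 0, seed = cfg$seed)
    jsonlite::write_json(sim$truth$ortholog_map,
                         file.path(outdir, "truth_orthologs.json"))
  } else {
    if (is.null(cfg$input_dir)) stop_invalid("no simulate block and no input_dir")
    tree <- ape::read.tree(file.path(cfg$input_dir, "tree.nwk"))
    gfiles <- list.files(cfg$input_dir, "^genome_.*\\.tsv$",
                         full.names = TRUE)
    if (!length(gfiles)) stop_invalid("missing artifact: genome_<sp>.tsv")
    genomes <- setNames(lapply(gfiles, read_genome_tsv),
                        sub("^genome_(.*)\\.tsv$", "\\1", basename(gfiles)))
    hfiles <- list.files(cfg$input_dir, "^hits_.*\\.tsv$",
                         full.names = TRUE)
    if (!length(hfiles)) stop_invalid("missing artifact: hits_<A>__<B>.tsv")
    keys <- sub("^hits_(.*)\\.tsv$", "\\1", basename(hfiles))
    hits <- setNames(lapply(seq_along(hfiles), function(i)
      read_hit_table(hfiles[i], species = strsplit(keys[i], "__")[[1]])),
      keys)
  }
  ape::write.tree(tree, file.path(outdir, "tree.nwk"))
  for (sp in names(genomes))
    write_genome_tsv(genomes[[sp]],
                     file.path(outdir, paste0("genome_", sp, ".tsv")), meta)
  species <- names(genomes)
  # stage: orthology
  pairsets <- list()
  for (i in seq_len(length(species) - 1L))
    for (j in (i + 1L):length(species)) {
      a <- species[i]; b <- species[j]
      kab <- paste0(a, "__", b); kba <- paste0(b, "__", a)
      if (is.null(hits[[kab]]) || is.null(hits[[kba]]))
        stop_invalid("missing artifact: hit tables for pair ", a, "/", b)
      pairsets[[kab]] <- rbh_pairs(hits[[kab]], hits[[kba]],
                                   evalue_max = cfg$evalue_max)
      write_pairs_tsv(pairsets[[kab]],
                      file.path(outdir, paste0("pairs_", kab, ".tsv")), meta)
    }
  # stage: synteny matrices
  mats <- pairwise_loss_matrix(genomes, pairsets, tree,
                               min_genes = cfg$min_genes,
                               max_gap = cfg$max_gap,
                               max_inversions = cfg$max_inversions,
                               t_convention = cfg$t_convention)
  write_phylip_dist(mats$loss, file.path(outdir, "loss_matrix.phylip"))
  write_phylip_dist(mats$rate, file.path(outdir, "rate_matrix.phylip"))
  # stage: branch fitting
  fit <- fit_branch_lengths(tree, mats$loss,
                            weight_power = cfg$weight_power)
  rates <- branch_rates(fit)
  write_tsv_meta(rates, file.path(outdir, "branch_rates.tsv"), meta)
  ape::write.tree(as_loss_tree(fit, "loss"),
                  file.path(outdir, "loss_tree.nwk"))
  # stage: family dynamics
  counts <- cfg$family_counts
  if (is.null(counts) && !is.null(cfg$simulate))
    counts <- simulate_family_counts(tree, n_families = 1000,
                                     base_lambda = 0.05, seed = cfg$seed)
  dyn <- NULL
  if (!is.null(counts)) {
    dyn <- permutation_percentiles(counts, tree, n_perm = cfg$n_perm,
                                   seed = cfg$seed)
    write_tsv_meta(as.data.frame(dyn),
                   file.path(outdir, "node_dynamics.tsv"), meta)
  }
  report <- list(meta = meta,
                 config = unclass(cfg)[setdiff(names(unclass(cfg)),
                                               "family_counts")],
                 species = species,
                 p_s = mats$p_s, loss = mats$loss, rate = mats$rate,
                 branch_rates = rates,
                 node_dynamics = if (!is.null(dyn)) as.data.frame(dyn),
                 treefit_rss = fit$rss)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor", force = TRUE)
  invisible(report)
}
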