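#' Run the full community-assembly analysis
#'
#' Orchestrates the pipeline on one study: align inputs, classify OTUs into
#' generalists / specialists, then for each community subset (all taxa,
#' generalists, specialists) compute betaNTI with its assembly-process
#' fractions and the Sloan neutral-model fit; compute per-sample pollution
#' indices, alpha diversity, Bray-Curtis dissimilarity, Mantel tests of each
#' metal against community composition, the Spearman betaNTI-metal
#' correlations, the betaNTI~Pn regression, and the shared/unique OTU
#' partition. All artifacts are written as TSV/JSON under `out_dir` together
#' with a machine-readable run manifest; one global seed drives every stage
#' through stage-specific sub-seeds ([derive_seed()]), so stage order never
#' affects results and a rerun with the same config is numerically identical.
#'
#' Group subsets keep only the OTUs with the given niche label (relative
#' abundances are renormalized within the subset by the downstream
#' statistics); samples left empty by subsetting are dropped from that
#' group's analyses with a warning. Groups with too few OTUs for a stage are
#' skipped with a warning and recorded as `NA` in the manifest.
#'
#' @param table samples x OTUs count matrix, or path to a TSV readable by
#'   [read_otu_table()] (samples as rows).
#' @param tree `phylo` or path to a newick file; tips must cover the table's
#'   OTUs.
#' @param metadata data.frame or path to a metadata CSV ([read_metadata()]).
#' @param backgrounds named per-element background concentrations (mg/kg).
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed.
#' @param n_perm_niche permutations for the niche null (default 999).
#' @param n_null_bnti randomizations for the betaNTI null (default 999).
#' @param detection_reads NCM detection limit in reads (default 1).
#' @param alpha two-sided level for niche classification (default 0.05).
#' @param pairing pairwise mapping of per-sample covariates
#'   (`"pair_mean"` or `"pair_abs_difference"`).
#' @param null_model niche null model (see [classify_otus()]).
#' @return invisibly, the manifest list (also written as `summary.json`).
#' @export
run_pipeline <- function(table, tree, metadata, backgrounds = DEFAULT_BACKGROUNDS,
                         out_dir, seed, n_perm_niche = 999, n_null_bnti = 999,
                         detection_reads = 1, alpha = 0.05,
                         pairing = "pair_mean", null_model = "quasiswap") {
  if (is.character(table)) table <- read_otu_table(table)
  if (is.character(tree)) tree <- read_tree(tree)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.null(tree)) stop("betaNTI stage requires a phylogeny; none supplied")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aligned <- align_samples(validate_otu_table(table), metadata)
  table <- aligned$table; metadata <- aligned$metadata
  tree <- prune_tree(tree, colnames(table))

  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # niche classification
  niche <- classify_otus(table, n_perm = n_perm_niche, alpha = alpha,
                         seed = derive_seed("niche", seed),
                         null_model = null_model)
  tsv(niche, "niche_labels.tsv")

  groups <- list(all = colnames(table),
                 generalist = niche$otu_id[niche$label == "generalist"],
                 specialist = niche$otu_id[niche$label == "specialist"])

  manifest <- list(config = list(seed = seed, n_perm_niche = n_perm_niche,
                                 n_null_bnti = n_null_bnti,
                                 detection_reads = detection_reads,
                                 alpha = alpha, pairing = pairing,
                                 null_model = null_model),
                   n_samples = nrow(table), n_otus = ncol(table),
                   n_generalists = sum(niche$label == "generalist"),
                   n_specialists = sum(niche$label == "specialist"),
                   r_version = as.character(getRversion()),
                   groups = list())

  # pollution, diversity, composition
  pollution <- pollution_indices(metadata, backgrounds)
  tsv(pollution, "pollution.tsv")
  tsv(alpha_diversity(table), "diversity.tsv")
  bc <- bray_curtis(table)
  tsv(data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
      "bray_curtis.tsv")

  mantel_rows <- lapply(METAL_ELEMENTS, function(el) {
    Dm <- as.matrix(stats::dist(metadata[[el]]))
    mt <- mantel_test(bc, Dm, n_perm = 999,
                      seed = derive_seed(paste0("mantel_", el), seed))
    data.frame(variable = el, r = mt$r, p_value = mt$p_value,
               stars = significance_stars(mt$p_value), stringsAsFactors = FALSE)
  })
  tsv(do.call(rbind, mantel_rows), "mantel.tsv")

  tsv(data.frame(region = names(shared_otu_partition(table, metadata)$regions),
                 n_otus = unname(shared_otu_partition(table, metadata)$regions)),
      "venn_regions.tsv")

  # group-wise assembly analyses
  for (g in names(groups)) {
    ids <- groups[[g]]
    entry <- list(n_otus = length(ids))
    if (length(ids) >= 2) {
      sub <- table[, ids, drop = FALSE]
      keep_samples <- rowSums(sub) > 0
      if (!all(keep_samples))
        warning(sprintf("group '%s': dropping %d empty sample(s)",
                        g, sum(!keep_samples)))
      sub <- sub[keep_samples, , drop = FALSE]
      if (nrow(sub) >= 3) {
        bn <- beta_nti(sub, tree, n_null = n_null_bnti,
                       seed = derive_seed(paste0("bnti_", g), seed))
        tsv(bn, paste0("bnti_", g, ".tsv"))
        entry$assembly <- tryCatch(assembly_fractions(bn), error = function(e) {
          warning(sprintf("group '%s': %s", g, conditionMessage(e)))
          NULL
        })
        entry$mean_bnti <- if (all(is.na(bn$bnti))) NA_real_ else
          mean(bn$bnti, na.rm = TRUE)
        reg <- tryCatch(bnti_vs_pollution(bn, pollution, pairing = pairing),
                        error = function(e) NULL)
        entry$bnti_pn_regression <- reg
        sp <- tryCatch(bnti_vs_covariates(bn, metadata, pairing = pairing),
                       error = function(e) NULL)
        if (!is.null(sp)) tsv(sp, paste0("spearman_bnti_metals_", g, ".tsv"))
      }
      fit <- tryCatch(fit_ncm(sub, d_reads = detection_reads),
                      error = function(e) {
                        warning(sprintf("group '%s': NCM fit skipped (%s)",
                                        g, conditionMessage(e)))
                        NULL
                      })
      if (!is.null(fit)) {
        tsv(fit$otus, paste0("ncm_", g, ".tsv"))
        entry$ncm <- list(m = fit$m, Nm = fit$Nm, N = fit$N,
                          r_squared = fit$r_squared,
                          neutral_fraction = fit$neutral_fraction)
      }
    }
    manifest$groups[[g]] <- entry
  }

  jsonlite::write_json(manifest, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Simulate a complete synthetic study
#'
#' One call producing mutually consistent inputs for [run_pipeline()]: a
#' Yule phylogeny, per-sample metadata with a heavy-metal gradient, an OTU
#' table whose assembly mixes Sloan neutral dynamics with Gaussian
#' environmental selection along the pollution axis (conserved optima, so
#' selection is betaNTI-detectable), and planted generalists/specialists
#' with known labels.
#'
#' @param n_samples,n_otus study dimensions (defaults 60 samples, 250 OTUs,
#'   the scale of a small regional survey).
#' @param N reads per sample (default 1000).
#' @param m migration rate (default 0.05).
#' @param selection_strength Gaussian selection intensity along the pollution
#'   gradient (default 1; 0 gives a fully neutral study).
#' @param n_plant_generalists,n_plant_specialists OTUs overwritten with known
#'   niche structure (defaults 15 and 10, matching the scarce-generalist /
#'   abundant-specialist prevalence typical of these surveys; 0 disables
#'   planting).
#' @param pollution_profile passed to [simulate_metadata()].
#' @param seed global integer seed.
#' @return list: `table`, `tree`, `metadata`, `backgrounds`, `optima`,
#'   `planted_labels`.
#' @export
simulate_study <- function(n_samples = 60, n_otus = 250, N = 1000, m = 0.05,
                           selection_strength = 1,
                           n_plant_generalists = 15, n_plant_specialists = 10,
                           pollution_profile = "decreasing_with_distance",
                           seed) {
  tree <- simulate_phylogeny(n_otus, seed = derive_seed("tree", seed))
  metadata <- simulate_metadata(n_samples, pollution_profile = pollution_profile,
                                seed = derive_seed("metadata", seed))
  # selection acts along the pollution axis: the gradient is the (scaled)
  # distance to the urban center that also drives the metal concentrations
  env <- metadata$distance_km / max(metadata$distance_km)
  spec <- selection_sim_spec(n_samples = n_samples, n_otus = n_otus, N = N,
                             m = m, tree = tree, seed = derive_seed("table", seed),
                             env_gradient = env,
                             selection_strength = selection_strength)
  sim <- simulate_selected_table(spec)
  table <- sim$table
  rownames(table) <- metadata$sample_id
  planted <- NULL
  if (n_plant_generalists + n_plant_specialists > 0) {
    pl <- plant_generalists_specialists(table, n_plant_generalists,
                                        n_plant_specialists,
                                        seed = derive_seed("plant", seed))
    table <- pl$table
    planted <- pl$labels
  }
  list(table = table, tree = tree, metadata = metadata,
       backgrounds = DEFAULT_BACKGROUNDS, optima = sim$optima,
       planted_labels = planted)
}
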