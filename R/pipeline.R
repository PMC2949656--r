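# End-to-end orchestration: filter -> cluster -> subtype -> signature ->
# enrichment -> projection (+ aCGH and IHC when inputs are given), with a
# machine-readable run manifest.

#' Build and validate a pipeline configuration
#'
#' A configuration is a named list of input paths (or in-memory objects) and
#' thresholds. `seed` is mandatory because the signature stage uses a random
#' forest. Unknown entries are rejected so typos fail early.
#'
#' @param expression expression matrix or TSV path (required).
#' @param probe_annotation annotation data.frame or TSV path (required).
#' @param sample_annotation sample annotation data.frame or TSV path;
#'   required for the signature stage (supplies `contrast_column`).
#' @param centroids named list of centroid matrices or TSV paths (each a
#'   label scheme, e.g. `sorlie`, `hu`).
#' @param gene_sets gene-set list or GMT path.
#' @param clone_table `acgh_experiment` or TSV path.
#' @param centromeres centromere map or TSV path (defaults to
#'   [default_centromeres()] when aCGH input is given).
#' @param ihc_table IHC table or TSV path.
#' @param contrast_column sample-annotation column defining the two-group
#'   contrast (default `cowden_status`).
#' @param n_clusters dendrogram cut size for the association test
#'   (default 6).
#' @param p_thresh,rcv_cap,rcv_percentile,min_log2 filtering thresholds.
#' @param n_keep,n_trees signature parameters.
#' @param snr_min,sd_max,gain,loss,amp aCGH parameters.
#' @param seed RNG seed (required).
#' @param outdir output directory; `NULL` disables file output.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(expression, probe_annotation,
                            sample_annotation = NULL, centroids = NULL,
                            gene_sets = NULL, clone_table = NULL,
                            centromeres = NULL, ihc_table = NULL,
                            contrast_column = "cowden_status",
                            n_clusters = 6L, p_thresh = 0.01, rcv_cap = 10,
                            rcv_percentile = 95, min_log2 = 10,
                            n_keep = 200L, n_trees = 1000L, snr_min = 3,
                            sd_max = 0.1, gain = 1.2, loss = 0.8, amp = 2.0,
                            seed = NULL, outdir = NULL) {
  if (is.null(seed))
    stop("pipeline_config: a seed is mandatory (the signature stage is stochastic)")
  stopifnot(p_thresh > 0, p_thresh <= 1, rcv_cap > 0,
            rcv_percentile > 0, rcv_percentile < 100,
            gain > loss, amp >= gain)
  cfg <- list(expression = expression, probe_annotation = probe_annotation,
              sample_annotation = sample_annotation, centroids = centroids,
              gene_sets = gene_sets, clone_table = clone_table,
              centromeres = centromeres, ihc_table = ihc_table,
              contrast_column = contrast_column, n_clusters = n_clusters,
              p_thresh = p_thresh, rcv_cap = rcv_cap,
              rcv_percentile = rcv_percentile, min_log2 = min_log2,
              n_keep = n_keep, n_trees = n_trees, snr_min = snr_min,
              sd_max = sd_max, gain = gain, loss = loss, amp = amp,
              seed = as.integer(seed), outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; path-valued
#' entries are loaded by [run_pipeline()].
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.load <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x

#' Run the full analysis pipeline
#'
#' Executes, in order: probe filtering, unsupervised Ward clustering of
#' samples (1 - Pearson), centroid subtype assignment for every supplied
#' centroid scheme, two-group signature derivation, gene-set enrichment of
#' the signature, PCA projection with model-based clustering, and -- when
#' inputs are present -- aCGH calling with perturbation rates and IHC
#' marker tests. Any stage error aborts with the stage name. A
#' machine-readable manifest (thresholds, seed, per-stage counts) is
#' returned and, when `outdir` is set, written as JSON beside the stage
#' tables.
#'
#' @param config a `pipeline_config` (or YAML path).
#' @return list with per-stage results and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("apocrine")),
                   seed = config$seed,
                   thresholds = config[c("p_thresh", "rcv_cap",
                                         "rcv_percentile", "min_log2",
                                         "n_keep", "n_trees", "snr_min",
                                         "sd_max", "gain", "loss", "amp")],
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  odir <- config$outdir
  if (!is.null(odir) && !dir.exists(odir)) dir.create(odir, recursive = TRUE)
  save_tsv <- function(df, name) {
    if (!is.null(odir)) .write_tsv(df, file.path(odir, paste0(name, ".tsv")))
  }

  X <- stage("read_expression", .load(config$expression, read_expression_matrix))
  ann <- stage("read_annotation", .load(config$probe_annotation, read_probe_annotation))
  samp <- if (!is.null(config$sample_annotation))
    stage("read_samples", .load(config$sample_annotation, read_sample_annotation))

  filt <- stage("probe_filter", select_clustering_probes(
    X, ann, p_thresh = config$p_thresh, rcv_cap = config$rcv_cap,
    rcv_percentile = config$rcv_percentile, min_log2 = config$min_log2))
  out$filter <- filt
  manifest$stages$probe_filter <- filt$report[c("n_input", "n_after_intensity",
                                                "n_after_variance", "n_after_rcv")]
  save_tsv(filt$report$per_probe, "filter_report")

  kept <- intensity_filter(X, ann, min_log2 = config$min_log2)
  Xf <- X[kept, , drop = FALSE]
  Xc <- X[filt$probes, , drop = FALSE]

  tree <- stage("clustering", ward_cluster(correlation_distance(Xc, "samples")))
  labels <- cut_dendrogram(tree, config$n_clusters)
  out$clustering <- list(tree = tree, labels = labels)
  manifest$stages$clustering <- list(n_probes_used = nrow(Xc),
                                     k = config$n_clusters,
                                     cluster_sizes = as.integer(table(labels)))

  if (!is.null(config$centroids)) {
    out$subtypes <- lapply(config$centroids, function(ct) {
      cent <- .load(ct, read_centroids)
      stage("subtype", assign_subtypes(Xf, ann, cent))
    })
    for (nm in names(out$subtypes)) save_tsv(out$subtypes[[nm]],
                                             paste0("subtypes_", nm))
    manifest$stages$subtypes <- lapply(out$subtypes, function(s)
      list(n_common_genes = s$n_common_genes[1L],
           counts = as.list(table(s$subtype))))
  }

  if (!is.null(samp)) {
    groups <- samp[[config$contrast_column]][match(colnames(X), samp$sample_id)]
    assoc <- stage("association",
                   cluster_class_association(labels, groups))
    out$association <- assoc
    manifest$stages$association <- list(test = assoc$test_used,
                                        p_value = assoc$p_value)
    sig <- stage("signature", derive_signature(
      Xf, groups, annotation = ann, p_thresh = config$p_thresh,
      n_keep = config$n_keep, n_trees = config$n_trees, seed = config$seed))
    out$signature <- sig
    manifest$stages$signature <- list(screen_size = sig$screen_size,
                                      n_selected = length(sig$selected),
                                      lfdr_at_screen = sig$lfdr_at_screen,
                                      pi0 = sig$pi0)
    save_tsv(sig$stats, "signature_stats")

    if (!is.null(config$gene_sets)) {
      sets <- .load(config$gene_sets, read_gene_sets)
      universe <- unique(ann$gene_symbol[ann$probe_id %in% rownames(Xf) &
                                           nzchar(ann$gene_symbol)])
      enr <- stage("enrichment", enrich_signature(
        c(sig$genes_up, sig$genes_down), sets, universe))
      out$enrichment <- enr
      manifest$stages$enrichment <- list(n_sets = nrow(enr),
                                         top_set = enr$set_name[1L],
                                         top_p = enr$p_value[1L])
      save_tsv(enr, "enrichment")
    }

    proj <- stage("projection", pca_scores(Xf, sig$selected))
    gmm <- stage("projection", gmm_cluster(proj$scores, seed = config$seed))
    out$projection <- list(pca = proj, gmm = gmm)
    manifest$stages$projection <- list(explained = proj$explained,
                                       gmm_k = gmm$k)
  }

  if (!is.null(config$clone_table)) {
    expt <- stage("acgh", .load(config$clone_table, read_clone_table))
    cmap <- if (is.null(config$centromeres)) default_centromeres()
            else .load(config$centromeres, read_centromeres)
    ratios <- stage("acgh", aggregate_ratios(expt, config$snr_min, config$sd_max))
    keep_clones <- exclude_sparse_clones(ratios)
    ratios <- ratios[keep_clones, , drop = FALSE]
    clones <- expt$clones[match(keep_clones, expt$clones$clone_id), ]
    calls <- apply(ratios, 2L, call_status,
                   gain = config$gain, loss = config$loss, amp = config$amp)
    rates <- vapply(colnames(calls), function(tid)
      perturbation_rate(calls[, tid], clones, cmap)$rate, numeric(1L))
    out$acgh <- list(ratios = ratios, calls = calls, clones = clones,
                     rates = rates)
    manifest$stages$acgh <- list(n_clones_retained = length(keep_clones),
                                 rates = as.list(rates))
    save_tsv(data.frame(tumor_id = names(rates), rate = rates,
                        row.names = NULL), "perturbation_rates")
  }

  if (!is.null(config$ihc_table)) {
    tab <- stage("ihc", .load(config$ihc_table, read_ihc_table))
    markers <- intersect(.ihc_panel, colnames(tab))
    ihc <- lapply(markers, function(mk) {
      a <- marker_counts(tab, mk, "cowden")
      b <- marker_counts(tab, mk, "non_cowden")
      test <- tryCatch(proportion_test(a$n_positive, a$n_total,
                                       b$n_positive, b$n_total),
                       error = function(e) NULL)
      data.frame(marker = mk, cowden_positive = a$n_positive,
                 cowden_total = a$n_total,
                 other_positive = b$n_positive, other_total = b$n_total,
                 p_value = if (is.null(test)) NA_real_ else test$p_value,
                 test_used = if (is.null(test)) NA_character_ else test$test_used,
                 stringsAsFactors = FALSE)
    })
    out$ihc <- do.call(rbind, ihc)
    manifest$stages$ihc <- list(n_markers = nrow(out$ihc))
    save_tsv(out$ihc, "ihc_tests")
  }

  out$manifest <- manifest
  if (!is.null(odir))
    jsonlite::write_json(manifest, file.path(odir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out
}
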