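#' Run the full strain-level analysis pipeline
#'
#' Orders the stages as the downstream statistics require: load and
#' validate the ASV table, optional type-strain species disambiguation,
#' relative abundances, strain-cluster inference and shared-ASV
#' decomposition, alpha/beta diversity with optional PERMANOVA, optional
#' taxa-metabolite correlations, and optional sensory Z-scores. All
#' outputs are written as TSV/JSON under `out_dir` together with a
#' manifest of MD5 checksums, the seed and a parameter echo, so two runs
#' with the same config and seed produce identical manifests.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{table}{An `asv_table`, or `counts_dir` pointing at files
#'       written by [write_asv_table()].}
#'     \item{params}{[inference_params()] (optional).}
#'     \item{references, threshold}{Optional named reference sequences and
#'       identity threshold for species disambiguation of all ASVs.}
#'     \item{declared_clusters}{Optional extra clusters (shared-ASV) merged
#'       into the decomposition stage.}
#'     \item{group_var}{Optional metadata column for PERMANOVA.}
#'     \item{metabolites}{Optional samples x metabolites matrix.}
#'     \item{sensory}{Optional raw panel score data.frame.}
#'     \item{out_dir}{Output directory.}
#'     \item{seed}{Integer seed (permutations).}
#'   }
#' @return Invisibly, the result bundle (species calls, clusters,
#'   decomposition, diversity, permanova, associations, sensory,
#'   manifest).
#' @export
run_pipeline <- function(config) {
  # validate before any stage runs
  if (is.null(config$table) && is.null(config$counts_dir))
    stop("config error: provide 'table' or 'counts_dir'")
  if (!is.null(config$counts_dir) && !dir.exists(config$counts_dir))
    stop("config error: counts_dir does not exist: ", config$counts_dir)
  if (is.null(config$out_dir)) stop("config error: out_dir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- if (is.null(config$params)) inference_params() else config$params

  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  tab <- stage("load", {
    if (!is.null(config$table)) config$table else read_asv_table(config$counts_dir)
  })
  message("  table: ", nrow(tab$counts), " samples x ", ncol(tab$counts), " ASVs")

  out <- list(seed = seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(name, writer) {
    p <- file.path(config$out_dir, name)
    writer(p)
    written <<- c(written, p)
  }

  if (!is.null(config$references)) {
    out$species_calls <- stage("assign", {
      cfg <- assignment_config(config$references,
                               threshold = if (is.null(config$threshold))
                                 0.9980 else config$threshold)
      assign_species_table(tab$asv_seqs, cfg)
    })
    emit("species_calls.tsv", function(p)
      utils::write.table(out$species_calls, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }

  rel <- stage("relative_abundances", relative_abundances(tab))
  emit("relative_abundances.tsv", function(p) write_tsv_matrix(rel, p))

  out$clusters <- stage("cluster", build_strain_clusters(tab, params))
  emit("clusters.json", function(p)
    jsonlite::write_json(lapply(out$clusters, function(cl)
      cl[c("cluster_id", "species", "member_asvs", "ratio",
           "copy_number_lower_bound", "fit_deviation", "n_support")]),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE))

  all_clusters <- c(out$clusters, config$declared_clusters)
  out$decomposition <- stage("decompose", decompose_clusters(tab, all_clusters))
  emit("cluster_abundances.tsv", function(p)
    write_tsv_matrix(out$decomposition$abundance, p))

  out$diversity <- stage("diversity", {
    data.frame(sample = rownames(rel), inverse_simpson = inverse_simpson(rel))
  })
  emit("alpha_diversity.tsv", function(p)
    utils::write.table(out$diversity, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  D <- stage("beta_diversity", bray_curtis_matrix(tab$counts))
  emit("bray_curtis.tsv", function(p) write_tsv_matrix(D, p))

  if (!is.null(config$group_var)) {
    out$permanova <- stage("permanova", {
      g <- tab$sample_meta[[config$group_var]]
      permanova(D, g, seed = seed)
    })
    emit("permanova.json", function(p)
      jsonlite::write_json(unclass(out$permanova), p, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE))
  }

  if (!is.null(config$metabolites)) {
    out$associations <- stage("correlate", {
      filt <- prevalence_filter(rel)
      correlation_matrix(filt, config$metabolites, method = "spearman")
    })
    emit("correlations_rho.tsv", function(p)
      write_tsv_matrix(out$associations$r, p, id_col = "taxon"))
    emit("correlations_p.tsv", function(p)
      write_tsv_matrix(out$associations$p, p, id_col = "taxon"))
    emit("leaf_orders.json", function(p)
      jsonlite::write_json(list(rows = out$associations$row_order,
                                cols = out$associations$col_order),
                           p, pretty = TRUE))
  }

  if (!is.null(config$sensory)) {
    out$sensory <- stage("sensory", {
      z <- assessor_zscores(config$sensory)
      cheese_zscore(z)
    })
    emit("sensory_z.tsv", function(p)
      utils::write.table(out$sensory, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }

  manifest <- list(
    seed = seed,
    params = unclass(params),
    files = as.list(stats::setNames(unname(tools::md5sum(written)),
                                    basename(written))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  message("pipeline complete: ", length(written), " outputs in ", config$out_dir)
  invisible(out)
}
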