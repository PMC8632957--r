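#' Run the full analysis pipeline from a config
#'
#' Chains fit-trees -> similarity -> connect -> cluster on the input tables
#' named in the config, writing each stage's outputs under `out_dir` and a
#' `manifest.json` recording parameters, the seed, package version, stage
#' status and the MD5 of every output file, so a rerun with the same config
#' is byte-reproducible. Stages whose outputs already exist are skipped
#' unless `force = TRUE`.
#'
#' Config fields (YAML or a named list): `responses` (required path),
#' `alterations`, `expression`, `gene_list` (optional paths), `out_dir`,
#' `alpha` (0.05), `min_node` (6), `fdr` (0.1), `pcc` (0.3), `cluster_k`
#' (2), `seed` (1).
#'
#' @param config path to a YAML file or a named list.
#' @param out_dir output directory (overrides the config field).
#' @param force rerun stages whose outputs already exist.
#' @param verbose log stage progress to stderr.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, force = FALSE,
                         verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(alpha = 0.05, min_node = 6L, fdr = 0.1, pcc = 0.3,
                   cluster_k = 2L, seed = 1L, out_dir = "pharmtree_out")
  config <- utils::modifyList(defaults, config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message("[pharmtree] ", ...)
  stages <- character(0)

  run_stage <- function(name, outputs, fn) {
    paths <- file.path(out, outputs)
    if (!force && all(file.exists(paths))) {
      log_msg("stage ", name, ": outputs present, skipped")
      stages[[length(stages) + 1L]] <<- name
      return(invisible(NULL))
    }
    log_msg("stage ", name, " ...")
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[length(stages) + 1L]] <<- name
  }

  rm <- read_response_table(config$responses)
  set.seed(config$seed)

  trees_dir <- file.path(out, "trees")
  run_stage("fit-trees", "trees/trees_summary.tsv", function() {
    write_trees(grow_trees(rm, alpha = config$alpha,
                           min_node = config$min_node), trees_dir)
  })
  trees <- read_trees(trees_dir)

  run_stage("similarity", c("cell_similarity.tsv", "drug_similarity.tsv"),
            function() {
    pcs <- lapply(trees, function(tr)
      pair_concordance(tr, drug_labels(rm, tr$drug)))
    cs <- cell_similarity(pcs)
    S <- cs$S; S[is.na(S)] <- 0
    write_gene_matrix(`rownames<-`(S, cs$cells),
                      file.path(out, "cell_similarity.tsv"))
    write.table(drug_similarity_table(pcs),
                file.path(out, "drug_similarity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage("connect", "connections.tsv", function() {
    alt <- if (!is.null(config$alterations))
      read_alteration_matrix(config$alterations) else NULL
    expr <- if (!is.null(config$expression))
      read_expression_matrix(config$expression) else NULL
    conn <- connect_cohort(rm, trees, alt, expr, fdr = config$fdr,
                           pcc_threshold = config$pcc)
    write.table(conn, file.path(out, "connections.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  run_stage("cluster", "cell_clusters.tsv", function() {
    S <- read_expression_matrix(file.path(out, "cell_similarity.tsv"))
    k <- min(config$cluster_k, nrow(S))
    asg <- cluster_items(unclass(S), k = max(2L, k))
    df <- data.frame(cell = asg$items, cluster = asg$cluster,
                     stringsAsFactors = FALSE)
    write.table(df, file.path(out, "cell_clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  files <- sort(list.files(out, recursive = TRUE))
  files <- files[files != "manifest.json"]
  manifest <- list(
    package = "pharmtree",
    version = as.character(utils::packageVersion("pharmtree")),
    parameters = config[c("alpha", "min_node", "fdr", "pcc", "cluster_k")],
    seed = config$seed,
    stages = stages,
    outputs = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

validate_pipeline_config <- function(config) {
  if (is.null(config$responses) || !file.exists(config$responses))
    stop("config must name an existing `responses` table", call. = FALSE)
  for (th in c("alpha", "fdr", "pcc"))
    if (config[[th]] <= 0 || config[[th]] >= 1)
      stop("threshold `", th, "` must lie in (0, 1)", call. = FALSE)
  if (config$min_node < 6L)
    stop("`min_node` must be at least 6", call. = FALSE)
  invisible(TRUE)
}
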