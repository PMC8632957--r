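#' Configuration for a synthetic pharmacogenomic cohort
#'
#' Describes a planted-subtype cohort: per drug, cells fall into ordered
#' response groups whose ln-IC50 values are drawn from normal components
#' straddling the screening ceiling; alteration frequencies and expression
#' slopes are planted per group so downstream recovery can be scored.
#'
#' Defaults state a well-separated three-group world: group means -6/-1/+4
#' ln-units with sd 0.5 against a 1 uM ceiling (ln(1) = 0), so the first two
#' groups are essentially all sensitive and the third all resistant.
#'
#' @param n_cells number of cell lines.
#' @param n_drugs number of drugs.
#' @param group_means ascending per-group ln-IC50 means (ln uM).
#' @param group_sd within-group sd of ln-IC50.
#' @param group_props per-group membership proportions (default uniform).
#' @param max_conc per-drug screening ceiling(s) in uM, recycled
#'   (default 1 uM).
#' @param histology_labels optional histology vocabulary; labels are sampled
#'   per planted group of the first drug.
#' @param histology_mixing labels x groups matrix of sampling proportions
#'   (default uniform: histology carries no subtype signal).
#' @param genomic_effects data frame (`gene`, `drug`, `freqs` list-column of
#'   per-group alteration frequencies) of planted genomic effects, or `NULL`.
#' @param expression_effects data frame (`gene`, `drug`, `slope`,
#'   `noise_sd`) of planted expression effects, or `NULL`.
#' @param n_null_genes count of null genes added per modality (alterations:
#'   Bernoulli(`null_freq`) everywhere; expression: standard normal noise).
#' @param null_freq alteration frequency of null genes (default 0.1).
#' @param seed integer seed governing every draw.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 60L, n_drugs = 1L,
                             group_means = c(-6, -1, 4), group_sd = 0.5,
                             group_props = NULL, max_conc = 1,
                             histology_labels = NULL,
                             histology_mixing = NULL,
                             genomic_effects = NULL,
                             expression_effects = NULL,
                             n_null_genes = 0L, null_freq = 0.1,
                             seed = 1L) {
  if (is.unsorted(group_means, strictly = TRUE))
    stop("group means must be strictly ascending", call. = FALSE)
  stopifnot(group_sd > 0, n_cells >= 1L, n_drugs >= 1L, all(max_conc > 0))
  g <- length(group_means)
  if (is.null(group_props)) group_props <- rep(1 / g, g)
  stopifnot(length(group_props) == g, all(group_props > 0))
  group_props <- group_props / sum(group_props)
  max_conc <- rep_len(max_conc, n_drugs)
  if (!is.null(genomic_effects))
    stopifnot(all(c("gene", "drug", "freqs") %in% names(genomic_effects)),
              all(vapply(genomic_effects$freqs,
                         function(f) length(f) == g && all(f >= 0 & f <= 1),
                         logical(1))))
  if (!is.null(expression_effects))
    stopifnot(all(c("gene", "drug", "slope", "noise_sd") %in%
                    names(expression_effects)))
  structure(
    list(n_cells = as.integer(n_cells), n_drugs = as.integer(n_drugs),
         group_means = group_means, group_sd = group_sd,
         group_props = group_props, max_conc = max_conc,
         histology_labels = histology_labels,
         histology_mixing = histology_mixing,
         genomic_effects = genomic_effects,
         expression_effects = expression_effects,
         n_null_genes = as.integer(n_null_genes), null_freq = null_freq,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate a synthetic cohort with planted subtype structure
#'
#' Draws, per drug, a planted group per cell and an ln-IC50 from that
#' group's normal component; sensitivity labels then follow from the
#' screening-ceiling rule. Alteration status is Bernoulli with the planted
#' group-specific frequency; expression of effect genes is
#' `slope * ln_ic50 + noise`, null genes are pure noise. Fully reproducible
#' from the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `responses` ([response_matrix()]), `alterations` (0/1
#'   gene x cell matrix or `NULL`), `expression` (matrix or `NULL`), and
#'   `truth` (class `synthetic_truth`: `membership` cells x drugs group
#'   index matrix, `connections` data frame of planted effects with expected
#'   directions, `histology`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cells
  g <- length(config$group_means)
  cells <- sprintf("CL%04d", seq_len(n))
  drugs <- sprintf("DRUG%03d", seq_len(config$n_drugs))

  membership <- matrix(NA_integer_, n, config$n_drugs,
                       dimnames = list(cells, drugs))
  ln <- matrix(NA_real_, n, config$n_drugs, dimnames = list(cells, drugs))
  for (j in seq_len(config$n_drugs)) {
    grp <- sample.int(g, n, replace = TRUE, prob = config$group_props)
    membership[, j] <- grp
    ln[, j] <- rnorm(n, mean = config$group_means[grp], sd = config$group_sd)
  }
  mc <- config$max_conc
  names(mc) <- drugs

  histology <- NULL
  if (!is.null(config$histology_labels)) {
    labs <- config$histology_labels
    mix <- config$histology_mixing
    if (is.null(mix))
      mix <- matrix(1 / length(labs), length(labs), g,
                    dimnames = list(labs, NULL))
    histology <- vapply(seq_len(n), function(i)
      sample(labs, 1L, prob = mix[, membership[i, 1L]]), character(1))
    names(histology) <- cells
  }
  responses <- response_matrix(ln, mc, histology)

  planted <- list()
  alterations <- NULL
  ge <- config$genomic_effects
  null_alt <- config$n_null_genes
  if (!is.null(ge) || null_alt > 0L) {
    genes <- character(0); rows <- list()
    if (!is.null(ge)) {
      for (i in seq_len(nrow(ge))) {
        freqs <- ge$freqs[[i]]
        grp <- membership[, ge$drug[i]]
        rows[[ge$gene[i]]] <- rbinom(n, 1L, freqs[grp])
        planted[[length(planted) + 1L]] <- data.frame(
          gene = ge$gene[i], drug = ge$drug[i], modality = "genomic",
          direction = if (freqs[1L] > freqs[g]) "sensitive" else "resistant",
          stringsAsFactors = FALSE)
      }
    }
    for (k in seq_len(null_alt)) {
      rows[[sprintf("NULLG%03d", k)]] <- rbinom(n, 1L, config$null_freq)
    }
    alterations <- do.call(rbind, rows)
    colnames(alterations) <- cells
  }

  expression <- NULL
  ee <- config$expression_effects
  if (!is.null(ee) || null_alt > 0L) {
    rows <- list()
    if (!is.null(ee)) {
      for (i in seq_len(nrow(ee))) {
        v <- ee$slope[i] * ln[, ee$drug[i]] + rnorm(n, sd = ee$noise_sd[i])
        rows[[ee$gene[i]]] <- v
        planted[[length(planted) + 1L]] <- data.frame(
          gene = ee$gene[i], drug = ee$drug[i], modality = "expression",
          direction = if (ee$slope[i] < 0) "sensitive" else "resistant",
          stringsAsFactors = FALSE)
      }
    }
    for (k in seq_len(null_alt)) {
      rows[[sprintf("NULLE%03d", k)]] <- rnorm(n)
    }
    expression <- do.call(rbind, rows)
    colnames(expression) <- cells
  }

  truth <- structure(
    list(membership = membership,
         connections = if (length(planted)) do.call(rbind, planted)
                       else data.frame(gene = character(0),
                                       drug = character(0),
                                       modality = character(0),
                                       direction = character(0)),
         histology = histology),
    class = "synthetic_truth")
  list(responses = responses, alterations = alterations,
       expression = expression, truth = truth)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label renaming), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(ifelse(sum_ij == maximum, 1, 0))
  (sum_ij - expected) / (maximum - expected)
}

#' Score recovery of planted structure
#'
#' Compares grown trees and retained connections against the generating
#' truth: per-drug adjusted Rand index between the leaf partition and the
#' planted groups, precision/recall of planted connections among retained
#' records, and direction accuracy on the recovered ones.
#'
#' @param truth a `synthetic_truth`.
#' @param trees named list of `subtype_tree` objects.
#' @param connections optional [connect_cohort()] table.
#' @return list with `ari` (named per drug), `precision`, `recall`,
#'   `direction_accuracy` (NA when not applicable).
#' @export
evaluate_recovery <- function(truth, trees, connections = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ari <- vapply(trees, function(tr) {
    if (!tr$drug %in% colnames(truth$membership))
      stop("drug not in truth: ", tr$drug, call. = FALSE)
    part <- leaf_partition(tr)
    if (!all(names(part) %in% rownames(truth$membership)))
      stop("tree cells not in truth", call. = FALSE)
    adjusted_rand_index(part, truth$membership[names(part), tr$drug])
  }, numeric(1))
  names(ari) <- vapply(trees, `[[`, "", "drug")

  precision <- recall <- dir_acc <- NA_real_
  if (!is.null(connections)) {
    ret <- connections[connections$retained, , drop = FALSE]
    key <- function(df) paste(df$gene, df$drug, df$modality, sep = "\r")
    planted <- truth$connections
    hit <- key(ret) %in% key(planted)
    recall <- if (nrow(planted)) sum(key(planted) %in% key(ret)) /
                                 nrow(planted) else NA_real_
    precision <- if (nrow(ret)) mean(hit) else NA_real_
    if (any(hit)) {
      m <- match(key(ret)[hit], key(planted))
      dir_acc <- mean(ret$direction[hit] == planted$direction[m])
    }
  }
  list(ari = ari, precision = precision, recall = recall,
       direction_accuracy = dir_acc)
}
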