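#' Response matrix: cell x drug ln-IC50 with screening ceilings
#'
#' Container for a drug-response cohort: a cell x drug matrix of natural-log
#' IC50 values (ln uM; `NA` = not assayed), a per-drug maximum screened
#' concentration (uM) and an optional per-cell histology label.
#'
#' @param ln_ic50 numeric matrix, rows = cells, columns = drugs, dimnames
#'   required. `NA` entries mark cell/drug pairs that were not assayed.
#' @param max_conc named numeric vector of per-drug maximum screened
#'   concentrations in uM; names must match `colnames(ln_ic50)`.
#' @param histology optional named character vector of per-cell histology
#'   labels (TCGA-style codes); names must match `rownames(ln_ic50)`.
#' @return An object of class `response_matrix` with fields `ln_ic50`,
#'   `max_conc`, `histology`, `cells`, `drugs`.
#' @export
response_matrix <- function(ln_ic50, max_conc, histology = NULL) {
  if (!is.matrix(ln_ic50) || !is.numeric(ln_ic50))
    stop("`ln_ic50` must be a numeric matrix", call. = FALSE)
  cells <- rownames(ln_ic50)
  drugs <- colnames(ln_ic50)
  if (is.null(cells) || is.null(drugs))
    stop("`ln_ic50` must carry cell row names and drug column names", call. = FALSE)
  if (anyDuplicated(cells)) stop("duplicated cell IDs", call. = FALSE)
  if (anyDuplicated(drugs)) stop("duplicated drug IDs", call. = FALSE)
  if (nrow(ln_ic50) == 0L || ncol(ln_ic50) == 0L)
    stop("response matrix must contain at least one cell and one drug", call. = FALSE)
  bad <- !is.na(ln_ic50) & !is.finite(ln_ic50)
  if (any(bad)) stop("non-finite ln-IC50 entries present", call. = FALSE)

  max_conc <- max_conc[drugs]
  if (anyNA(max_conc) || length(max_conc) != length(drugs))
    stop("`max_conc` must name every drug", call. = FALSE)
  offending <- drugs[!is.finite(max_conc) | max_conc <= 0]
  if (length(offending))
    stop("non-positive max concentration for drug(s): ",
         paste(offending, collapse = ", "), call. = FALSE)

  if (!is.null(histology)) {
    histology <- histology[cells]
    names(histology) <- cells
    histology[is.na(histology)] <- "UNKNOWN"
  }

  structure(
    list(ln_ic50 = ln_ic50, max_conc = max_conc, histology = histology,
         cells = cells, drugs = drugs),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d cells x %d drugs, %d assayed entries\n",
              length(x$cells), length(x$drugs), sum(!is.na(x$ln_ic50))))
  invisible(x)
}

#' Read a long-format drug-response table
#'
#' Reads a GDSC-style long table (one row per cell/drug assay) into a
#' [response_matrix()]. Cells whose histology label is `"UNCLASSIFIED"` are
#' excluded, and the number removed is reported via a message.
#'
#' @param path path to a delimited text file.
#' @param dialect `"tsv"` or `"csv"`.
#' @param cols named list overriding column names; defaults are
#'   `cell`, `drug`, `ln_ic50`, `max_conc`, `histology` (histology optional).
#' @return A [response_matrix()].
#' @export
read_response_table <- function(path, dialect = c("tsv", "csv"),
                                cols = list()) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  cols <- utils::modifyList(
    list(cell = "cell", drug = "drug", ln_ic50 = "ln_ic50",
         max_conc = "max_conc", histology = "histology"), cols)
  df <- read.delim(path, sep = if (dialect == "tsv") "\t" else ",",
                   stringsAsFactors = FALSE, check.names = FALSE)
  required <- c(cols$cell, cols$drug, cols$ln_ic50, cols$max_conc)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("response table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("response table is empty", call. = FALSE)

  has_hist <- cols$histology %in% names(df)
  if (has_hist) {
    uncls <- unique(df[[cols$cell]][df[[cols$histology]] == "UNCLASSIFIED"])
    if (length(uncls)) {
      message(length(uncls), " UNCLASSIFIED cell line(s) excluded")
      df <- df[!(df[[cols$cell]] %in% uncls), , drop = FALSE]
    }
    if (nrow(df) == 0L)
      stop("all cells were UNCLASSIFIED; nothing to read", call. = FALSE)
  }

  cells <- sort(unique(df[[cols$cell]]))
  drugs <- sort(unique(df[[cols$drug]]))
  ln <- matrix(NA_real_, length(cells), length(drugs),
               dimnames = list(cells, drugs))
  ln[cbind(match(df[[cols$cell]], cells), match(df[[cols$drug]], drugs))] <-
    as.numeric(df[[cols$ln_ic50]])

  mc <- tapply(as.numeric(df[[cols$max_conc]]), df[[cols$drug]],
               function(v) unique(v)[1])
  mc <- as.numeric(mc[drugs])
  names(mc) <- drugs
  bad <- drugs[!is.finite(mc) | mc <= 0]
  if (length(bad))
    stop("non-positive max concentration for drug(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  hist <- NULL
  if (has_hist) {
    hist <- tapply(df[[cols$histology]], df[[cols$cell]],
                   function(v) unique(v)[1])
    hist <- as.character(hist[cells])
    names(hist) <- cells
  }
  response_matrix(ln, mc, hist)
}

#' Write a response matrix to a long-format TSV
#'
#' @param rm a [response_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(rm, path) {
  stopifnot(inherits(rm, "response_matrix"))
  idx <- which(!is.na(rm$ln_ic50), arr.ind = TRUE)
  df <- data.frame(
    cell = rm$cells[idx[, 1]],
    drug = rm$drugs[idx[, 2]],
    ln_ic50 = rm$ln_ic50[idx],
    max_conc = rm$max_conc[rm$drugs[idx[, 2]]],
    stringsAsFactors = FALSE
  )
  if (!is.null(rm$histology)) df$histology <- rm$histology[df$cell]
  df <- df[order(df$cell, df$drug), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_binary_or_numeric_matrix <- function(path, binary) {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, row.names = NULL)
  if (ncol(df) < 2L) stop("matrix file needs an ID column plus data", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated row ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicated column IDs", call. = FALSE)
  if (binary) {
    bad <- which(!(m %in% c(0, 1)), arr.ind = FALSE)
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(m))
      stop(sprintf("non-binary entry %s at gene '%s', cell '%s'",
                   format(m[bad[1]]), rownames(m)[rc[1]], colnames(m)[rc[2]]),
           call. = FALSE)
    }
  } else if (any(!is.finite(m))) {
    stop("non-finite expression entries present", call. = FALSE)
  }
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Read a binary gene x cell alteration matrix
#'
#' First column = gene/fusion IDs, remaining columns = cells; entries must be
#' 0/1 (1 = mutation or translocation present).
#'
#' @param path path to a TSV file.
#' @return numeric 0/1 matrix of class `alteration_matrix`.
#' @export
read_alteration_matrix <- function(path) {
  m <- read_binary_or_numeric_matrix(path, binary = TRUE)
  class(m) <- c("alteration_matrix", class(m))
  m
}

#' Read a continuous gene x cell expression matrix
#'
#' @param path path to a TSV file (first column = gene IDs).
#' @return numeric matrix of class `expression_matrix`.
#' @export
read_expression_matrix <- function(path) {
  m <- read_binary_or_numeric_matrix(path, binary = FALSE)
  class(m) <- c("expression_matrix", class(m))
  m
}

#' Write a gene x cell matrix as TSV
#' @param m matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
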