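#' Serialize a subtype tree to JSON
#'
#' Nested-record JSON with explicit child pointers; internal nodes carry
#' their split p-value, leaves their response class. Round-trips losslessly
#' through [read_tree()], including leaf order.
#'
#' @param tree a `subtype_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "subtype_tree"))
  pack <- function(node) {
    out <- list(cells = as.list(node$cells), n = node$n)
    if (is.null(node$left)) {
      out$response_class <- node$response_class
    } else {
      out$split_p <- node$split_p
      out$left <- pack(node$left)
      out$right <- pack(node$right)
    }
    out
  }
  doc <- list(format = "pharmtree/subtype_tree/v1",
              drug = tree$drug, alpha = tree$alpha,
              min_node = tree$min_node, root = pack(tree$root))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a subtype tree written by [write_tree()]
#'
#' @param path path to a tree JSON file.
#' @return a `subtype_tree`.
#' @export
read_tree <- function(path) {
  stopifnot(file.exists(path))
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("malformed tree file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, "pharmtree/subtype_tree/v1") ||
      is.null(doc$root) || is.null(doc$drug))
    stop("malformed tree file '", path, "': missing header fields",
         call. = FALSE)
  unpack <- function(rec) {
    node <- list(cells = vapply(rec$cells, as.character, character(1)),
                 n = as.integer(rec$n))
    if (length(node$cells) != node$n)
      stop("malformed tree file: node cell count mismatch", call. = FALSE)
    if (is.null(rec$left)) {
      node$response_class <- rec$response_class
    } else {
      node$split_p <- as.numeric(rec$split_p)
      node$left <- unpack(rec$left)
      node$right <- unpack(rec$right)
    }
    node
  }
  root <- unpack(doc$root)
  tree <- structure(
    list(drug = doc$drug, root = root, cells = root$cells,
         alpha = as.numeric(doc$alpha), min_node = as.integer(doc$min_node)),
    class = "subtype_tree")
  tree$leaves <- tree_leaves(tree)
  tree
}

#' Write trees for many drugs plus a summary table
#'
#' Writes `<drug>.tree.json` per drug under `dir` and a `trees_summary.tsv`
#' (drug, k, leaf sizes, leaf response classes).
#'
#' @param trees named list of `subtype_tree` objects.
#' @param dir output directory (created if needed).
#' @return the summary data frame, invisibly.
#' @export
write_trees <- function(trees, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(trees, function(tr) {
    leaves <- tree_leaves(tr)
    write_tree(tr, file.path(dir, paste0(sanitize_id(tr$drug), ".tree.json")))
    data.frame(drug = tr$drug, k = length(leaves),
               leaf_sizes = paste(vapply(leaves, `[[`, 0L, "n"),
                                  collapse = ","),
               leaf_classes = paste(vapply(leaves, `[[`, "", "response_class"),
                                    collapse = ","),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  write.table(summary, file.path(dir, "trees_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(summary)
}

#' Read all trees from a directory written by [write_trees()]
#' @param dir directory holding `*.tree.json` files.
#' @return named list of `subtype_tree` objects.
#' @export
read_trees <- function(dir) {
  files <- list.files(dir, pattern = "\\.tree\\.json$", full.names = TRUE)
  if (!length(files)) stop("no tree files under ", dir, call. = FALSE)
  trees <- lapply(files, read_tree)
  names(trees) <- vapply(trees, `[[`, "", "drug")
  trees[order(names(trees))]
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
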