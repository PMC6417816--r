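#' Write a labeled dataset to disk
#'
#' Cell Ranger-style triplet layout: `matrix.mtx` (MatrixMarket sparse
#' counts), `genes.tsv`, `barcodes.tsv`, plus `labels.tsv` (cell_id, group)
#' and a `params.yaml` provenance echo of the generating parameters.
#'
#' @param dataset a `labeled_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(dataset$counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(dataset$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(dataset$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(cell_id = colnames(dataset$counts), group = dataset$labels),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  yaml::write_yaml(unclass(dataset$params), file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Read a labeled dataset written by [write_dataset()]
#'
#' @param dir directory containing the triplet files.
#' @return a `labeled_dataset` (without the simulation-truth fields when only
#'   counts and labels are on disk).
#' @export
read_dataset <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  stopifnot(identical(lab$cell_id, colnames(counts)))
  params_file <- file.path(dir, "params.yaml")
  params <- NULL
  if (file.exists(params_file)) {
    params <- yaml::read_yaml(params_file)
    class(params) <- "sim_params"
  }
  labels <- lab$group
  if (!is.numeric(labels)) labels <- as.integer(factor(labels))
  structure(
    list(counts = counts, labels = as.integer(labels), params = params),
    class = "labeled_dataset"
  )
}

#' Read a genes x cells count matrix with cell labels (real-data adapter)
#'
#' Accepts either a MatrixMarket `.mtx` file (with `genes.tsv` /
#' `barcodes.tsv` sidecars next to it) or a dense TSV with gene rows and a
#' header of cell ids, plus a two-column cell-label TSV (`cell_id`,
#' `group`).  Labels are matched to matrix columns by cell id.
#'
#' @param counts_path path to the `.mtx` or dense `.tsv` count matrix.
#' @param labels_path path to the two-column label TSV.
#' @return a `labeled_dataset` with integer-coded labels and a
#'   `label_names` attribute carrying the original label strings.
#' @export
read_count_matrix <- function(counts_path, labels_path) {
  if (grepl("\\.mtx$", counts_path)) {
    counts <- as.matrix(Matrix::readMM(counts_path))
    side <- dirname(counts_path)
    g <- file.path(side, "genes.tsv")
    b <- file.path(side, "barcodes.tsv")
    if (file.exists(g)) rownames(counts) <- readLines(g)
    if (file.exists(b)) colnames(counts) <- readLines(b)
  } else {
    tab <- utils::read.delim(counts_path, check.names = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab[[1]]
  }
  lab <- utils::read.delim(labels_path)
  if (!all(c("cell_id", "group") %in% names(lab)))
    stop("labels TSV must have columns cell_id and group")
  if (!is.null(colnames(counts))) {
    idx <- match(colnames(counts), lab$cell_id)
    if (anyNA(idx)) stop("some matrix cells have no label row")
    lab <- lab[idx, ]
  } else if (nrow(lab) != ncol(counts)) {
    stop("label rows do not match matrix columns")
  }
  f <- factor(lab$group)
  structure(
    list(counts = counts, labels = as.integer(f), params = NULL),
    label_names = levels(f),
    class = "labeled_dataset"
  )
}

#' Write / read a latent embedding as TSV
#'
#' TSV with a `cell_id` column followed by one column per latent dimension;
#' the method tag (method name plus full hyperparameter record) is stored as
#' a JSON comment line so re-running from the record is possible.
#'
#' @param embedding a `latent_embedding`.
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "latent_embedding"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method_tag: ", jsonlite::toJSON(
    embedding$method_tag, auto_unbox = TRUE, digits = NA)), con)
  df <- data.frame(cell_id = rownames(embedding$coords),
                   embedding$coords, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  first <- readLines(path, n = 1)
  tag <- NULL
  if (startsWith(first, "# method_tag: ")) {
    tag <- jsonlite::fromJSON(sub("^# method_tag: ", "", first),
                              simplifyVector = TRUE)
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  coords <- as.matrix(df[, -1, drop = FALSE])
  rownames(coords) <- df$cell_id
  latent_embedding(coords, method = if (is.null(tag$method)) "unknown"
                   else tag$method, params = tag)
}
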