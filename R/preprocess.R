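#' Normalized expression matrix container
#'
#' Thin S3 wrapper tracking which normalizations have been applied to a
#' genes x cells matrix.  Tags compose (e.g. `c("tpm", "log_tpm")`) and are
#' never silently overwritten.
#'
#' @param values genes x cells numeric matrix.
#' @param tags character vector of applied normalizations, in order.
#' @param gene_lengths optional positive gene lengths used for TPM.
#' @param scaler optional list of per-gene min/max used by zero-one scaling.
#' @return object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, tags = "raw", gene_lengths = NULL,
                              scaler = NULL) {
  structure(list(values = values, tags = tags, gene_lengths = gene_lengths,
                 scaler = scaler),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), paste(x$tags, collapse = " > ")))
  invisible(x)
}

as_value_matrix <- function(x) {
  if (inherits(x, "normalized_matrix")) x$values
  else if (inherits(x, "labeled_dataset")) x$counts
  else as.matrix(x)
}

existing_tags <- function(x) {
  if (inherits(x, "normalized_matrix")) x$tags else character(0)
}

#' TPM normalization
#'
#' Transcripts per kilobase million:
#' `tpm(g, c) = 1e6 * (count(g, c) / len(g)) / sum_g'(count(g', c) / len(g'))`.
#' Simulated counts carry no gene lengths, so by default unit lengths are
#' used and the transform reduces to counts per million.  Cells with zero
#' total are left all-zero and reported with a warning rather than scaled.
#'
#' @param counts genes x cells non-negative matrix (or `labeled_dataset` /
#'   `normalized_matrix`).
#' @param gene_lengths optional positive lengths (kilobase units are
#'   irrelevant: lengths enter as ratios).
#' @param log also apply `log1p`, tagging the result `log_tpm`.
#' @return a `normalized_matrix` tagged `tpm` (and `log_tpm` if `log`).
#' @export
tpm_normalize <- function(counts, gene_lengths = NULL, log = FALSE) {
  x <- as_value_matrix(counts)
  if (any(x < 0)) stop("counts must be non-negative")
  if (!is.null(gene_lengths)) {
    if (length(gene_lengths) != nrow(x) || any(gene_lengths <= 0))
      stop("gene_lengths must be positive, one per gene")
    x <- x / gene_lengths
  }
  tot <- colSums(x)
  empty <- tot == 0
  if (any(empty)) {
    warning(sprintf("%d cell(s) have zero total count; left all-zero",
                    sum(empty)))
    tot[empty] <- 1
  }
  vals <- sweep(x, 2, tot, "/") * 1e6
  tags <- c(existing_tags(counts)[existing_tags(counts) != "raw"], "tpm")
  if (log) {
    vals <- log1p(vals)
    tags <- c(tags, "log_tpm")
  }
  normalized_matrix(vals, tags = tags, gene_lengths = gene_lengths)
}

#' Per-gene zero-one (min-max) scaling
#'
#' Scales every gene to `[0, 1]` using its min and max.  Constant genes map
#' to 0.  The scaling parameters are stored in the result so held-out cells
#' can be scaled with the training-set min/max (values outside the training
#' range are clipped to `[0, 1]`), via the `scaler` argument.
#'
#' @param x genes x cells matrix (or `normalized_matrix`).
#' @param scaler optional scaler (from a previous call's `$scaler`) to apply
#'   instead of computing new parameters.
#' @return a `normalized_matrix` tagged `zero_one`, with `$scaler`.
#' @export
zero_one_scale <- function(x, scaler = NULL) {
  v <- as_value_matrix(x)
  if (any(!is.finite(v))) stop("matrix must be finite")
  if (is.null(scaler)) {
    mins <- apply(v, 1, min)
    maxs <- apply(v, 1, max)
    scaler <- list(mins = mins, maxs = maxs)
  }
  rng <- scaler$maxs - scaler$mins
  rng[rng == 0] <- 1    # constant genes -> 0 after centering
  out <- (v - scaler$mins) / rng
  out[out < 0] <- 0
  out[out > 1] <- 1
  normalized_matrix(out, tags = c(existing_tags(x), "zero_one"),
                    scaler = scaler)
}

#' Label-stratified train/test split
#'
#' Splits cell indices into disjoint, exhaustive train and test sets,
#' stratified by group label so small groups are represented in both parts.
#' A group with fewer cells than `1 / test_fraction` triggers a warning and
#' an unstratified fallback for the whole split.
#'
#' @param labels integer/factor label per cell, or a `labeled_dataset`.
#' @param test_fraction fraction of cells held out (default 0.1).
#' @param seed integer seed; the split is a pure function of
#'   (labels, test_fraction, seed).
#' @param stratify set `FALSE` to force a simple random split.
#' @return list with integer vectors `train` and `test`.
#' @export
split_train_test <- function(labels, test_fraction = 0.1, seed = 1L,
                             stratify = TRUE) {
  if (inherits(labels, "labeled_dataset")) labels <- labels$labels
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n <- length(labels)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (stratify && min(table(labels)) < ceiling(1 / test_fraction)) {
    warning("a group has fewer cells than 1/test_fraction; ",
            "falling back to an unstratified split")
    stratify <- FALSE
  }
  if (!stratify) {
    test <- sort(sample.int(n, round(n * test_fraction)))
  } else {
    test <- sort(unlist(lapply(split(seq_len(n), labels), function(idx) {
      sample(idx, round(length(idx) * test_fraction))
    }), use.names = FALSE))
  }
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Write / read a normalized matrix as TSV
#'
#' Full-precision TSV round-trip (gene rows, cell columns); the tag chain is
#' stored in a header comment.
#'
#' @param nm a `normalized_matrix`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_normalized <- function(nm, path) {
  stopifnot(inherits(nm, "normalized_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tags: ", paste(nm$tags, collapse = ",")), con)
  df <- data.frame(gene = rownames(nm$values) %||%
                     paste0("gene", seq_len(nrow(nm$values))),
                   format(nm$values, digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_normalized
#' @export
read_normalized <- function(path) {
  first <- readLines(path, n = 1)
  tags <- if (startsWith(first, "# tags: "))
    strsplit(sub("^# tags: ", "", first), ",")[[1]] else "raw"
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$gene
  normalized_matrix(v, tags = tags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
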