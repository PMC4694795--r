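# Multi-dataset expression matrices: assembly, read-support filtering and
# the three normalizations (sequencing depth, laboratory rescaling, rank).

#' Assemble a fragments-by-datasets expression matrix
#'
#' @param profiles list of `trf_profile` objects (see [profile_reads()]).
#' @return numeric matrix, rows = fragment labels (union, sorted),
#'   columns = dataset ids, values = raw counts. Attributes: `depths`
#'   (named per-dataset sequencing depths), `normalization = "raw"`.
#' @export
build_expression_matrix <- function(profiles) {
  ids <- vapply(profiles, function(p) p$dataset_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate dataset ids")
  labels <- sort(unique(unlist(lapply(profiles,
                                      function(p) p$counts$label))))
  m <- matrix(0, nrow = length(labels), ncol = length(profiles),
              dimnames = list(labels, ids))
  for (j in seq_along(profiles)) {
    ct <- profiles[[j]]$counts
    m[ct$label, j] <- ct$count
  }
  attr(m, "depths") <- setNames(
    vapply(profiles, function(p) p$total_reads, numeric(1)), ids)
  attr(m, "normalization") <- "raw"
  m
}

#' Filtering presets for read support
#'
#' Minimum read support per dataset and minimum number of supporting
#' datasets used for the three cohort types: `lcl` (30 reads in each of
#' at least 30 datasets), `brca` (30 reads / 20 datasets), `clip`
#' (30 reads / 3 datasets).
#'
#' @param name one of `"lcl"`, `"brca"`, `"clip"`.
#' @return list with `min_reads` and `min_datasets`.
#' @export
filter_preset <- function(name = c("lcl", "brca", "clip")) {
  name <- match.arg(name)
  switch(name,
         lcl = list(min_reads = 30, min_datasets = 30),
         brca = list(min_reads = 30, min_datasets = 20),
         clip = list(min_reads = 30, min_datasets = 3))
}

#' Filter lowly-supported fragments from a raw count matrix
#'
#' Keeps fragments (rows) whose raw count is at least `min_reads` in at
#' least `min_datasets` datasets; the column set is unchanged. Applied
#' to raw counts, before normalization.
#'
#' @param m raw count matrix from [build_expression_matrix()].
#' @param min_reads minimum reads per supporting dataset.
#' @param min_datasets minimum number of supporting datasets.
#' @param preset optional preset name (see [filter_preset()]); overrides
#'   the two thresholds.
#' @return the filtered matrix (attributes preserved).
#' @export
filter_matrix <- function(m, min_reads = 30, min_datasets = 1,
                          preset = NULL) {
  if (!is.null(preset)) {
    p <- filter_preset(preset)
    min_reads <- p$min_reads
    min_datasets <- p$min_datasets
  }
  if (min_datasets > ncol(m))
    stop("min_datasets (", min_datasets, ") exceeds the number of ",
         "datasets (", ncol(m), ")")
  keep <- rowSums(m >= min_reads) >= min_datasets
  out <- m[keep, , drop = FALSE]
  attr(out, "depths") <- attr(m, "depths")
  attr(out, "normalization") <- attr(m, "normalization")
  out
}

#' Normalize a count matrix by sequencing depth
#'
#' `value[i, j] = raw[i, j] * scale / depth[j]` (reads per million for
#' the default scale).
#'
#' @param m raw count matrix.
#' @param depths named per-dataset depths; defaults to the `depths`
#'   attribute set by [build_expression_matrix()].
#' @param scale scaling constant (default `1e6`, RPM).
#' @return depth-normalized matrix.
#' @export
depth_normalize <- function(m, depths = attr(m, "depths"), scale = 1e6) {
  if (is.null(depths)) stop("no depths supplied")
  if (!is.null(names(depths))) {
    missing_d <- setdiff(colnames(m), names(depths))
    if (length(missing_d) > 0)
      stop("missing depth for dataset(s): ",
           paste(missing_d, collapse = ", "))
    depths <- depths[colnames(m)]
  }
  if (any(depths <= 0)) stop("depths must be positive")
  out <- sweep(m, 2, depths / scale, "/")
  attr(out, "depths") <- depths
  attr(out, "normalization") <- "depth"
  out
}

#' Rescale datasets across sequencing laboratories
#'
#' For cohorts sequenced by several laboratories, uses samples sequenced
#' in every laboratory to estimate, per fragment and laboratory, the
#' ratio of the reference laboratory's mean abundance to that
#' laboratory's mean abundance over the shared samples, then multiplies
#' every dataset of the laboratory row-wise by this factor. Factors are
#' computed on depth-normalized values. Undefined factors (zero or
#' non-finite means) fall back to 1 with a warning.
#'
#' @param m depth-normalized matrix.
#' @param lab_of named character vector mapping dataset id to
#'   laboratory.
#' @param shared data.frame with columns `sample` and `dataset`: the
#'   replicate datasets of the samples sequenced in all laboratories.
#' @param ref_lab reference laboratory; defaults to the laboratory with
#'   the most datasets.
#' @return rescaled matrix.
#' @export
lab_rescale <- function(m, lab_of, shared, ref_lab = NULL) {
  if (is.null(names(lab_of))) stop("lab_of must be a named vector")
  missing_lab <- setdiff(colnames(m), names(lab_of))
  if (length(missing_lab) > 0)
    stop("no laboratory for dataset(s): ",
         paste(missing_lab, collapse = ", "))
  labs <- unique(unname(lab_of[colnames(m)]))
  if (is.null(ref_lab))
    ref_lab <- names(which.max(table(unname(lab_of[colnames(m)]))))
  if (!ref_lab %in% labs) stop("ref_lab '", ref_lab, "' has no datasets")
  if (nrow(shared) == 0) stop("no shared samples")
  shared$lab <- unname(lab_of[shared$dataset])
  lab_mean <- function(lab) {
    ds <- shared$dataset[shared$lab == lab]
    ds <- intersect(ds, colnames(m))
    if (length(ds) == 0)
      stop("laboratory '", lab, "' has no shared samples")
    rowMeans(m[, ds, drop = FALSE])
  }
  ref_mean <- lab_mean(ref_lab)
  out <- m
  n_fallback <- 0L
  for (lab in labs) {
    factor_f <- ref_mean / lab_mean(lab)
    und <- !is.finite(factor_f)
    n_fallback <- n_fallback + sum(und & lab != ref_lab)
    factor_f[und] <- 1
    cols <- colnames(m)[unname(lab_of[colnames(m)]) == lab]
    out[, cols] <- m[, cols, drop = FALSE] * factor_f
  }
  if (n_fallback > 0)
    warning(n_fallback,
            " undefined rescaling factor(s) replaced by 1")
  attr(out, "depths") <- attr(m, "depths")
  attr(out, "normalization") <- "depth+lab"
  out
}

#' Rank-normalize each dataset
#'
#' Within each column, every abundance is replaced by its ascending rank;
#' tied values receive the average of the ranks they span. Column sums
#' therefore equal `n(n+1)/2` for `n` fragments.
#'
#' @param m expression matrix.
#' @return rank matrix with the same dimnames.
#' @export
rank_normalize <- function(m) {
  out <- apply(m, 2, rank, ties.method = "average")
  if (is.null(dim(out)))  # single-row matrix
    out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  dimnames(out) <- dimnames(m)
  attr(out, "normalization") <- "rank"
  out
}

#' Write / read an expression matrix as TSV
#'
#' @param m matrix with fragment-label rownames and dataset colnames.
#' @param path file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix`
#'   returns the matrix.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
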