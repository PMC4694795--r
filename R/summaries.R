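# Cohort summaries: length distributions with standard errors,
# nuclear/mitochondrial decomposition, per-anticodon Pearson correlation
# matrices and Mann-Whitney group comparisons.

region_levels <- c("5p", "i", "3p")

#' Extract fragment annotation for the rows of an expression matrix
#'
#' @param lookup a `trf_lookup` (see [build_lookup()]).
#' @param labels fragment labels to annotate; defaults to all lookup
#'   rows.
#' @return data.frame with `label`, `region`, `length`, `frag_start`,
#'   `anticodon`, `origin`.
#' @export
fragment_info <- function(lookup, labels = lookup$label) {
  idx <- match(labels, lookup$label)
  if (anyNA(idx))
    stop("label(s) absent from lookup: ",
         paste(head(labels[is.na(idx)], 3), collapse = ", "))
  data.frame(label = labels, region = lookup$region[idx],
             length = lookup$length[idx],
             frag_start = lookup$frag_start[idx],
             anticodon = lookup$anticodon[idx],
             origin = lookup$origin[idx], stringsAsFactors = FALSE)
}

info_for <- function(m, info) {
  idx <- match(rownames(m), info$label)
  if (anyNA(idx))
    stop("fragment(s) of the matrix missing from the annotation: ",
         paste(head(rownames(m)[is.na(idx)], 3), collapse = ", "))
  info[idx, , drop = FALSE]
}

#' Per-length relative abundance distribution of a fragment region
#'
#' For every dataset, sums the abundance of the fragments of the chosen
#' region by fragment length and converts to fractions. By default the
#' denominator is the dataset's total abundance over *all* regions, so
#' the per-region panels of a figure share a common scale; set
#' `denominator = "region"` to normalize within the region. Group means
#' and standard errors (`sd/sqrt(n)`) are computed across datasets.
#'
#' @param m expression matrix (typically depth-normalized).
#' @param info fragment annotation from [fragment_info()].
#' @param region `"5p"`, `"i"`, `"3p"` or `"all"`.
#' @param groups optional named vector mapping dataset id to group; one
#'   group (`"all"`) when omitted.
#' @param lengths integer vector of lengths to tabulate.
#' @param denominator `"all"` or `"region"`.
#' @param pool_min optional length at which to pool: all lengths
#'   `>= pool_min` are reported as one `">=pool_min"` bin. Useful for
#'   data sequenced with 30 PCR cycles, where every longer molecule is
#'   represented by a 30-mer proxy; a presentation option only — the
#'   underlying matrix keeps true lengths.
#' @return object of class `length_distribution`: list with `region`,
#'   `fractions` (lengths x datasets matrix), and `summary`
#'   (data.frame `region`, `length`, `group`, `mean`, `se`, `n`).
#' @export
length_distribution <- function(m, info, region = "all", groups = NULL,
                                lengths = 16:50,
                                denominator = c("all", "region"),
                                pool_min = NULL) {
  denominator <- match.arg(denominator)
  info <- info_for(m, info)
  sel <- if (region == "all") rep(TRUE, nrow(m)) else
    info$region == region
  if (!any(sel))
    warning("no fragments in region '", region, "'")
  msel <- m[sel, , drop = FALSE]
  lensel <- factor(info$length[sel], levels = lengths)
  mass <- rowsum(msel, lensel)  # drops empty levels; reinflate
  full <- matrix(0, nrow = length(lengths), ncol = ncol(m),
                 dimnames = list(as.character(lengths), colnames(m)))
  full[rownames(mass), ] <- mass
  denom <- if (denominator == "all") colSums(m) else colSums(full)
  frac <- sweep(full, 2, ifelse(denom == 0, 1, denom), "/")
  length_labels <- lengths
  if (!is.null(pool_min) && any(lengths >= pool_min)) {
    pooled <- colSums(frac[lengths >= pool_min, , drop = FALSE])
    frac <- rbind(frac[lengths < pool_min, , drop = FALSE],
                  matrix(pooled, nrow = 1,
                         dimnames = list(paste0(">=", pool_min),
                                         colnames(frac))))
    length_labels <- rownames(frac)
  }
  if (is.null(groups)) groups <- setNames(rep("all", ncol(m)),
                                          colnames(m))
  grp <- unname(groups[colnames(m)])
  summ <- do.call(rbind, lapply(unique(grp), function(g) {
    cols <- which(grp == g)
    v <- frac[, cols, drop = FALSE]
    data.frame(region = region, length = length_labels, group = g,
               mean = rowMeans(v),
               se = apply(v, 1, sd) / sqrt(length(cols)),
               n = length(cols), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(region = region, fractions = frac, summary = summ),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("length_distribution (region %s): %d datasets\n",
              x$region, ncol(x$fractions)))
  top <- x$summary[order(-x$summary$mean), ][1:min(3, nrow(x$summary)), ]
  cat("  top lengths:",
      paste(sprintf("%s nt (%.3f)", top$length, top$mean),
            collapse = ", "), "\n")
  invisible(x)
}

#' Decompose fragment abundance by genomic origin
#'
#' Splits the per-length abundance of an expression matrix into its
#' nuclear and mitochondrial contributions. Fragments whose source-proxy
#' is a mitochondrial tRNA *or* an exact nuclear lookalike of one are
#' attributed to the mitochondrial panel (lookalikes carry the
#' mitochondrial tRNA's identity). Absolute per-length contributions of
#' the two panels sum to the combined totals.
#'
#' @inheritParams length_distribution
#' @return list with lengths x datasets abundance matrices `nuclear`,
#'   `mitochondrial` and `total`.
#' @export
decompose_by_origin <- function(m, info, region = "all",
                                lengths = 16:50) {
  info <- info_for(m, info)
  sel <- if (region == "all") rep(TRUE, nrow(m)) else
    info$region == region
  mito <- info$origin %in% c("mitochondrial", "lookalike")
  sum_mass <- function(which_rows) {
    full <- matrix(0, nrow = length(lengths), ncol = ncol(m),
                   dimnames = list(as.character(lengths), colnames(m)))
    if (any(which_rows)) {
      mass <- rowsum(m[which_rows, , drop = FALSE],
                     factor(info$length[which_rows], levels = lengths))
      full[rownames(mass), ] <- mass
    }
    full
  }
  list(nuclear = sum_mass(sel & !mito),
       mitochondrial = sum_mass(sel & mito),
       total = sum_mass(sel))
}

#' Pearson correlation matrix of an anticodon's fragments
#'
#' Correlates (across datasets) the abundances of all fragments whose
#' source-proxy carries the given anticodon. Rows are ordered by
#' (region, fragment start, length) with regions ordered 5p, i, 3p.
#' Fragments with zero variance across datasets get `NA` correlations.
#'
#' @param m expression matrix.
#' @param info fragment annotation from [fragment_info()].
#' @param anticodon anticodon name, e.g. `"AspGTC"`.
#' @param origin optional origin filter (`"nuclear"`,
#'   `"mitochondrial"`, `"lookalike"`).
#' @return symmetric correlation matrix with fragment labels as
#'   dimnames.
#' @export
anticodon_correlation <- function(m, info, anticodon, origin = NULL) {
  info <- info_for(m, info)
  sel <- info$anticodon == anticodon
  if (!is.null(origin)) sel <- sel & info$origin %in% origin
  if (sum(sel) < 2)
    stop("need at least 2 fragments for anticodon '", anticodon, "'")
  if (ncol(m) < 3) stop("need at least 3 datasets")
  sub <- m[sel, , drop = FALSE]
  isub <- info[sel, , drop = FALSE]
  ord <- order(match(isub$region, region_levels), isub$frag_start,
               isub$length)
  sub <- sub[ord, , drop = FALSE]
  novar <- apply(sub, 1, sd) == 0
  cc <- suppressWarnings(cor(t(sub)))
  diag(cc) <- 1
  if (any(novar)) {
    cc[novar, ] <- NA_real_
    cc[, novar] <- NA_real_
    warning(sum(novar), " zero-variance fragment(s): correlations ",
            "reported as NA")
  }
  cc
}

#' Mann-Whitney U comparison of two dataset groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with tie correction.
#' The U statistic reported is for the first group
#' (`U = R1 - n1(n1+1)/2`, so `U` lies in `[0, n1*n2]`); an exact
#' p-value is used for small untied samples and the normal approximation
#' otherwise.
#'
#' @param values_a,values_b numeric vectors (both nonempty).
#' @param exact_limit use the exact distribution when both groups are
#'   smaller than this and there are no ties.
#' @return object of class `group_comparison`: list with `U`,
#'   `p_value`, `n1`, `n2`.
#' @export
compare_groups <- function(values_a, values_b, exact_limit = 50) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both groups must be nonempty")
  n1 <- length(values_a)
  n2 <- length(values_b)
  r <- rank(c(values_a, values_b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  if (length(unique(c(values_a, values_b))) == 1) {
    warning("all values tied across both groups")
    p <- 1
  } else {
    p <- suppressWarnings(wilcox.test(
      values_a, values_b,
      exact = !ties && n1 < exact_limit && n2 < exact_limit,
      correct = TRUE))$p.value
  }
  structure(list(U = U, p_value = min(1, p), n1 = n1, n2 = n2),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), p = %.4g\n",
              x$U, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Table underlying a start-position / length abundance landscape
#'
#' Mean abundance of each (fragment start, length) combination across
#' datasets — the data behind 3-D start/length renderings of internal
#' fragment repertoires.
#'
#' @inheritParams length_distribution
#' @param region region to tabulate (default the internal region).
#' @return data.frame `frag_start`, `length`, `mean_abundance`.
#' @export
start_length_table <- function(m, info, region = "i") {
  info <- info_for(m, info)
  sel <- info$region == region
  if (!any(sel))
    return(data.frame(frag_start = integer(0), length = integer(0),
                      mean_abundance = numeric(0)))
  mean_ab <- rowMeans(m[sel, , drop = FALSE])
  agg <- rowsum(mean_ab,
                paste(info$frag_start[sel], info$length[sel], sep = "_"))
  key <- do.call(rbind, strsplit(rownames(agg), "_", fixed = TRUE))
  out <- data.frame(frag_start = as.integer(key[, 1]),
                    length = as.integer(key[, 2]),
                    mean_abundance = as.numeric(agg[, 1]))
  out[order(out$frag_start, out$length), ]
}
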