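#' Median-of-ratios size factors
#'
#' Per-sample normalization constants for a raw count matrix: the
#' reference profile is the per-gene geometric mean across samples, and
#' a sample's factor is the median, over genes expressed in every
#' sample, of the ratio of its count to the reference,
#' \deqn{f_j = \mathrm{median}_g \, ( c_{gj} / (\prod_k c_{gk})^{1/J} ).}
#' Sequencing-depth differences move all ratios together, so the median
#' tracks depth while staying insensitive to a minority of
#' differentially expressed genes.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (ncol(counts) < 1L) stop("no samples", call. = FALSE)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    stop("no gene has nonzero counts in every sample; cannot compute ",
         "median-of-ratios size factors", call. = FALSE)
  }
  geo <- exp(rowMeans(log(counts[ok, , drop = FALSE])))
  f <- apply(counts[ok, , drop = FALSE] / geo, 2, median)
  if (is.null(names(f))) names(f) <- colnames(counts)
  f
}

#' Normalize a count matrix
#'
#' Drops unexpressed genes (zero total count across samples), then
#' divides each column by its median-of-ratios size factor.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param factors optional precomputed size factors; computed with
#'   [size_factors()] on the filtered matrix when `NULL`.
#' @return matrix of normalized counts (same orientation, unexpressed
#'   genes removed).
#' @export
normalize_counts <- function(counts, factors = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (is.null(factors)) factors <- size_factors(counts)
  if (any(factors <= 0)) stop("size factors must be positive", call. = FALSE)
  sweep(counts, 2, factors, "/")
}

#' Bin normalized expression into resistance categories
#'
#' Three-way binning of normalized read counts as used for efflux-pump
#' (ABCB1) expression: `low` for 0--99, `mid` for 100--1000 (both
#' boundaries inclusive), `high` for strictly more than 1000 normalized
#' reads. The bins partition `[0, Inf)` with no gaps or overlaps.
#'
#' @param normalized_reads non-negative numeric vector.
#' @return factor with levels `low`, `mid`, `high`.
#' @examples
#' bin_expression(c(99, 100, 1000, 1000.5))
#' @export
bin_expression <- function(normalized_reads) {
  if (any(normalized_reads < 0) || anyNA(normalized_reads)) {
    stop("normalized reads must be non-negative and non-missing",
         call. = FALSE)
  }
  factor(
    ifelse(normalized_reads < 100, "low",
           ifelse(normalized_reads <= 1000, "mid", "high")),
    levels = c("low", "mid", "high")
  )
}

# All stratified group assignments: for each batch stratum, choose which
# of its samples are labelled group A, preserving per-stratum group
# sizes. Returns a logical matrix (samples x assignments), TRUE = A.
# NULL when the number of assignments exceeds `limit`.
enumerate_assignments <- function(is_a, batch, limit) {
  strata <- split(seq_along(is_a), batch)
  per <- lapply(strata, function(idx) {
    k <- sum(is_a[idx])
    combn(idx, k, simplify = FALSE)
  })
  total <- prod(vapply(per, length, numeric(1)))
  if (total > limit) return(NULL)
  grid <- expand.grid(lapply(per, seq_along))
  out <- matrix(FALSE, nrow = length(is_a), ncol = nrow(grid))
  for (r in seq_len(nrow(grid))) {
    for (s in seq_along(per)) {
      out[per[[s]][[grid[r, s]]], r] <- TRUE
    }
  }
  out
}

#' Batch-stratified permutation test for differential expression
#'
#' A nonparametric substitute for a negative-binomial GLM fit: counts
#' are normalized by median-of-ratios size factors, transformed to
#' `log2(x + 1)`, and mean-centered per batch and gene (a
#' removeBatchEffect-style adjustment). The per-gene statistic is the
#' difference of group means in this adjusted space — the batch-adjusted
#' log2 fold change. Significance comes from permuting the group labels
#' within each batch stratum (so label/batch confounding cannot
#' masquerade as signal): when the number of distinct stratified
#' assignments is at most `n_perm` they are enumerated exhaustively and
#' the p-value is the exact fraction of assignments with `|stat| >=
#' |observed|`; otherwise `n_perm` random assignments are drawn and the
#' add-one estimate `(1 + #extreme) / (1 + n_perm)` is used. q-values
#' are Benjamini-Hochberg.
#'
#' @param counts raw count matrix, genes x samples (column names are
#'   sample ids).
#' @param group_a,group_b character vectors of sample ids for the two
#'   groups (>= 2 each).
#' @param batch optional named vector mapping each used sample to a
#'   batch label; a batch whose samples all lie in one group makes the
#'   stratified permutation impossible and is rejected.
#' @param n_perm permutation budget (default 10000).
#' @param seed seed for the sampled-permutation branch.
#' @return data.frame with columns `gene`, `log2fc` (A vs B), `p`, `q`,
#'   ordered as the (filtered) input genes.
#' @export
de_test <- function(counts, group_a, group_b, batch = NULL,
                    n_perm = 10000, seed = 1) {
  counts <- as.matrix(counts)
  used <- c(group_a, group_b)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  if (anyDuplicated(used)) stop("a sample appears in both groups", call. = FALSE)
  if (!all(used %in% colnames(counts))) {
    stop("group sample(s) absent from the count matrix: ",
         paste(setdiff(used, colnames(counts)), collapse = ", "),
         call. = FALSE)
  }
  counts <- counts[, used, drop = FALSE]
  if (is.null(batch)) {
    batch <- setNames(rep("b1", length(used)), used)
  }
  if (!all(used %in% names(batch))) {
    stop("batch label missing for sample(s): ",
         paste(setdiff(used, names(batch)), collapse = ", "), call. = FALSE)
  }
  batch <- as.character(batch[used])
  is_a <- used %in% group_a
  for (b in unique(batch)) {
    in_b <- batch == b
    if (all(is_a[in_b]) || all(!is_a[in_b])) {
      stop("batch '", b, "' lies entirely within one group; stratified ",
           "permutation is impossible", call. = FALSE)
    }
  }

  norm <- normalize_counts(counts)
  l2 <- log2(norm + 1)
  # per-gene, per-batch centering (keeps the grand mean irrelevant to
  # the group-difference statistic)
  for (b in unique(batch)) {
    in_b <- batch == b
    l2[, in_b] <- l2[, in_b, drop = FALSE] -
      rowMeans(l2[, in_b, drop = FALSE])
  }
  w_of <- function(a) {
    w <- ifelse(a, 1 / sum(a), -1 / sum(!a))
    w
  }
  obs <- drop(l2 %*% w_of(is_a))

  exact <- enumerate_assignments(is_a, batch, n_perm)
  if (!is.null(exact)) {
    W <- apply(exact, 2, w_of)
    stats <- l2 %*% W
    p <- rowMeans(abs(stats) >= abs(obs) - 1e-12)
  } else {
    p <- with_seed(seed, {
      hits <- numeric(nrow(l2))
      strata <- split(seq_along(is_a), batch)
      for (r in seq_len(n_perm)) {
        perm <- logical(length(is_a))
        for (idx in strata) {
          perm[sample(idx, sum(is_a[idx]))] <- TRUE
        }
        stat <- drop(l2 %*% w_of(perm))
        hits <- hits + (abs(stat) >= abs(obs) - 1e-12)
      }
      (1 + hits) / (1 + n_perm)
    })
  }
  data.frame(
    gene = rownames(l2),
    log2fc = unname(obs),
    p = unname(p),
    q = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Volcano table of differential-expression results
#'
#' Effect size against evidence: `log2fc` on the x axis,
#' `-log10(p)` on the y axis, with a significance flag at `q <= 0.05`.
#'
#' @param de_results output of [de_test()].
#' @param q_cutoff significance threshold on the BH q-value.
#' @return data.frame with columns `gene`, `log2fc`, `neg_log10_p`,
#'   `significant`.
#' @export
volcano <- function(de_results, q_cutoff = 0.05) {
  if (nrow(de_results) == 0L) {
    return(data.frame(gene = character(0), log2fc = numeric(0),
                      neg_log10_p = numeric(0), significant = logical(0)))
  }
  data.frame(
    gene = de_results$gene,
    log2fc = de_results$log2fc,
    neg_log10_p = -log10(de_results$p),
    significant = de_results$q <= q_cutoff,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Simulate a cohort count matrix with an efflux-pump-high subgroup
#'
#' Negative-binomial gene x sample counts with per-sample sequencing
#' depth, a log-additive gene x batch offset, and one designated
#' resistance gene (default `"ABCB1"`) drawn highly expressed
#' (normalized mean well above 1000) in a chosen number of progression
#' samples and low (below 100) everywhere else. The truth component
#' records the depth factors (centered to geometric mean 1, i.e. the
#' true size factors), the high samples and the planted gene, so both
#' normalization and binning can be scored.
#'
#' @param n_genes number of background genes (the planted gene is one of
#'   them).
#' @param group_labels character vector of response groups, one per
#'   sample.
#' @param batch_labels optional character vector of batch labels, one
#'   per sample (single batch when `NULL`).
#' @param abcb1_spec list with `gene` (name), `n_high` (number of
#'   progression samples drawn high), `high_mean` and `low_mean`
#'   (normalized-scale means).
#' @param depth_sdlog log-normal sd of per-sample depth factors.
#' @param batch_sdlog log-normal sd of the gene x batch offsets.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`;
#'   0 gives Poisson).
#' @param mean_meanlog,mean_sdlog log-normal parameters of background
#'   gene means.
#' @param seed integer seed.
#' @return list with `counts` (matrix), `meta` (data.frame sample_id,
#'   group, batch) and `truth` (list: `size_factors`, `abcb1_high`,
#'   `de_gene`).
#' @export
gen_counts <- function(n_genes = 2000, group_labels,
                       batch_labels = NULL,
                       abcb1_spec = list(gene = "ABCB1", n_high = 2,
                                         high_mean = 6000, low_mean = 20),
                       depth_sdlog = 0.25, batch_sdlog = 0.2,
                       dispersion = 0.1,
                       mean_meanlog = log(100), mean_sdlog = 1,
                       seed = 1) {
  n_samples <- length(group_labels)
  if (n_samples < 2L) stop("need at least two samples", call. = FALSE)
  if (is.null(batch_labels)) batch_labels <- rep("b1", n_samples)
  if (length(batch_labels) != n_samples) {
    stop("`batch_labels` length must match `group_labels`", call. = FALSE)
  }
  prog <- which(group_labels == "progression")
  if (abcb1_spec$n_high > length(prog)) {
    stop("fewer progression samples than requested ABCB1-high samples",
         call. = FALSE)
  }
  with_seed(seed, {
    sample_id <- sprintf("S%03d", seq_len(n_samples))
    genes <- sprintf("G%05d", seq_len(n_genes))
    genes[1L] <- abcb1_spec$gene
    mu <- rlnorm(n_genes, mean_meanlog, mean_sdlog)
    depth <- rlnorm(n_samples, 0, depth_sdlog)
    depth <- depth / exp(mean(log(depth)))  # true size factors, geomean 1
    batches <- unique(batch_labels)
    offset <- matrix(rlnorm(n_genes * length(batches), 0, batch_sdlog),
                     nrow = n_genes, dimnames = list(genes, batches))
    if (length(batches) == 1L) offset[] <- 1

    high <- if (abcb1_spec$n_high > 0) {
      sort(sample(prog, abcb1_spec$n_high))
    } else integer(0)
    mu_mat <- outer(mu, depth) * offset[, batch_labels, drop = FALSE]
    mu_mat[1L, ] <- abcb1_spec$low_mean * depth
    if (length(high)) mu_mat[1L, high] <- abcb1_spec$high_mean * depth[high]

    size <- if (dispersion > 0) 1 / dispersion else Inf
    counts <- matrix(
      if (is.finite(size)) {
        rnbinom(length(mu_mat), mu = mu_mat, size = size)
      } else {
        stats::rpois(length(mu_mat), lambda = mu_mat)
      },
      nrow = n_genes, dimnames = list(genes, sample_id)
    )
    list(
      counts = counts,
      meta = data.frame(sample_id = sample_id, group = group_labels,
                        batch = batch_labels, stringsAsFactors = FALSE),
      truth = list(size_factors = setNames(depth, sample_id),
                   abcb1_high = sample_id[high],
                   de_gene = abcb1_spec$gene)
    )
  })
}
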