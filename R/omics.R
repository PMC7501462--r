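# Cross-strain omics utilities: regulon-profile time-point alignment by
# monotone dynamic programming, proteome PCA with variance-explained
# reporting, and per-feature Z-scoring for heatmaps.

#' Expression matrix container
#'
#' @param values numeric matrix, features x samples.
#' @param samples tibble with one row per column of `values`: `sample_id`,
#'   `strain`, `time_h`, `replicate`.
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(values, samples) {
  samples <- as_tibble(samples)
  stopifnot(ncol(values) == nrow(samples))
  if (anyDuplicated(rownames(values))) {
    abort("duplicated feature ids", class = "switchflux_usage_error")
  }
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' Build an expression matrix from a long table
#'
#' @param tbl tibble with columns `feature_id`, `strain`, `time_h`,
#'   `replicate`, `value`.
#' @return an `expression_matrix`.
#' @export
as_expression_matrix <- function(tbl) {
  tbl <- mutate(as_tibble(tbl),
                sample_id = paste(.data$strain, .data$time_h,
                                  .data$replicate, sep = "_"))
  wide <- tidyr::pivot_wider(tbl, id_cols = "feature_id",
                             names_from = "sample_id",
                             values_from = "value")
  values <- as.matrix(wide[, -1])
  rownames(values) <- wide$feature_id
  samples <- distinct(tbl, .data$sample_id, .data$strain, .data$time_h,
                      .data$replicate)
  expression_matrix(values, samples[match(colnames(values),
                                          samples$sample_id), ])
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  flag <- is.na(s) | s == 0
  z <- (m - mu) / ifelse(flag, 1, s)
  z[flag, ] <- 0
  list(z = z, flag = flag)
}

#' Align strain time points by a regulon's expression profile
#'
#' Each strain's regulon genes are Z-scored over time and averaged into one
#' profile per time point; the monotone pairing of the two profiles that
#' minimizes the total squared distance (dynamic programming over monotone
#' maps) is returned. Identical inputs give the identity alignment with
#' score 0.
#'
#' @param expr_a,expr_b `expression_matrix` of the two strains (replicates
#'   averaged per time point internally).
#' @param regulon character vector of feature ids (e.g., a
#'   phosphate-starvation regulon).
#' @return an `alignment_map` tibble with columns `index_a`, `index_b`,
#'   `time_a`, `time_b`; attribute `score`.
#' @export
align_by_regulon <- function(expr_a, expr_b, regulon) {
  profile_of <- function(expr) {
    feats <- intersect(regulon, rownames(expr$values))
    if (!length(feats)) {
      abort("regulon has no overlap with the expression features",
            class = "switchflux_usage_error")
    }
    sub <- expr$values[feats, , drop = FALSE]
    times <- sort(unique(expr$samples$time_h))
    avg <- vapply(times, function(t) {
      rowMeans(sub[, expr$samples$time_h == t, drop = FALSE])
    }, numeric(length(feats)))
    if (length(feats) == 1) avg <- matrix(avg, nrow = 1)
    z <- zscore_rows(avg)$z
    list(profile = colMeans(z), times = times)
  }
  a <- profile_of(expr_a)
  b <- profile_of(expr_b)
  na <- length(a$profile)
  nb <- length(b$profile)
  cost <- outer(a$profile, b$profile, function(x, y) (x - y)^2)
  D <- matrix(Inf, na, nb)
  D[1, 1] <- cost[1, 1]
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (i == 1 && j == 1) next
      prev <- Inf
      if (i > 1) prev <- min(prev, D[i - 1, j])
      if (j > 1) prev <- min(prev, D[i, j - 1])
      if (i > 1 && j > 1) prev <- min(prev, D[i - 1, j - 1])
      D[i, j] <- cost[i, j] + prev
    }
  }
  # backtrack
  i <- na; j <- nb
  pairs <- list(c(i, j))
  while (i > 1 || j > 1) {
    opts <- c(if (i > 1 && j > 1) D[i - 1, j - 1] else Inf,
              if (i > 1) D[i - 1, j] else Inf,
              if (j > 1) D[i, j - 1] else Inf)
    step <- which.min(opts)
    if (step == 1) { i <- i - 1; j <- j - 1 }
    else if (step == 2) i <- i - 1
    else j <- j - 1
    pairs[[length(pairs) + 1]] <- c(i, j)
  }
  pairs <- do.call(rbind, rev(pairs))
  out <- tibble(index_a = pairs[, 1], index_b = pairs[, 2],
                time_a = a$times[pairs[, 1]], time_b = b$times[pairs[, 2]])
  structure(out, class = c("alignment_map", class(out)), score = D[na, nb])
}

#' Principal-component scores of an expression matrix
#'
#' Samples are projected on the principal components of the (centered,
#' optionally unit-scaled) feature space. The sign convention makes each
#' component's largest-magnitude loading positive. Zero-variance features
#' are dropped with a warning before scaling.
#'
#' @param expr an `expression_matrix`.
#' @param n_components number of components to return (truncated to the
#'   rank, with a warning).
#' @param scale. unit-scale features (default TRUE).
#' @return a `pca_result`: list with `scores` (tibble: sample metadata plus
#'   `PC1..PCk`), `variance` (tibble: `component`, `variance_pct`) and
#'   `loadings`.
#' @export
pca_scores <- function(expr, n_components = 2, scale. = TRUE) {
  X <- t(expr$values)
  if (nrow(X) < 2) {
    abort("need at least 2 samples", class = "switchflux_usage_error")
  }
  keep <- apply(X, 2, sd) > 0
  if (!all(keep)) {
    warn(paste0("dropping ", sum(!keep), " zero-variance feature(s)"))
    X <- X[, keep, drop = FALSE]
  }
  p <- prcomp(X, center = TRUE, scale. = scale.)
  rank <- sum(p$sdev > 1e-12)
  if (n_components > rank) {
    warn(paste0("n_components reduced to rank ", rank))
    n_components <- rank
  }
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  loadings <- p$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    top <- which.max(abs(loadings[, k]))
    if (loadings[top, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  var_pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(
    list(scores = bind_cols(expr$samples, as_tibble(scores)),
         variance = tibble(component = paste0("PC", seq_len(n_components)),
                           variance_pct = var_pct[seq_len(n_components)]),
         loadings = loadings),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$variance), " components; variance explained: ",
      paste(sprintf("%.1f%%", x$variance$variance_pct), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) x$scores

#' @export
glance.pca_result <- function(x, ...) {
  tidyr::pivot_wider(x$variance, names_from = "component",
                     values_from = "variance_pct")
}

#' Per-feature Z-scoring of an expression matrix
#'
#' Optionally log2(x + pseudocount) transforms non-negative values first.
#' Zero-variance features are emitted as 0 and flagged.
#'
#' @param expr an `expression_matrix`.
#' @param log_transform logical.
#' @param pseudocount added before the log transform.
#' @return an `expression_matrix` of Z-scores with attribute
#'   `zero_variance` (feature ids).
#' @export
zscore_expression <- function(expr, log_transform = FALSE, pseudocount = 1) {
  v <- expr$values
  if (log_transform) {
    if (any(v < 0)) {
      abort("log transform requires non-negative values",
            class = "switchflux_usage_error")
    }
    v <- log2(v + pseudocount)
  }
  zs <- zscore_rows(v)
  out <- expression_matrix(zs$z, expr$samples)
  attr(out, "zero_variance") <- rownames(v)[zs$flag]
  out
}
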