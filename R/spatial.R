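#' Cell-to-cell spatial relationship metrics
#'
#' Two metrics over phenotyped cell tables, computed per sample on the
#' global mosaic coordinates (2-D, micrometres): the average number of
#' type-B cells within 15 µm of each type-A cell (proximity), and the
#' median distance from each type-A cell to its nearest type-B cell.
#' Cross-sample distances are never computed; edge effects at section
#' borders are not corrected.
#'
#' @name spatial
NULL

spatial_pair <- function(table, type_A, type_B, sample) {
  sub <- table[table$sample_id == sample, ]
  list(a = as.matrix(sub[sub$phenotype == type_A, c("x_um", "y_um")]),
       b = as.matrix(sub[sub$phenotype == type_B, c("x_um", "y_um")]))
}

# Pairwise Euclidean distances between two 2-D point sets, from explicit
# coordinate differences (exact; no catastrophic cancellation).
cross_dist <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2)
}

spatial_metric_result <- function(sample_id, type_A, type_B, metric,
                                  value, n_A, n_B, defined = TRUE) {
  structure(list(sample_id = sample_id, type_A = type_A, type_B = type_B,
                 metric = metric, value = value, n_A = n_A, n_B = n_B,
                 defined = defined),
            class = "spatial_metric_result")
}

#' @export
print.spatial_metric_result <- function(x, ...) {
  cat("<spatial_metric_result> ", x$metric, " ", x$type_A, " -> ",
      x$type_B, " [", x$sample_id, "]: ",
      if (x$defined) signif(x$value, 6) else "undefined",
      " (n_A=", x$n_A, ", n_B=", x$n_B, ")\n", sep = "")
  invisible(x)
}

#' Mean proximity count within a radius
#'
#' For each cell of `type_A`, counts the cells of `type_B` whose centroid
#' lies within `radius_um` (inclusive boundary: a pair at exactly the
#' radius counts); when `type_A == type_B` the cell itself is excluded.
#' The reported value is the mean count over the type-A cells of the
#' sample.
#'
#' @param table a phenotyped cell table.
#' @param type_A,type_B phenotype labels.
#' @param radius_um proximity radius in micrometres (default 15).
#' @param sample_id sample to evaluate; default the single sample present.
#' @return A `spatial_metric_result`; `defined = FALSE` (value `NA`) when
#'   either phenotype is absent from the sample.
#' @export
proximity_count <- function(table, type_A, type_B, radius_um = 15,
                            sample_id = NULL) {
  if (is.null(table$phenotype)) stop("run assign_phenotypes() first")
  if (is.null(sample_id)) {
    sample_id <- unique(table$sample_id)
    if (length(sample_id) > 1L) stop("multiple samples; give sample_id")
  }
  p <- spatial_pair(table, type_A, type_B, sample_id)
  if (!nrow(p$a) || !nrow(p$b)) {
    return(spatial_metric_result(sample_id, type_A, type_B,
                                 "proximity_count", NA_real_,
                                 nrow(p$a), nrow(p$b), defined = FALSE))
  }
  d <- cross_dist(p$a, p$b)
  hits <- d <= radius_um
  counts <- rowSums(hits)
  if (type_A == type_B) counts <- counts - 1  # self-distance 0 always hits
  spatial_metric_result(sample_id, type_A, type_B, "proximity_count",
                        mean(counts), nrow(p$a), nrow(p$b))
}

#' Median nearest-neighbour distance between phenotypes
#'
#' For each cell of `type_A`, the distance to the nearest `type_B` cell
#' (self excluded when the types coincide); the reported value is the
#' median over type-A cells (linear interpolation for even counts).
#'
#' @inheritParams proximity_count
#' @return A `spatial_metric_result` in micrometres; undefined when a
#'   phenotype is absent, or when `type_A == type_B` with fewer than two
#'   cells.
#' @export
nearest_neighbor_distance <- function(table, type_A, type_B,
                                      sample_id = NULL) {
  if (is.null(table$phenotype)) stop("run assign_phenotypes() first")
  if (is.null(sample_id)) {
    sample_id <- unique(table$sample_id)
    if (length(sample_id) > 1L) stop("multiple samples; give sample_id")
  }
  p <- spatial_pair(table, type_A, type_B, sample_id)
  same <- type_A == type_B
  if (!nrow(p$a) || !nrow(p$b) || (same && nrow(p$a) < 2L)) {
    return(spatial_metric_result(sample_id, type_A, type_B, "nn_distance",
                                 NA_real_, nrow(p$a), nrow(p$b),
                                 defined = FALSE))
  }
  d <- cross_dist(p$a, p$b)
  if (same) diag(d) <- Inf
  nn <- apply(d, 1, min)
  spatial_metric_result(sample_id, type_A, type_B, "nn_distance",
                        stats::median(nn), nrow(p$a), nrow(p$b))
}

#' All pairwise spatial metrics for a sample
#'
#' Convenience wrapper evaluating both metrics over every ordered pair of
#' the given phenotypes.
#'
#' @param table a phenotyped cell table.
#' @param phenotypes labels to cross; default all assigned labels.
#' @param radius_um proximity radius.
#' @param sample_id sample to evaluate.
#' @return A long data.frame with one row per (pair, metric).
#' @export
spatial_metrics_table <- function(table, phenotypes = NULL, radius_um = 15,
                                  sample_id = NULL) {
  if (is.null(phenotypes)) {
    phenotypes <- setdiff(sort(unique(table$phenotype)), "unassigned")
  }
  rows <- list()
  for (a in phenotypes) for (b in phenotypes) {
    for (res in list(proximity_count(table, a, b, radius_um, sample_id),
                     nearest_neighbor_distance(table, a, b, sample_id))) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = res$sample_id, type_A = a, type_B = b,
        metric = res$metric, value = res$value,
        n_A = res$n_A, n_B = res$n_B, defined = res$defined,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
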