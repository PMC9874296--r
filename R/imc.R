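#' Imaging mass cytometry single-cell pipeline
#'
#' From a per-cell intensity table (one row per segmented cell; columns
#' `cell_id, sample_id, roi_id, x_um, y_um, area_um2, <channel>...`):
#' z-normalisation, per-channel two-component Gaussian-mixture positivity
#' gating, K-means clustering on the z-scores, canonical-marker phenotype
#' assignment at the cluster level, and per-sample cell-type ratios.
#'
#' @name imc
NULL

RESERVED_CELL_COLS <- c("cell_id", "sample_id", "roi_id", "x_um", "y_um",
                        "area_um2", "cluster_id", "phenotype")

#' Channel columns of a cell table
#'
#' All columns that are not structural (`cell_id`, coordinates, ...) and
#' not derived (`z_*`, `pos_*`) are treated as raw channel intensities.
#'
#' @param table a cell table data.frame.
#' @return Character vector of channel names.
#' @export
cell_channels <- function(table) {
  cols <- setdiff(colnames(table), RESERVED_CELL_COLS)
  cols[!grepl("^(z|pos)_", cols)]
}

#' Define a cell phenotype by canonical markers
#'
#' @param name phenotype label.
#' @param positive channels that must be expressed (at least one).
#' @param negative channels that must not be expressed; disjoint from
#'   `positive`.
#' @param priority optional numeric priority; lower matches first. When
#'   omitted, list order is the priority.
#' @return An object of class `phenotype_definition`.
#' @export
phenotype_definition <- function(name, positive, negative = character(),
                                 priority = NULL) {
  if (!length(positive)) stop("phenotype '", name, "' needs at least one ",
                              "required-positive channel")
  if (length(intersect(positive, negative))) {
    stop("phenotype '", name, "' lists ",
         paste(intersect(positive, negative), collapse = ", "),
         " as both positive and negative")
  }
  structure(list(name = name, required_positive = positive,
                 required_negative = negative, priority = priority),
            class = "phenotype_definition")
}

#' Canonical lymph-node phenotype panel
#'
#' The phenotype rules used throughout: follicular dendritic cells
#' (CD21+CD20-), follicular B cells (CD20+Bcl6+), B cells (CD20+Bcl6-),
#' regulatory T cells (CD4+FoxP3+), T follicular helper cells (CD3+Bcl6+),
#' cytotoxic T cells (CD3+CD8+), helper T cells (CD3+CD4+), macrophages
#' (CD68+) and antigen-presenting cells (MHCII+), in that priority order
#' (most marker-specific first).
#'
#' @return An ordered list of [phenotype_definition]s.
#' @export
default_phenotypes <- function() {
  list(
    phenotype_definition("follicular_dendritic_cell", "CD21", "CD20"),
    phenotype_definition("follicular_B_cell", c("CD20", "Bcl6")),
    phenotype_definition("B_cell", "CD20", "Bcl6"),
    phenotype_definition("regulatory_T_cell", c("CD4", "FoxP3")),
    phenotype_definition("T_follicular_helper", c("CD3", "Bcl6")),
    phenotype_definition("cytotoxic_T_cell", c("CD3", "CD8")),
    phenotype_definition("helper_T_cell", c("CD3", "CD4")),
    phenotype_definition("macrophage", "CD68"),
    phenotype_definition("antigen_presenting_cell", "MHCII")
  )
}

#' Z-normalise channel intensities
#'
#' Adds a `z_<channel>` column per channel: `(x - mean) / sd` with the
#' population SD convention, computed per sample (default) or pooled over
#' the whole table. Raw intensities are retained.
#'
#' @param table a cell table.
#' @param scope `"per_sample"` or `"pooled"`.
#' @param channels channels to normalise; default all raw channels.
#' @return The table with `z_*` columns appended.
#' @export
znormalize <- function(table, scope = c("per_sample", "pooled"),
                       channels = cell_channels(table)) {
  scope <- match.arg(scope)
  groups <- if (scope == "per_sample") table$sample_id else
    rep("all", nrow(table))
  for (ch in channels) {
    z <- rep(NA_real_, nrow(table))
    for (g in unique(groups)) {
      idx <- groups == g
      x <- table[[ch]][idx]
      mu <- mean(x)
      sdp <- sqrt(mean((x - mu)^2))
      if (!is.finite(sdp) || sdp == 0) {
        stop("channel '", ch, "' has zero variance in scope '", g, "'")
      }
      z[idx] <- (x - mu) / sdp
    }
    table[[paste0("z_", ch)]] <- z
  }
  table
}

# One EM run for a univariate 2-component Gaussian mixture.
em_gmm2 <- function(x, mu, sd2, w, max_iter, tol) {
  n <- length(x)
  sd_floor <- max(stats::sd(x), .Machine$double.eps) * 1e-4
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd2[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd2[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      return(list(mu = mu, sd = sd2, w = w, loglik = ll, iter = it,
                  converged = TRUE, resp1 = g))
    }
    ll_old <- ll
    n1 <- sum(g); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # a component collapsed
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sd2 <- c(sqrt(sum(g * (x - mu[1])^2) / n1),
             sqrt(sum((1 - g) * (x - mu[2])^2) / n2))
    sd2 <- pmax(sd2, sd_floor)
    w <- c(n1, n2) / n
  }
  list(mu = mu, sd = sd2, w = w, loglik = ll_old, iter = max_iter,
       converged = FALSE, resp1 = g)
}

#' Gate one channel with a two-component Gaussian mixture
#'
#' Fits a two-component univariate Gaussian mixture to the z-scores of one
#' channel by EM with `n_init` random restarts (best log-likelihood kept).
#' The component with the larger mean is the positively expressing
#' population; a cell is called positive when its posterior probability of
#' that component exceeds 0.5 (the Bayes rule for the fitted mixture).
#'
#' @param z_values numeric vector of z-scores (length >= `min_n`).
#' @param seed integer seed controlling the restarts.
#' @param n_init number of EM restarts.
#' @param min_n minimum number of values required.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A list with `positive` (logical per cell), `posterior`
#'   (probability of the positive component), `means`, `sds`, `weights`
#'   (ordered negative, positive), `loglik`, and `degenerate` (TRUE when
#'   the component means are separated by less than 0.1 pooled SD).
#' @export
gate_channel <- function(z_values, seed = 1L, n_init = 5L, min_n = 20L,
                         max_iter = 500L, tol = 1e-8) {
  x <- as.numeric(z_values)
  if (length(x) < min_n) {
    stop("gating needs at least ", min_n, " cells, got ", length(x))
  }
  if (stats::sd(x) == 0) stop("all values identical; mixture is degenerate")

  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      mu0 <- sample(x, 2L)
      while (mu0[1] == mu0[2]) mu0 <- sample(x, 2L)
      fit <- em_gmm2(x, mu = mu0, sd2 = rep(stats::sd(x), 2L),
                     w = c(0.5, 0.5), max_iter = max_iter, tol = tol)
      if (fit$converged && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) {
    stop("EM did not converge in any of ", n_init, " restarts (",
         max_iter, " iterations each); consider raising max_iter")
  }
  pos_comp <- which.max(best$mu)
  post_pos <- if (pos_comp == 1L) best$resp1 else 1 - best$resp1
  ord <- order(best$mu)
  degenerate <- abs(diff(best$mu)) < 0.1 * stats::sd(x)
  if (degenerate) {
    warning("mixture components nearly coincide (separation < 0.1 SD); ",
            "positivity calls are unreliable for this channel")
  }
  list(positive = post_pos > 0.5, posterior = post_pos,
       means = best$mu[ord], sds = best$sd[ord], weights = best$w[ord],
       loglik = best$loglik, iterations = best$iter, degenerate = degenerate)
}

#' Gate every channel of a cell table
#'
#' Runs [gate_channel()] on the z-scores of each channel, within each
#' sample (default) or pooled across samples, and appends `pos_<channel>`
#' logical columns.
#'
#' @param table a z-normalised cell table (see [znormalize()]).
#' @param scope `"per_sample"` or `"pooled"`.
#' @param channels channels to gate.
#' @param seed,n_init passed to [gate_channel()]; the seed is varied
#'   deterministically per (channel, sample).
#' @return The table with `pos_*` columns appended; the fitted mixture
#'   parameters are attached as attribute `"gates"`.
#' @export
gate_cells <- function(table, scope = c("per_sample", "pooled"),
                       channels = cell_channels(table), seed = 1L,
                       n_init = 5L) {
  scope <- match.arg(scope)
  zc <- paste0("z_", channels)
  if (!all(zc %in% colnames(table))) {
    stop("z-scores missing; run znormalize() first")
  }
  groups <- if (scope == "per_sample") table$sample_id else
    rep("all", nrow(table))
  gates <- list()
  counter <- 0L
  for (ch in channels) {
    pos <- rep(NA, nrow(table))
    for (g in unique(groups)) {
      counter <- counter + 1L
      idx <- groups == g
      fit <- gate_channel(table[[paste0("z_", ch)]][idx],
                          seed = seed + counter, n_init = n_init)
      pos[idx] <- fit$positive
      gates[[paste(ch, g, sep = ":")]] <-
        fit[c("means", "sds", "weights", "loglik", "degenerate")]
    }
    table[[paste0("pos_", ch)]] <- as.logical(pos)
  }
  attr(table, "gates") <- gates
  table
}

# k-means++ seeding: spread initial centers with D^2 sampling.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
    dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

#' Cluster cells by K-means on z-scored channels
#'
#' K-means with k-means++ initialisation and `n_init` restarts; the run
#' with the lowest total within-cluster sum of squares is kept. Assignment
#' is deterministic under a fixed seed.
#'
#' @param table a z-normalised cell table.
#' @param k number of clusters (default 15: at least the number of defined
#'   phenotypes, with slack for split populations).
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @param channels channels whose z-scores form the feature space.
#' @return The table with a `cluster_id` integer column appended; cluster
#'   centers are attached as attribute `"centers"`.
#' @export
cluster_cells <- function(table, k = 15L, seed = 1L, n_init = 10L,
                          channels = cell_channels(table)) {
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(table)) {
    stop("k (", k, ") exceeds the number of cells (", nrow(table), ")")
  }
  zc <- paste0("z_", channels)
  if (!all(zc %in% colnames(table))) {
    stop("z-scores missing; run znormalize() first")
  }
  x <- as.matrix(table[, zc, drop = FALSE])

  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      cen <- kmeanspp_centers(x, k)
      cen <- cen[!duplicated(cen), , drop = FALSE]
      fit <- suppressWarnings(
        stats::kmeans(x, centers = cen, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  table$cluster_id <- as.integer(best$cluster)
  attr(table, "centers") <- best$centers
  table
}

#' Assign phenotypes to clusters by canonical markers
#'
#' A channel counts as cluster-positive when more than `majority_frac` of
#' the cluster's cells are gated positive for it. Each cluster receives the
#' first phenotype definition (in priority order) whose required-positive
#' channels are all cluster-positive and required-negative channels all
#' cluster-negative; clusters matching no definition are labelled
#' `"unassigned"`. Every member cell inherits its cluster's label.
#'
#' @param table a gated and clustered cell table.
#' @param defs ordered list of [phenotype_definition]s; explicit numeric
#'   priorities, when present, override list order and must be unique
#'   among definitions that can match simultaneously.
#' @param majority_frac cluster-positivity majority threshold (default
#'   0.5).
#' @return The table with a `phenotype` column appended; the per-cluster
#'   positivity fractions are attached as attribute `"cluster_profiles"`.
#' @export
assign_phenotypes <- function(table, defs = default_phenotypes(),
                              majority_frac = 0.5) {
  if (is.null(table$cluster_id)) stop("run cluster_cells() first")
  channels <- cell_channels(table)
  pc <- paste0("pos_", channels)
  if (!all(pc %in% colnames(table))) stop("run gate_cells() first")

  prio <- vapply(seq_along(defs), function(i) {
    p <- defs[[i]]$priority
    if (is.null(p)) i else as.numeric(p)
  }, numeric(1))
  ord <- order(prio)

  clusters <- sort(unique(table$cluster_id))
  profiles <- matrix(NA_real_, length(clusters), length(channels),
                     dimnames = list(clusters, channels))
  label_of <- stats::setNames(rep("unassigned", length(clusters)),
                              clusters)
  for (ci in seq_along(clusters)) {
    idx <- table$cluster_id == clusters[ci]
    frac <- vapply(channels, function(ch) {
      mean(table[[paste0("pos_", ch)]][idx])
    }, numeric(1))
    profiles[ci, ] <- frac
    pos_set <- channels[frac > majority_frac]
    matches <- which(vapply(defs, function(d) {
      all(d$required_positive %in% pos_set) &&
        !any(d$required_negative %in% pos_set)
    }, logical(1)))
    if (length(matches)) {
      mp <- prio[matches]
      tied <- matches[mp == min(mp)]
      if (length(tied) > 1L) {
        stop("cluster ", clusters[ci], " matches definitions ",
             paste(vapply(defs[tied], `[[`, "", "name"), collapse = " and "),
             " at equal priority; set explicit priorities")
      }
      label_of[ci] <- defs[[tied]]$name
    }
  }
  table$phenotype <- unname(label_of[as.character(table$cluster_id)])
  attr(table, "cluster_profiles") <- profiles
  table
}

#' Per-sample cell-type ratios
#'
#' The ratio of each phenotype (including `"unassigned"`) to all cells of
#' the sample, aggregating every ROI of the sample; ratios per sample sum
#' to 1.
#'
#' @param table a phenotyped cell table.
#' @param phenotypes phenotype labels to report; defaults to all labels
#'   present plus `"unassigned"`.
#' @return A data.frame with columns `sample_id, phenotype, n_cells,
#'   ratio`.
#' @export
cell_type_ratio <- function(table, phenotypes = NULL) {
  if (is.null(table$phenotype)) stop("run assign_phenotypes() first")
  if (!nrow(table)) stop("cell table is empty")
  if (is.null(phenotypes)) {
    phenotypes <- union(sort(unique(table$phenotype)), "unassigned")
  }
  out <- list()
  for (s in unique(table$sample_id)) {
    sub <- table[table$sample_id == s, ]
    n <- nrow(sub)
    if (!n) stop("sample '", s, "' is empty")
    cnt <- vapply(phenotypes, function(p) sum(sub$phenotype == p),
                  numeric(1))
    out[[s]] <- data.frame(sample_id = s, phenotype = phenotypes,
                           n_cells = as.integer(cnt), ratio = cnt / n,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
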