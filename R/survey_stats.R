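#' Drop columns with missing values
#'
#' Mirrors the survey convention of restricting multivariate analyses to
#' parameters measured at every plant: any column containing a missing
#' value is removed, and the removed names are reported.
#'
#' @param x numeric matrix or data frame (rows = plants/digesters).
#' @return The complete-column submatrix.
#' @export
drop_incomplete <- function(x) {
  x <- as.matrix(x)
  keep <- colSums(is.na(x)) == 0
  if (!any(keep)) stop("no complete columns remain")
  if (any(!keep))
    message("dropping incomplete column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  x[, keep, drop = FALSE]
}

#' Scale survey features
#'
#' Centres each column to mean 0 and scales to unit standard deviation,
#' keeping the centring/scaling metadata as attributes. Zero-variance
#' columns are removed with a warning (they carry no information and break
#' scaling).
#'
#' @param x numeric matrix or data frame.
#' @return Scaled matrix with `center` and `scale` attributes.
#' @export
scale_features <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("removing zero-variance column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  scale(x)
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering under Ward's minimum-variance criterion,
#' implemented with the Lance-Williams update on squared Euclidean
#' distances (the "Ward.D2" contract: merge heights are in Euclidean
#' distance units, and each merge minimizes the increase in total
#' within-cluster sum of squares). Ties are broken deterministically by
#' the lowest pair of cluster indices, in formation order.
#'
#' @param x numeric matrix (rows = observations), typically the output of
#'   [scale_features()].
#' @return Object of classes `ward_clust` and `hclust` with the usual
#'   `merge`, `height`, `order`, `labels` elements, so that
#'   [stats::cutree()] and plotting work directly.
#' @export
ward_cluster <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("ward_cluster requires a numeric matrix")
  n <- nrow(x)
  if (n < 2) stop("need at least 2 rows to cluster")
  d2 <- as.matrix(stats::dist(x))^2
  size <- rep(1L, n)
  active <- seq_len(n)          # active cluster slots
  id <- -seq_len(n)             # hclust coding: negative = singleton
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    # lowest-index-first scan makes tie-breaking deterministic
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in seq((ii + 1), length(active))) {
        dij <- d2[active[ii], active[jj]]
        if (dij < best_d - 1e-14) { best <- c(ii, jj); best_d <- dij }
      }
    }
    i <- best[1]; j <- best[2]
    ai <- active[i]; aj <- active[j]
    merge[step, ] <- sort(c(id[ai], id[aj]))
    height[step] <- sqrt(max(best_d, 0))
    # Lance-Williams update for Ward on squared distances
    ni <- size[ai]; nj <- size[aj]
    for (kk in seq_along(active)) {
      if (kk == i || kk == j) next
      ak <- active[kk]; nk <- size[ak]
      d2new <- ((ni + nk) * d2[ai, ak] + (nj + nk) * d2[aj, ak] -
                  nk * d2[ai, aj]) / (ni + nj + nk)
      d2[ai, ak] <- d2[ak, ai] <- d2new
    }
    size[ai] <- ni + nj
    id[ai] <- step
    active <- active[-j]
  }
  order <- dendrogram_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = rownames(x), method = "ward.D2",
                 call = match.call(), dist.method = "euclidean"),
            class = c("ward_clust", "hclust"))
}

# Leaf order by depth-first traversal of the merge tree.
dendrogram_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Principal component analysis of survey features
#'
#' PCA on scaled and centred data via the singular value decomposition
#' ([stats::prcomp()]), with a deterministic sign convention: within each
#' component, the loading with the largest magnitude is made positive.
#' Rank-deficient inputs are truncated to the positive-variance components
#' with a warning.
#'
#' @param x numeric matrix or data frame (rows = plants), complete.
#' @param n_components number of components to keep (default: all).
#' @return List with `scores`, `loadings` and `explained` (fraction of
#'   variance per kept component, computed against the total variance).
#' @export
pca_survey <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  if (any(is.na(x))) stop("PCA input must be complete; see drop_incomplete()")
  sc <- scale_features(x)
  p <- stats::prcomp(sc, center = FALSE, scale. = FALSE)
  var <- p$sdev^2
  pos <- var > max(var) * 1e-12
  if (any(!pos)) {
    warning("rank-deficient input: truncating to ", sum(pos), " component(s)")
  }
  k <- sum(pos)
  if (!is.null(n_components)) k <- min(k, n_components)
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (c_i in seq_len(k)) {
    s <- sign(rot[which.max(abs(rot[, c_i])), c_i])
    if (s < 0) { rot[, c_i] <- -rot[, c_i]; scores[, c_i] <- -scores[, c_i] }
  }
  list(scores = scores, loadings = rot,
       explained = var[seq_len(k)] / sum(var))
}

#' Pairwise Pearson correlation scan
#'
#' Pearson's r with its two-sided t-distribution p-value for each requested
#' pair of columns, on pairwise-complete observations. A
#' Benjamini-Hochberg adjusted p-value column (`p_bh`) is included as an
#' extension beyond the plain per-pair thresholds; the unadjusted `p` is
#' the primary value. Pairs with fewer than 3 complete observations or
#' zero variance yield `NA`.
#'
#' @param x numeric matrix or data frame.
#' @param pairs two-column character (or index) matrix of variable pairs;
#'   default: all distinct pairs.
#' @return data.frame with columns `var1`, `var2`, `n`, `r`, `p`, `p_bh`.
#' @export
pearson_scan <- function(x, pairs = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(pairs)) {
    idx <- utils::combn(colnames(x), 2)
    pairs <- t(idx)
  }
  pairs <- as.matrix(pairs)
  res <- data.frame(var1 = character(0), var2 = character(0),
                    n = integer(0), r = numeric(0), p = numeric(0))
  for (row in seq_len(nrow(pairs))) {
    a <- x[, pairs[row, 1]]; b <- x[, pairs[row, 2]]
    ok <- stats::complete.cases(a, b)
    n <- sum(ok); r <- NA_real_; p <- NA_real_
    if (n >= 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
      ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    res[row, ] <- list(as.character(pairs[row, 1]),
                       as.character(pairs[row, 2]), n, r, p)
  }
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Normalize enzyme activities to the per-enzyme maximum
#'
#' Each activity is divided by the highest recorded activity of that
#' enzyme, giving relative values in `[0, 1]` with at least one exact 1.
#'
#' @param values numeric vector of activities for one enzyme.
#' @return Relative activities.
#' @export
normalize_enzyme_activity <- function(values) {
  if (any(values < 0)) stop("activities must be >= 0")
  m <- max(values)
  if (m <= 0) stop("all activities are zero; cannot normalize")
  values / m
}
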