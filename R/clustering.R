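#' Extract the (begin hour, end hour) time points of activities
#'
#' @param activities A `casas_activities` tibble.
#' @return Numeric matrix with columns `bt` and `et`, one row per instance.
#'   Both axes are hours on the same 0--23 range, so no scaling is applied
#'   before clustering.
#' @export
time_points <- function(activities) {
  cbind(bt = as.numeric(activities$bt), et = as.numeric(activities$et))
}

#' k-means clustering of activity time points
#'
#' Lloyd's algorithm with k-means++ initialisation, 10 restarts, keeping the
#' model with the smallest within-cluster sum of squares. Deterministic
#' given `(points, k, seed)`.
#'
#' @param points Numeric matrix of (bt, et) rows, as from [time_points()].
#' @param k Number of clusters, `1 <= k <=` number of distinct points.
#' @param seed Integer seed controlling the restarts.
#' @param nstart Number of k-means++ restarts (default 10).
#' @return A `cluster_model`: list with `k`, `centroids` (k x 2 matrix),
#'   `assignment` (integer vector over the training points) and `sse`.
#' @export
fit_kmeans <- function(points, k, seed = 1L, nstart = 10L) {
  points <- as.matrix(points)
  n_distinct <- nrow(unique(points))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n_distinct) {
    stop("k (", k, ") exceeds the number of distinct points (", n_distinct,
         ")", call. = FALSE)
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(nstart)) {
      centers <- kmeanspp_init(points, k)
      fit <- tryCatch(
        stats::kmeans(points, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(stats::kmeans(points, centers = centers,
                                         iter.max = 100L,
                                         algorithm = "Lloyd"))
        })
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed for every restart", call. = FALSE)
  structure(list(k = k,
                 centroids = unname(best$centers),
                 assignment = unname(best$cluster),
                 sse = best$tot.withinss),
            class = "cluster_model")
}

# k-means++ seeding: first centre uniform over distinct points, then each
# next centre drawn with probability proportional to squared distance to the
# nearest centre already chosen.
kmeanspp_init <- function(points, k) {
  pts <- unique(points)
  n <- nrow(pts)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- apply(pts, 1, function(p) {
      min(colSums((t(pts[idx, , drop = FALSE]) - p)^2))
    })
    if (all(d2 == 0)) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = d2))
    }
  }
  pts[idx, , drop = FALSE]
}

#' Within-cluster sum of squared errors
#'
#' The clustering error of all samples: the squared Euclidean distance of
#' every point to the centroid of its cluster, summed.
#'
#' @param points Numeric matrix of points.
#' @param model A `cluster_model` assigning every point.
#' @return Non-negative number.
#' @export
cluster_sse <- function(points, model) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(model$assignment))
  sum((points - model$centroids[model$assignment, , drop = FALSE])^2)
}

#' Assign new points to their nearest centroid
#'
#' @param model A `cluster_model`.
#' @param points Matrix (or single row) of (bt, et) points.
#' @return Integer vector of cluster indices.
#' @export
predict_cluster <- function(model, points) {
  points <- matrix(as.numeric(points), ncol = ncol(model$centroids))
  apply(points, 1, function(p) {
    which.min(colSums((t(model$centroids) - p)^2))
  })
}

#' SSE-versus-k curve
#'
#' Fits k-means for k = 1 .. `k_max` and tabulates the best-of-restarts SSE,
#' the curve the elbow method inspects.
#'
#' @inheritParams fit_kmeans
#' @param k_max Largest k scanned (capped at the number of distinct points,
#'   with a warning).
#' @return Tibble with columns `k` and `sse`.
#' @export
sse_curve <- function(points, k_max, seed = 1L, nstart = 10L) {
  points <- as.matrix(points)
  n_distinct <- nrow(unique(points))
  if (k_max > n_distinct) {
    warning("reducing the k scan from ", k_max, " to the ", n_distinct,
            " distinct points available", call. = FALSE)
    k_max <- n_distinct
  }
  sse <- vapply(seq_len(k_max), function(k) {
    fit_kmeans(points, k, seed = seed + k, nstart = nstart)$sse
  }, numeric(1))
  tibble::tibble(k = seq_len(k_max), sse = sse)
}

#' Choose the number of clusters by the elbow method
#'
#' Scans k = 1 .. `num_classes` and returns the k at the elbow -- the point
#' of largest curvature -- of the SSE-versus-k curve. The default
#' operationalisation is the kneedle criterion: the interior k whose SSE
#' lies furthest below the chord joining the curve's endpoints. This is
#' scale-free and robust; the naive alternative, the maximum discrete
#' second difference `SSE(k-1) - 2 SSE(k) + SSE(k+1)` (available as
#' `method = "second_diff"`), is dominated by the steep initial drop of the
#' curve and tends to answer k = 2 whatever the data.
#'
#' @inheritParams fit_kmeans
#' @param num_classes Upper end of the scan; in practice the number of
#'   activity classes in the training data. Must be at least 3 so an
#'   interior k exists.
#' @param method `"distance"` (kneedle chord distance, default) or
#'   `"second_diff"`.
#' @return The selected integer k, in `[2, num_classes - 1]`.
#' @export
select_k <- function(points, num_classes, seed = 1L,
                     method = c("distance", "second_diff"), nstart = 10L) {
  method <- match.arg(method)
  stopifnot(num_classes >= 3)
  curve <- sse_curve(points, num_classes, seed = seed, nstart = nstart)
  if (nrow(curve) < 3) {
    # too few distinct points for an interior elbow: the curve bottoms out
    # at one cluster per distinct point
    return(curve$k[nrow(curve)])
  }
  s <- curve$sse
  n <- length(s)
  inner <- 2:(n - 1)
  if (method == "distance") {
    chord <- s[1] + (s[n] - s[1]) * (curve$k - curve$k[1]) / (n - 1)
    curve$k[inner][which.max((chord - s)[inner])]
  } else {
    cur <- s[1:(n - 2)] - 2 * s[2:(n - 1)] + s[3:n]
    curve$k[which.max(cur) + 1L]
  }
}
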