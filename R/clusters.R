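#' Cluster frames into structural states in ccPCA score space
#'
#' Average-linkage agglomerative clustering on Euclidean distances between
#' component scores. The number of clusters is chosen deterministically by
#' maximum mean silhouette width over a small grid (2 .. `max_k`); when even
#' the best split scores below `silhouette_floor`, the frames are treated as
#' a single state. Clusters are numbered by descending population; the
#' medoid of a cluster is the member frame minimizing the summed distance to
#' all members.
#'
#' @param scores A [ccpca()] object, or a numeric matrix / data frame of
#'   per-frame scores.
#' @param max_k Largest cluster count tried (default 8).
#' @param silhouette_floor Mean silhouette width below which no split is
#'   accepted (default 0.5).
#' @param noise_threshold Frames farther than this from every cluster medoid
#'   are flagged unassigned (`NA` cluster). Default `Inf` (off).
#' @return A tibble of class `contact_clusters` with one row per cluster
#'   (`cluster`, `n_frames`, `population`, `medoid_frame`) and the per-frame
#'   assignment as attribute `assignments` (also via [tidy()]).
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60) + 20, 30))
#' cluster_states(pts)
cluster_states <- function(scores, max_k = 8, silhouette_floor = 0.5,
                           noise_threshold = Inf) {
  if (inherits(scores, "ccpca")) {
    frames <- scores$frames
    S <- scores$scores
  } else {
    S <- as.matrix(scores)
    frames <- if (!is.null(rownames(S))) {
      suppressWarnings(as.integer(rownames(S)))
    } else NULL
    if (is.null(frames) || anyNA(frames)) frames <- seq_len(nrow(S))
  }
  n <- nrow(S)
  if (n < 1) abort("no frames to cluster.")
  if (ncol(S) == 0 || n < 3) {
    cl <- rep(1L, n)
  } else {
    d <- dist(S)
    if (max(d) < 1e-12) {
      cl <- rep(1L, n)
    } else {
      hc <- hclust(d, method = "average")
      ks <- 2:min(max_k, n - 1)
      sil <- vapply(ks, function(k) {
        ct <- cutree(hc, k = k)
        if (length(unique(ct)) < 2) return(-Inf)
        mean(cluster::silhouette(ct, d)[, "sil_width"])
      }, numeric(1))
      best <- which.max(sil)
      cl <- if (sil[best] >= silhouette_floor) cutree(hc, k = ks[best]) else rep(1L, n)
    }
  }
  # renumber by descending population (tie: earliest member frame)
  sizes <- table(cl)
  first_member <- vapply(names(sizes), function(g) min(which(cl == g)), numeric(1))
  ord <- order(-as.vector(sizes), first_member)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  cl <- as.integer(relabel[as.character(cl)])

  Sm <- as.matrix(S)
  medoid_row <- vapply(sort(unique(cl)), function(g) {
    rows <- which(cl == g)
    if (length(rows) == 1 || ncol(Sm) == 0) return(rows[1])
    dd <- as.matrix(dist(Sm[rows, , drop = FALSE]))
    rows[which.min(rowSums(dd))]
  }, integer(1))

  if (is.finite(noise_threshold)) {
    dmed <- proxy_cross_dist(Sm, Sm[medoid_row, , drop = FALSE])
    cl[apply(dmed, 1, min) > noise_threshold] <- NA_integer_
  }

  assigned <- !is.na(cl)
  out <- tibble(
    cluster = sort(unique(cl[assigned])),
    n_frames = as.vector(table(cl[assigned])),
    population = as.vector(table(cl[assigned])) / n,
    medoid_frame = frames[medoid_row[sort(unique(cl[assigned]))]]
  )
  attr(out, "assignments") <- tibble(frame = frames, cluster = cl)
  class(out) <- c("contact_clusters", class(out))
  out
}

#' @describeIn cluster_states Per-frame cluster assignments.
#' @param x A `contact_clusters` object.
#' @param ... Unused.
#' @method tidy contact_clusters
#' @export
tidy.contact_clusters <- function(x, ...) {
  attr(x, "assignments")
}

#' Dominant structural state
#'
#' The cluster with the largest population fraction; ties resolve to the
#' lowest cluster id.
#'
#' @param clusters A [cluster_states()] result.
#' @return One-row tibble (the dominant cluster's summary row).
#' @export
dominant_cluster <- function(clusters) {
  if (!nrow(clusters)) abort("empty cluster list.")
  best <- which(clusters$population == max(clusters$population))
  clusters[best[which.min(clusters$cluster[best])], ]
}

#' Member frames of a cluster
#'
#' @param clusters A [cluster_states()] result.
#' @param cluster_id Cluster number.
#' @return Integer vector of frame ids.
#' @export
cluster_frames <- function(clusters, cluster_id) {
  a <- attr(clusters, "assignments")
  a$frame[!is.na(a$cluster) & a$cluster == cluster_id]
}
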