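#' Contact-contact principal component analysis (ccPCA)
#'
#' PCA on the binary contact fingerprint matrix: columns are mean-centered
#' (never scaled) and the smallest number of components whose cumulative
#' explained-variance fraction reaches `variance_target` is retained.
#' Component signs follow a fixed convention -- the largest-magnitude loading
#' of each component is positive -- so results are fully deterministic.
#'
#' @param fp A [contact_fingerprints()] object, or any numeric matrix / data
#'   frame with one row per frame.
#' @param variance_target Fraction of total variance the retained components
#'   must explain (default 0.9).
#' @return An object of class `ccpca` with fields `scores` (frames x k),
#'   `components` (k x P loadings), `explained_variance_fraction` (length k),
#'   `center`, and `frames`. A constant input yields k = 0 with a warning.
#' @export
#' @examples
#' m <- matrix(rep(c(0, 1), each = 30), 6, 10)
#' ccpca(m)$explained_variance_fraction
ccpca <- function(fp, variance_target = 0.9) {
  if (variance_target <= 0 || variance_target > 1) {
    abort("variance_target must lie in (0, 1].")
  }
  if (inherits(fp, "contact_fingerprints")) {
    X <- fp$matrix
    frames <- as.integer(rownames(X))
    pair_index <- fp$pair_index
  } else {
    X <- as.matrix(fp)
    frames <- seq_len(nrow(X))
    pair_index <- NULL
  }
  if (nrow(X) < 2) abort("ccpca needs at least 2 frames.")
  storage.mode(X) <- "double"
  ctr <- colMeans(X)
  v <- apply(X, 2, stats::var)
  keep <- which(v > 0)
  P <- ncol(X)
  if (!length(keep)) {
    warn("fingerprint matrix is constant: zero variance, returning k = 0 components.")
    out <- list(
      scores = matrix(0, nrow(X), 0), components = matrix(0, 0, P),
      explained_variance_fraction = numeric(0), center = ctr,
      frames = frames, pair_index = pair_index, variance_target = variance_target
    )
    return(structure(out, class = "ccpca"))
  }
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  evf <- pc$sdev^2 / sum(v)
  k <- which(cumsum(evf) >= variance_target - 1e-9)[1]
  if (is.na(k)) k <- length(evf)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) { # sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  components <- matrix(0, k, P)
  components[, keep] <- t(rot)
  rownames(scores) <- as.character(frames)
  structure(
    list(scores = scores, components = components,
         explained_variance_fraction = evf[seq_len(k)], center = ctr,
         frames = frames, pair_index = pair_index,
         variance_target = variance_target),
    class = "ccpca"
  )
}

#' @export
print.ccpca <- function(x, ...) {
  cat(sprintf("<ccpca> %d frames, %d components (%.1f%% variance explained)\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained_variance_fraction)))
  invisible(x)
}

#' @describeIn ccpca Long tibble of per-frame component scores.
#' @param x A `ccpca` object.
#' @param ... Unused.
#' @method tidy ccpca
#' @export
tidy.ccpca <- function(x, ...) {
  k <- ncol(x$scores)
  if (k == 0) return(tibble(frame = x$frames))
  out <- as_tibble(x$scores, .name_repair = ~ paste0("PC", seq_len(k)))
  out <- mutate(out, frame = x$frames)
  tidyr::pivot_longer(out, -"frame", names_to = "component",
                      values_to = "score")
}

#' @describeIn ccpca One-row summary (components kept, variance explained).
#' @method glance ccpca
#' @export
glance.ccpca <- function(x, ...) {
  tibble(
    n_frames = nrow(x$scores),
    n_components = ncol(x$scores),
    variance_target = x$variance_target,
    variance_explained = sum(x$explained_variance_fraction)
  )
}

#' @describeIn ccpca Score scatter plot of the first two components.
#' @param object A `ccpca` object.
#' @param clusters Optional [cluster_states()] result used to colour frames.
#' @method autoplot ccpca
#' @export
autoplot.ccpca <- function(object, clusters = NULL, ...) {
  k <- ncol(object$scores)
  if (k == 0) abort("nothing to plot: 0 components.")
  df <- tibble(
    frame = object$frames,
    PC1 = object$scores[, 1],
    PC2 = if (k >= 2) object$scores[, 2] else 0
  )
  if (!is.null(clusters)) {
    df <- left_join(df, tidy(clusters), by = "frame")
    df$cluster <- factor(df$cluster)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                          colour = .data$cluster))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance_fraction[1]),
      y = if (k >= 2) {
        sprintf("PC2 (%.1f%%)", 100 * object$explained_variance_fraction[2])
      } else "PC2 (absent)"
    ) +
    ggplot2::theme_minimal()
}
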