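#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired point sets, with the usual reflection guard (the determinant of
#' the rotation is forced to +1 by flipping the smallest singular
#' direction). Degenerate (rank-deficient) point sets are handled by the
#' same guard, with a warning.
#'
#' @param source Matrix / data frame of points (n x 3) to be transformed.
#' @param target Matrix / data frame of points (n x 3) to fit onto.
#' @return Object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd`. The fitted source is
#'   `source %*% t(rotation) + translation` (row-wise).
#' @export
#' @examples
#' X <- matrix(rnorm(30), 10)
#' kabsch_superpose(X, X)$rmsd
kabsch_superpose <- function(source, target) {
  X <- as.matrix(source)
  Y <- as.matrix(target)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3 || nrow(X) < 3) {
    abort("point sets must be equal-sized n x 3 with n >= 3.")
  }
  if (!all(is.finite(X)) || !all(is.finite(Y))) abort("coordinates must be finite.")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  if (min(sv$d) < 1e-10 * max(sv$d, 1e-300)) {
    warn("degenerate (rank-deficient) point set: superposition resolved by the reflection guard.")
  }
  s <- sign(det(tcrossprod(sv$v, sv$u)))
  if (s == 0) s <- 1
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  structure(
    list(rotation = R, translation = as.vector(cy - R %*% cx), rmsd = rmsd),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A", x$rmsd))
  if (!is.null(x$chain_mapping)) {
    cat("  mapping:", paste(names(x$chain_mapping), x$chain_mapping,
                            sep = "->", collapse = " "))
  }
  cat("\n")
  invisible(x)
}

# split a complex tibble into per-chain coordinate matrices keyed by resid
chain_coord_list <- function(complex) {
  need <- c("chain", "resid", "x", "y", "z")
  if (!all(need %in% names(complex))) {
    abort(paste("complex must have columns:", paste(need, collapse = ", ")))
  }
  if ("frame" %in% names(complex) && length(unique(complex$frame)) > 1) {
    abort("complex must be a single frame; filter the trajectory first.")
  }
  if ("insert" %in% names(complex) &&
      any(!is.na(complex$insert) & complex$insert != "")) {
    abort("insertion codes are not supported; renumber the structure first.")
  }
  complex <- arrange(complex, .data$chain, .data$resid)
  lapply(split(complex, complex$chain), function(d) {
    m <- as.matrix(d[, c("x", "y", "z")])
    rownames(m) <- d$resid
    m
  })
}

#' Chain-permutation-aware RMSD between two complexes
#'
#' Minimum RMSD over all chain-to-chain bijections between two complexes of
#' identical chains, each candidate mapping evaluated with a full
#' least-squares superposition over the residues common to the paired
#' chains. Exhaustive over at most 8 chains.
#'
#' @param a,b Complex tibbles (`chain`, `resid`, `x`, `y`, `z`), e.g. from
#'   [read_complex()] or a single trajectory frame.
#' @return A `superposition` with the winning `chain_mapping` (named vector,
#'   chains of `a` to chains of `b`) and `all_mappings`, a tibble of every
#'   mapping's RMSD.
#' @export
multichain_rmsd <- function(a, b) {
  ca <- chain_coord_list(a)
  cb <- chain_coord_list(b)
  if (length(ca) != length(cb)) abort("complexes must have the same number of chains.")
  nc <- length(ca)
  if (nc > 8) abort("refusing > 8 chains (factorial number of mappings).")
  perms <- perms_lex(nc)
  results <- vector("list", nrow(perms))
  for (p in seq_len(nrow(perms))) {
    pm <- perms[p, ]
    Xs <- vector("list", nc)
    Ys <- vector("list", nc)
    for (i in seq_len(nc)) {
      ra <- rownames(ca[[i]])
      rb <- rownames(cb[[pm[i]]])
      keep <- intersect(ra, rb)
      if (!length(keep)) abort("no residue overlap between paired chains.")
      Xs[[i]] <- ca[[i]][keep, , drop = FALSE]
      Ys[[i]] <- cb[[pm[i]]][keep, , drop = FALSE]
    }
    sp <- kabsch_superpose(do.call(rbind, Xs), do.call(rbind, Ys))
    results[[p]] <- list(rmsd = sp$rmsd, sp = sp, pm = pm)
  }
  rmsds <- vapply(results, function(r) r$rmsd, numeric(1))
  best <- which.min(rmsds)
  out <- results[[best]]$sp
  out$chain_mapping <- setNames(names(cb)[results[[best]]$pm], names(ca))
  out$all_mappings <- tibble(
    mapping = vapply(results, function(r)
      paste(names(cb)[r$pm], collapse = ""), character(1)),
    rmsd = rmsds
  )
  out
}
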