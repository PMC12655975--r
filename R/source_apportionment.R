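# Correlation-matrix PCA with Kaiser retention and varimax rotation, and the
# element-to-source contribution matrix M derived from squared rotated
# loadings.

#' Column-standardize a concentration matrix
#'
#' Centres and scales each element column to mean 0 and SD 1 (n-1
#' denominator) — the prerequisite for correlation-matrix PCA on elements
#' with heterogeneous scales.
#'
#' @param values numeric site x element matrix with at least 3 rows.
#' @return standardized matrix of the same shape.
#' @export
standardize <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 3) stop("standardize needs at least 3 sites")
  sds <- apply(values, 2, stats::sd)
  constant <- which(sds == 0)
  if (length(constant))
    stop("constant column(s): ",
         paste(colnames(values)[constant] %||% constant, collapse = ", "))
  scale(values)[, , drop = FALSE]
}

#' Principal component analysis with Kaiser retention
#'
#' Eigendecomposition of the correlation matrix of a standardized site x
#' element matrix. Components with eigenvalue strictly greater than 1 are
#' retained (Kaiser criterion); retained loadings are varimax-rotated by
#' default and sign-normalized so each component's largest-magnitude loading
#' is positive.
#'
#' @param z standardized matrix from [standardize()] (raw matrices are
#'   accepted and standardized internally).
#' @param rotation `"varimax"` (default) or `"none"`.
#' @param retention `"kaiser"` or a fixed component count.
#' @return A `source_model`: list with `eigenvalues` (descending, summing to
#'   the number of elements), `retained_k`, `cumulative_variance` (percent
#'   explained by the retained set, after rotation unchanged in total),
#'   `loadings` (element x retained component), `scores` (site x retained
#'   component), `rotation`, and `m_matrix` (NULL until
#'   [element_source_contributions()] is applied).
#' @export
pca_kaiser <- function(z, rotation = c("varimax", "none"),
                       retention = "kaiser") {
  rotation <- match.arg(rotation)
  z <- as.matrix(z)
  centred <- all(abs(colMeans(z)) < 1e-8) &&
    all(abs(apply(z, 2, stats::sd) - 1) < 1e-8)
  if (!centred) z <- standardize(z)
  n <- nrow(z); pcount <- ncol(z)
  if (n < pcount)
    warning("fewer sites than elements: correlation matrix is rank deficient")
  R <- stats::cor(z)
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  k <- if (identical(retention, "kaiser")) sum(ev > 1) else as.integer(retention)
  if (k < 1) stop("no components retained")
  # loadings = eigenvectors scaled by sqrt(eigenvalue): correlations between
  # elements and components
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  L <- V %*% diag(sqrt(ev[seq_len(k)]), k)
  rot <- diag(k)
  if (rotation == "varimax" && k > 1) {
    vm <- stats::varimax(L, normalize = TRUE)
    L <- unclass(L %*% vm$rotmat)
    rot <- vm$rotmat
  }
  flips <- vapply(seq_len(k), function(j)
    if (L[which.max(abs(L[, j])), j] < 0) -1 else 1, 0)
  L <- sweep(L, 2, flips, "*")
  dimnames(L) <- list(colnames(z), paste0("PC", seq_len(k)))
  # unit-variance scores of the (rotated, sign-normalized) components
  scores <- z %*% sweep(V %*% diag(1 / sqrt(ev[seq_len(k)]), k) %*% rot,
                        2, flips, "*")
  colnames(scores) <- colnames(L)
  structure(list(eigenvalues = ev, retained_k = k,
                 cumulative_variance = 100 * sum(ev[seq_len(k)]) / pcount,
                 loadings = L, scores = scores, rotation = rotation,
                 m_matrix = NULL),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %d retained component(s) (%s), %.1f%% variance\n",
              x$retained_k, x$rotation, x$cumulative_variance))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Element-to-source contribution matrix
#'
#' Converts retained (rotated) loadings into per-element source contribution
#' rates: M[i, k] = L[i, k]^2 / sum_k' L[i, k']^2. Rows sum to 1, and M is
#' invariant to loading sign conventions and to column permutations.
#'
#' @param model a `source_model` from [pca_kaiser()].
#' @return element x source matrix M with rows summing to 1 (also stored back
#'   in the returned model when `model` is assigned).
#' @export
element_source_contributions <- function(model) {
  stopifnot(inherits(model, "source_model"))
  L2 <- model$loadings^2
  comm <- rowSums(L2)
  zero <- which(comm == 0)
  if (length(zero))
    stop("element(s) with all-zero retained loadings: ",
         paste(rownames(L2)[zero], collapse = ", "))
  sweep(L2, 1, comm, "/")
}

#' Cosine similarity between columns of two matrices
#'
#' Used to match recovered rotated components against known source
#' signatures in parameter-recovery checks.
#'
#' @param a,b numeric vectors of equal length.
#' @return cosine of the angle between `a` and `b`.
#' @export
cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
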