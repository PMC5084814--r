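# Surface-level preprocessing: qT1 -> qR1 conversion with bounding, search
# masks over parcellations, and iterative Gaussian smoothing of per-vertex
# maps to a target FWHM.

#' Convert quantitative T1 (ms) to quantitative R1 (1/s) with bounding
#'
#' qR1 = 1000 / qT1, then winsorized to \[`lower`, `upper`\] s^-1 (the
#' default band 0.25..10 s^-1 corresponds to qT1 between 100 and 4000 ms).
#' Nonpositive qT1 values are marked invalid (NA) with a warning rather
#' than clamped.
#'
#' @param qt1_ms Numeric vector of qT1 values in milliseconds.
#' @param lower,upper Bounds in s^-1.
#' @return Numeric vector of qR1 values with attributes `n_clamped` (values
#'   moved to a bound) and `n_invalid` (nonpositive inputs set to NA).
#' @examples
#' qt1_to_qr1(c(4000, 1000, 50))
#' @export
qt1_to_qr1 <- function(qt1_ms, lower = 0.25, upper = 10) {
  qr1 <- 1000 / qt1_ms
  bad <- !is.na(qt1_ms) & qt1_ms <= 0
  if (any(bad)) {
    warning(sum(bad), " nonpositive qT1 value(s) marked invalid")
    qr1[bad] <- NA_real_
  }
  n_clamped <- sum(qr1 < lower | qr1 > upper, na.rm = TRUE)
  qr1 <- pmin(pmax(qr1, lower), upper)
  attr(qr1, "n_clamped") <- n_clamped
  attr(qr1, "n_invalid") <- sum(bad)
  qr1
}

#' Build a search mask from a vertex parcellation
#'
#' Excludes named parcels (and typically the medial wall / patch boundary)
#' from the statistical search region; downstream statistics and resel
#' counts are computed only over retained vertices.
#'
#' @param mesh A `triangle_mesh`.
#' @param parcel_labels Character vector, one label per vertex.
#' @param exclude Character vector of parcel names to drop.
#' @return A `search_mask`: logical vector (TRUE = retained) with
#'   attributes `area_mm2` (retained barycentric area), `perimeter_mm`
#'   (boundary length of the retained region) and `excluded`.
#' @export
build_search_mask <- function(mesh, parcel_labels, exclude = character()) {
  stopifnot(length(parcel_labels) == nrow(mesh$vertices))
  unknown <- setdiff(exclude, unique(parcel_labels))
  if (length(unknown) > 0) {
    stop("unknown parcel name(s): ", paste(unknown, collapse = ", "))
  }
  mask <- !(parcel_labels %in% exclude)
  if (!any(mask)) stop("empty search region: all parcels excluded")
  structure(mask, class = c("search_mask", "logical"),
            area_mm2 = sum(mesh$vertex_areas[mask]),
            perimeter_mm = .mask_perimeter(mesh, mask),
            excluded = exclude)
}

# boundary length of the submesh induced by `mask`: edges used by exactly
# one retained triangle
.mask_perimeter <- function(mesh, mask) {
  keep <- mask[mesh$faces[, 1]] & mask[mesh$faces[, 2]] & mask[mesh$faces[, 3]]
  f <- mesh$faces[keep, , drop = FALSE]
  if (nrow(f) == 0) return(0)
  n <- nrow(mesh$vertices)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- (pmin(e[, 1], e[, 2]) - 1) * n + pmax(e[, 1], e[, 2])
  cnt <- table(key)
  bkey <- as.numeric(names(cnt))[cnt == 1]
  i <- (bkey - 1) %/% n + 1
  j <- (bkey - 1) %% n + 1
  sum(sqrt(rowSums((mesh$vertices[i, , drop = FALSE] -
                    mesh$vertices[j, , drop = FALSE])^2)))
}

#' Precompute an iterative Gaussian smoothing operator
#'
#' One application of the returned operator is a Gaussian-weighted local
#' average with per-iteration kernel width `fwhm_mm / sqrt(n_iter)`, so
#' `n_iter` applications compose to approximately the target FWHM. The
#' kernel is supported on the geodesic ball of radius 3 per-iteration sigma
#' and is Sinkhorn-balanced against the barycentric vertex areas, which
#' makes every application conserve both constants and area-weighted mass
#' exactly (to floating point).
#'
#' @param mesh A `triangle_mesh`.
#' @param fwhm_mm Target composed FWHM in mm.
#' @param n_iter Number of diffusion iterations the target is split over.
#' @param mask Optional logical vertex mask; kernel support is restricted
#'   to retained vertices and renormalized.
#' @return A `mesh_smoother`: list with the sparse operator `W` (acting on
#'   masked vertices), `mask`, `fwhm_mm`, `n_iter`, `sigma_iter`.
#' @export
build_smoother <- function(mesh, fwhm_mm = 8, n_iter = 10, mask = NULL) {
  stopifnot(fwhm_mm > 0, n_iter >= 1)
  n <- nrow(mesh$vertices)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / sqrt(n_iter)
  r <- 3 * sigma

  idx <- which(mask)
  A <- mesh$adjacency[idx, idx, drop = FALSE]
  m <- length(idx)
  P <- A + Matrix::Diagonal(m)
  P@x[] <- 1
  k <- max(1L, ceiling(r / (0.8 * mesh$mean_edge)))
  S <- P
  for (step in seq_len(k - 1L)) {
    S <- S %*% P
    S@x[] <- 1
  }
  trip <- Matrix::summary(S)
  V <- mesh$vertices[idx, , drop = FALSE]
  d2 <- rowSums((V[trip$i, , drop = FALSE] - V[trip$j, , drop = FALSE])^2)
  keep <- d2 <= r^2
  K <- Matrix::sparseMatrix(i = trip$i[keep], j = trip$j[keep],
                            x = exp(-d2[keep] / (2 * sigma^2)), dims = c(m, m))
  iso <- Matrix::rowSums(K > 0) <= 1
  if (any(iso)) {
    warning(sum(iso), " masked vertex/vertices isolated at this kernel scale; ",
            "left unsmoothed")
  }

  # symmetric Sinkhorn balancing: diag(d) K diag(d) has row sums equal to
  # the vertex areas, so W = diag(1/a) K~ is simultaneously row-stochastic
  # and area-mass-conserving
  a <- mesh$vertex_areas[idx]
  dvec <- sqrt(a / Matrix::rowSums(K))
  for (it in 1:500) {
    rs <- dvec * as.vector(K %*% dvec)
    if (max(abs(rs - a) / a) < 1e-14) break
    dvec <- dvec * sqrt(a / rs)  # square-root damping: plain iteration oscillates
  }
  Kt <- Matrix::Diagonal(m, dvec) %*% K %*% Matrix::Diagonal(m, dvec)
  W <- Matrix::Diagonal(m, 1 / a) %*% Kt
  structure(list(W = methods::as(W, "CsparseMatrix"), mask = mask,
                 fwhm_mm = fwhm_mm, n_iter = n_iter, sigma_iter = sigma),
            class = "mesh_smoother")
}

#' @export
print.mesh_smoother <- function(x, ...) {
  cat(sprintf(
    "mesh_smoother: target FWHM %.2f mm over %d iterations (sigma/iter %.3f mm), %d vertices\n",
    x$fwhm_mm, x$n_iter, x$sigma_iter, sum(x$mask)))
  invisible(x)
}

#' Smooth per-vertex maps on a mesh to a target FWHM
#'
#' Applies `n_iter` mass-conserving Gaussian diffusion iterations (see
#' [build_smoother()]). Vertices outside the mask are returned as NA.
#'
#' @param x Numeric vector (one map) or matrix with one map per row
#'   (columns = vertices).
#' @param mesh A `triangle_mesh` (ignored when `smoother` is given).
#' @param fwhm_mm,n_iter,mask See [build_smoother()].
#' @param smoother Optional precomputed `mesh_smoother`; reuse it when
#'   smoothing many maps on one mesh.
#' @return Smoothed map(s), same shape as `x`.
#' @export
smooth_vertex_map <- function(x, mesh = NULL, fwhm_mm = 8, n_iter = 10,
                              mask = NULL, smoother = NULL) {
  if (is.null(smoother)) {
    smoother <- build_smoother(mesh, fwhm_mm = fwhm_mm, n_iter = n_iter,
                               mask = mask)
  }
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  stopifnot(ncol(X) == length(smoother$mask))
  Wt <- Matrix::t(smoother$W)
  M <- X[, smoother$mask, drop = FALSE]
  for (it in seq_len(smoother$n_iter)) M <- as.matrix(M %*% Wt)
  out <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  out[, smoother$mask] <- M
  if (vec) out[1, ] else out
}

#' Empirical FWHM of smoothed maps from spatial autocorrelation
#'
#' Estimates the effective Gaussian kernel width of (noise) maps from the
#' decay of the between-vertex correlation with distance: for white noise
#' smoothed by a Gaussian of width sigma, corr(d) = exp(-d^2 / (4 sigma^2)).
#' Correlations are pooled over vertex pairs binned by distance and the
#' log-correlation is regressed on d^2 through the origin.
#'
#' @param maps Matrix of independent realizations, one map per row, or a
#'   single map as a vector (several maps give a far more stable estimate).
#' @param mesh A `triangle_mesh`.
#' @param mask Optional logical vertex mask; estimation uses only retained
#'   vertices (use an interior mask to avoid boundary effects).
#' @param max_lag_mm Largest pair distance used (default 6).
#' @param max_vertices Subsample size for the pair set (default 500).
#' @param seed Seed for the vertex subsample.
#' @return Estimated FWHM in mm.
#' @export
estimate_map_fwhm <- function(maps, mesh, mask = NULL, max_lag_mm = 6,
                              max_vertices = 500, seed = 1) {
  X <- if (is.null(dim(maps))) matrix(maps, nrow = 1) else as.matrix(maps)
  n <- nrow(mesh$vertices)
  if (is.null(mask)) mask <- rep(TRUE, n)
  idx <- which(mask)
  if (length(idx) > max_vertices) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    idx <- sort(sample(idx, max_vertices))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  V <- mesh$vertices[idx, , drop = FALSE]
  D <- as.matrix(stats::dist(V))
  Z <- t(X[, idx, drop = FALSE])          # vertices x maps
  if (ncol(Z) >= 4) {
    # center each vertex across realizations: avoids the negative bias that
    # spatial mean-removal induces in long-range correlations
    Z <- Z - rowMeans(Z)
  } else {
    Z <- Z - rep(colMeans(Z), each = nrow(Z))
  }
  Z <- Z / sqrt(rowSums(Z^2))
  C <- tcrossprod(Z)                      # pairwise correlation estimates
  ut <- upper.tri(D)
  d <- D[ut]; cc <- C[ut]
  keep <- d > 0 & d <= max_lag_mm
  d <- d[keep]; cc <- cc[keep]
  br <- seq(0, max_lag_mm, by = 0.5)
  bin <- cut(d, br)
  rho <- tapply(cc, bin, mean)
  dmid <- tapply(d, bin, mean)
  ok <- !is.na(rho) & rho > 0.05 & rho < 0.95
  if (sum(ok) < 2) stop("too few usable distance bins for FWHM estimation")
  y <- -log(rho[ok])
  x2 <- dmid[ok]^2 / 4
  slope <- sum(x2 * y) / sum(x2 * x2)    # 1 / sigma^2
  2 * sqrt(2 * log(2)) / sqrt(slope)
}

#' Residual-based smoothness estimate (FWHM, mm)
#'
#' Alternative to assuming the nominal applied FWHM: estimates smoothness
#' from normalized residual maps via the along-edge variance of
#' standardized differences (for a Gaussian autocorrelation,
#' E\[(u_i - u_j)^2\] ~ d^2 / (2 sigma^2) at small d).
#'
#' @param resid Matrix of residual maps, one per row (columns = vertices).
#' @param mesh A `triangle_mesh`.
#' @param mask Optional logical vertex mask.
#' @return Estimated FWHM in mm.
#' @export
estimate_smoothness_resid <- function(resid, mesh, mask = NULL) {
  X <- if (is.null(dim(resid))) matrix(resid, nrow = 1) else as.matrix(resid)
  n <- nrow(mesh$vertices)
  if (is.null(mask)) mask <- rep(TRUE, n)
  U <- scale(t(X[, mask, drop = FALSE]))  # vertices x maps, unit variance
  map_back <- match(seq_len(n), which(mask))
  e <- mesh$edges
  inside <- mask[e[, 1]] & mask[e[, 2]]
  i <- map_back[e[inside, 1]]; j <- map_back[e[inside, 2]]
  len <- mesh$edge_lengths[inside]
  v <- rowMeans((U[i, , drop = FALSE] - U[j, , drop = FALSE])^2) / len^2
  sigma2 <- 1 / (2 * mean(v))
  2 * sqrt(2 * log(2)) * sqrt(sigma2)
}
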