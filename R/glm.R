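# Vertex-wise general linear models over surface-sampled qR1 and
# random-field-theory cluster-level inference on the masked mesh.

#' Build a design matrix and contrast for a study model
#'
#' Models, in the covariate order intercept, age, sex, ethnicity, group /
#' score:
#' \describe{
#'   \item{`ap`}{qR1 ~ 1 + age + sex + ethnicity + AP; contrast on AP.}
#'   \item{`aps`}{AP group indicator replaced by the continuous
#'     (timbre-averaged) AP score; contrast on APS.}
#'   \item{`ap_europeans`}{European subset only, ethnicity dropped:
#'     qR1 ~ 1 + age + sex + AP; contrast on AP.}
#'   \item{`ap_fdt`}{`ap` plus -log10(FDT); contrast on the FDT term.}
#' }
#' Binary codings: sex female = 1, ethnicity Asian = 1, AP = 1.
#'
#' @param subjects Data frame with columns `age`, `sex`, `ethnicity`, `ap`,
#'   and (as needed) `aps`, `neg_log10_fdt`; indicators coded 0/1.
#' @param model One of `"ap"`, `"aps"`, `"ap_europeans"`, `"ap_fdt"`.
#' @return A `design_spec`: list with `X` (design matrix), `contrast`,
#'   `model`, `rows` (row indices of `subjects` used; the European subset
#'   for `ap_europeans`), and `df` (residual degrees of freedom).
#' @examples
#' tab <- simulate_subject_table(seed = 1)
#' build_design(tab, "ap")$df   # 17 subjects, 5 columns -> 12
#' @export
build_design <- function(subjects,
                         model = c("ap", "aps", "ap_europeans", "ap_fdt")) {
  model <- match.arg(model)
  need <- switch(model,
                 ap = c("age", "sex", "ethnicity", "ap"),
                 aps = c("age", "sex", "ethnicity", "aps"),
                 ap_europeans = c("age", "sex", "ethnicity", "ap"),
                 ap_fdt = c("age", "sex", "ethnicity", "ap", "neg_log10_fdt"))
  miss <- setdiff(need, names(subjects))
  if (length(miss) > 0) stop("missing subject column(s): ", paste(miss, collapse = ", "))
  if (anyNA(subjects[need])) stop("missing values in model variables")

  rows <- seq_len(nrow(subjects))
  if (model == "ap_europeans") {
    rows <- which(subjects$ethnicity == 0)
    if (length(rows) < 3) stop("too few European subjects for the subset model")
    s <- subjects[rows, ]
    X <- cbind(intercept = 1, age = s$age, sex = s$sex, ap = s$ap)
    contrast <- c(0, 0, 0, 1)
  } else if (model == "ap") {
    X <- cbind(intercept = 1, age = subjects$age, sex = subjects$sex,
               ethnicity = subjects$ethnicity, ap = subjects$ap)
    contrast <- c(0, 0, 0, 0, 1)
  } else if (model == "aps") {
    X <- cbind(intercept = 1, age = subjects$age, sex = subjects$sex,
               ethnicity = subjects$ethnicity, aps = subjects$aps)
    contrast <- c(0, 0, 0, 0, 1)
  } else {
    X <- cbind(intercept = 1, age = subjects$age, sex = subjects$sex,
               ethnicity = subjects$ethnicity, ap = subjects$ap,
               neg_log10_fdt = subjects$neg_log10_fdt)
    contrast <- c(0, 0, 0, 0, 0, 1)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient",
         if (model %in% c("ap", "aps", "ap_fdt") &&
             length(unique(X[, "ethnicity"])) == 1)
           " (ethnicity is constant; use model = \"ap_europeans\")" else "")
  }
  structure(list(X = X, contrast = contrast, model = model, rows = rows,
                 df = nrow(X) - ncol(X)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("design_spec '%s': %d subjects x %d regressors (%s), df %d\n",
              x$model, nrow(x$X), ncol(x$X),
              paste(colnames(x$X), collapse = " + "), x$df))
  invisible(x)
}

#' Fit a vertex-wise general linear model
#'
#' Ordinary least squares at every vertex with a shared design matrix; the
#' reported effect is `contrast' beta_hat` with its standard error and
#' t-statistic. Vertices with zero residual variance get `t = +/-Inf` with
#' a warning.
#'
#' @param data A `vertex_dataset` (see [simulate_qr1_dataset()]) or a
#'   numeric matrix, subjects in rows and vertices in columns.
#' @param design A `design_spec` from [build_design()], or a list with
#'   elements `X` and `contrast` (and optionally `rows`).
#' @param keep_residuals Retain the residual maps (needed for
#'   residual-based smoothness estimation).
#' @return A `vertex_glm`: list with per-vertex `effect`, `se`, `t`,
#'   scalar `df`, `design`, and optionally `residuals`.
#' @export
fit_glm <- function(data, design, keep_residuals = FALSE) {
  Y <- if (inherits(data, "vertex_dataset")) data$values else as.matrix(data)
  rows <- design$rows
  if (!is.null(rows)) Y <- Y[rows, , drop = FALSE]
  X <- design$X
  stopifnot(nrow(Y) == nrow(X))
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop("nonpositive residual degrees of freedom (n <= p)")

  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  cvar <- drop(t(design$contrast) %*% xtx_inv %*% design$contrast)
  effect <- drop(t(design$contrast) %*% beta)
  se <- sqrt(cvar * sigma2)
  tval <- effect / se
  # residual variance indistinguishable from zero at this data scale
  zero <- sigma2 <= .Machine$double.eps^1.5 * (colMeans(Y^2) + .Machine$double.xmin)
  if (any(zero)) {
    warning(sum(zero), " vertex/vertices with zero residual variance; t set to +/-Inf")
    tval[zero] <- sign(effect[zero]) * Inf
  }
  structure(list(effect = effect, se = se, t = tval, df = df,
                 beta = beta, design = design,
                 residuals = if (keep_residuals) res else NULL),
            class = "vertex_glm")
}

#' @export
print.vertex_glm <- function(x, ...) {
  cat(sprintf("vertex_glm (%s): %d vertices, df %d; max |t| = %.2f\n",
              if (!is.null(x$design$model)) x$design$model else "custom",
              length(x$t), x$df, max(abs(x$t[is.finite(x$t)]))))
  invisible(x)
}

#' @export
coef.vertex_glm <- function(object, ...) object$effect

#' @export
summary.vertex_glm <- function(object, ...) {
  out <- list(model = object$design$model, df = object$df,
              n_vertices = length(object$t),
              t_range = range(object$t[is.finite(object$t)]),
              effect_range = range(object$effect))
  class(out) <- "summary.vertex_glm"
  out
}

#' @export
print.summary.vertex_glm <- function(x, ...) {
  cat(sprintf("vertex-wise GLM '%s': %d vertices, df %d\n", x$model, x$n_vertices, x$df))
  cat(sprintf("  t in [%.2f, %.2f]; effect in [%.4g, %.4g]\n",
              x$t_range[1], x$t_range[2], x$effect_range[1], x$effect_range[2]))
  invisible(x)
}

#' Euler-characteristic density of a t random field
#'
#' Unified EC densities for a t field with `df` degrees of freedom, in
#' FWHM-standardized (resel) units, for dimensions 0..2.
#'
#' @param t Threshold(s).
#' @param df Degrees of freedom.
#' @param d Dimension: 0, 1 or 2.
#' @return Density value(s).
#' @export
ec_density_t <- function(t, df, d) {
  l2 <- 4 * log(2)
  if (d == 0) return(stats::pt(t, df, lower.tail = FALSE))
  if (d == 1) return(sqrt(l2) / (2 * pi) * (1 + t^2 / df)^(-(df - 1) / 2))
  if (d == 2) {
    cf <- exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2)
    return(l2 / (2 * pi)^1.5 * cf * t * (1 + t^2 / df)^(-(df - 1) / 2))
  }
  stop("d must be 0, 1 or 2")
}

#' Resel counts and EC model for a masked 2D search region
#'
#' Resolution elements (resels) standardize the search region by the
#' smoothing kernel: the 2D resel count is area / FWHM^2; the boundary
#' contributes perimeter / (2 FWHM) and the region topology a
#' zero-dimensional term.
#'
#' @param area_mm2 Retained search area in mm^2 (or a `search_mask`, from
#'   which area and perimeter are taken).
#' @param fwhm_mm Smoothness FWHM in mm (nominal applied FWHM by default in
#'   the pipeline; a residual-based estimate may be supplied instead).
#' @param df Degrees of freedom of the t field.
#' @param perimeter_mm Boundary length of the region (default 0: closed
#'   surface).
#' @return A `resel_model`: list with `resels` (length-3 vector, d = 0..2),
#'   `fwhm_mm`, `area_mm2`, `df`, and `expected_ec(t)`.
#' @examples
#' estimate_resels(6400, 8, df = 12)$resels[3]  # 100
#' @export
estimate_resels <- function(area_mm2, fwhm_mm, df, perimeter_mm = 0) {
  stopifnot(fwhm_mm > 0)
  if (inherits(area_mm2, "search_mask")) {
    perimeter_mm <- attr(area_mm2, "perimeter_mm")
    area_mm2 <- attr(area_mm2, "area_mm2")
  }
  resels <- c(r0 = 1, r1 = perimeter_mm / (2 * fwhm_mm),
              r2 = area_mm2 / fwhm_mm^2)
  obj <- list(resels = resels, fwhm_mm = fwhm_mm, area_mm2 = area_mm2,
              perimeter_mm = perimeter_mm, df = df)
  obj$expected_ec <- function(t) {
    unname(resels[1] * ec_density_t(t, df, 0) +
           resels[2] * ec_density_t(t, df, 1) +
           resels[3] * ec_density_t(t, df, 2))
  }
  structure(obj, class = "resel_model")
}

#' @export
print.resel_model <- function(x, ...) {
  cat(sprintf("resel_model: area %.1f mm^2 at FWHM %.1f mm -> %.2f resels (2D), df %d\n",
              x$area_mm2, x$fwhm_mm, x$resels[3], x$df))
  invisible(x)
}

#' Suprathreshold clusters of a t map
#'
#' Thresholds the t map at the upper `p_thresh` quantile of t(df)
#' (strictly greater), then takes connected components of suprathreshold
#' vertices under 1-ring (edge) adjacency within the mask. Extent is the
#' barycentric vertex area.
#'
#' @param tmap Numeric per-vertex t values.
#' @param mesh A `triangle_mesh`.
#' @param mask Logical vertex mask (search region).
#' @param df Degrees of freedom of the t map.
#' @param p_thresh Cluster-defining (uncorrected) threshold, default 0.001.
#' @param direction `"pos"` (default) tests t > u; `"neg"` tests -t.
#' @return A `cluster_report`: list with `clusters` (data frame: `id`,
#'   `n_vertices`, `area_mm2`, `peak_t`, `peak_vertex`), `members` (list of
#'   vertex index vectors), `threshold_t`, `p_thresh`, `df`, `direction`.
#'   Zero rows when nothing survives.
#' @export
find_clusters <- function(tmap, mesh, mask = NULL, df, p_thresh = 0.001,
                          direction = c("pos", "neg")) {
  direction <- match.arg(direction)
  stopifnot(df >= 1)
  n <- nrow(mesh$vertices)
  if (is.null(mask)) mask <- rep(TRUE, n)
  tt <- if (direction == "neg") -tmap else tmap
  u <- stats::qt(1 - p_thresh, df)
  supra <- which(mask & !is.na(tt) & tt > u)
  empty <- list(clusters = data.frame(id = integer(), n_vertices = integer(),
                                      area_mm2 = numeric(), peak_t = numeric(),
                                      peak_vertex = integer()),
                members = list(), threshold_t = u, p_thresh = p_thresh,
                df = df, direction = direction)
  if (length(supra) == 0) return(structure(empty, class = "cluster_report"))

  inside <- mesh$edges[, 1] %in% supra & mesh$edges[, 2] %in% supra
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(matrix(match(mesh$edges[inside, , drop = FALSE], supra),
                             ncol = 2)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(supra)))
  comp <- igraph::components(g)$membership[as.character(seq_along(supra))]
  members <- split(supra, comp)
  ord <- order(vapply(members, function(m) max(tt[m]), 0), decreasing = TRUE)
  members <- members[ord]
  cl <- do.call(rbind, lapply(seq_along(members), function(k) {
    m <- members[[k]]
    data.frame(id = k, n_vertices = length(m),
               area_mm2 = sum(mesh$vertex_areas[m]),
               peak_t = max(tt[m]), peak_vertex = m[which.max(tt[m])])
  }))
  out <- empty
  out$clusters <- cl
  out$members <- unname(members)
  structure(out, class = "cluster_report")
}

#' Cluster-level corrected p-values by random field theory
#'
#' Attaches to each cluster the family-wise-corrected p-value
#' `1 - exp(-E[N] * P(S >= s))`, where `E[N]` is the expected number of
#' clusters over the masked resels at the cluster-defining threshold
#' (unified EC expansion) and `P(S >= s) = exp(-s / E[S])` is the standard
#' exponential approximation to the cluster-extent distribution in resel
#' units, with `E[S]` the expected extent per cluster.
#'
#' @param report A `cluster_report` from [find_clusters()].
#' @param resel_model A `resel_model` from [estimate_resels()] (same df and
#'   cluster-defining threshold regime).
#' @return The report with columns `extent_resels` and `p_fwer` added, and
#'   attributes `expected_n_clusters`, `fwer_df_warning` (TRUE when df < 3,
#'   where the extent approximation is unreliable).
#' @export
cluster_pvalues <- function(report, resel_model) {
  stopifnot(inherits(report, "cluster_report"), inherits(resel_model, "resel_model"))
  df <- report$df
  u <- report$threshold_t
  en <- resel_model$expected_ec(u)
  # expected suprathreshold resels / expected cluster count
  es <- unname(resel_model$resels[3]) * ec_density_t(u, df, 0) / en
  low_df <- df < 3
  if (low_df) warning("df < 3: cluster-extent approximation unreliable")
  cl <- report$clusters
  if (nrow(cl) > 0) {
    s <- cl$area_mm2 / resel_model$fwhm_mm^2
    cl$extent_resels <- s
    cl$p_fwer <- 1 - exp(-en * exp(-s / es))
  } else {
    cl$extent_resels <- numeric()
    cl$p_fwer <- numeric()
  }
  report$clusters <- cl
  attr(report, "expected_n_clusters") <- unname(en)
  attr(report, "fwer_df_warning") <- low_df
  report
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report: t(%d) > %.2f (p_uncorr %.4g, %s direction): %d cluster(s)\n",
              x$df, x$threshold_t, x$p_thresh, x$direction, nrow(x$clusters)))
  if (nrow(x$clusters) > 0) print(x$clusters, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the configured study on prepared vertex datasets
#'
#' For each dataset (layer/hemisphere) and each requested model: smooth the
#' maps, fit the GLM, and perform RFT cluster inference over the dataset's
#' search mask. Families (layer x hemisphere) are not corrected across by
#' default, matching per-family reporting; `bonferroni_families = TRUE`
#' multiplies cluster p-values by the number of dataset/model families.
#'
#' @param datasets A `vertex_dataset` or named list of them.
#' @param models Character vector of models for [build_design()].
#' @param fwhm_mm,n_iter Smoothing target and iterations.
#' @param p_thresh Cluster-defining threshold (uncorrected p).
#' @param fwer Cluster-level significance level (default 0.05).
#' @param smoothness `"nominal"` (use the applied FWHM for resels, default)
#'   or `"residual"` (estimate from residual maps).
#' @param direction Contrast direction passed to [find_clusters()].
#' @param bonferroni_families Correct across dataset/model families.
#' @return A `study_result`: per dataset and model, the fitted `vertex_glm`,
#'   the corrected `cluster_report`, the `resel_model`, and a combined
#'   significant-cluster table `$significant`.
#' @export
run_study <- function(datasets, models = "ap", fwhm_mm = 8, n_iter = 10,
                      p_thresh = 0.001, fwer = 0.05,
                      smoothness = c("nominal", "residual"),
                      direction = "pos", bonferroni_families = FALSE) {
  smoothness <- match.arg(smoothness)
  if (inherits(datasets, "vertex_dataset")) datasets <- list(data = datasets)
  if (is.null(names(datasets))) names(datasets) <- paste0("data", seq_along(datasets))
  n_fam <- length(datasets) * length(models)
  runs <- list()
  for (dn in names(datasets)) {
    ds <- datasets[[dn]]
    stopifnot(inherits(ds, "vertex_dataset"))
    sm <- build_smoother(ds$mesh, fwhm_mm = fwhm_mm, n_iter = n_iter)
    Ys <- smooth_vertex_map(ds$values, smoother = sm)
    for (mod in models) {
      design <- build_design(ds$subjects, mod)
      fit <- fit_glm(Ys, design, keep_residuals = smoothness == "residual")
      fw <- if (smoothness == "residual") {
        estimate_smoothness_resid(fit$residuals, ds$mesh, ds$mask)
      } else fwhm_mm
      rm_ <- estimate_resels(ds$mask, fw, df = fit$df)
      rep_ <- find_clusters(fit$t, ds$mesh, ds$mask, df = fit$df,
                            p_thresh = p_thresh, direction = direction)
      rep_ <- cluster_pvalues(rep_, rm_)
      if (bonferroni_families && nrow(rep_$clusters) > 0) {
        rep_$clusters$p_fwer <- pmin(1, rep_$clusters$p_fwer * n_fam)
      }
      runs[[paste(dn, mod, sep = ".")]] <-
        list(dataset = dn, model = mod, fit = fit, resels = rm_, report = rep_)
    }
  }
  sig <- do.call(rbind, lapply(names(runs), function(nm) {
    cl <- runs[[nm]]$report$clusters
    cl <- cl[cl$p_fwer < fwer, , drop = FALSE]
    if (nrow(cl) == 0) return(NULL)
    fit <- runs[[nm]]$fit
    cbind(data.frame(run = nm), cl,
          peak_effect = fit$effect[cl$peak_vertex],
          peak_se = fit$se[cl$peak_vertex])
  }))
  structure(list(runs = runs, significant = sig, fwer = fwer,
                 p_thresh = p_thresh, fwhm_mm = fwhm_mm),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d run(s), cluster-defining p %.4g, FWER %.2f\n",
              length(x$runs), x$p_thresh, x$fwer))
  if (is.null(x$significant) || nrow(x$significant) == 0) {
    cat("  no significant clusters\n")
  } else {
    print(x$significant, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
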