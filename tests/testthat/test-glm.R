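# Designs, vertex-wise OLS, resels, clustering and RFT p-values.

test_that("study designs have the expected shape and degrees of freedom", {
  tab <- std_subjects()
  d_ap <- build_design(tab, "ap")
  expect_identical(dim(d_ap$X), c(17L, 5L))
  expect_identical(d_ap$df, 12L)
  d_eur <- build_design(tab, "ap_europeans")
  expect_identical(dim(d_eur$X), c(12L, 4L))
  expect_identical(d_eur$df, 8L)
  expect_true(all(tab$ethnicity[d_eur$rows] == 0))
  d_fdt <- build_design(tab, "ap_fdt")
  expect_identical(d_fdt$df, 11L)
  expect_identical(unname(which(d_fdt$contrast == 1)), 6L)
  # constant ethnicity makes the full model rank deficient
  tab2 <- tab
  tab2$ethnicity <- 0
  expect_error(build_design(tab2, "ap"), "ap_europeans")
  expect_error(build_design(tab[, c("age", "sex")], "ap"), "missing subject column")
})

test_that("vertex-wise OLS matches the normal-equations oracle", {
  set.seed(21)
  for (case in 1:40) {
    n <- sample(8:20, 1)
    p <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    Y <- matrix(rnorm(n * 7), n)
    ctr <- as.numeric(seq_len(p) == p)
    fit <- fit_glm(Y, list(X = X, contrast = ctr))
    # independent route: explicit normal equations
    bt <- solve(t(X) %*% X, t(X) %*% Y)
    res <- Y - X %*% bt
    s2 <- colSums(res^2) / (n - p)
    se <- sqrt(drop(t(ctr) %*% solve(t(X) %*% X) %*% ctr) * s2)
    expect_equal(fit$effect, drop(t(ctr) %*% bt), tolerance = 1e-10)
    expect_equal(fit$t, drop(t(ctr) %*% bt) / se, tolerance = 1e-8)
    expect_identical(fit$df, n - p)
  }
})

test_that("noise-free data reproduce the generating coefficients exactly", {
  tab <- std_subjects()
  des <- build_design(tab, "ap")
  beta <- rbind(0.6, -4e-4, 2e-3, 1e-3, 0.017)
  Y <- des$X %*% beta %*% t(rep(1, 5))
  expect_warning(fit <- fit_glm(Y, des), "zero residual variance")
  expect_equal(fit$effect, rep(0.017, 5), tolerance = 1e-10)
  expect_true(all(is.infinite(fit$t)))
})

test_that("with no covariates the single-vertex GLM is the pooled two-sample t", {
  set.seed(22)
  g <- rep(c(0, 1), c(9, 8))
  y <- rnorm(17, mean = g * 0.3)
  fit <- fit_glm(matrix(y, ncol = 1), list(X = cbind(1, g), contrast = c(0, 1)))
  ref <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
  expect_equal(fit$t[1], unname(ref$statistic), tolerance = 1e-10)
  expect_identical(fit$df, 15L)
})

test_that("adding a constant to all maps changes only the intercept", {
  tab <- std_subjects()
  des <- build_design(tab, "ap")
  set.seed(23)
  Y <- matrix(rnorm(17 * 50), 17)
  f1 <- fit_glm(Y, des)
  f2 <- fit_glm(Y + 5, des)
  expect_equal(f1$t, f2$t, tolerance = 1e-9)
  expect_equal(f1$effect, f2$effect, tolerance = 1e-9)
})

test_that("injected group effects are recovered without bias", {
  tab <- std_subjects()
  des <- build_design(tab, "ap")
  set.seed(24)
  n_rep <- 300
  Y <- outer(tab$ap, rep(0.017, n_rep)) +
    matrix(rnorm(17 * n_rep, sd = 0.01), 17)
  fit <- fit_glm(Y, des)
  se_mean <- sd(fit$effect) / sqrt(n_rep)
  expect_lt(abs(mean(fit$effect) - 0.017), 2 * se_mean + 1e-6)
})

test_that("degenerate designs are refused", {
  expect_error(fit_glm(matrix(1:4, 1), list(X = cbind(1, 0:1), contrast = c(0, 1))))
  # n = p leaves no residual degrees of freedom
  expect_error(fit_glm(matrix(rnorm(4), 2),
                       list(X = cbind(1, c(0, 1)), contrast = c(0, 1))),
               "degrees of freedom")
})

test_that("resel counts follow area / FWHM^2 and EC expectation is well behaved", {
  rm_ <- estimate_resels(6400, 8, df = 12)
  expect_equal(unname(rm_$resels[3]), 100)
  # expected EC decreasing in threshold, vanishing at huge FWHM
  ts <- seq(2, 8, by = 0.5)
  expect_true(all(diff(rm_$expected_ec(ts)) < 0))
  # at huge FWHM the 1D/2D terms vanish; only the topological floor remains
  rm_inf <- estimate_resels(6400, 1e6, df = 12)
  expect_lt(rm_inf$expected_ec(4.5) - ec_density_t(4.5, 12, 0), 1e-6)
  # doubling the area doubles the 2D term
  rm2 <- estimate_resels(12800, 8, df = 12)
  expect_equal(unname(rm2$resels[3]), 200)
  expect_equal(rm2$expected_ec(5) - ec_density_t(5, 12, 0),
               2 * (rm_$expected_ec(5) - ec_density_t(5, 12, 0)))
})

test_that("clustering finds connected suprathreshold components with correct extents", {
  m <- std_patch()
  mask <- std_mask()
  df <- 12
  u <- qt(1 - 0.001, df)
  # empty map: no clusters
  expect_identical(nrow(find_clusters(rep(0, nrow(m$vertices)), m, mask, df)$clusters), 0L)

  # two islands separated by a subthreshold moat
  center <- which.min(colSums((t(m$vertices) - colMeans(m$vertices))^2))
  left <- which.min(colSums((t(m$vertices) - (colMeans(m$vertices) - c(12, 0, 0)))^2))
  d_center <- geodesic_distances(m, center)
  d_left <- geodesic_distances(m, left)
  tmap <- numeric(nrow(m$vertices))
  tmap[d_center <= 4] <- u + 2
  tmap[d_left <= 4] <- u + 1
  rep2 <- find_clusters(tmap, m, mask, df)
  expect_identical(nrow(rep2$clusters), 2L)
  expect_equal(rep2$clusters$peak_t[1], u + 2)

  # planted disc of radius r has extent ~ pi r^2
  r <- 5
  tmap2 <- numeric(nrow(m$vertices))
  tmap2[d_center <= r] <- u + 1
  rep3 <- find_clusters(tmap2, m, mask, df)
  expect_identical(nrow(rep3$clusters), 1L)
  expect_lt(abs(rep3$clusters$area_mm2 - pi * r^2), 2 * pi * r * m$mean_edge + 5)

  # values exactly at the threshold are subthreshold (strict inequality)
  tmap3 <- numeric(nrow(m$vertices))
  tmap3[d_center <= 3] <- u
  expect_identical(nrow(find_clusters(tmap3, m, mask, df)$clusters), 0L)
})

test_that("cluster p-values decrease in extent and respect the zero-extent limit", {
  rm_ <- estimate_resels(1600, 8, df = 12, perimeter_mm = 160)
  u <- qt(1 - 0.001, 12)
  en <- rm_$expected_ec(u)
  fake <- structure(list(
    clusters = data.frame(id = 1:4, n_vertices = c(1, 10, 50, 200),
                          area_mm2 = c(0.001, 10, 40, 160),
                          peak_t = rep(u + 1, 4), peak_vertex = 1:4),
    members = list(1, 2, 3, 4), threshold_t = u, p_thresh = 0.001,
    df = 12, direction = "pos"), class = "cluster_report")
  out <- cluster_pvalues(fake, rm_)
  p <- out$clusters$p_fwer
  expect_true(all(diff(p) < 0))
  expect_equal(p[1], 1 - exp(-en), tolerance = 1e-3)
  expect_true(all(p > 0 & p <= 1))
})

test_that("cluster inference is invariant to vertex relabeling", {
  m <- small_patch()
  n <- nrow(m$vertices)
  labels <- rep("keep", n)
  labels[mesh_boundary_vertices(m)] <- "rim"
  mask <- build_search_mask(m, labels, exclude = "rim")
  center <- which.min(colSums((t(m$vertices) - colMeans(m$vertices))^2))
  tmap <- numeric(n)
  tmap[geodesic_distances(m, center) <= 3] <- 5
  rm_ <- estimate_resels(mask, 4, df = 12)
  p1 <- cluster_pvalues(find_clusters(tmap, m, mask, 12), rm_)$clusters$p_fwer

  set.seed(31)
  perm <- sample(n)                       # perm[i]: new index of old vertex i
  m2 <- triangle_mesh(m$vertices[order(perm), ],
                      matrix(perm[m$faces], ncol = 3))
  tmap2 <- numeric(n); tmap2[perm] <- tmap
  mask2 <- logical(n); mask2[perm] <- mask
  rm2 <- estimate_resels(sum(m2$vertex_areas[mask2]), 4, df = 12,
                         perimeter_mm = attr(mask, "perimeter_mm"))
  p2 <- cluster_pvalues(find_clusters(tmap2, m2, mask2, 12), rm2)$clusters$p_fwer
  expect_equal(sort(p1), sort(p2), tolerance = 1e-10)
})

test_that("run_study recovers a planted cluster and reports effect tables", {
  tab <- std_subjects()
  ds <- simulate_qr1_dataset(std_patch(), tab, seed = 41)
  st <- run_study(ds, models = c("ap", "aps"))
  sig <- st$significant
  expect_false(is.null(sig))
  ap_sig <- sig[sig$run == "data.ap", ]
  expect_gte(nrow(ap_sig), 1)
  # the detected cluster overlaps the planted disc
  members <- st$runs[["data.ap"]]$report$members[[ap_sig$id[1]]]
  expect_gt(length(intersect(members, ds$effect$disc)) / length(members), 0.5)
  expect_true(all(c("peak_effect", "peak_se") %in% names(sig)))
  # single subject fails fast
  ds1 <- ds
  ds1$values <- ds$values[1, , drop = FALSE]
  ds1$subjects <- ds$subjects[1, ]
  expect_error(run_study(ds1, models = "ap"))
})
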