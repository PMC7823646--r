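test_that("gradient and Hessian are exact on quadratic surfaces", {
  # flat patch
  gh <- gradientHessian(matrix(900, 3, 3))
  expect_equal(gh$g, c(0, 0))
  expect_equal(gh$H, matrix(0, 2, 2))
  # f(x, y) = (x^2 + y^2)/2 sampled around (1, 0): g = (1, 0), H = I
  gh <- gradientHessian(patchFromFunction(function(x, y) (x^2 + y^2) / 2 + 100,
                                          x0 = 1, y0 = 0))
  expect_equal(gh$g, c(1, 0))
  expect_equal(gh$H, diag(2))
  # f(x, y) = xy around the origin: pure mixed second derivative
  gh <- gradientHessian(patchFromFunction(function(x, y) x * y + 100))
  expect_equal(gh$H[1, 2], 1)
  expect_equal(gh$H[2, 1], 1)
  # random quadratics: derivatives recovered to machine precision
  set.seed(42)
  for (i in 1:20) {
    cf <- rnorm(6)
    f <- function(x, y) cf[1] + cf[2] * x + cf[3] * y +
      cf[4] * x^2 / 2 + cf[5] * y^2 / 2 + cf[6] * x * y + 1000
    gh <- gradientHessian(patchFromFunction(f, x0 = 2, y0 = -1))
    expect_equal(gh$g, c(cf[2] + 2 * cf[4] / 2 * 2 + cf[6] * -1,
                         cf[3] + cf[5] * -1 + cf[6] * 2),
                 tolerance = 1e-9)
    expect_equal(gh$H, matrix(c(cf[4], cf[6], cf[6], cf[5]), 2, 2),
                 tolerance = 1e-9)
  }
  expect_error(gradientHessian(matrix(c(0, rep(5, 8)), 3, 3)), "incomplete")
})

test_that("mean curvature evaluates the closed form with the zero-gradient convention", {
  expect_equal(meanCurvature(c(0, 0), diag(2)), 0)
  expect_equal(meanCurvature(c(1, 0), diag(2)), -0.5)
  expect_equal(meanCurvature(c(1, 1), matrix(c(0, 1, 1, 0), 2, 2)),
               2 / (2 * 2^1.5))
})

test_that("local variance uses denominator 8 and matches the two-pass oracle", {
  expect_equal(localVariance(matrix(700, 3, 3)), 0)
  # 7 values d, 2 values d + 1 -> 126/648; 8 values d, 1 value d + 1 -> 72/648
  expect_equal(localVariance(matrix(c(rep(672, 7), 673, 673), 3, 3)), 126 / 648)
  expect_equal(localVariance(matrix(c(rep(644, 8), 645), 3, 3)), 72 / 648)
  set.seed(11)
  for (i in 1:1000) {
    patch <- matrix(sample(500:4000, 9, replace = TRUE), 3, 3)
    m <- mean(patch)
    expect_equal(localVariance(patch), sum((patch - m)^2) / 8,
                 tolerance = 1e-12)
  }
})

test_that("polygon labelling follows the strict even-odd rule", {
  sq <- list(vertices = rbind(c(2, 2), c(2, 6), c(6, 6), c(6, 2)), part = "He")
  mask <- labelByPolygons(10L, 10L, list(sq))
  expect_equal(mask[5, 5], 1L)     # pixel (4, 4)
  expect_equal(mask[1, 1], 0L)     # pixel (0, 0)
  expect_equal(labelByPolygons(8L, 8L, list()), matrix(0L, 8, 8))
  # strict interior of a w x h rectangle on the integer grid
  for (dims in list(c(5, 9), c(7, 4), c(12, 12))) {
    h <- dims[1]; w <- dims[2]
    rect <- list(vertices = rbind(c(1, 1), c(1, 1 + w), c(1 + h, 1 + w),
                                  c(1 + h, 1)), part = "Ru")
    mask <- labelByPolygons(20L, 20L, list(rect))
    expect_equal(sum(mask == 2L), (w - 1) * (h - 1))
  }
  # later polygons win on overlap
  a <- list(vertices = rbind(c(0, 0), c(0, 8), c(8, 8), c(8, 0)), part = "He")
  b <- list(vertices = rbind(c(2, 2), c(2, 6), c(6, 6), c(6, 2)), part = "Ud")
  mask <- labelByPolygons(10L, 10L, list(a, b))
  expect_equal(mask[5, 5], 8L)
  expect_equal(mask[2, 2], 1L)
  expect_error(labelByPolygons(4L, 4L, list(list(vertices = rbind(c(0, 0),
               c(1, 1)), part = "He"))), "3 vertices")
})

test_that("extractFeatures matches an independent eligibility enumeration", {
  # a single isolated foreground pixel yields no complete patch
  d <- matrix(0L, 8, 8); d[4, 4] <- 900L
  l <- matrix(0L, 8, 8); l[4, 4] <- 2L
  sc <- new("DepthScene", depth = d, labels = l, pose = presetPose("S"),
            noiseSigma = 0)
  expect_equal(nrow(featureData(extractFeatures(sc))), 0L)
  # 5x5 constant block: 9 interior pixels, flat features
  d <- matrix(0L, 9, 9); d[3:7, 3:7] <- 800L
  l <- matrix(0L, 9, 9); l[3:7, 3:7] <- 2L
  tab <- extractFeatures(new("DepthScene", depth = d, labels = l,
                             pose = presetPose("S"), noiseSigma = 0))
  df <- featureData(tab)
  expect_equal(nrow(df), 9L)
  expect_true(all(df$m_curv == 0))
  expect_true(all(df$var == 0))
  expect_true(all(df$Ru == 1L))
  # enumeration oracle on a real rendered crop
  sc <- smallScene("S", noise = 2, seed = 4, w = 64L, h = 64L)
  d <- depthMap(sc); l <- labelMask(sc)
  count <- 0L
  for (r in 2:63) for (cl in 2:63)
    if (l[r, cl] > 0 && all(d[(r - 1):(r + 1), (cl - 1):(cl + 1)] > 0))
      count <- count + 1L
  expect_equal(nrow(featureData(extractFeatures(sc))), count)
  # per-pixel values agree with the scalar feature functions
  df <- featureData(extractFeatures(sc))
  set.seed(3)
  for (i in sample(nrow(df), 25)) {
    r <- df$row[i] + 1L; cl <- df$col[i] + 1L
    patch <- d[(r - 1):(r + 1), (cl - 1):(cl + 1)]
    gh <- gradientHessian(patch)
    expect_equal(df$m_curv[i], meanCurvature(gh$g, gh$H), tolerance = 1e-9)
    expect_equal(df$var[i], localVariance(patch), tolerance = 1e-9)
    expect_equal(df$depth[i], d[r, cl])
  }
})

test_that("sphere curvature is sign-uniform on renders and radius-ordered on exact samples", {
  intr <- cameraIntrinsics(64L, 64L, 57)
  pose <- presetPose("S")
  centre <- pose@translation + 1.5 * pose@rotation[, 3]
  render_sphere <- function(radius) {
    s <- new("Primitive", shape = "ellipsoid", center = centre,
             size = rep(radius, 3), orientation = diag(3), part = "He")
    sc <- renderDepth(list(s), intr, pose, noise_sigma = 0, seed = 1)
    featureData(extractFeatures(sc))
  }
  # rendered cap, away from the silhouette: uniform curvature sign
  pick <- function(df) df[abs(df$row - 31.5) < 3 & abs(df$col - 31.5) < 3, ]
  for (r in c(0.15, 0.30)) {
    mc <- pick(render_sphere(r))$m_curv
    expect_true(all(mc < 0))
  }
  # analytic derivatives of the sphere depth z = d0 - sqrt(R^2 - rho^2)
  # through the curvature formula obey the exact law -1/(2 rho), rho the
  # offset from the cap centre
  sphere_curv <- function(R, x0, y0) {
    w <- sqrt(R^2 - x0^2 - y0^2)
    g <- c(x0, y0) / w
    H <- diag(2) / w + outer(c(x0, y0), c(x0, y0)) / w^3
    meanCurvature(g, H)
  }
  for (pt in list(c(2, 0), c(3, 1), c(1, 4), c(5, 5)))
    for (R in c(12, 25))
      expect_equal(sphere_curv(R, pt[1], pt[2]),
                   -1 / (2 * sqrt(sum(pt^2))), tolerance = 1e-12)
  # hence at matched relative positions on the cap (offset a fixed
  # fraction of the sphere radius) the smaller sphere's curvature
  # strictly exceeds the larger sphere's in absolute value
  for (frac in c(0.2, 0.5, 0.8)) {
    cs <- sphere_curv(12, frac * 12, 0)
    cl <- sphere_curv(25, frac * 25, 0)
    expect_lt(cs, 0); expect_lt(cl, 0)
    expect_gt(abs(cs), abs(cl))
  }
})

test_that("MinMax standardisation maps to [0, 1] without clipping new data", {
  x <- cbind(c(2, 4, 6), c(5, 5, 5), c(0, 10, 5), c(1, 2, 3), c(0, 1, 2))
  tab <- tableFromMatrix(x, c(1L, 2L, 3L))
  params <- minmaxFit(tab)
  scaled <- featureData(minmaxApply(tab, params))
  expect_equal(scaled$row, c(0, 0.5, 1))
  expect_equal(scaled$col, c(0, 0, 0))  # constant feature -> 0
  # unseen value beyond the fitted range extrapolates past 1
  tab2 <- tableFromMatrix(matrix(c(12, rep(0, 4)), 1), 1L)
  params2 <- list(min = c(row = 0, col = 0, depth = 0, m_curv = 0, var = 0),
                  max = c(row = 10, col = 1, depth = 1, m_curv = 1, var = 1))
  expect_equal(featureData(minmaxApply(tab2, params2))$row, 1.2)
  # fitted-on-self features always land inside [0, 1]
  sc <- smallScene("N", noise = 2, seed = 6, w = 96L, h = 72L)
  tab3 <- extractFeatures(sc)
  scaled3 <- featureData(minmaxApply(tab3, minmaxFit(tab3)))
  for (col in c("row", "col", "depth", "m_curv", "var")) {
    expect_gte(min(scaled3[[col]]), 0)
    expect_lte(max(scaled3[[col]]), 1)
  }
  empty <- tableFromMatrix(matrix(numeric(0), 0, 5), integer(0))
  expect_error(minmaxFit(empty), "empty")
})

test_that("hold-out split is disjoint, exhaustive, stratified and seeded", {
  x <- matrix(runif(500), 100, 5)
  tab <- tableFromMatrix(x, rep(c(2L, 8L), c(90, 10)))  # 90 Ru, 10 Ud
  sp <- splitHoldout(tab, 0.3, seed = 5)
  expect_equal(nrow(featureData(sp$train)), 70L)
  expect_equal(nrow(featureData(sp$holdout)), 30L)
  expect_equal(sum(featureData(sp$holdout)$Ru), 27)  # 90 * 0.3
  expect_equal(sum(featureData(sp$holdout)$Ud), 3)   # 10 * 0.3
  sp2 <- splitHoldout(tab, 0.3, seed = 5)
  expect_identical(featureData(sp$holdout), featureData(sp2$holdout))
  expect_error(splitHoldout(tab, 1.5), "between 0 and 1")
})

test_that("feature CSV keeps the canonical header and round-trips", {
  sc <- smallScene("S", noise = 2, seed = 2, w = 64L, h = 48L)
  tab <- extractFeatures(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureCSV(tab, path)
  expect_identical(strsplit(readLines(path, n = 1), ",")[[1]],
                   c("No", "row", "col", "depth", "m_curv", "var",
                     "He", "Ru", "Ba", "fFL", "aFL", "fHL", "aHL", "Ud"))
  back <- readFeatureCSV(path, "S")
  expect_equal(featureData(back), featureData(tab), ignore_attr = TRUE)
})
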