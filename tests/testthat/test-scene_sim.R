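test_that("camera presets encode the recording geometry", {
  s <- presetPose("S")
  expect_equal(s@translation[3], 0.6)
  # optical axis (third rotation column) is horizontal for the side view
  expect_equal(s@rotation[3, 3], 0, tolerance = 1e-12)
  expect_false(s@flipped)
  u <- presetPose("U")
  expect_true(u@flipped)
  # top-view axes point downward-inward
  expect_lt(u@rotation[3, 3], 0)
  n <- presetPose("N")
  expect_lt(n@rotation[3, 3], 0)
  # rotations are orthonormal
  for (p in list(s, n, u))
    expect_equal(crossprod(p@rotation), diag(3), tolerance = 1e-12)
  expect_error(presetPose("X"), "unknown camera position")
})

test_that("buildCow is deterministic, covers all parts, scales with height", {
  a <- buildCow(1.46, 2.4, seed = 7)
  b <- buildCow(1.46, 2.4, seed = 7)
  expect_identical(lapply(a@primitives, function(p) p@center),
                   lapply(b@primitives, function(p) p@center))
  parts <- vapply(a@primitives, function(p) p@part, character(1))
  expect_setequal(parts, bodyParts())
  # z extents grow monotonically with sacrum height at fixed seed
  lo <- buildCow(1.43, 2.2, seed = 1)
  hi <- buildCow(1.49, 2.6, seed = 1)
  zlo <- vapply(lo@primitives, function(p) primitiveBBox(p)["max", 3], numeric(1))
  zhi <- vapply(hi@primitives, function(p) primitiveBBox(p)["max", 3], numeric(1))
  expect_true(all(zhi > zlo))
  expect_error(buildCow(-1, 2.4), "positive")
})

test_that("renderDepth handles degenerate scenes and exact geometry", {
  intr <- cameraIntrinsics(101L, 101L, 57)
  pose <- presetPose("S")
  empty <- renderDepth(list(), intr, pose, noise_sigma = 0, seed = 1)
  expect_true(all(depthMap(empty) == 0))
  expect_true(all(labelMask(empty) == 0))
  # sphere of radius 0.2 m centred on the optical axis 1.5 m ahead:
  # principal-point depth is 1500 - 200 = 1300 mm
  centre <- pose@translation + 1.5 * pose@rotation[, 3]
  sphere <- new("Primitive", shape = "ellipsoid", center = centre,
                size = rep(0.2, 3), orientation = diag(3), part = "He")
  sc <- renderDepth(list(sphere), intr, pose, noise_sigma = 0, seed = 1)
  expect_equal(depthMap(sc)[51, 51], 1300L)
  expect_equal(labelMask(sc)[51, 51], 1L)
})

test_that("rendered scenes are deterministic and label-consistent", {
  a <- smallScene("N", noise = 2, seed = 3)
  b <- smallScene("N", noise = 2, seed = 3)
  expect_identical(depthMap(a), depthMap(b))
  expect_identical(labelMask(a), labelMask(b))
  # depth == 0 exactly where label == 0 (class validity enforces this,
  # but check the rendered instance explicitly)
  expect_identical(depthMap(a) == 0L, labelMask(a) == 0L)
  expect_true(all(depthMap(a)[depthMap(a) > 0] >= 500))
  expect_true(all(depthMap(a) <= 4000))
})

test_that("udder is occluded from pose U but visible from N and S", {
  for (seed in 1:3) {
    cow <- buildCow(1.43 + 0.03 * (seed - 1), 2.3, seed = seed)
    intr <- cameraIntrinsics(320L, 240L, 57)
    labU <- labelMask(renderDepth(cow, intr, presetPose("U"), 0, seed))
    expect_false(8L %in% labU)
    # the other seven parts are all seen from U
    expect_setequal(setdiff(unique(as.vector(labU)), 0L), 1:7)
    for (p in c("N", "S")) {
      lab <- labelMask(renderDepth(cow, intr, presetPose(p), 0, seed))
      expect_setequal(setdiff(unique(as.vector(lab)), 0L), 1:8)
    }
  }
})

test_that("rendered depth matches a per-pixel analytic oracle", {
  # independent scalar oracle: per pixel, per primitive, smallest
  # positive root of the quadratic via polyroot / explicit cap checks
  oracleDepth <- function(prims, intr, pose) {
    W <- intr@width; H <- intr@height; f <- intr@focal
    R <- pose@rotation; o <- pose@translation
    out <- matrix(0, H, W)
    for (r in seq_len(H)) for (cl in seq_len(W)) {
      u <- (cl - 1 + 0.5 - W / 2) / f
      v <- (r - 1 + 0.5 - H / 2) / f
      D <- as.vector(R %*% c(u, v, 1))
      tbest <- Inf
      for (prim in prims) {
        Q <- prim@orientation
        ol <- as.vector(t(Q) %*% (o - prim@center))
        dl <- as.vector(t(Q) %*% D)
        if (prim@shape == "ellipsoid") {
          s <- prim@size
          a <- sum((dl / s)^2); b <- 2 * sum(ol * dl / s^2)
          cc <- sum((ol / s)^2) - 1
          disc <- b^2 - 4 * a * cc
          if (disc >= 0) {
            for (t in sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a)))
              if (t > 1e-9 && t < tbest) { tbest <- t; break }
          }
        } else {
          rad <- prim@size[1]; h <- prim@size[2]
          a <- dl[1]^2 + dl[2]^2; b <- 2 * (ol[1] * dl[1] + ol[2] * dl[2])
          cc <- ol[1]^2 + ol[2]^2 - rad^2
          disc <- b^2 - 4 * a * cc
          cand <- numeric(0)
          if (disc >= 0 && a > 0) {
            ts <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
            cand <- c(cand, ts[ts > 1e-9 & abs(ol[3] + ts * dl[3]) <= h])
          }
          for (zc in c(-h, h)) {
            tc <- (zc - ol[3]) / dl[3]
            if (is.finite(tc) && tc > 1e-9 &&
                (ol[1] + tc * dl[1])^2 + (ol[2] + tc * dl[2])^2 <= rad^2)
              cand <- c(cand, tc)
          }
          if (length(cand)) tbest <- min(tbest, min(cand))
        }
      }
      if (is.finite(tbest)) {
        d <- tbest * 1000
        if (d >= 500 && d <= 4000) out[r, cl] <- round(d)
      }
    }
    out
  }
  intr <- cameraIntrinsics(32L, 32L, 57)
  cow <- buildCow(1.46, 2.4, seed = 2)
  for (p in c("S", "U")) {
    sc <- renderDepth(cow, intr, presetPose(p), noise_sigma = 0, seed = 1)
    expect_equal(depthMap(sc), matrix(as.integer(oracleDepth(cow@primitives,
                 intr, presetPose(p))), 32, 32), tolerance = 0)
  }
})

test_that("depth noise has the configured standard deviation", {
  clean <- smallScene("S", noise = 0, seed = 5, w = 320L, h = 240L)
  noisy <- smallScene("S", noise = 4, seed = 5, w = 320L, h = 240L)
  fg <- depthMap(clean) > 0 & depthMap(noisy) > 0
  expect_gt(sum(fg), 1e4)
  resid <- (depthMap(noisy) - depthMap(clean))[fg]
  expect_lt(abs(sd(resid) - 4) / 4, 0.1)
})

test_that("PGM round trip is bit-exact and rejects malformed input", {
  sc <- smallScene("N", noise = 2, seed = 9, w = 64L, h = 48L)
  stem <- file.path(withr::local_tempdir(), "scene")
  sceneToPGM(sc, stem)
  back <- pgmToScene(stem)
  expect_identical(depthMap(back), depthMap(sc))
  expect_identical(labelMask(back), labelMask(sc))
  expect_equal(back@pose@rotation, sc@pose@rotation)
  expect_equal(back@pose@preset, sc@pose@preset)
  # stored maxval covers the full 16-bit depth contract
  header <- readLines(paste0(stem, ".depth.pgm"), n = 3, warn = FALSE)
  expect_gte(as.integer(header[3]), 4000L)
  # truncated pixel payload is a format error
  full <- readBin(paste0(stem, ".depth.pgm"), "raw",
                  file.size(paste0(stem, ".depth.pgm")))
  writeBin(full[1:100], paste0(stem, ".depth.pgm"))
  expect_error(pgmToScene(stem), "truncated")
  writeLines("P6 broken", paste0(stem, ".depth.pgm"))
  expect_error(pgmToScene(stem), "PGM")
})
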