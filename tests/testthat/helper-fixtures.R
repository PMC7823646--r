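# Shared fixtures: small renders and hand-built patches/tables used
# across the module tests. Everything is generated in code and seeded.

smallIntrinsics <- function(w = 160L, h = 120L) cameraIntrinsics(w, h, 57)

# a small labelled render of a standard cow from one pose
smallScene <- function(position = "S", noise = 0, seed = 1L,
                       w = 160L, h = 120L) {
  renderDepth(buildCow(1.46, 2.4, seed = seed), smallIntrinsics(w, h),
              presetPose(position), noise_sigma = noise, seed = seed + 100L)
}

# 3x3 patch sampling f at (x0 + dx, y0 + dy), dx/dy in -1..1; x = column
# direction, y = row direction
patchFromFunction <- function(f, x0 = 0, y0 = 0) {
  outer(-1:1, -1:1, function(dy, dx) f(x0 + dx, y0 + dy))
}

# feature table built directly from a data.frame of features + class
# indices (1..8), bypassing rendering
tableFromMatrix <- function(x, y, position = "S") {
  onehot <- matrix(0L, length(y), 8L,
                   dimnames = list(NULL, bodyParts()))
  onehot[cbind(seq_along(y), y)] <- 1L
  df <- cbind(as.data.frame(x), as.data.frame(onehot))
  names(df)[1:5] <- c("row", "col", "depth", "m_curv", "var")
  new("FeatureTable", data = df, position = position)
}

# random 5-column feature matrix with two well-separated class blobs
twoBlobData <- function(n_per = 50L, sep = 1, sigma = 0.05, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 5, 0, sigma), n_per),
             matrix(rnorm(n_per * 5, sep, sigma), n_per))
  list(x = x, y = rep(1:2, each = n_per))
}

# plain-R reference kNN with the package's tie rules: distances by loop,
# order() is stable so exact distance ties keep lower row index first
oracleKnn <- function(train, labels, queries, k, n_classes) {
  apply(queries, 1, function(q) {
    d <- sqrt(colSums((t(train) - q)^2))
    nb <- order(d)[seq_len(k)]
    votes <- tabulate(labels[nb], nbins = n_classes)
    best <- which(votes == max(votes))
    if (length(best) == 1L) best
    else labels[nb][match(TRUE, labels[nb] %in% best)]
  })
}
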