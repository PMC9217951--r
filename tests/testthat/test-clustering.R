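# PCA projection, mixture fitting/assignment, DNM2-positive cluster
# selection, and the end-to-end partition recovery property.

test_that("PCA keeps the smallest component set reaching the target", {
  set.seed(1)
  W <- qr.Q(qr(matrix(rnorm(30), 10, 3)))      # orthonormal 3-dim latent
  Z <- matrix(rnorm(600), 200, 3)
  X <- Z %*% t(W) + matrix(rnorm(2000, 0, 0.01), 200, 10)
  red <- reduceDimensions(X, varianceTarget = 0.9)
  expect_equal(red$basis$nComponents, 3L)
  # full variance target on full-rank data: near-perfect reconstruction
  set.seed(2)
  Y <- matrix(rnorm(40 * 6), 40, 6)
  redF <- reduceDimensions(Y, varianceTarget = 1.0)
  expect_equal(redF$basis$nComponents, 6L)
  rec <- redF$scores %*% t(redF$basis$rotation)
  rec <- sweep(rec, 2L, -redF$basis$center)
  expect_equal(rec, Y, tolerance = 1e-8, ignore_attr = TRUE)
  # projecting the training mean gives the zero vector
  expect_equal(as.numeric(projectFeatures(redF$basis,
                                          matrix(colMeans(Y), 1))),
               rep(0, 6), tolerance = 1e-10)
})

test_that("BIC selects the generating number of components", {
  set.seed(3)
  blob1 <- matrix(rnorm(300), 150, 2)
  blob2 <- sweep(matrix(rnorm(300), 150, 2), 2L, c(10, 10), "+")
  m2 <- fitMixture(rbind(blob1, blob2), kRange = 1:5, seed = 4)
  expect_equal(nClusters(m2), 2L)
  m1 <- fitMixture(blob1, kRange = 1:5, seed = 4)
  expect_equal(nClusters(m1), 1L)
  # deterministic given the seed
  m2b <- fitMixture(rbind(blob1, blob2), kRange = 1:5, seed = 4)
  expect_identical(m2@parameters$mean, m2b@parameters$mean)
  expect_error(fitMixture(blob1[1:40, ], kRange = 2:8, seed = 1),
               "more than max\\(kRange\\)")
})

test_that("posterior assignment is normalized and confident at the means", {
  set.seed(5)
  X <- rbind(matrix(rnorm(200), 100, 2),
             sweep(matrix(rnorm(200), 100, 2), 2L, c(12, 0), "+"))
  m <- fitMixture(X, kRange = 2:3, seed = 6)
  asg <- assignClusters(m, X)
  expect_equal(rowSums(asg$posterior), rep(1, 200), tolerance = 1e-9)
  centers <- t(m@parameters$mean)
  asgC <- assignClusters(m, centers)
  expect_equal(asgC$labels, 1:2)
  expect_true(all(apply(asgC$posterior, 1L, max) > 0.99))
  expect_error(assignClusters(m, X[, 1, drop = FALSE]),
               "dimension mismatch")
})

test_that("the DNM2-positive cluster is pure on default synthetic mixtures", {
  p <- eventParams()
  ds <- simulateDataset(p, 400, seed = 21)
  f <- extractFeatures(ds$events)
  sc <- scaleFeatures(f)
  red <- reduceDimensions(sc$scaled)
  m <- fitMixture(red$scores, kRange = 2:8, seed = 22)
  asg <- assignClusters(m, red$scores)
  sel <- identifyDnm2PositiveCluster(asg$labels, f)
  truthCme <- ds$truth$class != "visitor"
  expect_gte(mean(truthCme[asg$labels == sel$cluster]), 0.95)
  # all floor-passing clusters together recover the CME/visitor partition
  predCme <- asg$labels %in% sel$dnm2Positive
  expect_gte(mclust::adjustedRandIndex(truthCme, predCme), 0.9)
})

test_that("degenerate selection cases are flagged", {
  feats <- data.frame(event_id = sprintf("e%02d", 1:40),
                      dnm2_sig_frac = rep(0.2, 40),
                      lifetime = rep(6, 40),
                      mean_step = rep(120, 40))
  # visitors-only: best cluster fails the DNM2 floor
  expect_warning(sel <- identifyDnm2PositiveCluster(rep(1L, 40), feats),
                 "floor")
  expect_true(is.na(sel$cluster))
  # a single healthy cluster is trivially selected
  feats$dnm2_sig_frac <- 1
  feats$lifetime <- 40
  feats$mean_step <- 25
  sel1 <- identifyDnm2PositiveCluster(rep(1L, 40), feats)
  expect_equal(sel1$cluster, 1L)
  # an exact tie demands manual review
  two <- rbind(feats, feats)
  expect_error(identifyDnm2PositiveCluster(rep(1:2, each = 40), two), "tie")
})

test_that("permuting event order permutes, but does not change, the partition", {
  p <- eventParams()
  ds <- simulateDataset(p, 200, seed = 31)
  f <- extractFeatures(ds$events)
  run <- function(feats) {
    sc <- scaleFeatures(feats)
    red <- reduceDimensions(sc$scaled)
    m <- fitMixture(red$scores, kRange = 2:6, seed = 32)
    assignClusters(m, red$scores)$labels
  }
  l1 <- run(f)
  set.seed(33)
  perm <- sample.int(nrow(f))
  l2 <- run(f[perm, ])
  expect_equal(mclust::adjustedRandIndex(l1[perm], l2), 1)
})
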