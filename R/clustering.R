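# PCA projection + Gaussian mixture clustering of scaled feature vectors,
# and selection of the DNM2-positive cluster (detectable DNM2 throughout,
# long lived, low motility).

#' Project scaled features to a low-dimensional space
#'
#' Principal component analysis keeping the smallest number of components
#' that explains at least `varianceTarget` of the total variance. Null
#' components (rank-deficient input) are dropped.
#'
#' @param scaled numeric matrix of scaled features (events in rows).
#' @param varianceTarget fraction of variance to retain, default 0.90.
#' @return list with `scores` (projected matrix) and `basis` (`center`,
#'   `rotation`, `nComponents`, `varianceExplained`), reusable via
#'   [projectFeatures()].
#' @export
reduceDimensions <- function(scaled, varianceTarget = 0.9) {
  m <- as.matrix(scaled)
  if (any(!is.finite(m))) stop("scaled feature matrix must be finite")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- ev > max(ev) * 1e-12          # drop null directions
  ev <- ev[keep]
  cumvar <- cumsum(ev) / sum(ev)
  nc <- which(cumvar >= varianceTarget - 1e-12)[1L]
  if (is.na(nc)) nc <- length(ev)
  basis <- list(center = pc$center,
                rotation = pc$rotation[, seq_len(nc), drop = FALSE],
                nComponents = nc, varianceExplained = cumvar[nc])
  list(scores = pc$x[, seq_len(nc), drop = FALSE], basis = basis)
}

#' @rdname reduceDimensions
#' @param basis a basis list from [reduceDimensions()] (or a
#'   [ClusterModel-class] `@basis`).
#' @param newdata matrix of scaled feature vectors to project.
#' @export
projectFeatures <- function(basis, newdata) {
  m <- as.matrix(newdata)
  sweep(m, 2L, basis$center) %*% basis$rotation
}

#' Fit a Gaussian mixture over a range of component counts
#'
#' Full-covariance Gaussian mixtures are fitted for each K in `kRange` and
#' the number of components is selected by BIC (via mclust, whose model-based
#' hierarchical initialization is deterministic; the seed is recorded with
#' the model).
#'
#' @param scores projected feature matrix from [reduceDimensions()].
#' @param kRange candidate component counts, default `2:8`.
#' @param seed integer seed recorded in the model.
#' @param basis optional projection basis stored alongside the mixture.
#' @return a [ClusterModel-class].
#' @export
fitMixture <- function(scores, kRange = 2:8, seed = 1L, basis = list()) {
  scores <- as.matrix(scores)
  if (nrow(scores) <= max(kRange) * 10)
    stop("need more than max(kRange) * 10 events to fit the mixture (have ",
         nrow(scores), ")")
  kRange <- sort(unique(as.integer(kRange)))
  set.seed(as.integer(seed))
  n <- nrow(scores)
  d <- ncol(scores)
  hcInit <- mclust::hcVVV(data = scores)
  bicVals <- rep(NA_real_, length(kRange))
  fits <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    K <- kRange[i]
    z <- if (K == 1L) matrix(1, n, 1L)
         else mclust::unmap(mclust::hclass(hcInit, K))
    emf <- tryCatch({
      ms <- mclust::mstepVVV(data = scores, z = z)
      mclust::emVVV(data = scores, parameters = ms$parameters)
    }, error = function(e) NULL)
    if (is.null(emf) || is.na(emf$loglik)) next
    bicVals[i] <- mclust::bic("VVV", emf$loglik, n, d, K)
    fits[[i]] <- emf
  }
  if (all(is.na(bicVals)))
    stop("Gaussian mixture failed to converge for all K in [",
         min(kRange), ", ", max(kRange), "]; inspect the scaled features")
  best <- which.max(bicVals)   # mclust BIC convention: larger is better
  fit <- fits[[best]]
  bic <- matrix(bicVals, ncol = 1L,
                dimnames = list(as.character(kRange), "VVV"))
  new("ClusterModel", K = kRange[best], modelName = "VVV",
      parameters = fit$parameters, basis = basis, bicTable = bic,
      seed = as.integer(seed), converged = TRUE)
}

#' Assign events to mixture components by maximum posterior
#'
#' @param model a [ClusterModel-class].
#' @param scores projected feature matrix (same space the model was fit in).
#' @return list with `labels` (component index per event; ties broken toward
#'   the lowest component index) and `posterior` (n x K matrix, rows summing
#'   to 1).
#' @export
assignClusters <- function(model, scores) {
  stopifnot(is(model, "ClusterModel"))
  scores <- as.matrix(scores)
  d <- nrow(model@parameters$mean)
  if (ncol(scores) != d)
    stop("dimension mismatch: model expects ", d, " components, got ",
         ncol(scores))
  dens <- mclust::cdensVVV(data = scores, parameters = model@parameters,
                           logarithm = TRUE)
  dens <- matrix(dens, nrow = nrow(scores))
  logw <- sweep(dens, 2L, log(model@parameters$pro), "+")
  mx <- apply(logw, 1L, max)
  w <- exp(logw - mx)
  post <- w / rowSums(w)
  labels <- max.col(post, ties.method = "first")
  list(labels = labels, posterior = post)
}

#' Identify the DNM2-positive cluster
#'
#' Productive CME events form the cluster with detectable DNM2 throughout,
#' long lifetimes, and sub-visitor motility. Clusters are scored by a
#' composite rank: rank of the median DNM2 significant-frame fraction (high)
#' plus rank of the median lifetime (high) plus rank of the median
#' frame-to-frame step (low); the top-ranked cluster is returned provided its
#' median DNM2 fraction reaches `floorDnm2`. A tie across the composite rank
#' stops with the per-cluster summaries for manual review; a best cluster
#' failing the floor is flagged (`cluster = NA`) with a warning.
#'
#' @param labels integer cluster labels from [assignClusters()].
#' @param features raw (unscaled) feature data.frame from
#'   [extractFeatures()], same event order as `labels`.
#' @param floorDnm2 minimum median DNM2 significant-frame fraction, default
#'   0.5.
#' @return list with `cluster` (the top-ranked cluster id or `NA`),
#'   `dnm2Positive` (all clusters passing the DNM2-fraction floor; when the
#'   mixture resolves sub-populations of bona-fide events, e.g. stalled vs
#'   unstalled, every such cluster is DNM2-positive) and `summaries`
#'   (per-cluster medians and sizes).
#' @export
identifyDnm2PositiveCluster <- function(labels, features, floorDnm2 = 0.5) {
  stopifnot(length(labels) == nrow(features))
  med <- function(col) tapply(features[[col]], labels, median)
  summaries <- data.frame(
    cluster = as.integer(names(med("lifetime"))),
    n = as.integer(table(labels)),
    median_dnm2_sig_frac = as.numeric(med("dnm2_sig_frac")),
    median_lifetime = as.numeric(med("lifetime")),
    median_mean_step = as.numeric(med("mean_step")))
  composite <- rank(summaries$median_dnm2_sig_frac) +
    rank(summaries$median_lifetime) +
    rank(-summaries$median_mean_step)
  summaries$composite_rank <- composite
  best <- which(composite == max(composite))
  if (length(best) > 1L) {
    # composite-rank ties are resolved on the raw criteria; only clusters
    # indistinguishable on all three demand manual review
    o <- order(-summaries$median_dnm2_sig_frac[best],
               -summaries$median_lifetime[best],
               summaries$median_mean_step[best])
    b1 <- best[o[1L]]; b2 <- best[o[2L]]
    if (summaries$median_dnm2_sig_frac[b1] ==
          summaries$median_dnm2_sig_frac[b2] &&
        summaries$median_lifetime[b1] == summaries$median_lifetime[b2] &&
        summaries$median_mean_step[b1] == summaries$median_mean_step[b2])
      stop("tie across the composite rank; manual review required.\n",
           paste(utils::capture.output(print(summaries)), collapse = "\n"))
    best <- b1
  }
  dnm2Positive <- summaries$cluster[summaries$median_dnm2_sig_frac >=
                                      floorDnm2]
  if (summaries$median_dnm2_sig_frac[best] < floorDnm2) {
    warning("best cluster fails the DNM2 significant-frame fraction floor (",
            signif(summaries$median_dnm2_sig_frac[best], 3), " < ",
            floorDnm2, "); no DNM2-positive cluster identified")
    return(list(cluster = NA_integer_, dnm2Positive = dnm2Positive,
                summaries = summaries))
  }
  list(cluster = summaries$cluster[best], dnm2Positive = dnm2Positive,
       summaries = summaries)
}
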