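#' Select the representative image of a cluster
#'
#' The representative is the member with maximal mean SSIM to all cluster
#' members (self included); ties are broken by the lowest index.
#'
#' @param sim square similarity matrix of the cluster members.
#' @return Index of the representative member.
#' @export
clusterRepresentative <- function(sim) {
  means <- rowMeans(sim)
  which.max(means)   # which.max returns the first (lowest-index) maximum
}

#' Build an ECG quality template library
#'
#' Within each quality group, images are clustered by average-linkage
#' agglomerative clustering on the dissimilarity `1 - SSIM`; each cluster
#' contributes its representative image (maximal mean within-cluster SSIM) as
#' a template. A linear-discriminant classifier is then fitted on the vectors
#' of SSIM values between every training image and every template.
#'
#' When `groups` is `NULL`, the initial good/poor partition is obtained by
#' 2-means clustering of each image's mean similarity to all others (the
#' higher-similarity cluster is labeled `good`), mirroring the unsupervised
#' split of similarity values.
#'
#' @param images list of [EcgImage-class] training images.
#' @param groups character vector `"good"`/`"poor"` per image, or `NULL`.
#' @param nClusters clusters (hence templates) per group, default 3.
#' @param seed RNG seed for the unsupervised 2-means initialization.
#' @return A [TemplateLibrary-class].
#' @seealso [classifyEcgQuality()]
#' @export
buildTemplates <- function(images, groups = NULL, nClusters = 3, seed = 1) {
  n <- length(images)
  sim <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    s <- ecgImageSimilarity(images[[i]], images[[j]])
    sim[i, j] <- s; sim[j, i] <- s
  }
  if (is.null(groups)) {
    ms <- rowMeans(sim)
    set.seed(seed)
    km <- stats::kmeans(ms, centers = 2, nstart = 5)
    goodCluster <- which.max(km$centers)
    groups <- ifelse(km$cluster == goodCluster, "good", "poor")
  }
  if (any(table(factor(groups, levels = c("good", "poor"))) < 2))
    stopWith("autonomiq_input_error",
             "need at least 2 training images per quality group")
  templates <- list(); tGroups <- character()
  for (g in c("good", "poor")) {
    idx <- which(groups == g)
    k <- min(nClusters, length(idx))
    cl <- if (length(idx) == 1) 1 else
      stats::cutree(stats::hclust(stats::as.dist(1 - sim[idx, idx]),
                                  method = "average"), k = k)
    for (c in unique(cl)) {
      members <- idx[cl == c]
      rep <- members[clusterRepresentative(sim[members, members, drop = FALSE])]
      templates <- c(templates, images[rep])
      tGroups <- c(tGroups, g)
    }
  }
  feats <- templateFeatures(images, templates)
  # drop feature columns with no pooled within-group variability
  keep <- which(vapply(seq_len(ncol(feats)), function(j) {
    all(vapply(split(feats[, j], groups), stats::sd, numeric(1)) > 1e-10)
  }, logical(1)))
  if (!length(keep)) keep <- seq_len(ncol(feats))
  fit <- MASS::lda(feats[, keep, drop = FALSE], grouping = factor(groups))
  methods::new("TemplateLibrary", templates = templates, groups = tGroups,
               lda = fit, featureCols = as.numeric(keep),
               nClusters = nClusters)
}

# SSIM feature matrix: one row per image, one column per template
templateFeatures <- function(images, templates) {
  t(vapply(images, function(im)
    vapply(templates, function(tp) ecgImageSimilarity(im, tp), numeric(1)),
    numeric(length(templates))))
}

setMethod("show", "TemplateLibrary", function(object) {
  cat(sprintf("TemplateLibrary: %d templates (good=%d, poor=%d), %s\n",
              length(object@templates), sum(object@groups == "good"),
              sum(object@groups == "poor"),
              if (is.null(object@lda)) "unfitted" else "LDA fitted"))
})

#' Classify the quality of an ECG image
#'
#' Computes the SSIM of the image against every template in the library and
#' applies the fitted linear-discriminant classifier.
#'
#' @param image an [EcgImage-class].
#' @param library a fitted [TemplateLibrary-class].
#' @return List with `quality` (`"good"`/`"poor"`), `score` (posterior
#'   probability of `good`) and the feature vector.
#' @export
classifyEcgQuality <- function(image, library) {
  if (is.null(library@lda))
    stopWith("autonomiq_input_error", "template library is not fitted")
  f <- templateFeatures(list(image), library@templates)
  f <- f[, library@featureCols, drop = FALSE]
  colnames(f) <- colnames(library@lda$means)
  pred <- stats::predict(library@lda, f)
  list(quality = as.character(pred$class),
       score = unname(pred$posterior[1, "good"]),
       features = as.numeric(f))
}

#' Persist / restore a template library
#'
#' The library is stored as a single versioned JSON archive (pixels included),
#' so it can be shipped or exchanged as text.
#'
#' @param library a [TemplateLibrary-class].
#' @param path archive path.
#' @return `saveTemplateLibrary`: `path` invisibly; `loadTemplateLibrary`: the
#'   restored [TemplateLibrary-class].
#' @export
saveTemplateLibrary <- function(library, path) {
  arch <- list(
    version = "1",
    nClusters = library@nClusters,
    groups = library@groups,
    featureCols = library@featureCols,
    templates = lapply(library@templates, function(im)
      list(pixels = as.numeric(im@pixels), dim = dim(im@pixels),
           leadRows = im@leadRows, config = im@config)),
    lda = list(prior = as.list(library@lda$prior),
               means = as.numeric(library@lda$means),
               meansDim = dim(library@lda$means),
               lev = library@lda$lev,
               svd = as.numeric(library@lda$svd),
               scaling = as.numeric(library@lda$scaling),
               scalingDim = dim(library@lda$scaling),
               colnames = colnames(library@lda$means)))
  jsonlite::write_json(arch, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveTemplateLibrary
#' @export
loadTemplateLibrary <- function(path) {
  arch <- jsonlite::read_json(path)       # plain nested lists
  num <- function(x) as.numeric(unlist(x))
  templates <- lapply(arch$templates, function(tp) {
    d <- num(tp$dim)
    cfg <- lapply(tp$config, num)
    methods::new("EcgImage",
                 pixels = matrix(num(tp$pixels), d[1], d[2]),
                 leadRows = lapply(tp$leadRows, function(r)
                   as.integer(unlist(r))),
                 config = cfg)
  })
  l <- arch$lda
  lev <- unlist(l$lev)
  cn <- unlist(l$colnames)
  mDim <- num(l$meansDim); sDim <- num(l$scalingDim)
  fit <- structure(list(
    prior = stats::setNames(num(l$prior), names(l$prior)),
    means = matrix(num(l$means), mDim[1], mDim[2],
                   dimnames = list(lev, cn)),
    scaling = matrix(num(l$scaling), sDim[1], sDim[2],
                     dimnames = list(cn, paste0("LD", seq_len(sDim[2])))),
    lev = lev, svd = num(l$svd), N = NA_integer_,
    call = quote(lda())), class = "lda")
  methods::new("TemplateLibrary", templates = templates,
               groups = unlist(arch$groups), lda = fit,
               featureCols = num(arch$featureCols),
               nClusters = num(arch$nClusters))
}
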