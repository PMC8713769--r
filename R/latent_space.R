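# PCA latent encoding space over the 31-parameter profiles:
# correlation-matrix PCA (parameters mix mm, pps and s), loadings expressed
# as parameter-PC correlations, group centroids, 95% confidence ellipses
# from the chi-square(2) quantile, and cOIN-minus-control shift vectors.

#' Standardize an encoding-profile table
#'
#' Centers and scales each of the 31 parameter columns to unit variance.
#' Missing flags (silent-neuron parameters) are mean-imputed after
#' standardization (i.e. set to 0) and counted; columns constant across
#' neurons carry no information for a correlation PCA and are dropped with
#' a warning.
#'
#' @param profiles data.frame of stacked encoding profiles (one row per
#'   neuron) containing the battery columns plus label columns.
#' @param parameters Parameter columns to use; defaults to the full
#'   battery intersected with available columns.
#' @return List: `x` (standardized matrix), `center`, `scale`,
#'   `imputed` (count per column), `dropped` (names of constant columns),
#'   `labels` (the non-parameter columns of `profiles`).
#' @export
standardize_profiles <- function(profiles,
                                 parameters = intersect(encoding_parameter_names(),
                                                        names(profiles))) {
  x <- as.matrix(profiles[, parameters, drop = FALSE])
  storage.mode(x) <- "double"
  ctr <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, stats::sd, na.rm = TRUE)
  constant <- !is.finite(scl) | scl < 1e-12 | !is.finite(ctr)
  if (any(constant)) {
    warning("dropping constant/empty parameter column(s): ",
            paste(parameters[constant], collapse = ", "), call. = FALSE)
    x <- x[, !constant, drop = FALSE]
    ctr <- ctr[!constant]; scl <- scl[!constant]
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  imputed <- colSums(is.na(z))
  z[is.na(z)] <- 0
  list(x = z, center = ctr, scale = scl, imputed = imputed,
       dropped = parameters[constant],
       labels = profiles[, setdiff(names(profiles), parameters), drop = FALSE])
}

#' Fit the PCA latent space
#'
#' Eigendecomposition of the correlation matrix of the standardized
#' profiles. Scores are the neuron coordinates; loadings are expressed as
#' parameter-PC correlations (eigenvector times sqrt eigenvalue), so each
#' loading magnitude is at most 1. Signs are fixed by forcing the
#' largest-magnitude loading on each PC to be positive, making the fit
#' deterministic.
#'
#' @param std Output of [standardize_profiles()], or a numeric matrix
#'   already standardized.
#' @return Object of class `latent_space`: `scores` (n x p),
#'   `loadings` (correlations), `rotation` (unit eigenvectors),
#'   `explained_variance` (percent per PC, non-increasing), `labels`.
#' @export
fit_pca <- function(std) {
  if (is.list(std) && !is.data.frame(std)) {
    z <- std$x; labels <- std$labels
  } else {
    z <- as.matrix(std); labels <- NULL
  }
  n <- nrow(z)
  if (n < 3) stop("PCA needs at least 3 neurons", call. = FALSE)
  cmat <- stats::cov(z)  # correlation matrix of the raw parameters
  eg <- eigen(cmat, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- z %*% vecs
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  loadings <- sweep(vecs, 2, sqrt(vals), "*")
  dimnames(loadings) <- list(colnames(z), colnames(scores))
  colnames(vecs) <- colnames(scores); rownames(vecs) <- colnames(z)
  structure(list(scores = scores, loadings = loadings, rotation = vecs,
                 explained_variance = 100 * vals / sum(vals),
                 eigenvalues = vals, labels = labels),
            class = "latent_space")
}

#' @export
print.latent_space <- function(x, ...) {
  cat(sprintf("<latent_space: %d neurons x %d parameters; PC1-2 %.1f%%>\n",
              nrow(x$scores), ncol(x$scores),
              sum(x$explained_variance[1:2])))
  invisible(x)
}

#' Group geometry in PC1-PC2
#'
#' Centroids per (class, treatment) group, 95% confidence ellipses from the
#' group 2D covariance and the chi-square(2) quantile, and treatment shift
#' vectors (cOIN centroid minus control centroid per class). Groups with
#' fewer than 3 members keep their centroid but omit the ellipse.
#'
#' @param space A `latent_space`.
#' @param class_labels,treatment_labels Per-neuron labels; default from
#'   `space$labels`.
#' @param level Ellipse confidence level.
#' @return List: `centroids` (data.frame), `ellipses` (named list of
#'   boundary matrices, 100 points each), `shift_vectors` (data.frame with
#'   `dPC1`, `dPC2`, `magnitude`).
#' @export
group_geometry <- function(space, class_labels = space$labels$neuron_class,
                           treatment_labels = space$labels$treatment,
                           level = 0.95) {
  sc <- space$scores[, 1:2, drop = FALSE]
  grp <- interaction(class_labels, treatment_labels, drop = TRUE, sep = "/")
  cent <- do.call(rbind, lapply(levels(grp), function(g) {
    m <- sc[grp == g, , drop = FALSE]
    data.frame(group = g,
               neuron_class = sub("/.*", "", g),
               treatment = sub(".*/", "", g),
               PC1 = mean(m[, 1]), PC2 = mean(m[, 2]), n = nrow(m))
  }))
  ellipses <- list()
  rad <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = 100)
  circ <- rbind(cos(theta), sin(theta))
  for (g in levels(grp)) {
    m <- sc[grp == g, , drop = FALSE]
    if (nrow(m) < 3) next
    ev <- eigen(stats::cov(m), symmetric = TRUE)
    shape <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
    b <- t(shape %*% (rad * circ)) +
      matrix(colMeans(m), 100, 2, byrow = TRUE)
    colnames(b) <- c("PC1", "PC2")
    ellipses[[g]] <- b
  }
  classes <- unique(cent$neuron_class)
  shifts <- do.call(rbind, lapply(classes, function(cl) {
    a <- cent[cent$neuron_class == cl & cent$treatment == "control", ]
    b <- cent[cent$neuron_class == cl & cent$treatment == "cOIN", ]
    if (!nrow(a) || !nrow(b)) return(NULL)
    data.frame(neuron_class = cl, dPC1 = b$PC1 - a$PC1, dPC2 = b$PC2 - a$PC2,
               magnitude = sqrt((b$PC1 - a$PC1)^2 + (b$PC2 - a$PC2)^2))
  }))
  list(centroids = cent, ellipses = ellipses, shift_vectors = shifts,
       level = level)
}
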