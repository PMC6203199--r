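# Background covariance estimation, low-rank whitening, and the angle-based
# score in the decorrelated annotation space.

#' Construct a background model from its components
#'
#' Mostly used internally and in tests; [estimate_background_model()] is the
#' standard entry point. Eigenvectors must be orthonormal and eigenvalues
#' sorted descending and strictly positive.
#'
#' @param mu background mean vector (length d).
#' @param eigenvalues positive eigenvalues, descending (length k).
#' @param eigenvectors d x k matrix of orthonormal eigenvectors.
#' @param variant_class `"intronic"`, `"intergenic"` or `"pooled"`.
#' @param variance_explained fraction of total background variance captured
#'   by the retained eigenpairs.
#' @param n_background number of background rows used for estimation.
#' @param schema_hash layout hash (see [schema_hash()]), if known.
#' @return object of class `background_model`.
#' @export
background_model <- function(mu, eigenvalues, eigenvectors,
                             variant_class = "pooled",
                             variance_explained = NA_real_,
                             n_background = NA_integer_,
                             schema_hash = NA_character_) {
  eigenvectors <- as.matrix(eigenvectors)
  k <- length(eigenvalues)
  stopifnot(ncol(eigenvectors) == k, nrow(eigenvectors) == length(mu))
  if (k < 1L) stop("background_model: at least one eigenpair required")
  if (any(eigenvalues <= 0)) stop("background_model: eigenvalues must be positive")
  if (is.unsorted(rev(eigenvalues))) stop("background_model: eigenvalues must be descending")
  ortho <- crossprod(eigenvectors)
  if (max(abs(ortho - diag(k))) > 1e-8) {
    stop("background_model: eigenvectors not orthonormal (tol 1e-8)")
  }
  if (!all(is.finite(mu))) stop("background_model: mu must be finite")
  structure(list(variant_class = variant_class, mu = as.numeric(mu),
                 eigenvalues = as.numeric(eigenvalues),
                 eigenvectors = eigenvectors, k = k,
                 variance_explained = variance_explained,
                 n_background = n_background, schema_hash = schema_hash),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model (%s): d=%d, k=%d, variance explained %.1f%%, n=%s\n",
              x$variant_class, length(x$mu), x$k,
              100 * x$variance_explained, format(x$n_background)))
  invisible(x)
}

# rows of the annotation matrix belonging to a class ("pooled" = everything
# not excluded), imputed to the column mean
class_rows <- function(mat, variant_class) {
  cls <- mat$variants$variant_class
  if (variant_class == "pooled") {
    which(is.na(cls) | cls != "excluded")
  } else {
    which(!is.na(cls) & cls == variant_class)
  }
}

impute_colmean <- function(X, mu = NULL) {
  if (is.null(mu)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0     # columns missing for all rows carry no information
  }
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- mu[(idx - 1L) %/% nrow(X) + 1L]
  X
}

#' Estimate the background covariance model
#'
#' Computes the background mean vector and the top-k eigenpairs of the sample
#' covariance of the (mean-imputed) background annotation matrix. The model
#' defines the decorrelated space: the covariance is approximated by its
#' rank-k truncation and inverted on that subspace (Moore-Penrose), which is
#' what [whiten()] applies. Backgrounds are estimated per variant class
#' because intronic and intergenic variants have different annotation
#' architectures.
#'
#' @param background an [annotation_matrix()] (or plain 0/1/NA matrix) of
#'   background variants.
#' @param variant_class which rows to use: `"intronic"`, `"intergenic"` or
#'   `"pooled"` (default; all non-excluded rows).
#' @param k target rank (default 30, chosen as a reproducible stand-in for
#'   scree-plot inspection). Reduced automatically when fewer usable positive
#'   eigenvalues exist; eigenvalues below `1e-10 * lambda_1` are dropped for
#'   numerical stability of the inverse.
#' @param variance_target optional fraction in (0,1]; when given, k is the
#'   smallest rank whose cumulative variance explained reaches the target
#'   (still capped by `k`).
#' @return a [background_model()].
#' @export
estimate_background_model <- function(background, variant_class = "pooled",
                                      k = 30, variance_target = NULL) {
  if (k < 1) stop("estimate_background_model: k must be >= 1")
  shash <- NA_character_
  if (inherits(background, "annotation_matrix")) {
    rows <- class_rows(background, variant_class)
    X <- background$values[rows, , drop = FALSE]
    shash <- schema_hash(background$schema)
  } else {
    X <- as.matrix(background)
  }
  if (nrow(X) < k + 1) {
    stop(sprintf("estimate_background_model: need >= k+1 = %d background rows of class '%s', got %d",
                 k + 1, variant_class, nrow(X)))
  }
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  X <- impute_colmean(X, mu)
  S <- stats::cov(X)
  eg <- eigen(S, symmetric = TRUE)
  lam <- eg$values
  total <- sum(pmax(lam, 0))
  if (total <= 0) {
    stop("estimate_background_model: degenerate model (zero covariance)")
  }
  keep <- lam > 1e-10 * lam[1]
  lam <- lam[keep]
  U <- eg$vectors[, keep, drop = FALSE]
  k_eff <- min(k, length(lam))
  if (!is.null(variance_target)) {
    cumfrac <- cumsum(lam) / total
    k_eff <- min(k_eff, which(cumfrac >= variance_target)[1], na.rm = TRUE)
    if (is.na(k_eff)) k_eff <- min(k, length(lam))
  }
  background_model(mu = mu,
                   eigenvalues = lam[seq_len(k_eff)],
                   eigenvectors = U[, seq_len(k_eff), drop = FALSE],
                   variant_class = variant_class,
                   variance_explained = sum(lam[seq_len(k_eff)]) / total,
                   n_background = nrow(X),
                   schema_hash = shash)
}

# resolve a weight argument (NULL, numeric vector, or weight_vector) against
# the model dimension
resolve_weights <- function(W, d) {
  if (is.null(W)) return(rep(1, d))
  w <- if (inherits(W, "weight_vector")) W$weights else as.numeric(W)
  if (length(w) != d) stop("weights: length must equal the number of annotation columns")
  if (any(w < 0)) stop("weights: entries must be non-negative")
  w
}

#' Project an annotation vector into the decorrelated space
#'
#' Computes `z_i = lambda_i^(-1/2) * u_i' W (x - mu)` for the retained
#' eigenpairs, so that `sum(z^2)` equals the quadratic form
#' `(x-mu)' W SigmaHat^+ W (x-mu)` with the rank-k pseudo-inverse. Missing
#' entries of `x` are imputed to the background mean (their contribution to
#' `x - mu` is zero).
#'
#' @param x annotation vector (length d, entries 0/1/NA).
#' @param model a [background_model()].
#' @param W optional weights: numeric vector of per-column weights or a
#'   [weight_vector]; `NULL` means unweighted (all ones).
#' @return numeric vector of length `model$k`.
#' @export
whiten <- function(x, model, W = NULL) {
  d <- length(model$mu)
  if (length(x) != d) stop("whiten: x must have length ", d)
  w <- resolve_weights(W, d)
  x <- as.numeric(x)
  x[is.na(x)] <- model$mu[is.na(x)]
  v <- w * (x - model$mu)
  as.numeric(crossprod(model$eigenvectors, v)) / sqrt(model$eigenvalues)
}

# whiten all rows of X at once: returns n x k matrix
whiten_matrix <- function(X, model, W = NULL) {
  d <- length(model$mu)
  if (ncol(X) != d) stop("whiten: matrix must have ", d, " columns")
  w <- resolve_weights(W, d)
  X <- impute_colmean(as.matrix(X), model$mu)
  V <- sweep(X, 2L, model$mu) * rep(w, each = nrow(X))
  Z <- V %*% model$eigenvectors
  sweep(Z, 2L, sqrt(model$eigenvalues), "/")
}

#' Reweighted Mahalanobis distance to the background mean
#'
#' Length of the whitened vector: `sqrt((x-mu)' W SigmaHat^+ W (x-mu))`.
#'
#' @inheritParams whiten
#' @return non-negative scalar.
#' @export
mahalanobis_score <- function(x, model, W = NULL) {
  sqrt(sum(whiten(x, model, W)^2))
}

#' Cosine of the whitened angle to the maximal-annotation-load direction
#'
#' Correlation between the whitened projections of `x` and of the all-1
#' annotation vector; clipped to `[-1, 1]` before any `acos`.
#'
#' @inheritParams whiten
#' @return scalar in `[-1, 1]`.
#' @export
cosine_to_ones <- function(x, model, W = NULL) {
  zx <- whiten(x, model, W)
  z1 <- whiten(rep(1, length(model$mu)), model, W)
  nx <- sqrt(sum(zx^2)); n1 <- sqrt(sum(z1^2))
  if (nx == 0 || n1 == 0) {
    stop("cosine_to_ones: zero-length whitened projection, angle undefined")
  }
  clip_cosine(sum(zx * z1) / (nx * n1))
}

#' Angle-based functionality score of an annotation vector
#'
#' The score is the whitened angle between `x` and the all-1 annotation
#' vector, divided by the product of the whitened lengths of `x` and of the
#' all-1 vector:
#' `acos(cos) / (mahalanobis(x) * mahalanobis(1))`. Smaller scores indicate
#' greater evidence for functionality; the all-1 vector attains the global
#' minimum 0.
#'
#' @inheritParams whiten
#' @return non-negative scalar (radians per squared whitened length).
#' @export
pines_score <- function(x, model, W = NULL) {
  zx <- whiten(x, model, W)
  z1 <- whiten(rep(1, length(model$mu)), model, W)
  nx <- sqrt(sum(zx^2)); n1 <- sqrt(sum(z1^2))
  if (nx == 0 || n1 == 0) {
    stop("pines_score: zero-length whitened projection, angle undefined")
  }
  acos(clip_cosine(sum(zx * z1) / (nx * n1))) / (nx * n1)
}

#' Score every row of an annotation matrix
#'
#' Vectorized form of [pines_score()] / [mahalanobis_score()]. Rows whose
#' whitened projection has zero length have an undefined angle; they are
#' returned with `NA` score and `undefined = TRUE` (downstream they are
#' assigned empirical p = 1, flagged).
#'
#' @param X an [annotation_matrix()] or plain matrix (rows = variants).
#' @param model a [background_model()].
#' @param W optional weights (see [whiten()]).
#' @return data.frame with columns `raw_score`, `mahalanobis`, `cosine`,
#'   `undefined`.
#' @export
score_matrix <- function(X, model, W = NULL) {
  V <- if (inherits(X, "annotation_matrix")) X$values else as.matrix(X)
  Z <- whiten_matrix(V, model, W)
  z1 <- whiten(rep(1, length(model$mu)), model, W)
  n1 <- sqrt(sum(z1^2))
  if (n1 == 0) stop("score_matrix: all-1 vector has zero whitened length")
  nx <- sqrt(rowSums(Z^2))
  undef <- nx == 0
  cosv <- rep(NA_real_, nrow(Z))
  cosv[!undef] <- clip_cosine((Z[!undef, , drop = FALSE] %*% z1) /
                                (nx[!undef] * n1))
  raw <- acos(cosv) / (nx * n1)
  data.frame(raw_score = raw, mahalanobis = nx, cosine = cosv,
             undefined = undef)
}

#' Save / load a background model archive
#'
#' The archive is an RDS file; a YAML sidecar (`<path>.yaml`) records the
#' variant class, rank, variance explained and schema hash for quick
#' inspection.
#'
#' @param model a [background_model()].
#' @param path file path (`.rds`).
#' @return `read_background_model` returns the model; `write_background_model`
#'   returns `path` invisibly.
#' @export
write_background_model <- function(model, path) {
  saveRDS(model, path)
  yaml::write_yaml(list(variant_class = model$variant_class, k = model$k,
                        d = length(model$mu),
                        variance_explained = model$variance_explained,
                        n_background = model$n_background,
                        schema_hash = model$schema_hash),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_background_model
#' @export
read_background_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "background_model")) stop("not a background_model archive")
  m
}
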