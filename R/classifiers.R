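#' Fit a Riemannian covariance classifier
#'
#' Four classifier families operate on the SPD covariance epochs:
#' \describe{
#'   \item{`mdm`}{minimum distance to mean — one geodesic (Karcher) mean per
#'     class; an epoch is assigned to the nearest class mean under the
#'     affine-invariant metric.}
#'   \item{`mdm_filter`}{geodesic-filtered MDM — epochs are projected to the
#'     tangent space at the grand mean, filtered onto the linear discriminant
#'     subspace (supervised spatial filtering), mapped back to the manifold,
#'     and classified by MDM there.}
#'   \item{`ts_lda`}{tangent-space projection followed by linear discriminant
#'     analysis with Ledoit-Wolf shrinkage of the pooled covariance.}
#'   \item{`ts_svm`}{tangent-space projection followed by a linear-kernel
#'     soft-margin SVM (cost `C = 1`).}
#' }
#'
#' @param epochs Tibble with list-column `cov` and column `label`
#'   (`"walk"`/`"intent"`), as from [extract_class_epochs()].
#' @param classifier One of `"mdm"`, `"mdm_filter"`, `"ts_lda"`, `"ts_svm"`.
#' @param electrodes Optional integer vector: train on the principal
#'   submatrix of the covariances restricted to these channels.
#' @param config Optional [run_config()] recorded in the model.
#' @return A `riemann_model`.
#' @export
fit_riemann <- function(epochs,
                        classifier = c("mdm", "mdm_filter", "ts_lda", "ts_svm"),
                        electrodes = NULL, config = NULL) {
  classifier <- match.arg(classifier)
  labels <- factor(epochs$label, levels = c("walk", "intent"))
  if (nlevels(droplevels(labels)) < 2)
    abort("Both classes must be present in the training epochs.")
  if (any(table(labels) < 2))
    abort("Need at least two epochs per class.")
  covs <- epochs$cov
  if (!is.null(electrodes))
    covs <- lapply(covs, function(c) c[electrodes, electrodes, drop = FALSE])

  model <- list(classifier = classifier, electrodes = electrodes,
                config = config, levels = c("walk", "intent"))

  if (classifier == "mdm") {
    model$class_means <- lapply(split(covs, labels), riemann_mean)
  } else {
    ref <- riemann_mean(covs)
    tv <- tangent_project(covs, ref)
    model$tangent_ref <- ref
    if (classifier == "mdm_filter") {
      w <- lda_direction(tv, labels)
      # rank-one geodesic filter: keep only the discriminant component
      proj <- (w %*% t(w)) / sum(w * w)
      filt <- lapply(seq_len(nrow(tv)), function(i)
        tangent_back(as.numeric(proj %*% tv[i, ]), ref))
      model$filter_w <- w
      model$class_means <- lapply(split(filt, labels), riemann_mean)
    } else if (classifier == "ts_lda") {
      fitl <- shrinkage_lda(tv, labels)
      model$lda <- fitl
    } else {
      model$svm <- e1071::svm(x = tv, y = labels, kernel = "linear",
                              cost = 1, scale = FALSE, probability = FALSE)
    }
  }
  class(model) <- "riemann_model"
  model
}

# Fisher discriminant direction with shrinkage-regularized pooled covariance.
lda_direction <- function(x, labels) {
  mu <- lapply(split(as.data.frame(x), labels), colMeans)
  sw <- shrink_cov(x, labels)
  w <- solve(sw, mu[[2]] - mu[[1]])
  as.numeric(w / sqrt(sum(w^2)))
}

# Ledoit-Wolf-style shrinkage of the pooled within-class covariance toward a
# scaled identity; keeps tangent-space LDA well-posed when dimension exceeds
# the epoch count.
shrink_cov <- function(x, labels) {
  xc <- x
  for (lv in levels(labels)) {
    i <- labels == lv
    xc[i, ] <- sweep(x[i, , drop = FALSE], 2,
                     colMeans(x[i, , drop = FALSE]))
  }
  n <- nrow(xc); p <- ncol(xc)
  s <- crossprod(xc) / n
  mu <- sum(diag(s)) / p
  d2 <- norm(s - diag(mu, p), "F")^2
  b2 <- 0
  for (i in seq_len(n)) b2 <- b2 + norm(tcrossprod(xc[i, ]) - s, "F")^2
  b2 <- min(b2 / n^2, d2)
  lam <- if (d2 > 0) b2 / d2 else 1
  (1 - lam) * s + lam * diag(mu, p)
}

shrinkage_lda <- function(x, labels) {
  w <- lda_direction(x, labels)
  mu <- lapply(split(as.data.frame(x), labels), colMeans)
  thr <- sum(w * (mu[[1]] + mu[[2]])) / 2
  list(w = w, threshold = thr,
       positive = levels(labels)[2], negative = levels(labels)[1])
}

#' Predict class labels for covariance epochs
#'
#' MDM variants return the class with the nearest geodesic mean; ties are
#' broken toward `"walk"`, the safe class for an assistive device. Tangent
#' variants apply the fitted linear rule.
#'
#' @param object A `riemann_model`.
#' @param covs A single SPD matrix or a list of them (full-montage size;
#'   electrode subsetting stored in the model is applied internally).
#' @param ... Unused.
#' @return Tibble with `label` and per-class scores (`d_walk`/`d_intent`
#'   geodesic distances for MDM variants, `score` for linear variants).
#' @export
predict.riemann_model <- function(object, covs, ...) {
  if (is.matrix(covs)) covs <- list(covs)
  if (!is.null(object$electrodes))
    covs <- lapply(covs, function(c)
      c[object$electrodes, object$electrodes, drop = FALSE])

  if (object$classifier %in% c("mdm", "mdm_filter")) {
    if (object$classifier == "mdm_filter") {
      ref <- object$tangent_ref
      tv <- tangent_project(covs, ref)
      proj <- (object$filter_w %*% t(object$filter_w)) /
        sum(object$filter_w^2)
      covs <- lapply(seq_len(nrow(tv)), function(i)
        tangent_back(as.numeric(proj %*% tv[i, ]), ref))
    }
    d <- vapply(covs, function(c)
      c(airm_distance(c, object$class_means$walk),
        airm_distance(c, object$class_means$intent)), numeric(2))
    lab <- ifelse(d[2, ] < d[1, ], "intent", "walk")  # tie -> walk
    tibble::tibble(label = lab, d_walk = d[1, ], d_intent = d[2, ])
  } else {
    tv <- tangent_project(covs, object$tangent_ref)
    if (object$classifier == "ts_lda") {
      sc <- as.numeric(tv %*% object$lda$w) - object$lda$threshold
      tibble::tibble(label = ifelse(sc > 0, "intent", "walk"), score = sc)
    } else {
      lab <- as.character(predict(object$svm, tv))
      tibble::tibble(label = lab)
    }
  }
}

#' @export
print.riemann_model <- function(x, ...) {
  cat("<riemann_model>", x$classifier)
  if (!is.null(x$electrodes))
    cat(" on", length(x$electrodes), "electrodes")
  cat("\n")
  invisible(x)
}

#' @describeIn fit_riemann broom-style one-row summary of a fitted model.
#' @param x A `riemann_model`.
#' @export
glance.riemann_model <- function(x, ...) {
  tibble::tibble(
    classifier = x$classifier,
    n_electrodes = if (is.null(x$electrodes))
      nrow(x$class_means$walk %||% x$tangent_ref) else length(x$electrodes),
    class_mean_distance = if (!is.null(x$class_means))
      airm_distance(x$class_means$walk, x$class_means$intent) else NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
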