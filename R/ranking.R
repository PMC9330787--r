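#' Rank electrodes by class covariance difference
#'
#' Computes `V = |mean(cov | intent) - mean(cov | walk)|` entrywise, using
#' arithmetic class means of the covariance epochs, then walks the
#' upper-triangle entries of `V` (or its diagonal) in decreasing order,
#' appending each entry's electrode pair to the ranking until the requested
#' subset sizes are filled. Subsets are nested by construction.
#'
#' @param epochs Tibble with list-column `cov` and column `label`.
#' @param sizes Subset sizes to extract (default 15, 10, 5).
#' @param entries `"upper"` (upper triangle incl. diagonal) or `"diagonal"`.
#' @param labels Electrode names (defaults to covariance dimnames or the
#'   standard montage).
#' @return An `electrode_ranking`: list with the difference matrix `v`, the
#'   ordered electrode vector `ranking` (indices), `labels`, and `subsets`
#'   (named list of index vectors). If the class means are identical the
#'   ranking is flagged degenerate with a warning.
#' @export
rank_electrodes <- function(epochs, sizes = c(15, 10, 5),
                            entries = c("upper", "diagonal"),
                            labels = NULL) {
  entries <- match.arg(entries)
  if (!all(c("walk", "intent") %in% epochs$label))
    abort("Both classes must be present.")
  mean_of <- function(cls)
    Reduce(`+`, epochs$cov[epochs$label == cls]) /
      sum(epochs$label == cls)
  v <- abs(mean_of("intent") - mean_of("walk"))
  p <- nrow(v)
  if (is.null(labels))
    labels <- rownames(v) %||%
      (if (p == 27) eeg_channel_names() else paste0("ch", seq_len(p)))

  degenerate <- max(v) == 0
  if (degenerate)
    warn("Class covariance means are identical; ranking is degenerate.")

  if (entries == "upper") {
    idx <- which(upper.tri(v, diag = TRUE), arr.ind = TRUE)
  } else {
    idx <- cbind(seq_len(p), seq_len(p))
  }
  ord <- order(v[idx], decreasing = TRUE)
  ranking <- integer(0)
  for (k in ord) {
    for (el in unique(idx[k, ]))
      if (!el %in% ranking) ranking <- c(ranking, el)
    if (length(ranking) >= max(sizes)) break
  }
  subsets <- lapply(setNames(sizes, paste0("top", sizes)), function(s)
    head(ranking, s))
  structure(list(v = v, ranking = ranking, labels = labels,
                 subsets = subsets, degenerate = degenerate),
            class = "electrode_ranking")
}

#' @export
print.electrode_ranking <- function(x, ...) {
  cat("<electrode_ranking>",
      paste(x$labels[head(x$ranking, 10)], collapse = " "),
      if (length(x$ranking) > 10) "..." else "", "\n")
  invisible(x)
}

#' @describeIn rank_electrodes tidy the ranking into a tibble of electrodes
#'   with their rank and best-pair magnitude.
#' @param x An `electrode_ranking`.
#' @param ... Unused.
#' @export
tidy.electrode_ranking <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$ranking),
                 electrode = x$labels[x$ranking],
                 index = x$ranking)
}
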