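#' Spearman correlation matrix with clustering of quantification tables
#'
#' Computes Spearman rank correlations (average ranks for ties) of
#' log2-transformed values over pairwise-complete rows, the matching
#' p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` (reported alongside as
#' `-log10(p)`), the distance matrix `dist = (1 - rho) / 2`, and a
#' complete-linkage dendrogram on that distance. Values that are zero,
#' negative or missing become `NA` under the log2 transform and are
#' excluded pairwise; a pair with fewer than 3 complete observations has
#' undefined correlation.
#'
#' @param values A data frame or matrix, rows = features, columns =
#'   datasets (numeric).
#' @param log2_transform Log2-transform values first (default `TRUE`;
#'   non-positive values become `NA`).
#' @return An object of class `ends3p_corr` with elements `rho`,
#'   `pvalues`, `neglog10p`, `n` (pairwise complete counts), `dist` and
#'   `tree` (an [stats::hclust] object, `NULL` when any distance is
#'   undefined).
#' @export
correlation_matrix <- function(values, log2_transform = TRUE) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (log2_transform) {
    m[!is.finite(m) | m <= 0] <- NA_real_
    m <- log2(m)
  }
  k <- ncol(m)
  rho <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  nmat <- matrix(0L, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      ok <- complete.cases(m[, c(i, j), drop = FALSE])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) >= 3) {
        r <- cor(m[ok, i], m[ok, j], method = "spearman")
        rho[i, j] <- rho[j, i] <- r
      }
    }
  }
  diag(rho)[diag(nmat) >= 1] <- 1
  p <- rho_pvalue(rho, nmat)
  d <- (1 - rho) / 2
  tree <- if (!anyNA(d)) hclust(as.dist(d), method = "complete") else NULL
  structure(
    list(rho = rho, pvalues = p, neglog10p = -log10(p), n = nmat,
         dist = d, tree = tree),
    class = "ends3p_corr"
  )
}

rho_pvalue <- function(rho, nmat) {
  tstat <- rho * sqrt((nmat - 2) / pmax(1 - rho^2, 0))
  p <- 2 * pt(-abs(tstat), pmax(nmat - 2, 1))
  p[!is.finite(rho)] <- NA_real_
  p[is.finite(rho) & abs(rho) == 1] <- 0
  diag(p) <- 0
  p
}

#' @export
print.ends3p_corr <- function(x, ...) {
  cat("<ends3p_corr> ", ncol(x$rho), " datasets; rho range [",
      format(min(x$rho, na.rm = TRUE), digits = 3), ", ",
      format(max(x$rho[upper.tri(x$rho)], na.rm = TRUE), digits = 3), "]\n",
      sep = "")
  invisible(x)
}

#' Tidy a correlation result into a long tibble
#'
#' @param x An `ends3p_corr` object.
#' @param ... Unused.
#' @return Tibble with one row per dataset pair: `dataset1`, `dataset2`,
#'   `rho`, `dist`, `p_value`, `neglog10_p`, `n`.
#' @export
tidy.ends3p_corr <- function(x, ...) {
  nm <- colnames(x$rho)
  expand_grid(dataset1 = nm, dataset2 = nm) |>
    mutate(rho = as.vector(t(x$rho)),
           dist = as.vector(t(x$dist)),
           p_value = as.vector(t(x$pvalues)),
           neglog10_p = as.vector(t(x$neglog10p)),
           n = as.vector(t(x$n)))
}

#' @rdname tidy.ends3p_corr
#' @export
glance.ends3p_corr <- function(x, ...) {
  ut <- upper.tri(x$rho)
  tibble(n_datasets = ncol(x$rho),
         min_rho = min(x$rho[ut], na.rm = TRUE),
         median_rho = median(x$rho[ut], na.rm = TRUE),
         max_rho = max(x$rho[ut], na.rm = TRUE),
         clustered = !is.null(x$tree))
}

#' @export
autoplot.ends3p_corr <- function(object, ...) {
  ord <- if (!is.null(object$tree)) object$tree$order else seq_len(ncol(object$rho))
  lv <- colnames(object$rho)[ord]
  df <- tidy.ends3p_corr(object) |>
    mutate(dataset1 = factor(.data$dataset1, levels = lv),
           dataset2 = factor(.data$dataset2, levels = lv))
  ggplot2::ggplot(df, ggplot2::aes(.data$dataset1, .data$dataset2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  limits = c(-1, 1), name = "Spearman rho") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Export the clustering dendrogram in Newick format
#'
#' @param x An `ends3p_corr` object with a computed tree.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_corr_newick <- function(x, path) {
  if (is.null(x$tree)) abort("no dendrogram available (undefined distances)")
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export requires the ape package")
  }
  ape::write.tree(ape::as.phylo(x$tree), file = path)
  invisible(path)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
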