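#' Pairwise C-alpha RMSD matrix of an ensemble
#'
#' @param fits list of [atomic_structure()] placements sharing a C-alpha
#'   set; names (or labels) become the dimnames.
#' @return Symmetric matrix of [calpha_rmsd()] values with zero diagonal.
#' @export
rmsd_matrix <- function(fits) {
  n <- length(fits)
  if (n < 2L) stop("need at least two fits", call. = FALSE)
  tabs <- lapply(fits, calpha_table)
  ref_key <- tabs[[1L]]$key
  for (i in seq_len(n)) {
    if (!identical(tabs[[i]]$key, ref_key))
      stop("fit ", i, " does not share the reference C-alpha set", call. = FALSE)
  }
  ids <- vapply(seq_len(n), function(i) {
    lab <- fits[[i]]$label
    if (nzchar(lab)) lab else paste0("fit_", i)
  }, character(1))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sqrt(mean(rowSums((tabs[[i]]$xyz - tabs[[j]]$xyz)^2)))
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

#' Hierarchically cluster an ensemble of fits by C-alpha RMSD
#'
#' Agglomerative clustering (complete linkage by default, so the flat-cut
#' clusters have diameter bounded by the cutoff) of the `top_k`
#' best-ranked fits under a chosen score, with a flat cut either at a
#' fixed RMSD or, with `rule = "mean-top20"`, at the mean pairwise
#' C-alpha RMSD of those top fits — the data-driven cutoff used when
#' assessing local-search ensembles. The *top cluster* is the
#' non-singleton cluster containing the best-ranked fit among all fits
#' that belong to non-singleton clusters; when every cluster is a
#' singleton it is flagged undefined.
#'
#' @param matrix symmetric C-alpha RMSD matrix over the full ensemble
#'   (dimnames = fit ids), from [rmsd_matrix()].
#' @param score_table a [score_table()] covering the fits.
#' @param score score name used for ranking and top-cluster selection.
#' @param cutoff flat-cut height in Angstrom, or the string
#'   `"mean-top20"` (the default) for the mean pairwise RMSD rule.
#' @param top_k how many top-ranked fits to cluster (default 20; capped
#'   at the ensemble size). Set `top_k = Inf` to cluster all fits.
#' @param linkage linkage criterion for [stats::hclust()]:
#'   `"complete"` (default), `"single"` or `"average"`.
#' @return Object of class `cluster_result`: list with `hclust` (the
#'   merge tree), `labels` (named integer cluster ids), `cutoff`,
#'   `top_cluster` (id or `NA`), `singleton_only` flag, `fit_ids`,
#'   `score`, `ranks` (named score ranks of the clustered fits) and
#'   `matrix` (the clustered submatrix).
#' @export
cluster_fits <- function(matrix, score_table, score, cutoff = "mean-top20",
                         top_k = 20L, linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  if (!score %in% score_columns(score_table))
    stop("score '", score, "' not present in the score table", call. = FALSE)
  ids <- rownames(matrix)
  if (is.null(ids)) stop("`matrix` must carry fit ids as dimnames", call. = FALSE)
  if (!all(ids %in% score_table$fit_id))
    stop("score table does not cover all fits in the matrix", call. = FALSE)

  rk <- score_table[[paste0("rank_", score)]][match(ids, score_table$fit_id)]
  names(rk) <- ids
  k <- min(if (is.finite(top_k)) as.integer(top_k) else length(ids), length(ids))
  if (k < 2L) stop("need at least two fits to cluster", call. = FALSE)
  sel <- ids[order(rk)][seq_len(k)]
  sub <- matrix[sel, sel, drop = FALSE]

  if (identical(cutoff, "mean-top20")) {
    cutoff_val <- mean(sub[upper.tri(sub)])
  } else {
    cutoff_val <- as.numeric(cutoff)
    if (!is.finite(cutoff_val) || cutoff_val < 0)
      stop("`cutoff` must be a non-negative RMSD or \"mean-top20\"", call. = FALSE)
  }

  hc <- stats::hclust(stats::as.dist(sub), method = linkage)
  labels <- stats::cutree(hc, h = cutoff_val)

  sizes <- table(labels)
  nonsingle <- as.integer(names(sizes)[sizes >= 2L])
  singleton_only <- length(nonsingle) == 0L
  top_cluster <- NA_integer_
  if (!singleton_only) {
    in_ns <- labels[sel] %in% nonsingle
    best <- sel[in_ns][which.min(rk[sel][in_ns])]
    top_cluster <- unname(labels[best])
  } else {
    warning("all clusters are singletons at cutoff ",
            format(cutoff_val, digits = 4), "; top cluster undefined",
            call. = FALSE)
  }
  structure(list(hclust = hc, labels = labels, cutoff = cutoff_val,
                 top_cluster = top_cluster, singleton_only = singleton_only,
                 fit_ids = sel, score = score, ranks = rk[sel],
                 matrix = sub),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d fits, %d clusters at cutoff %.3f A (score %s)\n",
              length(x$labels), length(unique(x$labels)), x$cutoff, x$score))
  if (x$singleton_only) cat("  all singletons; top cluster undefined\n")
  else cat("  top non-singleton cluster:", x$top_cluster, "\n")
  invisible(x)
}

# Open a raster device if possible, otherwise fall back to PDF; returns the
# path actually used.
open_image_device <- function(path_png, width = 900, height = 600) {
  ok <- tryCatch({
    grDevices::png(path_png, width = width, height = height,
                   type = if (capabilities("cairo")) "cairo" else NULL)
    TRUE
  }, error = function(e) FALSE)
  if (ok) return(path_png)
  path_pdf <- sub("\\.png$", ".pdf", path_png)
  grDevices::pdf(path_pdf, width = width / 100, height = height / 100)
  path_pdf
}

#' Dendrogram and cluster summary report
#'
#' Writes `<out_prefix>_dendrogram.png` (dendrogram of the clustered fits
#' with a per-fit score colour bar running white = worst to blue = best)
#' and `<out_prefix>_clusters.tsv`, a deterministic text summary listing
#' each fit's cluster, score, rank and the mean intra-cluster C-alpha
#' RMSD.
#'
#' @param result a [cluster_result][cluster_fits()].
#' @param score_table the [score_table()] used for clustering.
#' @param out_prefix output path prefix.
#' @return Invisibly, a character vector of the files written.
#' @export
dendrogram_report <- function(result, score_table, out_prefix) {
  ids <- result$fit_ids
  sc <- score_table[[result$score]][match(ids, score_table$fit_id)]
  labels <- result$labels[ids]

  mean_intra <- vapply(sort(unique(labels)), function(cl) {
    mem <- ids[labels == cl]
    if (length(mem) < 2L) return(0)
    sub <- result$matrix[mem, mem]
    mean(sub[upper.tri(sub)])
  }, numeric(1))

  tsv <- paste0(out_prefix, "_clusters.tsv")
  df <- data.frame(fit_id = ids, cluster = unname(labels),
                   score = sprintf("%.6f", sc),
                   rank = unname(result$ranks[ids]),
                   mean_intra_rmsd = sprintf("%.6f", mean_intra[match(labels, sort(unique(labels)))]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$cluster, df$rank), ]
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  img <- open_image_device(paste0(out_prefix, "_dendrogram.png"))
  on.exit(grDevices::dev.off())
  pol <- score_polarity(result$score)
  rel <- rank(pol * sc) / length(sc)   # 0..1, 1 = best
  pal <- grDevices::colorRampPalette(c("white", "#08306B"))(100)
  cols <- pal[pmax(1L, ceiling(rel * 100))]
  graphics::layout(matrix(1:2, nrow = 2), heights = c(4, 1))
  graphics::par(mar = c(1, 4, 2, 1))
  dend <- stats::as.dendrogram(result$hclust)
  graphics::plot(dend, main = sprintf("C-alpha RMSD clustering (%s, cutoff %.2f A)",
                                      result$score, result$cutoff),
                 ylab = "RMSD (A)")
  graphics::abline(h = result$cutoff, lty = 2, col = "red")
  ord <- result$hclust$order
  graphics::par(mar = c(3, 4, 0, 1))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, length(ids) + 0.5), ylim = c(0, 1))
  graphics::rect(seq_along(ids) - 0.5, 0, seq_along(ids) + 0.5, 1,
                 col = cols[ord], border = "grey40")
  graphics::axis(1, at = seq_along(ids), labels = ids[ord], las = 2,
                 cex.axis = 0.6, tick = FALSE)
  graphics::mtext(result$score, side = 2, las = 1, cex = 0.8)
  invisible(c(tsv, img))
}
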