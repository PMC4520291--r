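#' Borda-count consensus ranking
#'
#' Re-ranks an ensemble by aggregating several scores with the classical
#' Borda count. For each score `i`, every fit `j` receives points
#' `b_ij = N - r_ij`, where `N` is the ensemble size and `r_ij` the fit's
#' rank under that score (1 = best by the score's polarity; ties share the
#' mean fractional rank, so the points are order-invariant). The Borda
#' score of a fit is the sum of its points over the chosen scores, and
#' fits are re-ranked by descending Borda score, final ties broken
#' lexicographically by fit id. Points convention is configurable
#' (`"N-r"`, the default, or `"N-r+1"`); the induced ordering is the same
#' under both.
#'
#' @param table a [score_table()].
#' @param scores character vector of at least two score names to
#'   aggregate (a consensus over a single score is meaningless).
#' @param points `"N-r"` (best fit gets `N - 1`) or `"N-r+1"`.
#' @return The table augmented with `borda_points` and `borda_rank`
#'   columns (still a [score_table()]; row order unchanged).
#' @export
borda_rank <- function(table, scores, points = c("N-r", "N-r+1")) {
  points <- match.arg(points)
  if (length(scores) < 2L)
    stop("Borda consensus needs at least two scores (S > 1)", call. = FALSE)
  missing_sc <- setdiff(scores, score_columns(table))
  if (length(missing_sc))
    stop("score(s) not in table: ", paste(missing_sc, collapse = ", "),
         call. = FALSE)
  n <- nrow(table)
  total <- numeric(n)
  for (sc in scores) {
    pol <- score_polarity(sc)
    r <- rank(-pol * table[[sc]], ties.method = "average")
    total <- total + (n - r) + if (points == "N-r+1") 1 else 0
  }
  table$borda_points <- total
  ord <- order(-total, table$fit_id)
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  table$borda_rank <- rk
  table
}

#' Consensus report: ranked table and per-score rank heatmap
#'
#' Writes `<out_prefix>_consensus.tsv` (the augmented table sorted by
#' Borda rank, deterministic bytes for fixed input) and
#' `<out_prefix>_heatmap.png`, a fits-by-scores image of the per-score
#' ranks colour-coded white (worst) to blue (best).
#'
#' @param table a [score_table()] with Borda columns (see
#'   [borda_rank()]).
#' @param out_prefix output path prefix.
#' @return Invisibly, character vector of files written.
#' @export
consensus_report <- function(table, out_prefix) {
  if (!all(c("borda_points", "borda_rank") %in% names(table)))
    stop("run borda_rank() first: Borda columns missing", call. = FALSE)
  df <- as.data.frame(table)[order(table$borda_rank), ]
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num])
    if (!is.integer(df[[cn]])) df[[cn]] <- sprintf("%.6f", df[[cn]])
  tsv <- paste0(out_prefix, "_consensus.tsv")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  rank_cols <- grep("^rank_", names(table), value = TRUE)
  n <- nrow(table)
  m <- as.matrix(as.data.frame(table)[, rank_cols, drop = FALSE])
  img <- open_image_device(paste0(out_prefix, "_heatmap.png"),
                           width = 200 + 40 * length(rank_cols),
                           height = 100 + 14 * n)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("#08306B", "white"))(100)
  graphics::par(mar = c(6, 6, 2, 1))
  graphics::image(x = seq_along(rank_cols), y = seq_len(n),
                  z = t(m[order(table$borda_rank), , drop = FALSE])[, n:1, drop = FALSE],
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = "per-score ranks (blue = best)")
  graphics::axis(1, at = seq_along(rank_cols),
                 labels = sub("^rank_", "", rank_cols), las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(n),
                 labels = rev(table$fit_id[order(table$borda_rank)]),
                 las = 2, cex.axis = 0.6)
  invisible(c(tsv, img))
}
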