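#' Score table for an ensemble of fits
#'
#' Per-fit values of one or more named scores together with derived ranks
#' (1 = best, respecting each score's polarity; ties broken by order of
#' appearance so that ranks are always a permutation of `1..N`).
#'
#' @param fit_ids character vector of fit identifiers.
#' @param scores data frame (one column per score, one row per fit).
#' @return Object of class `score_table`: data frame with `fit_id`, the
#'   score columns, and a `rank_<score>` column per score.
#' @export
score_table <- function(fit_ids, scores) {
  if (!is.data.frame(scores)) scores <- as.data.frame(scores)
  if (length(fit_ids) != nrow(scores))
    stop("fit_ids and scores disagree in length", call. = FALSE)
  if (anyDuplicated(fit_ids)) stop("fit_ids must be unique", call. = FALSE)
  tab <- data.frame(fit_id = as.character(fit_ids), scores,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (sc in names(scores)) {
    pol <- score_polarity(sc)
    tab[[paste0("rank_", sc)]] <-
      rank(-pol * tab[[sc]], ties.method = "first")
  }
  class(tab) <- c("score_table", "data.frame")
  tab
}

score_columns <- function(table) {
  nm <- names(table)
  setdiff(nm[!startsWith(nm, "rank_") & !startsWith(nm, "borda_")], "fit_id")
}

#' @export
print.score_table <- function(x, ...) {
  cat("score_table:", nrow(x), "fits;", "scores:",
      paste(score_columns(x), collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more fits\n")
  invisible(x)
}

#' Write / read a score table as tab-separated values
#'
#' @param table a [score_table()].
#' @param path TSV path.
#' @return `write_score_table` invisibly returns `path`;
#'   `read_score_table` returns the [score_table()].
#' @export
write_score_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"fit_id" %in% names(df))
    stop("not a score table: missing fit_id column", call. = FALSE)
  df$fit_id <- as.character(df$fit_id)
  class(df) <- c("score_table", "data.frame")
  df
}

#' Score an ensemble of rigid fits against a target map
#'
#' Applies each transform to the model, simulates its probe map at the
#' working resolution on the target's voxel spacing, resamples it onto the
#' target grid and evaluates the requested scores. Thresholds shared
#' across the ensemble are computed once from the target (volume threshold
#' at 1.21 A^3 per Dalton of the model mass); each probe map receives its
#' own volume threshold at the same molecular volume. Segment scores
#' (`sccc`, `smi`) require `segments` and produce one column per segment,
#' named `sccc.<label>` / `smi.<label>`.
#'
#' @param fits list of [fit_transform()] objects, or of
#'   [atomic_structure()] placements sharing the model's C-alpha set.
#' @param model reference [atomic_structure()] (ignored for structure
#'   fits except as C-alpha reference).
#' @param target target [density_map()].
#' @param resolution working resolution in Angstrom.
#' @param which character vector of score names (see
#'   [supported_scores()]).
#' @param segments optional list of [segment_selection()] for `sccc` /
#'   `smi`.
#' @param bins histogram bins for MI-family scores.
#' @param sigma_factor Gaussian width factor for blurring.
#' @return A [score_table()] whose rows follow the order of `fits`.
#' @export
score_ensemble <- function(fits, model, target, resolution,
                           which = c("ccc", "mi", "nv_s"),
                           segments = NULL, bins = 20L, sigma_factor = 0.225) {
  if (length(which) == 0L) stop("`which` must name at least one score", call. = FALSE)
  unknown <- setdiff(which, supported_scores())
  if (length(unknown))
    stop("unknown score name(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(supported_scores(), collapse = ", "),
         call. = FALSE)
  needs_seg <- intersect(which, c("sccc", "smi"))
  if (length(needs_seg) && is.null(segments))
    stop("scores ", paste(needs_seg, collapse = ", "),
         " require `segments`", call. = FALSE)

  target_thr <- volume_threshold(target, volume_from_mass(total_mass(model)))
  vol <- volume_from_mass(total_mass(model))

  placed <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "fit_transform")) {
      list(structure = apply_transform(model, f), id = f$fit_id)
    } else if (is_atomic_structure(f)) {
      id <- if (nzchar(f$label)) f$label else paste0("fit_", i)
      list(structure = f, id = id)
    } else stop("fits must be fit_transform or atomic_structure objects",
                call. = FALSE)
  })
  ids <- vapply(placed, `[[`, character(1), "id")

  rows <- lapply(placed, function(pf) {
    s <- pf$structure
    probe <- resample_on_grid(
      simulate_map(s, resolution, apix = target$apix,
                   sigma_factor = sigma_factor), target)
    vals <- list()
    if ("ccc" %in% which) vals$ccc <- ccc(probe, target)
    if ("lap" %in% which) vals$lap <- lap_ccc(probe, target)
    if ("mi" %in% which) vals$mi <- mutual_information(probe, target, bins = bins)
    if ("env" %in% which) vals$env <- envelope_score(s, target, target_thr)
    if (any(c("nv", "nv_s", "cd") %in% which)) {
      probe_thr <- volume_threshold(probe, vol)
      if ("nv" %in% which)
        vals$nv <- normal_vector_score(probe, target, target_thr, probe_thr,
                                       use_sobel = FALSE)
      if ("nv_s" %in% which)
        vals$nv_s <- normal_vector_score(probe, target, target_thr, probe_thr,
                                         use_sobel = TRUE)
      if ("cd" %in% which)
        vals$cd <- chamfer_distance(probe, target, target_thr, probe_thr)
    }
    for (seg in segments) {
      if ("sccc" %in% which)
        vals[[paste0("sccc.", seg$label)]] <-
          sccc(s, seg, target, resolution, sigma_factor = sigma_factor)
      if ("smi" %in% which)
        vals[[paste0("smi.", seg$label)]] <-
          smi(s, seg, target, resolution, bins = bins,
              sigma_factor = sigma_factor)
    }
    as.data.frame(vals, check.names = FALSE)
  })
  score_table(ids, do.call(rbind, rows))
}
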