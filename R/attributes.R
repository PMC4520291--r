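#' Write per-residue score attributes for molecular-graphics colouring
#'
#' Emits the widely used attribute-assignment text format: header lines
#' declaring the attribute, then one line per residue of the form
#' `<TAB>/chain:resnum<TAB>value`. Every residue covered by a segment gets
#' that segment's score; residues covered by several segments take the
#' last-listed segment's value (with a warning). Loading the file in a
#' molecular-graphics program colours the model by local fit quality.
#'
#' @param model an [atomic_structure()].
#' @param segment_scores named numeric vector, one value per segment
#'   label.
#' @param segments list of [segment_selection()] objects whose labels
#'   match `segment_scores`.
#' @param path output file path.
#' @param attribute attribute name declared in the header (default
#'   `"fit_score"`).
#' @return Invisibly, `path`.
#' @export
write_attributes <- function(model, segment_scores, segments, path,
                             attribute = "fit_score") {
  labs <- vapply(segments, `[[`, character(1), "label")
  if (length(segment_scores) && is.null(names(segment_scores)))
    stop("`segment_scores` must be named by segment label", call. = FALSE)
  unknown <- setdiff(names(segment_scores), labs)
  if (length(unknown))
    stop("segment_scores name(s) with no matching segment: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  res_value <- list()   # "chain:resnum" -> value, insertion order kept
  overlap <- FALSE
  for (seg in segments) {
    if (!seg$label %in% names(segment_scores)) next
    sel <- resolve_segment(model, seg)
    res <- unique(model$atoms[sel, c("chain", "res_seq")])
    keys <- paste0(res$chain, ":", res$res_seq)
    overlap <- overlap || any(keys %in% names(res_value))
    for (k in keys) res_value[[k]] <- unname(segment_scores[[seg$label]])
  }
  if (overlap)
    warning("overlapping segments: later segments override earlier values",
            call. = FALSE)

  lines <- c(paste0("attribute: ", attribute),
             "match mode: 1-to-1",
             "recipient: residues")
  if (length(res_value)) {
    keys <- names(res_value)
    lines <- c(lines, sprintf("\t/%s\t%.6f", keys, unlist(res_value)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write per-residue scores as a generic TSV
#'
#' Plain `chain`, `resnum`, `value` table — the format-agnostic
#' alternative to [write_attributes()].
#'
#' @inheritParams write_attributes
#' @return Invisibly, `path`.
#' @export
write_attributes_tsv <- function(model, segment_scores, segments, path) {
  rows <- list()
  for (seg in segments) {
    if (!seg$label %in% names(segment_scores)) next
    sel <- resolve_segment(model, seg)
    res <- unique(model$atoms[sel, c("chain", "res_seq")])
    rows[[seg$label]] <- data.frame(chain = res$chain, resnum = res$res_seq,
                                    value = unname(segment_scores[[seg$label]]))
  }
  df <- do.call(rbind, rows)
  df <- df[!duplicated(paste(df$chain, df$resnum), fromLast = TRUE), ]
  df <- df[order(df$chain, df$resnum), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
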