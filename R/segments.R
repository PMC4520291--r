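#' Segment (rigid-body) selection
#'
#' A named set of inclusive residue ranges, the unit of local fit
#' assessment (a domain, a secondary-structure element, or a rigid body
#' from a rigid-body decomposition file).
#'
#' @param ranges data frame with columns `chain`, `start`, `end`
#'   (inclusive residue numbers, `start <= end`).
#' @param label segment name.
#' @return Object of class `segment_selection`.
#' @export
segment_selection <- function(ranges, label = "segment") {
  if (!is.data.frame(ranges) || !all(c("chain", "start", "end") %in% names(ranges)))
    stop("`ranges` needs columns chain, start, end", call. = FALSE)
  if (nrow(ranges) == 0L) stop("segment has no ranges", call. = FALSE)
  ranges$start <- as.integer(ranges$start)
  ranges$end <- as.integer(ranges$end)
  if (any(ranges$start > ranges$end))
    stop("segment range has start > end", call. = FALSE)
  structure(list(ranges = ranges[, c("chain", "start", "end")],
                 label = as.character(label)[1L]),
            class = "segment_selection")
}

#' @export
print.segment_selection <- function(x, ...) {
  spans <- sprintf("%s:%d-%d", x$ranges$chain, x$ranges$start, x$ranges$end)
  cat("segment_selection '", x$label, "': ", paste(spans, collapse = ","),
      "\n", sep = "")
  invisible(x)
}

#' Read segment definitions from a text file
#'
#' One segment per line: a label followed by whitespace and comma-separated
#' `chain:start-end` tokens, e.g. `rb1 A:1-40,A:80-120`. Blank lines and
#' lines starting with `#` are skipped. This covers rigid-body files in
#' the style produced by rigid-body decomposition tools.
#'
#' @param path text file path.
#' @return List of [segment_selection()] objects.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    m <- regmatches(line, regexec("^(\\S+)\\s+(\\S+)$", line))[[1]]
    if (length(m) != 3L)
      stop("segment file parse error at line ", i,
           ": expected '<label> <chain:start-end>[,...]'", call. = FALSE)
    label <- m[2]
    toks <- strsplit(m[3], ",", fixed = TRUE)[[1]]
    parsed <- lapply(toks, function(tok) {
      tm <- regmatches(tok, regexec("^([A-Za-z0-9]):(-?\\d+)-(-?\\d+)$", tok))[[1]]
      if (length(tm) != 4L)
        stop("segment file parse error at line ", i, ": bad token '", tok, "'",
             call. = FALSE)
      data.frame(chain = tm[2], start = as.integer(tm[3]),
                 end = as.integer(tm[4]), stringsAsFactors = FALSE)
    })
    ranges <- do.call(rbind, parsed)
    if (any(ranges$start > ranges$end))
      stop("segment file error at line ", i, ": range start > end", call. = FALSE)
    out[[length(out) + 1L]] <- segment_selection(ranges, label = label)
  }
  if (length(out) == 0L) stop("no segments found in ", path, call. = FALSE)
  out
}

#' Write segment definitions to a text file
#'
#' Inverse of [read_segments()]; the round trip is lossless.
#'
#' @param segments list of [segment_selection()] objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_segments <- function(segments, path) {
  lines <- vapply(segments, function(s) {
    spans <- sprintf("%s:%d-%d", s$ranges$chain, s$ranges$start, s$ranges$end)
    paste(s$label, paste(spans, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Resolve a segment against a structure
#'
#' @param structure an [atomic_structure()].
#' @param segment a [segment_selection()].
#' @return Logical vector over the structure's atoms; errors if the
#'   segment matches no residue.
#' @export
resolve_segment <- function(structure, segment) {
  a <- structure$atoms
  sel <- rep(FALSE, nrow(a))
  for (r in seq_len(nrow(segment$ranges))) {
    rng <- segment$ranges[r, ]
    hit <- a$chain == rng$chain & a$res_seq >= rng$start & a$res_seq <= rng$end
    if (!any(hit))
      stop("segment '", segment$label, "' range ", rng$chain, ":", rng$start,
           "-", rng$end, " matches no residue", call. = FALSE)
    sel <- sel | hit
  }
  sel
}

#' Extract the sub-structure covered by a segment
#'
#' @inheritParams resolve_segment
#' @return An [atomic_structure()] restricted to the segment's residues.
#' @export
segment_structure <- function(structure, segment) {
  sel <- resolve_segment(structure, segment)
  atomic_structure(structure$atoms[sel, , drop = FALSE],
                   label = paste0(structure$label, "[", segment$label, "]"))
}
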