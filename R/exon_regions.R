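#' Define an analysis region as an ordered set of exon labels
#'
#' @param name region name token, e.g. `"Nterm_1_4"` or `"full"`.
#' @param exon_labels character vector of exon labels making up the region;
#'   empty only for the special `"full"` region (the whole protein).
#' @return a `region_spec` list.
#' @export
region_spec <- function(name, exon_labels = character(0)) {
  if (name != "full" && length(exon_labels) == 0)
    stop("non-'full' regions need at least one exon label")
  structure(list(name = name, exon_labels = as.character(exon_labels)),
            class = "region_spec")
}

#' Default MAPT-style analysis regions
#'
#' The regions mirror the classical decomposition of tau: the N-terminal
#' projection exons 1-4, the big exon 4a (or its longer 4a-L variant), the
#' microtubule-binding domain exons 9-13, and the full protein.
#'
#' @return named list of `region_spec` objects.
#' @export
default_region_specs <- function() {
  list(Nterm_1_4 = region_spec("Nterm_1_4", c("1", "2", "3", "4")),
       exon4a = region_spec("exon4a", "4a"),
       exon4aL = region_spec("exon4aL", "4a-L"),
       MTBD_9_13 = region_spec("MTBD_9_13", c("9", "10", "11", "12", "13")),
       full = region_spec("full"))
}

#' Extract a labeled region from an annotated protein
#'
#' Concatenates the intervals of the spec's exon labels in map order
#' (by start coordinate). The `"full"` region returns the whole protein and
#' needs no map.
#'
#' @param record one protein record (one-row `data.frame`).
#' @param map exon-map rows (may contain other records; filtered by id).
#' @param spec a `region_spec`.
#' @return list with `sequence` (residue string), `length` (aa), and
#'   `name` (the region name).
#' @export
extract_region <- function(record, map, spec) {
  if (spec$name == "full" || length(spec$exon_labels) == 0)
    return(list(sequence = record$residues, length = nchar(record$residues),
                name = "full"))
  sub <- map[map$record_id == record$record_id, , drop = FALSE]
  missing <- setdiff(spec$exon_labels, sub$exon_label)
  if (length(missing))
    stop("record ", record$record_id, " lacks exon label(s): ",
         paste(missing, collapse = ", "))
  sub <- sub[sub$exon_label %in% spec$exon_labels, , drop = FALSE]
  sub <- sub[order(sub$start), , drop = FALSE]
  pieces <- substring(record$residues, sub$start + 1, sub$end)
  seq <- paste(pieces, collapse = "")
  if (!nzchar(seq)) stop("empty region ", spec$name, " for ", record$record_id)
  list(sequence = seq, length = nchar(seq), name = spec$name)
}

#' Classify a big-exon candidate by length
#'
#' Length bands are induced from the observed size ranges of the two exon
#' classes across vertebrates: 4a-type exons cluster around 250 aa
#' (observed 208-320), 4a-L-type around 350 aa (observed 347-400); 335 aa
#' splits the gap between the two observed ranges.
#'
#' @param length candidate length in amino acids (vectorized).
#' @param min_4a lengths below this are class `"none"`.
#' @param min_4al lengths at or above this are class `"4a-L"`.
#' @return character vector over `"none"`, `"4a"`, `"4a-L"`.
#' @export
#' @examples
#' classify_exon4a(c(100, 251, 355))
classify_exon4a <- function(length, min_4a = 150, min_4al = 335) {
  if (any(length < 0)) stop("negative length")
  ifelse(length < min_4a, "none", ifelse(length < min_4al, "4a", "4a-L"))
}

#' Discover a big exon between two anchor exons
#'
#' Implements flank anchoring: the target is globally aligned against an
#' annotated reference; the reference coordinates "end of the left anchor
#' exon" and "start of the right anchor exon" are projected through the
#' alignment onto the target, and the target interval strictly between the
#' two projections is the candidate big exon. A reference anchor position
#' sitting in a gap column projects to the nearest target position toward
#' the candidate interior, which can only shrink the call.
#'
#' @param target protein record to scan (one-row `data.frame`).
#' @param reference annotated protein record used as anchor donor.
#' @param ref_map exon-map rows for the reference.
#' @param scheme scoring scheme for the full-length alignment.
#' @param min_len candidates shorter than this are class `"none"`.
#' @param anchors labels of the left and right anchor exons in `ref_map`
#'   (classically exons 4 and 5, which flank the 4a locus).
#' @param flank number of alignment columns on each side of each projection
#'   used for `anchor_confidence`.
#' @param min_4a,min_4al length bands passed to [classify_exon4a()].
#' @return a `big_exon_call` list: `record_id`, `start`, `end` (0-based,
#'   half-open on the target), `length`, `class_label`,
#'   `anchor_confidence` (fraction of flank columns identical).
#' @export
infer_big_exon <- function(target, reference, ref_map,
                           scheme = load_scoring_scheme(), min_len = 150,
                           anchors = c("4", "5"), flank = 30L,
                           min_4a = 150, min_4al = 335) {
  rmap <- ref_map[ref_map$record_id == reference$record_id, , drop = FALSE]
  missing <- setdiff(anchors, rmap$exon_label)
  if (length(missing))
    stop("reference map lacks anchor exon(s): ",
         paste(missing, collapse = ", "))
  left <- rmap[rmap$exon_label == anchors[1], ]
  right <- rmap[rmap$exon_label == anchors[2], ]
  if (left$start >= right$start)
    stop("anchor '", anchors[1], "' must precede anchor '", anchors[2], "'")
  aln <- align_global(target, reference, scheme)
  ct <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1]]
  cr <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1]]
  tpos <- ifelse(ct == "-", NA_integer_, cumsum(ct != "-") - 1L)
  rpos <- ifelse(cr == "-", NA_integer_, cumsum(cr != "-") - 1L)
  col4 <- which(!is.na(rpos) & rpos == left$end - 1L)
  col5 <- which(!is.na(rpos) & rpos == right$start)
  # project: left anchor -> last target residue at or before its column,
  # snapping rightward (toward the interior) when the column is a gap
  proj_left <- if (!is.na(tpos[col4])) tpos[col4] else {
    inside <- which(!is.na(tpos))
    inside <- inside[inside > col4 & inside < col5]
    if (length(inside)) tpos[inside[1]] else NA_integer_
  }
  proj_right <- if (!is.na(tpos[col5])) tpos[col5] else {
    inside <- which(!is.na(tpos))
    inside <- inside[inside > col4 & inside < col5]
    if (length(inside)) tpos[inside[length(inside)]] else NA_integer_
  }
  if (is.na(proj_left) || is.na(proj_right)) {
    start <- end <- 0L
  } else {
    start <- proj_left + 1L
    end <- proj_right          # exclusive
    if (end < start) end <- start
  }
  len <- end - start
  ident <- !is.na(tpos) & !is.na(rpos) & ct == cr
  fl_cols <- c(max(1, col4 - flank + 1):col4, col5:min(length(ct), col5 + flank - 1))
  conf <- mean(ident[fl_cols])
  cls <- if (len < min_len) "none" else
    classify_exon4a(len, min_4a = min_4a, min_4al = min_4al)
  structure(list(record_id = target$record_id, start = as.integer(start),
                 end = as.integer(end), length = as.integer(len),
                 class_label = cls, anchor_confidence = conf),
            class = "big_exon_call")
}

#' @export
print.big_exon_call <- function(x, ...) {
  cat(sprintf("big_exon_call: %s [%d,%d) length %d class %s (anchor conf %.2f)\n",
              x$record_id, x$start, x$end, x$length, x$class_label,
              x$anchor_confidence))
  invisible(x)
}
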