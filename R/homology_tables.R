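#' Region-wise homology table against a reference
#'
#' For every (target, region) pair the region is extracted from both a
#' reference and the target, globally aligned, and summarized with
#' EMBOSS-convention statistics. Several reference records may be supplied
#' (e.g. one isoform carrying the 4a exon and one carrying 4a-L); for each
#' region the first reference that resolves it is used. Pairs where either
#' side lacks the region are skipped with a message, mirroring the blank
#' cells of a printed homology table.
#'
#' @param references protein record `data.frame` (>= 1 row).
#' @param ref_maps exon-map rows covering the references.
#' @param targets protein record `data.frame`.
#' @param target_maps exon-map rows covering the targets.
#' @param regions list of `region_spec`s (default [default_region_specs()]).
#' @param scheme scoring scheme.
#' @param window window width for `max_window_identity`.
#' @return `data.frame` with one row per resolvable (target, region):
#'   `record_id`, `species_label`, `region_name`, `identity_pct`,
#'   `similarity_pct`, `max_window_identity`, `ref_region_len`,
#'   `target_region_len`, `ref_id`.
#' @export
region_homology_table <- function(references, ref_maps, targets, target_maps,
                                  regions = default_region_specs(),
                                  scheme = load_scoring_scheme(),
                                  window = 30L) {
  rows <- list()
  for (ti in seq_len(nrow(targets))) {
    tgt <- targets[ti, , drop = FALSE]
    for (spec in regions) {
      treg <- tryCatch(extract_region(tgt, target_maps, spec),
                       error = function(e) NULL)
      if (is.null(treg)) {
        message("skipping ", tgt$record_id, " / ", spec$name,
                ": region not annotated in target")
        next
      }
      rreg <- NULL; rid <- NA_character_
      for (ri in seq_len(nrow(references))) {
        ref <- references[ri, , drop = FALSE]
        rreg <- tryCatch(extract_region(ref, ref_maps, spec),
                         error = function(e) NULL)
        if (!is.null(rreg)) { rid <- ref$record_id; break }
      }
      if (is.null(rreg)) {
        message("skipping ", tgt$record_id, " / ", spec$name,
                ": region not annotated in any reference")
        next
      }
      aln <- align_global(treg$sequence, rreg$sequence, scheme)
      st <- alignment_stats(aln, scheme, window = window)
      rows[[length(rows) + 1]] <- data.frame(
        record_id = tgt$record_id, species_label = tgt$species_label,
        region_name = spec$name, identity_pct = st$identity_pct,
        similarity_pct = st$similarity_pct,
        max_window_identity = st$max_window_identity,
        ref_region_len = rreg$length, target_region_len = treg$length,
        ref_id = rid, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no resolvable regions for any target")
  do.call(rbind, rows)
}

#' All-vs-all percent identity matrix for one region
#'
#' Each unordered pair of records is aligned once on the extracted region
#' and the identity percentage is entered symmetrically; the diagonal is
#' set to 100. Records lacking the region are dropped with a message.
#'
#' @param records protein record `data.frame`.
#' @param maps exon-map rows (unused for the `"full"` region).
#' @param region a `region_spec`.
#' @param scheme scoring scheme.
#' @return square numeric matrix with record ids as dimnames.
#' @export
identity_matrix <- function(records, maps = NULL, region = region_spec("full"),
                            scheme = load_scoring_scheme()) {
  seqs <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    reg <- tryCatch(extract_region(rec, maps, region), error = function(e) NULL)
    if (is.null(reg)) {
      message("dropping ", rec$record_id, ": no region ", region$name)
      next
    }
    seqs[[rec$record_id]] <- reg$sequence
  }
  if (length(seqs) < 2)
    stop("need at least 2 records with region ", region$name)
  ids <- names(seqs)
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- alignment_stats(align_global(seqs[[i]], seqs[[j]], scheme), scheme)
      m[i, j] <- m[j, i] <- st$identity_pct
    }
  }
  m
}

#' Call significance of a homology signal
#'
#' A pair is significant when overall identity reaches `min_identity`
#' percent *and* at least one alignment window is locally conserved
#' (`max_window_identity >= window_min` percent). Low-identity alignments
#' whose matches are scattered, with no contiguous conserved stretch, are
#' classified as lacking important homology.
#'
#' @param stats an `alignment_stats` object.
#' @param min_identity minimum overall identity (percent).
#' @param window_min minimum best-window identity (percent).
#' @return list with `status` (`"significant"`/`"nonsignificant"`),
#'   `identity_pct`, `max_window_identity`, `reason`.
#' @export
classify_homology <- function(stats, min_identity = 20, window_min = 40) {
  ok_id <- stats$identity_pct >= min_identity
  ok_win <- stats$max_window_identity >= window_min
  status <- if (ok_id && ok_win) "significant" else "nonsignificant"
  reason <- if (ok_id && ok_win) {
    "identity and contiguous window identity above thresholds"
  } else if (!ok_id && !ok_win) {
    sprintf("identity %.1f%% < %.1f%% and best window %.1f%% < %.1f%% (scattered)",
            stats$identity_pct, min_identity, stats$max_window_identity, window_min)
  } else if (!ok_id) {
    sprintf("identity %.1f%% < %.1f%%", stats$identity_pct, min_identity)
  } else {
    sprintf("best window %.1f%% < %.1f%% (scattered matches)",
            stats$max_window_identity, window_min)
  }
  list(status = status, identity_pct = stats$identity_pct,
       max_window_identity = stats$max_window_identity, reason = reason)
}

#' Conservation of one region relative to another
#'
#' `100 * mean(numerator) / mean(denominator)`, e.g. mean big-exon identity
#' across a clade relative to mean microtubule-binding-domain identity.
#'
#' @param numerator_values,denominator_values nonempty numeric vectors of
#'   identity percentages.
#' @return list with `value` (unrounded percent) and `rounded`
#'   (nearest integer, as such ratios are conventionally reported).
#' @export
#' @examples
#' conservation_ratio(c(10), c(40))$rounded  # 25
conservation_ratio <- function(numerator_values, denominator_values) {
  if (!length(numerator_values) || !length(denominator_values))
    stop("both value lists must be nonempty")
  dm <- mean(denominator_values)
  if (dm == 0) stop("zero denominator mean")
  v <- 100 * mean(numerator_values) / dm
  list(value = v, rounded = round(v))
}

#' Rank database records by alignment similarity to a query
#'
#' A desk-scale similarity scan: the query is globally aligned against every
#' record (and, when exon maps are supplied, against every annotated exon of
#' every record), then hits are sorted by score (descending), ties broken by
#' identity and record id. Not a BLAST replacement - no E-values, no
#' seeding; intended for small curated sets.
#'
#' @param query residue string or one-row protein record.
#' @param database protein record `data.frame` (nonempty).
#' @param scheme scoring scheme.
#' @param maps optional exon-map rows; when given, per-exon hits are
#'   reported in addition to full-length hits.
#' @return `data.frame` of hits: `record_id`, `region`, `score`,
#'   `identity_pct`, `start`, `end` (matched interval on the record,
#'   0-based half-open).
#' @export
rank_by_similarity <- function(query, database, scheme = load_scoring_scheme(),
                               maps = NULL) {
  if (nrow(database) == 0) stop("empty database")
  q <- as_residues(query)
  one_hit <- function(subject_seq, offset, id, region) {
    aln <- align_global(q, subject_seq, scheme)
    st <- alignment_stats(aln, scheme)
    cq <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1]]
    cs <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1]]
    both <- which(cq != "-" & cs != "-")
    spos <- cumsum(cs != "-") - 1L
    if (length(both)) {
      s0 <- spos[both[1]]; s1 <- spos[both[length(both)]] + 1L
    } else { s0 <- 0L; s1 <- 0L }
    data.frame(record_id = id, region = region, score = aln$score,
               identity_pct = st$identity_pct,
               start = offset + s0, end = offset + s1,
               stringsAsFactors = FALSE)
  }
  hits <- list()
  for (i in seq_len(nrow(database))) {
    rec <- database[i, , drop = FALSE]
    hits[[length(hits) + 1]] <- one_hit(rec$residues, 0L, rec$record_id, "full")
    if (!is.null(maps)) {
      sub <- maps[maps$record_id == rec$record_id, , drop = FALSE]
      for (k in seq_len(nrow(sub))) {
        exseq <- substring(rec$residues, sub$start[k] + 1, sub$end[k])
        hits[[length(hits) + 1]] <- one_hit(exseq, sub$start[k],
                                            rec$record_id, sub$exon_label[k])
      }
    }
  }
  out <- do.call(rbind, hits)
  out[order(-out$score, -out$identity_pct, out$record_id), , drop = FALSE]
}
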