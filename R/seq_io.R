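#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
NULL

AA_ALPHABET_20X <- c("A","C","D","E","F","G","H","I","K","L",
                     "M","N","P","Q","R","S","T","V","W","Y","X")

#' Construct a table of protein records
#'
#' A protein record collection is a plain `data.frame` with one row per
#' protein and columns `record_id`, `species_label`, `residues`,
#' `source_accession`. Residues are uppercase single-letter amino acids
#' (the 20 standard letters plus `X`).
#'
#' @param record_id character vector of short unique tokens.
#' @param residues character vector of amino-acid strings.
#' @param species_label free-text species labels; defaults to `record_id`.
#' @param source_accession optional accession strings (e.g. a transcript id);
#'   `NA` when unknown.
#' @return a `data.frame` of validated protein records.
#' @export
#' @examples
#' protein_records("h1", "MAEPRQEF", species_label = "human")
protein_records <- function(record_id, residues, species_label = record_id,
                            source_accession = NA_character_) {
  n <- length(record_id)
  rec <- data.frame(record_id = as.character(record_id),
                    species_label = rep_len(as.character(species_label), n),
                    residues = toupper(as.character(residues)),
                    source_accession = rep_len(as.character(source_accession), n),
                    stringsAsFactors = FALSE)
  validate_protein_records(rec)
  rec
}

validate_protein_records <- function(rec) {
  stopifnot(is.data.frame(rec),
            all(c("record_id", "residues") %in% names(rec)))
  if (anyDuplicated(rec$record_id))
    stop("duplicate record_id: ",
         paste(unique(rec$record_id[duplicated(rec$record_id)]), collapse = ", "))
  if (any(!nzchar(rec$residues)))
    stop("empty residue string for record: ",
         paste(rec$record_id[!nzchar(rec$residues)], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET_20X, collapse = "")),
               rec$residues)
  if (any(bad))
    stop("illegal residue characters in record: ",
         paste(rec$record_id[bad], collapse = ", "))
  invisible(rec)
}

#' Read protein sequences from a FASTA file
#'
#' The first whitespace-delimited token of each header becomes `record_id`;
#' the remainder of the header is scanned for `species=...` and
#' `accession=...` key-value pairs (separated by `;`).
#'
#' @param path path to a FASTA file.
#' @return a protein record `data.frame` (see [protein_records()]); empty
#'   (zero rows) for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0 ||
      !any(startsWith(readLines(path, warn = FALSE), ">"))) {
    if (length(grep("\\S", readLines(path, warn = FALSE))))
      stop("malformed FASTA (no header) at line 1 of ", path)
    return(protein_records(character(0), character(0)))
  }
  pat <- sprintf("[^%s]", paste(AA_ALPHABET_20X, collapse = ""))
  bad_line <- function() {
    lines <- readLines(path, warn = FALSE)
    which(!startsWith(lines, ">") &
            grepl(pat, toupper(gsub("\\s", "", lines))) &
            nzchar(gsub("\\s", "", lines)))[1]
  }
  aa <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("illegal residue character at line ", bad_line(), " of ", path)
      invokeRestart("muffleWarning")
    })
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  kv <- function(d, key) {
    m <- regmatches(d, regexec(paste0(key, "=([^;]*)"), d))[[1]]
    if (length(m) == 2) trimws(m[2]) else NA_character_
  }
  species <- vapply(desc, kv, "", key = "species", USE.NAMES = FALSE)
  acc <- vapply(desc, kv, "", key = "accession", USE.NAMES = FALSE)
  species <- ifelse(is.na(species) | !nzchar(species), ids, species)
  seqs <- toupper(as.character(aa))
  # residues Biostrings accepts but this package does not (B, J, Z, ...)
  if (any(grepl(pat, seqs)))
    stop("illegal residue character at line ", bad_line(), " of ", path)
  protein_records(ids, seqs, species_label = species, source_accession = acc)
}

#' Write protein records to FASTA
#'
#' Sequences are wrapped at 60 columns. `species=` / `accession=` key-value
#' pairs are appended to the header so that [read_fasta()] round-trips the
#' records exactly.
#'
#' @param records a protein record `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  validate_protein_records(records)
  aa <- Biostrings::AAStringSet(records$residues)
  desc <- character(nrow(records))
  sp <- records$species_label
  extra <- ifelse(!is.na(sp) & sp != records$record_id,
                  paste0("species=", sp), "")
  acc <- records$source_accession
  extra2 <- ifelse(!is.na(acc) & nzchar(acc), paste0("accession=", acc), "")
  desc <- trimws(paste(extra, extra2, sep = ";"))
  desc <- gsub("^;|;$", "", desc)
  names(aa) <- trimws(paste(records$record_id, desc))
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' Read an exon map TSV
#'
#' The format is tab-separated with a header line
#' `record_id  exon_label  start  end`; `#`-prefixed comment lines are
#' permitted. Coordinates are 0-based, half-open, on the protein sequence.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with columns `record_id`, `exon_label`, `start`,
#'   `end`, validated per record (sorted, non-overlapping, unique labels).
#' @export
read_exon_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("record_id", "exon_label", "start", "end")
  if (!all(need %in% names(tb)))
    stop("exon map must have columns: ", paste(need, collapse = ", "))
  tb <- tb[, need]
  tb$record_id <- as.character(tb$record_id)
  tb$exon_label <- as.character(tb$exon_label)
  tb$start <- as.integer(tb$start)
  tb$end <- as.integer(tb$end)
  validate_exon_map(tb)
  tb
}

#' Validate an exon-map table
#'
#' Checks, per `record_id`: `0 <= start < end`, rows sorted by `start`,
#' intervals non-overlapping, labels unique.
#'
#' @param map exon-map `data.frame` (`record_id`, `exon_label`, `start`, `end`).
#' @return the map, invisibly; stops with a message listing offending rows.
#' @export
validate_exon_map <- function(map) {
  stopifnot(all(c("record_id", "exon_label", "start", "end") %in% names(map)))
  if (nrow(map) == 0) return(invisible(map))
  bad_rows <- character(0)
  rowdesc <- function(i) sprintf("(%s, %s, %d, %d)", map$record_id[i],
                                 map$exon_label[i], map$start[i], map$end[i])
  if (any(map$start < 0 | map$end <= map$start))
    bad_rows <- c(bad_rows, paste("bad interval:",
                                  sapply(which(map$start < 0 | map$end <= map$start), rowdesc)))
  for (id in unique(map$record_id)) {
    sub <- map[map$record_id == id, , drop = FALSE]
    idx <- which(map$record_id == id)
    if (is.unsorted(sub$start, strictly = TRUE) && nrow(sub) > 1) {
      if (any(diff(sub$start) <= 0))
        bad_rows <- c(bad_rows, paste("unsorted rows for", id, ":",
                                      paste(sapply(idx, rowdesc), collapse = " ")))
    }
    o <- order(sub$start)
    s <- sub[o, , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      bad_rows <- c(bad_rows, paste("overlapping intervals for", id, ":",
                                    paste(sapply(idx, rowdesc), collapse = " ")))
    if (anyDuplicated(sub$exon_label))
      bad_rows <- c(bad_rows, paste("duplicate labels for", id, ":",
                                    paste(unique(sub$exon_label[duplicated(sub$exon_label)]),
                                          collapse = ", ")))
  }
  if (length(bad_rows)) stop("invalid exon map:\n  ",
                             paste(bad_rows, collapse = "\n  "))
  invisible(map)
}

#' Write an exon-map table to TSV
#'
#' @param map exon-map `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exon_map <- function(map, path) {
  validate_exon_map(map)
  utils::write.table(map[, c("record_id", "exon_label", "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check an exon map against its protein record
#'
#' @param record a single protein record (one-row `data.frame` or a list with
#'   `record_id` and `residues`).
#' @param map exon-map rows for that record.
#' @return a list with elements `ok` (no errors), `errors` (intervals
#'   exceeding the protein length), and `warnings` (uncovered residue
#'   ranges, reported as `"uncovered [a,b)"`). Unannotated inter-exon
#'   residues are warnings, not errors.
#' @export
validate_annotation <- function(record, map) {
  map <- map[map$record_id == record$record_id, , drop = FALSE]
  len <- nchar(record$residues)
  errors <- character(0)
  warnings <- character(0)
  over <- map$end > len | map$start >= len
  if (any(over))
    errors <- c(errors, sprintf("interval %s [%d,%d) exceeds protein length %d",
                                map$exon_label[over], map$start[over],
                                map$end[over], len))
  cov <- rep(FALSE, len)
  for (i in seq_len(nrow(map))) {
    a <- max(map$start[i], 0); b <- min(map$end[i], len)
    if (b > a) cov[(a + 1):b] <- TRUE
  }
  if (!all(cov)) {
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    unc <- which(!r$values)
    warnings <- c(warnings, sprintf("uncovered [%d,%d)", starts[unc], ends[unc]))
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warnings)
}

#' Extract one record from a record table
#' @param records protein record `data.frame`.
#' @param id record id.
#' @return one-row `data.frame`.
#' @export
get_record <- function(records, id) {
  i <- match(id, records$record_id)
  if (is.na(i)) stop("no record with id: ", id)
  records[i, , drop = FALSE]
}
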