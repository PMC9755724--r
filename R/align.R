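#' Load a protein scoring scheme
#'
#' Wraps the substitution matrices shipped with Biostrings (BLOSUM and PAM
#' families) together with affine gap penalties. The defaults reproduce the
#' published defaults of the EMBOSS Needle global aligner: BLOSUM62,
#' gap open 10, gap extend 0.5, end gaps free. A gap of length L is charged
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param name matrix name, case-insensitive; one of blosum45/50/62/80/100,
#'   pam30/40/70/120/250.
#' @param gap_open non-negative penalty for opening a gap.
#' @param gap_extend non-negative penalty per additional gapped residue.
#' @param penalize_end_gaps if `TRUE`, terminal gaps are charged like
#'   internal ones.
#' @return an object of class `scoring_scheme`.
#' @export
#' @examples
#' sc <- load_scoring_scheme()
#' pair_score(sc, "W", "W")  # 11
load_scoring_scheme <- function(name = "blosum62", gap_open = 10,
                                gap_extend = 0.5, penalize_end_gaps = FALSE) {
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  nm <- toupper(name)
  if (!nm %in% known)
    stop("unknown scoring matrix '", name, "'; available: ",
         paste(tolower(known), collapse = ", "))
  stopifnot(gap_open >= 0, gap_extend >= 0)
  env <- new.env()
  utils::data(list = nm, package = "Biostrings", envir = env)
  mat <- get(nm, envir = env)
  structure(list(matrix_name = tolower(nm), matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend,
                 penalize_end_gaps = isTRUE(penalize_end_gaps)),
            class = "scoring_scheme")
}

#' Substitution score of a residue pair
#' @param scheme a `scoring_scheme`.
#' @param x,y single residue characters.
#' @return integer score.
#' @export
pair_score <- function(scheme, x, y) {
  unname(scheme$matrix[toupper(x), toupper(y)])
}

res_index <- function(seq, scheme) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(scheme$matrix))
  if (anyNA(idx))
    stop("residue not covered by scoring matrix: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx
}

as_residues <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x$residues
  } else if (is.list(x) && !is.null(x$residues)) {
    x$residues
  } else {
    as.character(x)
  }
}

#' Global alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under the three-state (Gotoh) affine
#' gap model. End gaps are free unless the scheme says otherwise. The
#' traceback tie-break (diagonal, then gap-in-second, then gap-in-first) is
#' fixed, so results are deterministic.
#'
#' @param a,b protein records (one-row `data.frame`) or plain residue
#'   strings; both nonempty.
#' @param scheme a `scoring_scheme`; see [load_scoring_scheme()].
#' @return an object of class `pairwise_alignment`: `gapped_a`, `gapped_b`
#'   (equal-length strings over residues and `-`), `score`, and the input
#'   ids (`id_a`, `id_b`) when available.
#' @export
#' @examples
#' sc <- load_scoring_scheme()
#' align_global("MKTAYIAK", "MKTWYIAK", sc)
align_global <- function(a, b, scheme = load_scoring_scheme()) {
  sa <- as_residues(a); sb <- as_residues(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be nonempty")
  ia <- res_index(sa, scheme); ib <- res_index(sb, scheme)
  res <- nw_align_cpp(ia, ib, scheme$matrix, scheme$gap_open,
                      scheme$gap_extend, scheme$penalize_end_gaps)
  ca <- strsplit(sa, "", fixed = TRUE)[[1]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1]]
  ga <- ifelse(res$a_pos == 0, "-", ca[pmax(res$a_pos, 1)])
  gb <- ifelse(res$b_pos == 0, "-", cb[pmax(res$b_pos, 1)])
  structure(list(gapped_a = paste(ga, collapse = ""),
                 gapped_b = paste(gb, collapse = ""),
                 score = res$score,
                 id_a = if (is.data.frame(a)) a$record_id else NA_character_,
                 id_b = if (is.data.frame(b)) b$record_id else NA_character_),
            class = "pairwise_alignment")
}

#' Construct a pairwise alignment from pre-gapped strings
#' @param gapped_a,gapped_b equal-length gapped strings.
#' @param score optional alignment score.
#' @return a `pairwise_alignment`.
#' @export
pairwise_alignment <- function(gapped_a, gapped_b, score = NA_real_) {
  stopifnot(nchar(gapped_a) == nchar(gapped_b))
  ca <- strsplit(gapped_a, "")[[1]]; cb <- strsplit(gapped_b, "")[[1]]
  if (any(ca == "-" & cb == "-")) stop("column with two gaps")
  structure(list(gapped_a = gapped_a, gapped_b = gapped_b, score = score,
                 id_a = NA_character_, id_b = NA_character_),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: %d columns, score %.1f\n",
              nchar(x$gapped_a), x$score))
  invisible(x)
}

#' Identity/similarity statistics of an alignment
#'
#' Counts follow the EMBOSS convention: the denominator of every percentage
#' is the total number of alignment columns, gap columns included. A column
#' is *identical* when both residues are present and equal, and *similar*
#' when identical or when the substitution score of the pair is positive.
#'
#' @param aln a `pairwise_alignment`.
#' @param scheme the `scoring_scheme` used to judge similarity.
#' @param window width (columns) of the sliding window for
#'   `max_window_identity`; if the alignment is shorter, one window of the
#'   full length is used.
#' @return an object of class `alignment_stats` with fields `length`,
#'   `n_identical`, `n_similar`, `n_gap_columns`, `identity_pct`,
#'   `similarity_pct`, `gaps_pct`, `max_window_identity` (percent of
#'   identical columns in the best window), `window`.
#' @export
alignment_stats <- function(aln, scheme = load_scoring_scheme(), window = 30L) {
  stopifnot(inherits(aln, "pairwise_alignment"), window >= 1)
  ca <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1]]
  L <- length(ca)
  gap <- ca == "-" | cb == "-"
  ident <- !gap & ca == cb
  sim <- ident
  ng <- which(!gap & !ident)
  if (length(ng))
    sim[ng] <- scheme$matrix[cbind(ca[ng], cb[ng])] > 0
  w <- min(window, L)
  cs <- c(0, cumsum(ident))
  win_id <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
  structure(list(length = L,
                 n_identical = sum(ident),
                 n_similar = sum(sim),
                 n_gap_columns = sum(gap),
                 identity_pct = 100 * sum(ident) / L,
                 similarity_pct = 100 * sum(sim) / L,
                 gaps_pct = 100 * sum(gap) / L,
                 max_window_identity = 100 * max(win_id),
                 window = w),
            class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf(paste0("alignment: %d columns | identity %.1f%% | ",
                     "similarity %.1f%% | gaps %.1f%% | ",
                     "best %d-col window %.1f%%\n"),
              x$length, x$identity_pct, x$similarity_pct, x$gaps_pct,
              x$window, x$max_window_identity))
  invisible(x)
}

#' Render a pairwise alignment as a text block
#'
#' 60-column blocks with a match line: `|` identical, `:` similar
#' (positive substitution score), space otherwise (including gap columns).
#'
#' @param aln a `pairwise_alignment`.
#' @param stats optional `alignment_stats` for the header.
#' @param scheme scoring scheme used for the `:` similarity marks.
#' @param width block width in columns.
#' @return a single character string (with embedded newlines).
#' @export
format_pair <- function(aln, stats = NULL, scheme = load_scoring_scheme(),
                        width = 60L) {
  ca <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1]]
  gap <- ca == "-" | cb == "-"
  ident <- !gap & ca == cb
  simil <- rep(FALSE, length(ca))
  ng <- which(!gap & !ident)
  if (length(ng))
    simil[ng] <- scheme$matrix[cbind(ca[ng], cb[ng])] > 0
  mk <- ifelse(ident, "|", ifelse(simil, ":", " "))
  hdr <- character(0)
  if (!is.null(stats))
    hdr <- c(sprintf("# Length: %d", stats$length),
             sprintf("# Identity: %d/%d (%.1f%%)", stats$n_identical,
                     stats$length, stats$identity_pct),
             sprintf("# Similarity: %d/%d (%.1f%%)", stats$n_similar,
                     stats$length, stats$similarity_pct),
             sprintf("# Gaps: %d/%d (%.1f%%)", stats$n_gap_columns,
                     stats$length, stats$gaps_pct),
             sprintf("# Score: %.1f", aln$score), "")
  blocks <- character(0)
  for (s in seq(1, length(ca), by = width)) {
    e <- min(s + width - 1, length(ca))
    blocks <- c(blocks,
                paste(ca[s:e], collapse = ""),
                paste(mk[s:e], collapse = ""),
                paste(cb[s:e], collapse = ""), "")
  }
  paste(c(hdr, blocks), collapse = "\n")
}
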