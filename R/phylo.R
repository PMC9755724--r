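#' Convert a percent identity matrix to a distance matrix
#'
#' `d[i,j] = 100 - (id[i,j] + id[j,i]) / 2`, diagonal forced to zero. No
#' evolutionary correction is applied: the resulting trees are descriptive
#' overviews of identity structure, not dated phylogenies, and correction
#' formulas diverge at identities near the random-alignment noise floor.
#'
#' @param id square numeric identity matrix with labels as dimnames.
#' @return symmetric distance matrix, zero diagonal, same labels.
#' @export
identity_to_distance <- function(id) {
  stopifnot(is.matrix(id), nrow(id) == ncol(id))
  d <- 100 - (id + t(id)) / 2
  diag(d) <- 0
  if (any(d < 0)) stop("identity above 100 produces negative distance")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}); negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to zero
#' with a message.
#'
#' @param d square symmetric distance matrix (>= 3 labels) or `dist`.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 leaves")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    message("clamping ", sum(tr$edge.length < 0),
            " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

newick_label <- function(x) {
  if (!nzchar(x)) return(x)
  if (grepl("[\\s(),:;\\[\\]']", x, perl = TRUE))
    paste0("'", gsub("'", "''", x), "'")
  else x
}

phylo_to_newick <- function(tr, digits = 6) {
  ntip <- length(tr$tip.label)
  children <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  rec <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) return(newick_label(tr$tip.label[node]))
    inner <- vapply(kids, function(e) {
      br <- if (is.null(tr$edge.length)) "" else paste0(":", fmt(tr$edge.length[e]))
      paste0(rec(tr$edge[e, 2]), br)
    }, "")
    nl <- if (is.null(tr$node.label)) "" else {
      l <- tr$node.label[node - ntip]
      if (is.na(l)) "" else newick_label(l)
    }
    paste0("(", paste(inner, collapse = ","), ")", nl)
  }
  paste0(rec(ntip + 1L), ";")
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 6 decimals; labels containing whitespace
#' or Newick metacharacters are single-quoted per the Newick convention
#' (embedded quotes doubled).
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  writeLines(phylo_to_newick(tree), path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that strips the single quotes
#' [write_newick()] may have added around labels.
#'
#' @param path file path (or use `text`).
#' @param text Newick string, alternative to `path`.
#' @return a `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}
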