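#' Curated MAPT cross-species region homology values
#'
#' A transcription of a published cross-species survey of MAPT (tau) region
#' homology at protein level: percent identity of the full protein, the
#' N-terminal exons 1-4, the big exon (4a or its longer 4a-L variant), and
#' the microtubule-binding domain exons 9-13, each against the human
#' reference isoforms (776 aa carrying 4a; 833 aa carrying 4a-L), plus
#' region sizes. Used as a desk-scale input for conservation-ratio
#' arithmetic and as the empirical basis of the [classify_exon4a()] length
#' bands.
#'
#' @return `data.frame` with columns `clade`, `species`, `record_note`,
#'   `region`, `identity_pct`, `size_aa`.
#' @export
mapt_reference_homology <- function() {
  path <- system.file("extdata", "mapt_region_identity.tsv",
                      package = "exonevo", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Per-species big-exon identity for a clade
#'
#' One value per species: the identity of the big-exon variant analyzed for
#' that species, preferring the 4a-L row when a species contributes both
#' variants (the longer variant subsumes 4a). The human reference rows are
#' excluded.
#'
#' @param tbl table from [mapt_reference_homology()].
#' @param clade clade name (`"primates"`, `"mammals"`, `"vertebrates"`).
#' @return named numeric vector of identity percentages, one per species.
#' @export
clade_big_exon_identities <- function(tbl, clade) {
  sub <- tbl[tbl$clade == clade & tbl$species != "human" &
               tbl$region %in% c("exon4a", "exon4aL"), , drop = FALSE]
  species <- unique(sub$species)
  vapply(setNames(species, species), function(sp) {
    rows <- sub[sub$species == sp, , drop = FALSE]
    if (any(rows$region == "exon4aL"))
      rows$identity_pct[rows$region == "exon4aL"][1]
    else rows$identity_pct[rows$region == "exon4a"][1]
  }, numeric(1))
}

#' Per-species identity of a fixed region for a clade
#'
#' One value per species (first record when a species contributes several),
#' human excluded.
#'
#' @inheritParams clade_big_exon_identities
#' @param region region name as in the table (e.g. `"MTBD_9_13"`, `"full"`).
#' @return named numeric vector.
#' @export
clade_region_identities <- function(tbl, clade, region) {
  sub <- tbl[tbl$clade == clade & tbl$species != "human" &
               tbl$region == region, , drop = FALSE]
  species <- unique(sub$species)
  vapply(setNames(species, species), function(sp)
    sub$identity_pct[sub$species == sp][1], numeric(1))
}
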