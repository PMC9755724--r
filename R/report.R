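#' Run the full exon-resolved homology report
#'
#' Orchestrates one end-to-end analysis: load (or simulate) annotated
#' proteins, build the region homology table against the reference, the
#' per-region percent identity matrices, significance and big-exon calls,
#' and a neighbor-joining overview tree, and write everything plus a
#' provenance-carrying `report.json` to an output directory. Any stage
#' failure aborts with a stage-named error and removes partial outputs.
#'
#' @param config a list with fields:
#'   \describe{
#'     \item{`fasta`, `exons`}{input FASTA and exon-map TSV paths; or}
#'     \item{`preset`}{a [make_preset()] name to simulate inputs
#'       (with `seed`).}
#'     \item{`reference_id`}{record id(s) used as reference; defaults to the
#'       preset's reference or the first record.}
#'     \item{`regions`}{named list of `region_spec`s; default regions are
#'       derived from the exon labels present (or [default_region_specs()]
#'       when the classical labels are found).}
#'     \item{`matrix`, `gap_open`, `gap_extend`}{scoring parameters
#'       (defaults blosum62 / 10 / 0.5).}
#'     \item{`min_identity`, `window_min`}{significance thresholds
#'       (defaults 20 / 40 percent).}
#'     \item{`anchors`}{anchor exon labels for big-exon discovery
#'       (default `c("4", "5")`).}
#'     \item{`out_dir`}{output directory (required).}
#'     \item{`seed`}{seed forwarded to the preset simulation.}
#'   }
#' @return (invisibly) the report list written to `report.json`.
#' @export
run_report <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- "load_inputs"
  emit <- function(name) {
    p <- file.path(config$out_dir, name)
    written <<- c(written, p)
    p
  }
  result <- tryCatch({
    if (!is.null(config$preset)) {
      cfg <- make_preset(config$preset,
                                    seed = if (is.null(config$seed)) 17L else config$seed)
      fam <- simulate_family(cfg)
      records <- fam$records; maps <- fam$exon_maps
      if (is.null(config$reference_id)) config$reference_id <- cfg$reference_id
      if (is.null(config$anchors)) config$anchors <- cfg$anchors
      inputs <- list(preset = config$preset, seed = cfg$seed)
    } else {
      records <- read_fasta(config$fasta)
      maps <- read_exon_map(config$exons)
      inputs <- list(fasta = config$fasta, exons = config$exons,
                     checksums = as.list(tools::md5sum(c(config$fasta, config$exons))))
    }
    if (is.null(config$reference_id)) config$reference_id <- records$record_id[1]
    refs <- records[records$record_id %in% config$reference_id, , drop = FALSE]
    targets <- records[!records$record_id %in% config$reference_id, , drop = FALSE]
    if (nrow(targets) == 0) stop("no targets")
    if (nrow(refs) == 0) stop("reference_id not found: ",
                              paste(config$reference_id, collapse = ", "))
    scheme <- load_scoring_scheme(
      name = if (is.null(config$matrix)) "blosum62" else config$matrix,
      gap_open = if (is.null(config$gap_open)) 10 else config$gap_open,
      gap_extend = if (is.null(config$gap_extend)) 0.5 else config$gap_extend)
    regions <- config$regions
    if (is.null(regions)) {
      labels <- unique(maps$exon_label)
      if (all(c("1", "4a", "9") %in% labels)) {
        regions <- default_region_specs()
      } else {
        regions <- c(lapply(setNames(labels, labels), function(l) region_spec(l, l)),
                     list(full = region_spec("full")))
      }
    }
    min_identity <- if (is.null(config$min_identity)) 20 else config$min_identity
    window_min <- if (is.null(config$window_min)) 40 else config$window_min
    anchors <- if (is.null(config$anchors)) c("4", "5") else config$anchors

    stage <- "region_homology_table"
    tableA <- suppressMessages(
      region_homology_table(refs, maps, targets, maps, regions, scheme))
    utils::write.table(tableA, emit("tableA.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

    stage <- "identity_matrices"
    pims <- list()
    for (nm in names(regions)) {
      m <- tryCatch(suppressMessages(
        identity_matrix(records, maps, regions[[nm]], scheme)),
        error = function(e) NULL)
      if (!is.null(m)) {
        pims[[nm]] <- m
        utils::write.table(data.frame(record_id = rownames(m), m,
                                      check.names = FALSE),
                           emit(paste0("pim_", nm, ".tsv")), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }

    stage <- "significance_and_bigexon_calls"
    sig <- do.call(rbind, lapply(seq_len(nrow(tableA)), function(i) {
      st <- list(identity_pct = tableA$identity_pct[i],
                 max_window_identity = tableA$max_window_identity[i])
      cl <- classify_homology(st, min_identity, window_min)
      data.frame(call_type = "homology", record_id = tableA$record_id[i],
                 region = tableA$region_name[i], status = cl$status,
                 start = NA_integer_, end = NA_integer_, length = NA_integer_,
                 class = NA_character_, anchor_confidence = NA_real_,
                 reason = cl$reason, stringsAsFactors = FALSE)
    }))
    bigexon <- NULL
    ref1 <- refs[1, , drop = FALSE]
    if (all(anchors %in% maps$exon_label[maps$record_id == ref1$record_id])) {
      bigexon <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
        call <- infer_big_exon(targets[i, , drop = FALSE], ref1, maps, scheme,
                               anchors = anchors)
        data.frame(call_type = "big_exon", record_id = call$record_id,
                   region = NA_character_, status = NA_character_,
                   start = call$start, end = call$end, length = call$length,
                   class = call$class_label,
                   anchor_confidence = call$anchor_confidence,
                   reason = NA_character_, stringsAsFactors = FALSE)
      }))
    }
    calls <- rbind(sig, bigexon)
    utils::write.table(calls, emit("calls.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

    stage <- "tree"
    tree_file <- NULL
    full_m <- pims[["full"]]
    if (is.null(full_m))
      full_m <- tryCatch(suppressMessages(
        identity_matrix(records, maps, region_spec("full"), scheme)),
        error = function(e) NULL)
    if (!is.null(full_m) && nrow(full_m) >= 3) {
      tr <- suppressMessages(nj_tree(identity_to_distance(full_m)))
      write_newick(tr, emit("tree.nwk"))
      tree_file <- "tree.nwk"
    }

    stage <- "report_json"
    report <- list(
      program = "exonevo",
      version = as.character(utils::packageVersion("exonevo")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      parameters = list(reference_id = config$reference_id,
                        matrix = scheme$matrix_name,
                        gap_open = scheme$gap_open,
                        gap_extend = scheme$gap_extend,
                        min_identity = min_identity, window_min = window_min,
                        anchors = anchors, regions = names(regions)),
      inputs = inputs,
      region_homology = tableA,
      identity_matrices = lapply(pims, function(m)
        list(labels = rownames(m), values = unname(m))),
      calls = calls,
      tree = tree_file)
    jsonlite::write_json(report, emit("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    report
  }, error = function(e) {
    suppressWarnings(file.remove(written[file.exists(written)]))
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

#' Simulation-and-recovery experiment
#'
#' Simulates a family from a preset (or explicit `sim_config`), runs the
#' analysis pipeline on the simulated records, and measures how well the
#' pipeline recovers the generative parameters: per-region identity means,
#' the Spearman correlation between configured region rates and pipeline
#' divergence (100 - identity), and big-exon detection
#' sensitivity/specificity with boundary errors against ground truth.
#'
#' @param preset preset name (see [make_preset()]) or a
#'   `sim_config`.
#' @param seed integer seed for the simulation.
#' @param out_dir optional directory; when given, `metrics.json` is written.
#' @param scheme scoring scheme.
#' @return list of metrics: `region_identity` (named means),
#'   `rate_identity_spearman`, `sensitivity`, `specificity`,
#'   `boundary_errors` (per detected carrier), `max_boundary_error`,
#'   `n_carriers`, `n_noncarriers`.
#' @export
run_recovery_experiment <- function(preset, seed = 17L, out_dir = NULL,
                                    scheme = load_scoring_scheme()) {
  cfg <- if (inherits(preset, "sim_config")) preset
         else make_preset(preset, seed = seed)
  fam <- simulate_family(cfg)
  records <- fam$records; maps <- fam$exon_maps
  # configured rate per region label (inserts take their event rate)
  rates <- setNames(cfg$architecture$rate, cfg$architecture$region)
  for (ev in cfg$exonization_events) {
    lb <- if (is.null(ev$label)) "4a" else ev$label
    rates[lb] <- if (is.null(ev$rate)) 0.3 else ev$rate
  }
  region_identity <- sapply(names(rates), function(lb) {
    have <- unique(maps$record_id[maps$exon_label == lb])
    if (length(have) < 2) return(NA_real_)
    ids <- combn(have, 2)
    mean(apply(ids, 2, function(pr) {
      r1 <- extract_region(get_record(records, pr[1]), maps, region_spec(lb, lb))
      r2 <- extract_region(get_record(records, pr[2]), maps, region_spec(lb, lb))
      alignment_stats(align_global(r1$sequence, r2$sequence, scheme), scheme)$identity_pct
    }))
  })
  sp_regions <- if (!is.null(cfg$spearman_regions)) cfg$spearman_regions
                else names(rates)[!is.na(region_identity)]
  sp_regions <- sp_regions[!is.na(region_identity[sp_regions])]
  rate_identity_spearman <-
    if (length(sp_regions) >= 3)
      stats::cor(rates[sp_regions], 100 - region_identity[sp_regions],
                 method = "spearman")
    else NA_real_
  # big-exon detection against truth
  sensitivity <- specificity <- NA_real_
  boundary_errors <- numeric(0)
  detected_classes <- character(0)
  if (length(cfg$exonization_events)) {
    ref_id <- if (!is.null(cfg$reference_id)) cfg$reference_id
              else records$record_id[1]
    anchors <- if (!is.null(cfg$anchors)) cfg$anchors else c("4", "5")
    ref <- get_record(records, ref_id)
    carriers <- unique(unlist(fam$truth$carriers))
    targets <- setdiff(records$record_id, ref_id)
    calls <- lapply(targets, function(id)
      infer_big_exon(get_record(records, id), ref, maps, scheme,
                     anchors = anchors))
    names(calls) <- targets
    is_carrier <- targets %in% carriers
    detected <- vapply(calls, function(cl) cl$class_label != "none", TRUE)
    detected_classes <- vapply(calls, function(cl) cl$class_label, "")
    if (any(is_carrier)) sensitivity <- mean(detected[is_carrier])
    if (any(!is_carrier)) specificity <- mean(!detected[!is_carrier])
    for (id in targets[is_carrier & detected]) {
      tru <- fam$truth$inserts[fam$truth$inserts$record_id == id, ]
      cl <- calls[[id]]
      boundary_errors <- c(boundary_errors,
                           max(abs(cl$start - tru$start[1]),
                               abs(cl$end - tru$end[1])))
    }
  }
  metrics <- list(preset = if (is.character(preset)) preset else "custom",
                  seed = cfg$seed,
                  region_identity = as.list(region_identity),
                  rate_identity_spearman = rate_identity_spearman,
                  sensitivity = sensitivity, specificity = specificity,
                  detected_classes = as.list(detected_classes),
                  boundary_errors = boundary_errors,
                  max_boundary_error = if (length(boundary_errors))
                    max(boundary_errors) else NA_real_,
                  n_carriers = length(unique(unlist(fam$truth$carriers))),
                  n_noncarriers = nrow(records) -
                    length(unique(unlist(fam$truth$carriers))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  metrics
}
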