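#' Run the full barcode-survey analysis pipeline
#'
#' End-to-end, deterministic under a fixed seed: trim to a shared region,
#' collapse and name haplotypes, compare against a reference library,
#' compute the K2P distance matrix, within/between-species summaries and
#' the barcoding gap (hybrid-suspect groups, and haplotypes molecularly
#' assigned to a different species sampled in the survey, are excluded from
#' species averages), build the neighbor-joining tree with bootstrap
#' supports, run
#' molecular identification with discrepancy and hybrid flagging, and
#' optionally a population distance table.  All tables are written as TSV,
#' the tree as Newick, and a JSON manifest records the configuration.
#'
#' @param records annotated sample records (see [read_barcode_fasta()] and
#'   [join_metadata()]), or a \code{barcode_survey_sim}.
#' @param reference optional reference library data.frame; identification
#'   steps are skipped when NULL.
#' @param out_dir output directory; created if needed.  On error, partial
#'   outputs written by this run are removed.
#' @param trim \code{"auto"} or \code{"explicit"}.
#' @param trim_start,trim_end 1-based window for explicit trimming.
#' @param group_key grouping for haplotype collapsing.
#' @param acronyms optional species acronym map for haplotype naming.
#' @param bootstrap_B bootstrap replicates (default 1000).
#' @param seed integer seed used for the bootstrap resampling.
#' @param min_identity identification screen, percent (default 97).
#' @param population_groups optional named list (population -> haplotype
#'   names) for the population distance table.
#' @return invisibly, a list with every intermediate object (aligned,
#'   haplotypes, dm, summaries, gap, boot, assignments, flags, populations,
#'   files).
#' @export
run_pipeline <- function(records, reference = NULL, out_dir,
                         trim = c("auto", "explicit"), trim_start = NULL,
                         trim_end = NULL,
                         group_key = c("species", "species+location"),
                         acronyms = NULL, bootstrap_B = 1000L, seed = 1L,
                         min_identity = 97, population_groups = NULL) {
  trim <- match.arg(trim)
  group_key <- match.arg(group_key)
  if (inherits(records, "barcode_survey_sim")) records <- records$records
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    p
  }
  on_error <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    aligned <- trim_to_region(records, mode = trim, start = trim_start,
                              end = trim_end)
    tab <- collapse_haplotypes(aligned, group_key = group_key)
    tab <- name_haplotypes(tab, acronyms = acronyms)
    if (!is.null(reference)) tab <- new_vs_reference(tab, reference)
    write_haplotype_table(tab, emit("haplotypes.tsv"))

    dm <- k2p_matrix(tab)
    write_distance_matrix(dm, emit("distance_matrix.tsv"))

    assignments <- NULL
    if (!is.null(reference)) {
      assignments <- identify_all(tab, reference,
                                  min_identity = min_identity)
      utils::write.table(assignments, emit("assignments.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    # Species averages exclude hybrid-suspect groups and any haplotype
    # molecularly assigned to a *different species sampled in this survey*
    # (a mislabeling/introgression signal that would otherwise corrupt
    # within-species statistics).  Both stay in the matrix, tree and
    # identification reports.
    group_map <- stats::setNames(tab$group, tab$haplotype)
    exclude <- tab$haplotype[endsWith(tab$group, "*")]
    if (!is.null(assignments)) {
      i <- match(tab$haplotype, assignments$query)
      cross <- !is.na(assignments$called_species[i]) &
        assignments$called_species[i] != tab$species &
        assignments$called_species[i] %in% tab$species
      exclude <- union(exclude, tab$haplotype[cross])
    }
    summ <- group_summaries(dm, group_map, exclude = exclude)
    utils::write.table(format_summaries(summ), emit("group_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    within <- summ[summ$group_a == summ$group_b, , drop = FALSE]
    between <- summ[summ$group_a != summ$group_b, , drop = FALSE]
    gap <- barcode_gap(within, between)
    jsonlite::write_json(
      list(within_range = gap$within_range, between_range = gap$between_range,
           overlap = gap$overlap,
           fold_ratio = if (is.finite(gap$fold_ratio)) gap$fold_ratio
                        else "Inf"),
      emit("gap_report.json"), auto_unbox = TRUE, digits = NA)

    boot <- bootstrap_support(as_named_seqs(tab), B = bootstrap_B,
                              seed = seed)
    write_newick(boot, emit("tree.nwk"))
    utils::write.table(boot$support, emit("support.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    flags <- NULL
    if (!is.null(reference)) {
      flags <- flag_discrepancies(assignments, tab, aligned$records)
      utils::write.table(flags, emit("discrepancies.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    pops <- NULL
    if (!is.null(population_groups)) {
      pops <- population_table(dm, population_groups)
      write_population_table(pops, emit("population_table.tsv"))
    }

    manifest <- list(
      package = "barcodegap",
      version = as.character(utils::packageVersion("barcodegap")),
      n_records = nrow(records), n_haplotypes = nrow(tab),
      trim = trim, window = aligned$window, length = aligned$length,
      group_key = group_key, bootstrap_B = bootstrap_B, seed = seed,
      min_identity = min_identity,
      dropped_records = aligned$dropped$id,
      dropped_bootstrap_replicates = boot$n_dropped)
    jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                         digits = NA)

    invisible(list(aligned = aligned, haplotypes = tab, dm = dm,
                   summaries = summ, gap = gap, boot = boot,
                   assignments = assignments, flags = flags,
                   populations = pops, files = written))
  }, error = on_error)
}

format_summaries <- function(summ) {
  out <- summ
  for (col in c("mean", "min", "max")) {
    out[[col]] <- sprintf("%.4f", out[[col]])
  }
  out
}
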