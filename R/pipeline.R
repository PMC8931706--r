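# End-to-end orchestration: scan -> ancestral placement -> branch-model
# suite -> relaxation test -> dating, with a machine-readable report bundle.

#' Build and validate a pipeline run configuration
#'
#' @param alignment Path to the codon-aware alignment FASTA.
#' @param tree Path to the rooted newick species tree.
#' @param reference_taxon Taxon defining the reading frame and indel
#'   polarity.
#' @param output_dir Directory for the report bundle.
#' @param cds Optional path to an ungapped CDS FASTA (defaults to ungapping
#'   the alignment rows).
#' @param exon_table Optional exon/splice TSV ([read_exon_table()]); species
#'   absent from it skip splice scanning.
#' @param time_table Optional divergence-time TSV ([read_time_table()]);
#'   required for the dating stage.
#' @param foreground Branch labels for the pseudogenized foreground
#'   (Models C/D); `NULL` derives it from the scanner: terminal branches of
#'   inactivated species plus single-gain origin branches of shared lesions.
#' @param relax_test Branch labels for the selection-intensity test
#'   (defaults to the foreground).
#' @param completeness_threshold Coverage threshold for [classify_gene()].
#' @param pi_method Codon frequency estimator.
#' @param models Which branch models to fit.
#' @param resolve_polytomies Passed to [read_newick()].
#' @param seed Seed recorded in the run log and used for optimizer jitter.
#' @param control Optimizer control list for [fit_model()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(alignment, tree, reference_taxon, output_dir,
                       cds = NULL, exon_table = NULL, time_table = NULL,
                       foreground = NULL, relax_test = NULL,
                       completeness_threshold = 0.9, pi_method = "F3X4",
                       models = c("A", "B", "C", "D", "E"),
                       resolve_polytomies = FALSE, seed = 1,
                       control = list()) {
  paths <- c(alignment = alignment, tree = tree, cds = cds,
             exon_table = exon_table, time_table = time_table)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    stop("input file(s) not found: ",
         paste(names(missing), "=", missing, collapse = ", "), call. = FALSE)
  }
  structure(list(
    alignment = alignment, tree = tree, cds = cds, exon_table = exon_table,
    time_table = time_table, reference_taxon = reference_taxon,
    output_dir = output_dir, foreground = foreground,
    relax_test = relax_test,
    completeness_threshold = completeness_threshold,
    pi_method = pi_method, models = models,
    resolve_polytomies = resolve_polytomies, seed = seed, control = control
  ), class = "run_config")
}

write_tsv_report <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(x) {
        paste(unlist(x), collapse = ";")
      }, character(1))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full gene-decay pipeline
#'
#' Executes every stage on one dataset and writes the report bundle:
#' per-species gene status (TSV), mutation events (TSV), ancestral placement
#' of shared lesions (TSV), the branch-model/LRT table (TSV + JSON), the
#' relaxation-K table (TSV), the dating table (TSV), and a run log echoing
#' the effective configuration and seeds. A stage failure aborts with a
#' stage-named error; outputs written so far stay on disk and the MANIFEST
#' marks the run incomplete.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every stage result (`statuses`, `events`,
#'   `placement`, `suite`, `relax`, `dating`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  log_lines <- character()
  note <- function(level, ...) {
    line <- paste0("[", level, "] ", paste0(..., collapse = ""))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  manifest <- list(complete = FALSE, files = character())
  files <- list()
  add_file <- function(name, path) {
    files[[name]] <<- path
    manifest$files <<- c(manifest$files, path)
    jsonlite::write_json(manifest, out("MANIFEST.json"), auto_unbox = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  note("INFO", "run seed: ", config$seed)
  # ---- stage: read ----------------------------------------------------------
  inputs <- stage("read", {
    aln <- read_codon_alignment(config$alignment, config$reference_taxon)
    tree <- read_newick(config$tree, config$resolve_polytomies)
    check_tree_alignment(tree, aln)
    records <- if (!is.null(config$cds)) {
      read_cds_fasta(config$cds)
    } else {
      read_cds_fasta(config$alignment)
    }
    if (!is.null(config$exon_table)) {
      records <- attach_exon_structure(records, read_exon_table(config$exon_table))
    }
    times <- if (!is.null(config$time_table)) read_time_table(config$time_table)
    list(aln = aln, tree = tree, records = records, times = times)
  })
  note("INFO", "read: ", length(inputs$aln$taxa), " taxa, ",
       ncol(inputs$aln$codon), " codon sites")

  # ---- stage: scan ----------------------------------------------------------
  statuses <- stage("scan", {
    scan_all(inputs$records, inputs$aln,
             threshold = config$completeness_threshold)
  })
  events <- all_events(statuses)
  add_file("statuses", write_tsv_report(
    statuses[, setdiff(names(statuses), "events")], out("gene_status.tsv")))
  add_file("events", write_tsv_report(events, out("mutation_events.tsv")))
  note("INFO", "scan: ", sum(statuses$status == "INACTIVATED"),
       " inactivated, ", sum(statuses$status == "INTACT"), " intact, ",
       sum(statuses$status == "INCOMPLETE"), " incomplete")

  # ---- stage: map -----------------------------------------------------------
  placement <- stage("map", {
    inact <- events[events$inactivating, , drop = FALSE]
    inact <- inact[inact$species_id %in%
                     statuses$species_id[statuses$status != "INCOMPLETE"], ]
    map_events_to_tree(inact, inputs$tree)
  })
  add_file("placement", write_tsv_report(placement, out("ancestral_placement.tsv")))

  # ---- foreground set -------------------------------------------------------
  foreground <- config$foreground
  if (is.null(foreground)) {
    inactivated <- statuses$species_id[statuses$status == "INACTIVATED"]
    origin <- placement$origin_branch[!placement$homoplasic &
                                        placement$n_carriers > 1]
    foreground <- unique(c(inactivated, stats::na.omit(origin)))
    note("INFO", "derived foreground: ", paste(foreground, collapse = ", "))
  }

  # ---- stage: model suite ---------------------------------------------------
  masked <- stage("mask", mask_lesions(inputs$aln, events))
  suite <- stage("model_suite", {
    run_branch_model_suite(masked, inputs$tree, foreground,
                           models = config$models,
                           pi_method = config$pi_method,
                           control = config$control)
  })
  for (f in suite$fits) {
    if (!f$converged) note("WARNING", "model ", f$model_label, " not converged")
  }
  add_file("model_table", write_tsv_report(suite$table, out("model_table.tsv")))
  add_file("model_comparisons",
           write_tsv_report(suite$comparisons, out("model_comparisons.tsv")))
  suite_json <- list(
    table = as.data.frame(suite$table),
    comparisons = as.data.frame(suite$comparisons),
    omega = lapply(suite$fits, function(f) as.list(f$omega))
  )
  jsonlite::write_json(suite_json, out("model_table.json"),
                       auto_unbox = TRUE, digits = NA)
  add_file("model_table_json", out("model_table.json"))

  # ---- stage: relaxation test ----------------------------------------------
  relax_branches <- config$relax_test %||% foreground
  relax <- NULL
  if (length(relax_branches) > 0) {
    relax <- stage("relax", {
      relaxation_k_test(masked, inputs$tree, relax_branches,
                        pi_method = config$pi_method,
                        init = suite$fits$A, control = config$control)
    })
    relax_tab <- dplyr::bind_cols(
      tibble::tibble(K = relax$K, lnL_null = relax$lnL_null,
                     lnL_alt = relax$lnL_alt),
      relax$lrt[, c("stat", "df", "p_value")]
    )
    add_file("relax", write_tsv_report(relax_tab, out("relaxation_k.tsv")))
    note("INFO", "relaxation test: K = ", formatC(relax$K, digits = 4),
         ", p = ", relax$lrt$p_formatted)
  }

  # ---- stage: dating --------------------------------------------------------
  dating <- NULL
  if (!is.null(inputs$times) && "E" %in% names(suite$fits)) {
    dating <- stage("dating", {
      withCallingHandlers(
        assemble_dating(suite$fits$E, suite$fits$A, inputs$times, foreground),
        warning = function(w) {
          note("WARNING", conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
    })
    add_file("dating", write_tsv_report(dating, out("dating.tsv")))
  }

  # ---- run log and manifest -------------------------------------------------
  cfg_echo <- unclass(config)
  cfg_echo$control <- NULL
  log_lines <- c(log_lines,
                 paste0("[INFO] R version: ", R.version.string),
                 paste0("[INFO] config: ",
                        jsonlite::toJSON(cfg_echo, auto_unbox = TRUE, null = "null")))
  writeLines(log_lines, out("run_log.txt"))
  add_file("log", out("run_log.txt"))
  manifest$complete <- TRUE
  jsonlite::write_json(manifest, out("MANIFEST.json"), auto_unbox = TRUE)

  invisible(list(statuses = statuses, events = events, placement = placement,
                 foreground = foreground, suite = suite, relax = relax,
                 dating = dating, files = files,
                 manifest = out("MANIFEST.json")))
}
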