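#' Analyze one annotated replicon end to end
#'
#' Runs the full per-replicon pipeline: read inputs, build position labels,
#' compute the five cumulative skew curves and the GSB curve on one window
#' grid, the Skew Index, the two-replichore div fit and the GSB-vs-CGC
#' correlation set, and assemble them into a single genome record. Replicon or
#' feature objects may be passed directly instead of file paths.
#'
#' @param fasta FASTA path or a `replicon`.
#' @param annotation GFF3 path or a `feature_table` (`NULL` for an
#'   unannotated replicon: total skew, SkewI and div only).
#' @param class_label replicon class for aggregation.
#' @param window_size CGC/GSB window in bases.
#' @param skewi_window SkewI window in bases.
#' @param feature_type annotation feature type to use.
#' @param out_prefix if non-`NULL`, write `<prefix>.profiles.tsv` (all skew
#'   classes) alongside the record.
#' @return object of class `genome_record`: replicon metadata, `skewi` result,
#'   `div` fit, `correlations`, window sizes, plus the computed `profiles`
#'   (list of cumulative curves) and `gsb`.
#' @export
analyze_replicon <- function(fasta, annotation = NULL, class_label = "other",
                             window_size = 4096L, skewi_window = 20000L,
                             feature_type = "CDS", out_prefix = NULL) {
  rep_ <- if (inherits(fasta, "replicon")) fasta else {
    reps <- read_replicons(fasta)
    if (length(reps) > 1L)
      message("multi-record FASTA: analyzing first record ", reps[[1L]]$id)
    reps[[1L]]
  }
  features <- if (is.null(annotation)) NULL
  else if (inherits(annotation, "feature_table")) annotation
  else read_features(annotation, "gff3", feature_type = feature_type,
                     seq_lengths = setNames(rep_$length, rep_$id))
  if (!is.null(features)) {
    features <- features[features$replicon_id == rep_$id, , drop = FALSE]
    class(features) <- c("feature_table", "data.frame")
    if (nrow(features) == 0L) {
      message("no features for replicon ", rep_$id,
              "; sub-skews and GSB omitted")
      features <- NULL
    }
  }

  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))

  labels <- if (!is.null(features))
    stage("genome_io", build_position_labels(rep_, features)) else NULL
  classes <- if (is.null(labels)) "total" else SKEW_CLASSES
  profiles <- stage("skew_core", lapply(setNames(classes, classes),
    function(cl) windowed_skew(rep_, labels, cl, window_size)))
  cumprofiles <- lapply(profiles, cumulative_profile)
  gsb <- if (!is.null(labels))
    stage("skew_core", gsb_profile(labels, window_size)) else NULL
  ski <- stage("skew_index", skew_index(rep_, skewi_window))
  dfit <- stage("div_fit", fit_div(cumprofiles$total,
                                   topology = rep_$topology,
                                   force_linear = rep_$topology == "linear"))
  cset <- if (!is.null(features))
    stage("stats_correlate",
          replicon_correlation_set(rep_, features, window_size, class_label))
  else NULL

  if (!is.null(out_prefix))
    write_profiles_tsv(profiles, paste0(out_prefix, ".profiles.tsv"))

  structure(list(replicon_id = rep_$id, length = rep_$length,
                 class_label = class_label, skewi = ski, div = dfit,
                 correlations = cset, window_size = window_size,
                 skewi_window = skewi_window,
                 profiles = cumprofiles, gsb = gsb),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s bp, %s)\n", x$replicon_id,
              format(x$length, big.mark = ","), x$class_label))
  cat(sprintf("  SkewI = %.3f (qc: %s)   div = %.3f (rms %.3g)\n",
              x$skewi$skewi, x$skewi$qc_reason, x$div$div,
              x$div$rms_residual))
  if (!is.null(x$correlations))
    cat(sprintf(
      "  PCC(GSB, CGC): total %.2f  codon1 %.2f  codon2 %.2f  codon3 %.2f  noncoding %.2f\n",
      x$correlations$pcc_total, x$correlations$pcc_codon1,
      x$correlations$pcc_codon2, x$correlations$pcc_codon3,
      x$correlations$pcc_noncoding))
  invisible(x)
}

#' Flatten genome records to a data.frame
#' @param records list of `genome_record`.
#' @return data.frame, one row per record.
#' @export
records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    cs <- r$correlations
    data.frame(replicon_id = r$replicon_id, length = r$length,
               class_label = r$class_label, skewi = r$skewi$skewi,
               skewi_qc = r$skewi$qc_pass, div = r$div$div,
               rms_residual = r$div$rms_residual,
               pcc_total = if (is.null(cs)) NA_real_ else cs$pcc_total,
               pcc_codon1 = if (is.null(cs)) NA_real_ else cs$pcc_codon1,
               pcc_codon2 = if (is.null(cs)) NA_real_ else cs$pcc_codon2,
               pcc_codon3 = if (is.null(cs)) NA_real_ else cs$pcc_codon3,
               pcc_noncoding = if (is.null(cs)) NA_real_ else cs$pcc_noncoding,
               stringsAsFactors = FALSE)
  }))
}

#' Batch analysis over a manifest
#'
#' Runs [analyze_replicon()] for every row of a manifest (columns `fasta`,
#' `annotation`, `class_label`). Failures are isolated per genome: a failing
#' row is logged and skipped, never silently dropped, and the run aborts only
#' if every row fails.
#'
#' @param manifest data.frame or path to a TSV with columns
#'   `fasta, annotation, class_label`.
#' @param window_size,skewi_window,feature_type passed through.
#' @return list with `records` (per-genome [records_to_df()] rows plus the
#'   record objects), `summaries` (per class x statistic `class_summary`
#'   list), `errors` (data.frame of failed rows).
#' @export
batch_run <- function(manifest, window_size = 4096L, skewi_window = 20000L,
                      feature_type = "CDS") {
  if (is.character(manifest)) manifest <- read.delim(manifest,
                                                     stringsAsFactors = FALSE)
  stopifnot(nrow(manifest) >= 1L,
            all(c("fasta", "annotation", "class_label") %in% names(manifest)))
  records <- list(); errs <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch(
      analyze_replicon(manifest$fasta[i], manifest$annotation[i],
                       class_label = manifest$class_label[i],
                       window_size = window_size,
                       skewi_window = skewi_window,
                       feature_type = feature_type),
      error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        row = i, fasta = manifest$fasta[i],
        error = conditionMessage(res), stringsAsFactors = FALSE)
    } else records[[length(records) + 1L]] <- res
  }
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(), fasta = character(), error = character())
  if (length(records) == 0L)
    stop("all ", nrow(manifest), " manifest rows failed; first error: ",
         errors$error[1L])
  if (nrow(errors) > 0L)
    message(nrow(errors), "/", nrow(manifest), " rows failed and were skipped")
  summaries <- summarize_records(records)
  list(records = records, table = records_to_df(records),
       summaries = summaries, errors = errors)
}

#' Aggregate genome records into Table-1/Table-2-shaped class summaries
#'
#' @param records list of `genome_record`.
#' @return list of `class_summary`, one per class x PCC statistic present.
#' @export
summarize_records <- function(records) {
  csets <- Filter(Negate(is.null), lapply(records, `[[`, "correlations"))
  if (length(csets) == 0L) return(list())
  classes <- unique(vapply(csets, `[[`, "", "class_label"))
  out <- list()
  for (cl in classes) {
    sub <- Filter(function(s) s$class_label == cl, csets)
    for (stat in paste0("pcc_", SKEW_CLASSES)) {
      s <- tryCatch(aggregate_class(sub, stat), error = function(e) NULL)
      if (!is.null(s)) out[[paste(cl, stat, sep = ".")]] <- s
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `analyze` (single genome), `batch` (manifest TSV), `simulate`
#' (config JSON -> FASTA/GFF3/truth), `summarize` (batch records TSV ->
#' class-summary TSV). Invoked by the `repliskew` script in `inst/exec`, or
#' directly: `Rscript -e 'repliskew::skew_cli()' analyze genome.fa genes.gff3 out`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
skew_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: repliskew <command> ...",
    "  analyze  <fasta> <gff3|-> <out_prefix> [class_label]",
    "  batch    <manifest.tsv> <out_prefix>",
    "  simulate <config.json|-> <out_prefix>",
    "  summarize <records.tsv> <out.tsv>", sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]; rest <- args[-1L]
  if (cmd == "analyze") {
    if (length(rest) < 3L) stop(usage)
    ann <- if (rest[2L] == "-") NULL else rest[2L]
    rec <- analyze_replicon(rest[1L], ann,
                            class_label = if (length(rest) >= 4L) rest[4L]
                            else "other", out_prefix = rest[3L])
    write.table(records_to_df(list(rec)), paste0(rest[3L], ".record.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    print(rec)
  } else if (cmd == "batch") {
    if (length(rest) < 2L) stop(usage)
    res <- batch_run(rest[1L])
    write.table(res$table, paste0(rest[2L], ".records.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(res$summaries))
      write_class_summary_tsv(res$summaries, paste0(rest[2L], ".summary.tsv"))
    if (nrow(res$errors))
      write.table(res$errors, paste0(rest[2L], ".errors.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  } else if (cmd == "simulate") {
    if (length(rest) < 2L) stop(usage)
    cfg_args <- if (rest[1L] == "-") list() else
      jsonlite::read_json(rest[1L], simplifyVector = TRUE)
    if (!is.null(cfg_args$codon_weights))
      cfg_args$codon_weights <- lapply(as.data.frame(cfg_args$codon_weights),
                                       identity)
    cfg <- do.call(synthetic_config, cfg_args)
    simulate_to_files(cfg, rest[2L])
  } else if (cmd == "summarize") {
    if (length(rest) < 2L) stop(usage)
    tab <- read.delim(rest[1L], stringsAsFactors = FALSE)
    sets <- lapply(seq_len(nrow(tab)), function(i)
      structure(as.list(tab[i, c("replicon_id", "class_label",
                                 paste0("pcc_", SKEW_CLASSES))]),
                class = "correlation_set"))
    out <- list()
    for (cl in unique(tab$class_label)) {
      sub <- Filter(function(s) s$class_label == cl, sets)
      for (stat in paste0("pcc_", SKEW_CLASSES)) {
        s <- tryCatch(aggregate_class(sub, stat), error = function(e) NULL)
        if (!is.null(s)) out[[length(out) + 1L]] <- s
      }
    }
    write_class_summary_tsv(out, rest[2L])
  } else stop("unknown command '", cmd, "'\n", usage)
  invisible(0L)
}
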