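#' Assemble a pipeline run configuration
#'
#' Collects input paths and every stage threshold into a single list that
#' round-trips losslessly through YAML ([read_run_config()]), so a manifest
#' echo makes every reported number traceable to its thresholds.
#'
#' @param srna Named list (two entries, one per library) of input paths:
#'   either FASTQ raw reads or collapsed tag TSVs ([write_tag_tsv()] format),
#'   distinguished by extension (`.fastq`/`.fq` vs `.tsv`).
#' @param transcripts Path to the transcript (unigene) FASTA.
#' @param references Named list of reference FASTA paths (any of `rRNA`,
#'   `tRNA`, `snRNA`, `snoRNA`, `other_ncRNA`, `mature_miRNA`).
#' @param degradome Optional path to a degradome tag TSV (`sequence`,
#'   `count`).
#' @param max_mismatch_conserved Conserved-matching mismatch allowance.
#' @param floor,fc_threshold,p_threshold Differential-expression settings.
#' @param hairpin [hairpin_thresholds()] list.
#' @param flank Precursor window flank, nt.
#' @param weights [site_weights()] list.
#' @param min_reads Minimum degradome reads at a slice position.
#' @param engine Folding engine.
#' @param seed Seed recorded in the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(srna, transcripts, references = list(),
                       degradome = NULL, max_mismatch_conserved = 2L,
                       floor = 0.01, fc_threshold = 1.0, p_threshold = 0.05,
                       hairpin = hairpin_thresholds(), flank = 150L,
                       weights = site_weights(), min_reads = 1L,
                       engine = "auto", seed = 1L) {
  stopifnot(length(srna) == 2, !is.null(names(srna)))
  structure(list(srna = srna, transcripts = transcripts,
                 references = references, degradome = degradome,
                 max_mismatch_conserved = max_mismatch_conserved,
                 floor = floor, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, hairpin = hairpin,
                 flank = flank, weights = weights, min_reads = min_reads,
                 engine = engine, seed = seed),
            class = "run_config")
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_run_config()]: a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.load_library <- function(path, name) {
  if (grepl("\\.(fastq|fq)$", path)) {
    raw <- read_fastq(path)
    filt <- filter_raw_reads(raw)
    lib <- collapse_tags(filt$reads, name)
    list(lib = lib, tally = filt$tally)
  } else {
    list(lib = read_tag_tsv(path, name), tally = NULL)
  }
}

#' Run the full small-RNA/degradome pipeline
#'
#' Executes the stages in order — preprocessing (when FASTQ input is given),
#' annotation, hairpin discovery, differential expression, degradome target
#' calling — writes every report into `outdir` and returns a manifest with a
#' content checksum per file. Rerunning with identical config and inputs
#' yields identical checksums.
#'
#' @param config A `run_config` list or path to its YAML form.
#' @param outdir Output directory (created if needed).
#' @return The manifest (list with `config`, `files` = named md5 vector,
#'   `summary`), invisibly written to `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, file) {
    path <- file.path(outdir, file)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  for (p in unlist(config$srna))
    if (!file.exists(p)) stop("missing input file: ", p)
  for (nm in names(config$references))
    if (!file.exists(config$references[[nm]]))
      stop("missing reference set file: ", config$references[[nm]])
  if (!file.exists(config$transcripts))
    stop("missing transcript file: ", config$transcripts)

  stage <- "preprocess"
  res <- tryCatch({
    libnames <- names(config$srna)
    loaded <- lapply(libnames, function(nm)
      .load_library(config$srna[[nm]], nm))
    names(loaded) <- libnames
    libs <- lapply(loaded, `[[`, "lib")
    for (nm in libnames) {
      if (!is.null(loaded[[nm]]$tally))
        emit(data.frame(reason = names(loaded[[nm]]$tally),
                        reads = unname(loaded[[nm]]$tally)),
             sprintf("cleaning_%s.tsv", nm))
      path <- file.path(outdir, sprintf("tags_%s.tsv", nm))
      write_tag_tsv(libs[[nm]], path)
      written <- c(written, path)
      emit(length_distribution(libs[[nm]]),
           sprintf("length_distribution_%s.tsv", nm))
    }

    stage <- "annotation"
    transcripts <- read_fasta(config$transcripts)
    refs <- lapply(config$references, read_fasta)
    mature_ref <- refs[["mature_miRNA"]]
    ncrna_sets <- refs[setdiff(names(refs), "mature_miRNA")]
    union_tags <- sort(unique(c(names(libs[[1]]$tags), names(libs[[2]]$tags))))
    lookup <- function(l) {
      cnt <- l$tags[union_tags]
      as.integer(ifelse(is.na(cnt), 0L, cnt))
    }
    cnt1 <- lookup(libs[[1]]); cnt2 <- lookup(libs[[2]])
    union_lib <- tag_library("union", setNames(cnt1 + cnt2, union_tags),
                             clean_total = libs[[1]]$clean_total)
    ann <- annotate_tags(union_lib, transcripts, ncrna_sets,
                         if (is.null(mature_ref)) character(0) else mature_ref,
                         config$max_mismatch_conserved)
    ann$count <- NULL
    ann[[paste0("count_", libnames[1])]] <- cnt1
    ann[[paste0("count_", libnames[2])]] <- cnt2
    emit(ann, "annotation.tsv")

    stage <- "hairpin_discovery"
    unann <- ann$tag[ann$class == "unannotated"]
    hits <- map_tags_to_transcripts(unann, transcripts)
    cands <- discover_hairpins(hits, transcripts, libs,
                               flank = config$flank,
                               thresholds = config$hairpin,
                               engine = config$engine)
    emit(cands[setdiff(names(cands), "pass")], "candidates.tsv")
    prec <- attr(cands, "candidates")
    if (length(prec)) {
      fa <- setNames(vapply(prec, function(cc) cc$precursor$sequence,
                            character(1)),
                     sprintf("%s|%s:%d-%d", cands$id, cands$transcript,
                             cands$precursor_start, cands$precursor_end))
      path <- file.path(outdir, "precursors.fa")
      write_fasta(fa, path)
      written <- c(written, path)
    }

    stage <- "differential_expression"
    de_rows <- list()
    cons <- ann[ann$class == "conserved_miRNA", , drop = FALSE]
    if (nrow(cons)) {
      agg1 <- rowsum(cons[[paste0("count_", libnames[1])]], cons$best_match)
      agg2 <- rowsum(cons[[paste0("count_", libnames[2])]], cons$best_match)
      de_rows$conserved <- data.frame(mirna = rownames(agg1),
                                      set = "conserved",
                                      c1 = as.integer(agg1),
                                      c2 = as.integer(agg2),
                                      stringsAsFactors = FALSE)
    }
    if (nrow(cands)) {
      de_rows$novel <- data.frame(mirna = cands$id, set = "novel",
                                  c1 = cands[[paste0("count_", libnames[1])]],
                                  c2 = cands[[paste0("count_", libnames[2])]],
                                  stringsAsFactors = FALSE)
    }
    de <- NULL
    if (length(de_rows)) {
      de <- do.call(rbind, de_rows)
      rownames(de) <- NULL
      de <- diff_expression(de, vapply(libs, `[[`, numeric(1), "clean_total"),
                            count_cols = c("c1", "c2"),
                            floor = config$floor,
                            fc_threshold = config$fc_threshold,
                            p_threshold = config$p_threshold)
      emit(de, "differential_expression.tsv")
    }

    stage <- "degradome"
    events <- NULL
    if (!is.null(config$degradome)) {
      dg <- read.delim(config$degradome, stringsAsFactors = FALSE)
      dtags <- setNames(as.integer(dg$count), dg$sequence)
      profiles <- map_degradome_tags(dtags, transcripts)
      mirnas <- character(0)
      if (!is.null(mature_ref)) mirnas <- c(mirnas, mature_ref)
      if (nrow(cands)) mirnas <- c(mirnas, setNames(cands$mature, cands$id))
      events <- call_targets(mirnas, transcripts, profiles,
                             weights = config$weights,
                             min_reads = config$min_reads)
      emit(events, "cleavage_events.tsv")
      tp <- do.call(rbind, lapply(names(profiles), function(tx)
        cbind(transcript = tx,
              tplot_series(profiles[[tx]],
                           events$slice_pos[events$transcript == tx]))))
      emit(tp, "tplots.tsv")
    }

    list(libs = libs, annotation = ann, candidates = cands, de = de,
         events = events)
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))

  summary <- list(
    n_tags = lapply(res$libs, function(l) length(l$tags)),
    class_counts = as.list(table(res$annotation$class)),
    n_candidates = nrow(res$candidates),
    de = if (!is.null(res$de)) as.list(table(res$de$status)) else NULL,
    degradome_events = if (!is.null(res$events)) nrow(res$events) else NULL,
    categories = if (!is.null(res$events))
      as.list(table(res$events$category)) else NULL)
  files <- sort(unique(written))
  manifest <- list(config = unclass(config),
                   files = as.list(setNames(unname(tools::md5sum(files)),
                                            basename(files))),
                   summary = summary)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

# parse a printed numeric string, keeping its decimal precision
.printed_decimals <- function(s) {
  frac <- sub("^-?[0-9]*\\.?", "", s)
  nchar(frac)
}

#' Reproduce the statistics of a printed two-library miRNA count table
#'
#' Recomputes the RPM log2 fold-change (with the zero floor) and the exact
#' two-library p-value for every row of a printed count table, compares each
#' fold-change with the printed value at its printed precision, aggregates
#' conserved families, tallies up/down regulation, and flags rows whose
#' printed p-value contradicts the stated significance rule (claimed
#' regulated but printed p above the threshold).
#'
#' @param counts Count table in the layout of [pa_mirna_counts()] (the
#'   default).
#' @param totals Clean-read totals (default [pa_clean_totals()]).
#' @param floor,fc_threshold,p_threshold Reproduction settings.
#' @return An object of class `table_reproduction`: list with `rows` (per-row
#'   recomputation and match columns), `families` (conserved family totals
#'   and shares), `summary_recomputed` and `summary_printed` (up/down
#'   tallies), and `flagged` (the discrepancy rows).
#' @export
table_reproduction <- function(counts = pa_mirna_counts(),
                               totals = pa_clean_totals(), floor = 0.01,
                               fc_threshold = 1.0, p_threshold = 0.05) {
  need <- c("set", "mirna", "pa2", "pa4", "fc_printed", "pvalue_printed")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("malformed count table: missing column(s) ",
         paste(miss, collapse = ", "))
  bad <- which(is.na(counts$pa2) | is.na(counts$pa4) |
               counts$pa2 < 0 | counts$pa4 < 0)
  if (length(bad))
    stop("malformed count table at row ", bad[1], ": invalid counts")
  rows <- diff_expression(counts, totals, count_cols = c("pa2", "pa4"),
                          floor = floor, fc_threshold = fc_threshold,
                          p_threshold = p_threshold)
  dec <- vapply(rows$fc_printed, .printed_decimals, numeric(1))
  rows$fc_recomputed_rounded <- round(rows$log2fc, dec)
  rows$fc_match <- rows$fc_recomputed_rounded == as.numeric(rows$fc_printed)
  # agreement to the printed precision: within one unit in the last printed
  # place (covers a publisher's rounding-vs-truncation ambiguity)
  rows$fc_within_ulp <- abs(rows$log2fc - as.numeric(rows$fc_printed)) <=
    10^-dec + 1e-9
  rows$pvalue_printed_num <- as.numeric(rows$pvalue_printed)
  rows$status_printed <- classify_de(as.numeric(rows$fc_printed),
                                     rows$pvalue_printed_num,
                                     fc_threshold, p_threshold)
  cons <- rows[rows$set == "conserved", , drop = FALSE]
  fam <- assign_families(cons[, c("mirna", "pa2", "pa4")],
                         count_cols = c("pa2", "pa4"),
                         family = if ("family" %in% names(cons))
                           cons$family else NULL)
  # claimed regulated set: |printed fold-change| >= threshold
  claimed <- abs(as.numeric(rows$fc_printed)) >= fc_threshold
  flagged <- rows[claimed & rows$pvalue_printed_num > p_threshold,
                  c("set", "mirna", "pa2", "pa4", "fc_printed",
                    "pvalue_printed", "pvalue"), drop = FALSE]
  structure(list(
    rows = rows,
    families = fam$families,
    summary_recomputed = de_summary(rows),
    summary_printed = de_summary(
      within(rows, status <- status_printed)),
    flagged = flagged,
    settings = list(totals = totals, floor = floor,
                    fc_threshold = fc_threshold,
                    p_threshold = p_threshold)
  ), class = "table_reproduction")
}

#' @export
print.table_reproduction <- function(x, ...) {
  cat(sprintf("table_reproduction: %d rows (%d conserved, %d novel)\n",
              nrow(x$rows), sum(x$rows$set == "conserved"),
              sum(x$rows$set == "novel")))
  cat(sprintf("  fold-changes matching printed values: %d/%d\n",
              sum(x$rows$fc_match), nrow(x$rows)))
  sr <- x$summary_recomputed
  cat(sprintf("  recomputed statistics: %d up / %d down\n",
              sr["up", "all"], sr["down", "all"]))
  sp <- x$summary_printed
  cat(sprintf("  printed statistics:    %d up / %d down\n",
              sp["up", "all"], sp["down", "all"]))
  if (nrow(x$flagged)) {
    cat("  flagged: printed p-value fails the significance rule for:\n")
    for (i in seq_len(nrow(x$flagged)))
      cat(sprintf("    %s (fold-change %s, printed p %s, recomputed p %.3g)\n",
                  x$flagged$mirna[i], x$flagged$fc_printed[i],
                  x$flagged$pvalue_printed[i], x$flagged$pvalue[i]))
  }
  invisible(x)
}
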