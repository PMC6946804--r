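# Pipeline configuration and end-to-end runner.

pipeline_defaults <- function() {
  list(top_n = 50, min_identity = 80, ani_threshold = 0.99, tol_ppm = 1,
       min_sample_fraction = 0.01, max_redundancy = 1.1,
       max_contamination = 5.0, k = 21, taxon = "SAR202", family = "FMNO",
       seed = 1,
       stages = list(qc_derep = TRUE, profiles = TRUE, recruitment = TRUE,
                     enzyme_depth = TRUE, msdiff = TRUE))
}

pipeline_path_keys <- function() {
  c("genomes", "annotations", "samples", "alignments", "gene_taxon",
    "mask_bed", "panel", "peaks_dir", "bins_dir", "ani_pairs")
}

param_ranges <- function() {
  list(top_n = c(1, Inf), min_identity = c(0, 100), ani_threshold = c(0, 1),
       tol_ppm = c(1e-9, Inf), min_sample_fraction = c(0, 1),
       max_redundancy = c(0, 100), max_contamination = c(0, 100),
       k = c(3, 26), seed = c(0, .Machine$integer.max))
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list. Applies documented defaults
#' (`top_n = 50`, `min_identity = 80`, `ani_threshold = 0.99`,
#' `tol_ppm = 1`, `min_sample_fraction = 0.01`, QC `< 1.1` / `< 5`), rejects
#' unknown keys, range-checks every parameter, and verifies that referenced
#' input paths exist. All problems are reported at once.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a YAML file path or a list")
  defaults <- pipeline_defaults()
  known <- c(names(defaults), "inputs")
  problems <- character()
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  if (!is.null(config$stages)) {
    bad <- setdiff(names(config$stages), names(defaults$stages))
    if (length(bad))
      problems <- c(problems, paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
    defaults$stages[names(config$stages)] <- config$stages
    config$stages <- NULL
  }
  inputs <- config$inputs %||% list()
  bad_in <- setdiff(names(inputs), pipeline_path_keys())
  if (length(bad_in))
    problems <- c(problems, paste0("unknown input key(s): ", paste(bad_in, collapse = ", ")))
  for (key in setdiff(names(inputs), bad_in)) {
    if (!file.exists(inputs[[key]]))
      problems <- c(problems, paste0("input '", key, "' does not exist: ", inputs[[key]]))
  }
  config$inputs <- NULL
  merged <- defaults
  merged[names(config)] <- config
  ranges <- param_ranges()
  for (p in names(ranges)) {
    v <- merged[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        v < ranges[[p]][1] || v > ranges[[p]][2])
      problems <- c(problems, sprintf("parameter '%s' = %s outside [%g, %g]",
                                      p, format(v), ranges[[p]][1], ranges[[p]][2]))
  }
  if (length(problems))
    stop_config("invalid configuration:\n  - ",
                paste(problems, collapse = "\n  - "))
  merged$inputs <- inputs
  class(merged) <- "pipeline_config"
  merged
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

write_matrix_tsv <- function(m, path, label = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- label
  write_tsv(df, path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — quality filtering and
#' dereplication, pangenome profiling, fragment recruitment, enzyme-depth
#' correlation, and mass-difference counting (independent) — writing every
#' stage's tables under `out_dir` and returning a machine-readable run
#' report. When an input is not supplied in the config, the corresponding
#' data must be passed directly via `data`; this is how the bundled
#' synthetic fixtures are run.
#'
#' @param config A validated `pipeline_config` (see [validate_config()]).
#' @param out_dir Output directory, created if needed.
#' @param data Optional named list of in-memory inputs overriding files:
#'   `genomes`, `annotations`, `samples`, `alignments`, `gene_taxon`,
#'   `panel`, `peaklists` (named list of m/z vectors), `ani_pairs`, `mask`.
#' @return A `run_report` list: per-stage status and row counts, parameter
#'   echo, warnings, package version, seed. Also written as `report.json`.
#' @export
run_pipeline <- function(config, out_dir, data = list()) {
  if (!inherits(config, "pipeline_config"))
    stop_config("'config' must come from validate_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- function(key, reader) {
    if (!is.null(data[[key]])) return(data[[key]])
    path <- config$inputs[[key]]
    if (is.null(path)) return(NULL)
    reader(path)
  }
  read_csv <- function(p) read.table(p, sep = ",", header = TRUE,
                                     stringsAsFactors = FALSE)
  read_tsv <- function(p) read.table(p, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE)

  genomes <- inp("genomes", read_csv)
  if (is.null(genomes)) stop_input("pipeline needs a genome table")
  annotations <- inp("annotations", read_tsv)
  samples <- inp("samples", read_csv)
  alignments <- inp("alignments", read_tsv)
  gene_taxon <- inp("gene_taxon", read_tsv)
  panel <- if (!is.null(data$panel)) data$panel else
    if (!is.null(config$inputs$panel)) readLines(config$inputs$panel) else NULL
  mask <- if (!is.null(data$mask)) data$mask else
    if (!is.null(config$inputs$mask_bed)) read_mask_bed(config$inputs$mask_bed) else NULL
  peaklists <- if (!is.null(data$peaklists)) data$peaklists else
    if (!is.null(config$inputs$peaks_dir)) {
      files <- list.files(config$inputs$peaks_dir, pattern = "^peaks_.*\\.csv$",
                          full.names = TRUE)
      stats::setNames(lapply(files, read_peaklist),
                      sub("^peaks_(.*)\\.csv$", "\\1", basename(files)))
    } else NULL
  pairs <- inp("ani_pairs", read_tsv)

  report <- list(package = "bathypan",
                 version = as.character(utils::packageVersion("bathypan")),
                 seed = config$seed, parameters = config[names(param_ranges())],
                 stages = list())
  warn <- character()
  run_stage <- function(name, fn) {
    res <- tryCatch(
      withCallingHandlers(fn(), warning = function(w) {
        warn <<- c(warn, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res)
    }
    !inherits(res, "error")
  }

  ok <- TRUE
  retained <- genomes
  if (isTRUE(config$stages$qc_derep)) {
    ok <- run_stage("qc_derep", function() {
      keep <- quality_filter(genomes, config$max_redundancy,
                             config$max_contamination)
      retained <<- genomes[genomes$genome_id %in% keep, ]
      rows <- list(genomes_in = nrow(genomes), genomes_retained = length(keep))
      if (!is.null(pairs)) {
        dec <- dereplicate(retained, pairs[pairs$bin_a %in% keep &
                                             pairs$bin_b %in% keep, ],
                           threshold = config$ani_threshold)
        rows$decisions <- write_tsv(dec, file.path(out_dir, "decisions.tsv"))
        retained <<- retained[retained$genome_id %in%
                                dec$bin[dec$action != "discard"], ]
      }
      write_tsv(retained, file.path(out_dir, "genomes_retained.tsv"))
      rows
    }) && ok
  }
  if (isTRUE(config$stages$profiles) && !is.null(annotations)) {
    ok <- run_stage("profiles", function() {
      ann <- annotations[annotations$genome_id %in% retained$genome_id, ]
      mat <- family_abundance(ann, retained)
      top <- select_top_families(mat, config$top_n)
      sub <- mat[top, , drop = FALSE]
      list(abundance = write_matrix_tsv(sub, file.path(out_dir, "abundance.tsv"), "family"),
           zscores = write_matrix_tsv(zscore_transform(sub),
                                      file.path(out_dir, "zscores.tsv"), "family"),
           correlations = write_matrix_tsv(family_correlation(sub),
                                           file.path(out_dir, "correlations.tsv"), "family"),
           expansions = write_tsv(expansion_scores(mat, retained,
                                                   annotations = ann),
                                  file.path(out_dir, "expansions.tsv")))
    }) && ok
  }
  if (isTRUE(config$stages$recruitment) && !is.null(alignments) &&
      !is.null(samples)) {
    ok <- run_stage("recruitment", function() {
      rec <- filter_alignments(alignments, config$min_identity, mask = mask)
      rm_ <- compute_recruitment(rec, retained, samples)
      list(alignments_in = nrow(alignments), alignments_kept = nrow(rec),
           recruitment = write_matrix_tsv(rm_$fraction,
                                          file.path(out_dir, "recruitment.tsv"), "genome"),
           per_mbp = write_matrix_tsv(rm_$per_mbp,
                                      file.path(out_dir, "recruitment_per_mbp.tsv"), "genome"))
    }) && ok
  }
  if (isTRUE(config$stages$enzyme_depth) && !is.null(gene_taxon) &&
      !is.null(samples) && !is.null(panel)) {
    ok <- run_stage("enzyme_depth", function() {
      na <- normalized_family_abundance(gene_taxon, config$taxon,
                                        config$family, panel, samples)
      dc <- depth_correlation(na)
      dc$family <- config$family
      list(normalized = write_tsv(na, file.path(out_dir, "normalized_abundance.tsv")),
           correlations = write_tsv(dc, file.path(out_dir, "depth_correlations.tsv")))
    }) && ok
  }
  if (isTRUE(config$stages$msdiff) && !is.null(peaklists) &&
      !is.null(samples)) {
    ok <- run_stage("msdiff", function() {
      counts <- do.call(rbind, lapply(names(peaklists), function(s)
        transformation_profile(peaklists[[s]], tol_ppm = config$tol_ppm,
                               sample_id = s)))
      prof <- msdiff_depth_profile(counts, samples)
      list(counts = write_tsv(counts, file.path(out_dir, "transformation_counts.tsv")),
           profile = write_tsv(prof, file.path(out_dir, "depth_profile.tsv")))
    }) && ok
  } else if (isTRUE(config$stages$msdiff)) {
    report$stages$msdiff <- list(status = "skipped")
  }
  for (st in names(config$stages))
    if (!isTRUE(config$stages[[st]]) && is.null(report$stages[[st]]))
      report$stages[[st]] <- list(status = "skipped")

  report$warnings <- warn
  report$success <- ok
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("bathypan run (version ", x$version, ", seed ", x$seed, ")\n", sep = "")
  for (s in names(x$stages))
    cat(sprintf("  %-14s %s\n", s, x$stages[[s]]$status))
  if (length(x$warnings)) cat(length(x$warnings), "warning(s)\n")
  invisible(x)
}
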