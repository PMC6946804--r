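# Fragment recruitment: BLAST-tabular parsing, identity/mask filtering,
# base-normalized recruitment matrices.

#' Parse tabular read alignments
#'
#' Reads a BLAST outfmt-6-style tab-separated alignment table (the dialect
#' emitted by BLAST, FR-HIT and kin). The default dialect takes query id,
#' subject id, percent identity, alignment length and subject start/end from
#' their outfmt-6 positions (1, 2, 3, 4, 9, 10) and bit score from 12 when
#' present. Subject coordinates are 1-based inclusive on input (start may
#' exceed end on the minus strand) and are normalized to 0-based half-open
#' internally.
#'
#' @param file Path to the alignment table, or a connection.
#' @param dialect Named integer vector mapping fields `read_id`, `genome_id`,
#'   `pct_identity`, `aligned_bases`, `ref_start`, `ref_end` (and optionally
#'   `bit_score`, `sample_id`) to column positions.
#' @param sample_id Sample identifier to stamp on every record when the table
#'   covers one sample and carries no sample column.
#' @return `data.frame` of alignment records with 0-based half-open
#'   `ref_start`/`ref_end`.
#' @export
parse_alignments <- function(file,
                             dialect = c(read_id = 1, genome_id = 2,
                                         pct_identity = 3, aligned_bases = 4,
                                         ref_start = 9, ref_end = 10,
                                         bit_score = 12),
                             sample_id = NULL) {
  need <- c("read_id", "genome_id", "pct_identity", "aligned_bases",
            "ref_start", "ref_end")
  if (!all(need %in% names(dialect)))
    stop_input("dialect must map fields: ", paste(need, collapse = ", "))
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- data.frame(read_id = character(), genome_id = character(),
                      pct_identity = numeric(), aligned_bases = integer(),
                      ref_start = integer(), ref_end = integer(),
                      bit_score = numeric(), sample_id = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  req_max <- max(dialect[need])
  bad <- which(ncols < req_max)
  if (length(bad))
    stop_input("line ", bad[1], ": expected >= ", req_max, " tab-separated columns, got ",
               ncols[bad[1]])
  grab <- function(i) vapply(parts, `[[`, "", i)
  num <- function(field) {
    v <- suppressWarnings(as.numeric(grab(dialect[[field]])))
    if (anyNA(v)) stop_input("line ", which(is.na(v))[1], ": non-numeric '", field, "'")
    v
  }
  s <- num("ref_start"); e <- num("ref_end")
  if (any(s < 0) || any(e < 0))
    stop_input("line ", which(s < 0 | e < 0)[1], ": negative coordinate")
  lo <- pmin(s, e); hi <- pmax(s, e)   # minus-strand hits have start > end
  out <- data.frame(
    read_id = grab(dialect[["read_id"]]),
    genome_id = grab(dialect[["genome_id"]]),
    pct_identity = num("pct_identity"),
    aligned_bases = as.integer(num("aligned_bases")),
    ref_start = as.integer(lo - 1),    # to 0-based half-open
    ref_end = as.integer(hi),
    stringsAsFactors = FALSE)
  out$bit_score <- if (!is.na(dialect["bit_score"]) &&
                       all(ncols >= dialect[["bit_score"]]))
    suppressWarnings(as.numeric(grab(dialect[["bit_score"]]))) else NA_real_
  out$sample_id <- if (!is.na(dialect["sample_id"]))
    grab(dialect[["sample_id"]]) else sample_id %||% NA_character_
  if (any(out$aligned_bases < 1))
    stop_input("line ", which(out$aligned_bases < 1)[1], ": aligned_bases < 1")
  if (any(out$pct_identity < 0 | out$pct_identity > 100))
    stop_input("pct_identity outside [0, 100]")
  out
}

#' Read a BED3 rRNA mask
#'
#' Standard BED: 0-based half-open intervals, one per line. Intervals are
#' normalized (sorted, overlapping/adjacent runs merged) per genome.
#'
#' @param file Path to a BED3 file (chrom = genome id).
#' @return Normalized mask `data.frame` with `genome_id`, `start`, `end`.
#' @export
read_mask_bed <- function(file) {
  bed <- read.table(file, sep = "\t", header = FALSE,
                    col.names = c("genome_id", "start", "end"),
                    colClasses = c("character", "integer", "integer"))
  normalize_mask(bed)
}

# sort and merge intervals per genome; 0-based half-open
normalize_mask <- function(mask) {
  check_columns(mask, c("genome_id", "start", "end"), "mask")
  if (any(mask$start < 0) || any(mask$end <= mask$start))
    stop_input("mask intervals must satisfy 0 <= start < end")
  out <- lapply(split(mask, mask$genome_id), function(m) {
    m <- m[order(m$start, m$end), ]
    s <- m$start; e <- m$end
    keep_s <- s[1]; keep_e <- e[1]; rs <- c(); re <- c()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= keep_e) keep_e <- max(keep_e, e[i])
      else { rs <- c(rs, keep_s); re <- c(re, keep_e); keep_s <- s[i]; keep_e <- e[i] }
    }
    data.frame(genome_id = m$genome_id[1], start = c(rs, keep_s),
               end = c(re, keep_e), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter alignments by identity, rRNA mask, and read coverage
#'
#' Retains records with percent identity at or above the threshold (the
#' canonical recruitment cutoff is 80), whose reference interval overlaps no
#' mask interval by even a single base. A read-coverage filter
#' (aligned length / read length) is available but off by default, since
#' aligners expose the 80 cutoff either as identity or as coverage depending
#' on the tool. When `one_per_read = TRUE`, multi-mapped reads are reduced to
#' one record per (read, genome): the best bit score when present, else the
#' first occurrence.
#'
#' @param records Alignment records from [parse_alignments()].
#' @param min_identity Percent identity threshold (inclusive), default 80.
#' @param mask Optional mask `data.frame` (`genome_id`, `start`, `end`,
#'   0-based half-open), e.g. from [read_mask_bed()].
#' @param min_coverage Optional minimal aligned fraction of the read; needs a
#'   `read_length` column or attribute to apply.
#' @param read_length Read length used by `min_coverage`.
#' @param one_per_read Deduplicate multi-hits per (read, genome)?
#' @return Filtered records, original order preserved.
#' @export
filter_alignments <- function(records, min_identity = 80, mask = NULL,
                              min_coverage = NULL, read_length = NULL,
                              one_per_read = FALSE) {
  min_identity <- check_number(min_identity, "min_identity", 0, 100)
  keep <- records$pct_identity >= min_identity
  if (!is.null(min_coverage)) {
    if (is.null(read_length))
      stop_input("'min_coverage' requires 'read_length'")
    keep <- keep & (records$aligned_bases / read_length >= min_coverage)
  }
  records <- records[keep, , drop = FALSE]
  if (!is.null(mask) && nrow(records)) {
    mask <- normalize_mask(mask)
    hit <- logical(nrow(records))
    for (g in unique(mask$genome_id)) {
      m <- mask[mask$genome_id == g, ]
      idx <- which(records$genome_id == g)
      if (!length(idx)) next
      for (j in seq_len(nrow(m))) {
        # any-overlap of half-open intervals
        hit[idx] <- hit[idx] | (records$ref_start[idx] < m$end[j] &
                                  records$ref_end[idx] > m$start[j])
      }
    }
    records <- records[!hit, , drop = FALSE]
  }
  if (one_per_read && nrow(records)) {
    key <- paste(records$sample_id, records$read_id, records$genome_id, sep = "\r")
    ord <- if (all(is.na(records$bit_score))) seq_len(nrow(records))
           else order(-ifelse(is.na(records$bit_score), -Inf, records$bit_score))
    first <- !duplicated(key[ord])
    sel <- sort(ord[first])
    dropped <- nrow(records) - length(sel)
    if (dropped) message(dropped, " multi-hit record(s) collapsed to best per (read, genome)")
    records <- records[sel, , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' Base-normalized recruitment matrices
#'
#' The primary metric is the recruitment fraction
#' `R(g, s) = sum(aligned_bases of g in s) / total_bases(s)` — aligned bases
#' normalized by the total base pairs of reads in the sample. A secondary
#' genome-size-normalized variant, `R / size_bp * 1e6` (per Mbp of genome),
#' is returned in a parallel matrix; callers choose explicitly which
#' normalization to plot.
#'
#' @param records Filtered alignment records with a `sample_id` column.
#' @param genomes Genome table with `genome_id` and `size_bp`.
#' @param samples Sample table with `sample_id` and `total_bases` (> 0).
#' @param genome_order Optional genome id vector fixing row order (e.g. a
#'   phylogenetic tip order); default: genome table order.
#' @return List with matrices `fraction` (dimensionless, <= 1 per cell when
#'   reads align uniquely) and `per_mbp`.
#' @export
compute_recruitment <- function(records, genomes, samples,
                                genome_order = NULL) {
  check_columns(genomes, c("genome_id", "size_bp"), "genomes")
  check_columns(samples, c("sample_id", "total_bases"), "samples")
  if (any(samples$total_bases <= 0))
    stop_input("sample(s) with total_bases = 0: ",
               paste(samples$sample_id[samples$total_bases <= 0], collapse = ", "))
  if (nrow(records)) {
    check_columns(records, c("sample_id", "genome_id", "aligned_bases"), "records")
    bad_g <- setdiff(unique(records$genome_id), genomes$genome_id)
    if (length(bad_g))
      stop_input("records reference unknown genome_id(s): ",
                 paste(bad_g, collapse = ", "))
    bad_s <- setdiff(unique(records$sample_id), samples$sample_id)
    if (length(bad_s))
      stop_input("records reference unknown sample_id(s): ",
                 paste(bad_s, collapse = ", "))
  }
  genome_order <- genome_order %||% genomes$genome_id
  if (!setequal(genome_order, genomes$genome_id))
    stop_input("'genome_order' must be a permutation of the genome ids")
  tot <- matrix(0, length(genome_order), nrow(samples),
                dimnames = list(genome_order, samples$sample_id))
  if (nrow(records)) {
    agg <- tapply(as.numeric(records$aligned_bases),
                  list(factor(records$genome_id, levels = genome_order),
                       factor(records$sample_id, levels = samples$sample_id)),
                  sum)
    agg[is.na(agg)] <- 0
    tot[] <- agg
  }
  fraction <- sweep(tot, 2, samples$total_bases, "/")
  size <- genomes$size_bp[match(genome_order, genomes$genome_id)]
  per_mbp <- sweep(fraction, 1, size, "/") * 1e6
  list(fraction = fraction, per_mbp = per_mbp)
}
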