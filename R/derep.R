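# Bin quality filtering, k-mer ANI estimation, and 99%-ANI dereplication.

#' Filter genome bins on redundancy and contamination
#'
#' Retains bins strictly below both thresholds ("less than" is strict: a bin
#' at exactly 1.1% redundancy or exactly 5.0% contamination is excluded).
#' Defaults are the conventional cutoffs for single-copy marker redundancy
#' (1.1) and contamination (5.0).
#'
#' @param genomes Genome table with `genome_id`, `redundancy`,
#'   `contamination` (percent).
#' @param max_redundancy,max_contamination Exclusive upper bounds (percent).
#' @return Character vector of retained genome ids, input order preserved.
#' @export
quality_filter <- function(genomes, max_redundancy = 1.1,
                           max_contamination = 5.0) {
  check_columns(genomes, c("genome_id", "redundancy", "contamination"),
                "genomes")
  bad <- genomes$genome_id[is.na(genomes$redundancy) |
                             is.na(genomes$contamination)]
  if (length(bad))
    stop_input("missing quality metric for genome(s): ",
               paste(bad, collapse = ", "))
  keep <- genomes$redundancy < max_redundancy &
    genomes$contamination < max_contamination
  genomes$genome_id[keep]
}

read_fasta_concat <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(path)
    return(paste(as.character(seqs), collapse = ""))
  }
  lines <- readLines(path)
  paste(lines[!startsWith(lines, ">")], collapse = "")
}

#' Estimate ANI between two sequences from canonical k-mer sets
#'
#' Computes the Jaccard similarity J of the two sequences' canonical k-mer
#' sets (a k-mer and its reverse complement are identified, so strandedness
#' is irrelevant) and converts it to average nucleotide identity through the
#' Mash relation `ANI = 1 + (1/k) * log(2J / (1 + J))`, clamped to \[0, 1\].
#' Multi-contig bins are concatenated for k-mer extraction; k-mers spanning
#' contig joins or ambiguous bases are a negligible fraction at genome scale.
#'
#' @param seq_a,seq_b DNA as character strings, or paths to FASTA files.
#' @param k Odd k-mer size, default 21 (odd so no k-mer is its own reverse
#'   complement).
#' @return `data.frame` with `ani`, `jaccard`, `no_overlap` (TRUE when the
#'   k-mer sets are disjoint, in which case `ani` is 0).
#' @export
estimate_ani <- function(seq_a, seq_b, k = 21) {
  k <- check_count(k, "k")
  if (k %% 2 == 0) stop_input("'k' must be odd")
  if (k > 26) stop_input("'k' must be <= 26")
  get_seq <- function(x, name) {
    if (length(x) != 1 || !is.character(x)) stop_input("'", name, "' must be a single string or path")
    if (nchar(x) < 1000 && file.exists(x)) x <- read_fasta_concat(x)
    if (nchar(x) < k) stop_input("'", name, "' is shorter than k = ", k)
    x
  }
  a <- canonical_kmer_set(get_seq(seq_a, "seq_a"), k)
  b <- canonical_kmer_set(get_seq(seq_b, "seq_b"), k)
  ov <- kmer_set_overlap(a, b)
  j <- if (ov[2] > 0) ov[1] / ov[2] else 0
  if (j == 0)
    return(data.frame(ani = 0, jaccard = 0, no_overlap = TRUE))
  ani <- 1 + log(2 * j / (1 + j)) / k
  data.frame(ani = min(1, max(0, ani)), jaccard = j, no_overlap = FALSE)
}

#' All-pairs ANI for a set of bins
#'
#' @param seqs Named character vector (or named list) of sequences or FASTA
#'   paths, names = bin ids.
#' @param k K-mer size passed to [estimate_ani()].
#' @return `data.frame` with `bin_a`, `bin_b`, `ani`, `jaccard` for every
#'   unordered pair.
#' @export
ani_pairs <- function(seqs, k = 21) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop_input("'seqs' must be named by bin id")
  if (length(ids) < 2)
    return(data.frame(bin_a = character(), bin_b = character(),
                      ani = numeric(), jaccard = numeric()))
  sets <- lapply(seqs, function(s) {
    if (nchar(s) < 1000 && file.exists(s)) s <- read_fasta_concat(s)
    canonical_kmer_set(s, check_count(k, "k"))
  })
  combs <- utils::combn(length(ids), 2)
  out <- apply(combs, 2, function(ij) {
    ov <- kmer_set_overlap(sets[[ij[1]]], sets[[ij[2]]])
    j <- if (ov[2] > 0) ov[1] / ov[2] else 0
    ani <- if (j > 0) min(1, max(0, 1 + log(2 * j / (1 + j)) / k)) else 0
    c(j, ani)
  })
  data.frame(bin_a = ids[combs[1, ]], bin_b = ids[combs[2, ]],
             ani = out[2, ], jaccard = out[1, ], stringsAsFactors = FALSE)
}

# minimal union-find for connected components
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i] <- parent[parent[i]]
  i
}

#' Dereplicate genome bins at an ANI threshold
#'
#' Builds a graph on bins with an edge wherever ANI is at or above the
#' threshold (default 0.99) and decides each connected component: if any edge
#' joins two bins from the same station, every member of the component
#' becomes a `merge_candidate` (coassembly of same-station near-identical
#' bins happens downstream, outside this package); otherwise the bin
#' maximizing the quality score `Q = completeness - 5 * contamination` is
#' retained — the conventional reading of "more complete and less
#' contaminated" — with ties broken by larger `size_bp`, then lexicographic
#' id, and the rest are discarded, each naming the retained partner.
#'
#' @param genomes Genome table with `genome_id`, `completeness`,
#'   `contamination`, `size_bp`, and `station` (station may be NA).
#' @param pairs `data.frame` with `bin_a`, `bin_b`, `ani` (e.g. from
#'   [ani_pairs()]).
#' @param threshold ANI threshold in (0, 1], inclusive; default 0.99.
#' @param contamination_weight Weight of contamination in Q; default 5.
#' @return `data.frame` with one row per input bin: `bin`, `action`
#'   (`retain` / `discard` / `merge_candidate`), `partner`, `reason`.
#'   Decisions are independent of input row order.
#' @export
dereplicate <- function(genomes, pairs, threshold = 0.99,
                        contamination_weight = 5) {
  check_columns(genomes, c("genome_id", "completeness", "contamination",
                           "size_bp", "station"), "genomes")
  threshold <- check_number(threshold, "threshold", 1e-9, 1)
  genomes <- genomes[order(genomes$genome_id), ]
  ids <- genomes$genome_id
  if (nrow(pairs)) {
    check_columns(pairs, c("bin_a", "bin_b", "ani"), "pairs")
    unknown <- setdiff(c(pairs$bin_a, pairs$bin_b), ids)
    if (length(unknown))
      stop_input("ANI pair references unknown bin(s): ",
                 paste(unknown, collapse = ", "))
  }
  n <- length(ids)
  parent <- seq_len(n)
  edges <- pairs[pairs$ani >= threshold, , drop = FALSE]
  if (nrow(edges)) {
    ia <- match(edges$bin_a, ids); ib <- match(edges$bin_b, ids)
    for (e in seq_len(nrow(edges))) {
      ra <- uf_find(parent, ia[e]); rb <- uf_find(parent, ib[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), 1L)

  same_station_edge <- logical(n)
  if (nrow(edges)) {
    st <- genomes$station
    ia <- match(edges$bin_a, ids); ib <- match(edges$bin_b, ids)
    same <- !is.na(st[ia]) & !is.na(st[ib]) & st[ia] == st[ib]
    for (e in which(same)) {
      root <- uf_find(parent, ia[e])
      same_station_edge[comp == root] <- TRUE
    }
  }

  q <- genomes$completeness - contamination_weight * genomes$contamination
  action <- character(n); partner <- rep(NA_character_, n); reason <- character(n)
  for (root in unique(comp)) {
    members <- which(comp == root)
    if (length(members) == 1) {
      action[members] <- "retain"
      reason[members] <- "no bin at or above the ANI threshold"
    } else if (any(same_station_edge[members])) {
      action[members] <- "merge_candidate"
      others <- vapply(members, function(i)
        paste(ids[setdiff(members, i)], collapse = ";"), "")
      partner[members] <- others
      reason[members] <- "near-identical bin(s) from the same station; coassembly candidate"
    } else {
      ord <- members[order(-q[members], -genomes$size_bp[members], ids[members])]
      best <- ord[1]
      action[best] <- "retain"
      reason[best] <- sprintf("best quality score Q = %.2f in its ANI cluster", q[best])
      losers <- ord[-1]
      action[losers] <- "discard"
      partner[losers] <- ids[best]
      reason[losers] <- sprintf("ANI >= %.3g with retained bin %s of higher quality",
                                threshold, ids[best])
    }
  }
  data.frame(bin = ids, action = action, partner = partner, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}
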