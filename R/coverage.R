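#' Binned coverage of one target sequence
#'
#' Divides the target into fixed-width bins and, for each alignment,
#' increments the count of every bin whose interval intersects the aligned
#' target interval by at least one base (no fractional weighting). The
#' caller is expected to have deduplicated overlapping alignments per query
#' first (see [dedup_overlaps()] / [coverage_map_tracks()]), so counts
#' approximate the number of distinct query sequences covering each bin.
#'
#' @param alignments_on_target an `aln_set` whose rows all hit one target.
#' @param target_length target length in bp.
#' @param bin_size bin width in bp (>= 1).
#' @param target_name name stored on the track; defaults to the first
#'   record's target (or `""` for an empty set).
#' @return a `coverage_track`: list with `target_name`, `target_length`,
#'   `bin_size` and integer `counts` of length
#'   `ceiling(target_length / bin_size)`.
#' @export
coverage_track <- function(alignments_on_target, target_length, bin_size,
                           target_name = NULL) {
  stopifnot(bin_size >= 1, target_length >= 1)
  aln <- alignments_on_target
  if (is.null(target_name)) {
    target_name <- if (nrow(aln) > 0) aln$target_name[1] else ""
  }
  if (nrow(aln) > 0 && any(aln$target_end > target_length)) {
    bad <- which(aln$target_end > target_length)[1]
    stop(sprintf("alignment of query '%s' ends at %d, beyond target length %d",
                 aln$query_name[bad], aln$target_end[bad], target_length))
  }
  n_bins <- ceiling(target_length / bin_size)
  counts <- integer(n_bins)
  if (nrow(aln) > 0) {
    lo <- floor(aln$target_start / bin_size) + 1
    hi <- floor((aln$target_end - 1) / bin_size) + 1
    hits <- unlist(mapply(seq.int, lo, hi, SIMPLIFY = FALSE), use.names = FALSE)
    counts <- tabulate(hits, nbins = n_bins)
  }
  structure(
    list(target_name = target_name, target_length = target_length,
         bin_size = bin_size, counts = counts),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d bp, %d bins of %d bp, max count %d\n",
              x$target_name, x$target_length, length(x$counts), x$bin_size,
              if (length(x$counts)) max(x$counts) else 0L))
  invisible(x)
}

# per-query dedup across the whole set, preserving record order
dedup_set <- function(aln) {
  if (nrow(aln) == 0) return(aln)
  groups <- split(seq_len(nrow(aln)),
                  factor(aln$query_name, levels = unique(aln$query_name)))
  keep <- unlist(lapply(groups, function(g) {
    g[dedup_indices(aln[g, , drop = FALSE])]
  }), use.names = FALSE)
  new_aln_set(aln[sort(keep), , drop = FALSE], validate = FALSE)
}

# target lengths in order of first appearance; fall back to max target_end
# when the input format did not carry lengths
observed_targets <- function(aln) {
  nm <- unique(aln$target_name)
  len <- vapply(nm, function(t) {
    rows <- aln$target_name == t
    l <- max(aln$target_length[rows])
    if (l <= 0) l <- max(aln$target_end[rows])
    l
  }, numeric(1))
  data.frame(name = nm, length = as.numeric(len), stringsAsFactors = FALSE)
}

#' Per-target coverage tracks for the coverage-map diagram
#'
#' Full pipeline step: deduplicate each query's overlapping alignments
#' (keeping the largest), then bin each target separately. Every target gets
#' the same number of bins, so each track renders to a heat map of constant
#' size irrespective of target length; the bin size therefore varies between
#' targets.
#'
#' @param aln an `aln_set` (filtered).
#' @param bins number of bins per target; default 10000 (a 100x100 wrapped
#'   square).
#' @return named list of `coverage_track` objects, in order of first
#'   appearance of each target.
#' @export
coverage_map_tracks <- function(aln, bins = 10000) {
  stopifnot(bins >= 1)
  aln <- dedup_set(aln)
  targets <- observed_targets(aln)
  out <- lapply(seq_len(nrow(targets)), function(i) {
    tl <- targets$length[i]
    bs <- max(1, ceiling(tl / bins))
    rows <- aln[aln$target_name == targets$name[i], , drop = FALSE]
    coverage_track(rows, tl, bs, target_name = targets$name[i])
  })
  stats::setNames(out, targets$name)
}

#' Whole-genome binned coverage at a constant bp-per-bin
#'
#' Builds one coverage representation over all targets, in order, with a
#' single shared bin size, so that one concatenated heat map shows every
#' chromosome at the same scale. The shared bin size is
#' `ceiling(total_length / total_bins)`.
#'
#' @param aln an `aln_set` (filtered).
#' @param target_order data frame with columns `name` and `length` giving
#'   the targets and their order; defaults to order of first appearance in
#'   `aln` with lengths taken from the records.
#' @param total_bins total bin budget across all targets (default 1000);
#'   must be at least the number of targets.
#' @return a `genome_coverage`: list with `tracks` (named list of
#'   `coverage_track` sharing one `bin_size`), `bin_size`, and `boundaries`
#'   (cumulative bin offsets, one per target).
#' @export
genome_coverage <- function(aln, target_order = NULL, total_bins = 1000) {
  aln <- dedup_set(aln)
  if (is.null(target_order)) target_order <- observed_targets(aln)
  stopifnot(is.data.frame(target_order),
            all(c("name", "length") %in% names(target_order)))
  if (nrow(target_order) == 0) {
    return(structure(list(tracks = list(), bin_size = NA_real_,
                          boundaries = numeric()),
                     class = "genome_coverage"))
  }
  stopifnot(total_bins >= nrow(target_order))
  unknown <- !aln$target_name %in% target_order$name
  if (any(unknown)) {
    warning(sum(unknown), " alignment(s) to targets absent from target_order skipped")
    aln <- aln[!unknown, , drop = FALSE]
  }
  bin_size <- ceiling(sum(target_order$length) / total_bins)
  tracks <- lapply(seq_len(nrow(target_order)), function(i) {
    rows <- aln[aln$target_name == target_order$name[i], , drop = FALSE]
    coverage_track(rows, target_order$length[i], bin_size,
                   target_name = target_order$name[i])
  })
  names(tracks) <- target_order$name
  n_bins <- vapply(tracks, function(t) length(t$counts), numeric(1))
  structure(
    list(tracks = tracks, bin_size = bin_size,
         boundaries = unname(cumsum(c(0, n_bins))[seq_along(tracks)])),
    class = "genome_coverage"
  )
}

#' @export
print.genome_coverage <- function(x, ...) {
  cat(sprintf("<genome_coverage> %d target(s), bin size %s bp, %d bins total\n",
              length(x$tracks), format(x$bin_size, big.mark = ","),
              sum(vapply(x$tracks, function(t) length(t$counts), numeric(1)))))
  invisible(x)
}

#' Export coverage tracks as a table
#'
#' @param tracks a list of `coverage_track` objects or a `genome_coverage`.
#' @param path optional path; when given, written as tab-separated text.
#' @return data frame with columns `target`, `bin`, `count` (bins 0-based).
#' @export
coverage_table <- function(tracks, path = NULL) {
  if (inherits(tracks, "genome_coverage")) tracks <- tracks$tracks
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(target = t$target_name,
               bin = seq_along(t$counts) - 1L,
               count = t$counts, stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(target = character(), bin = integer(), count = integer())
  }
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
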