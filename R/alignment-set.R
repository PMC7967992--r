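#' Construct a set of normalised pairwise alignments
#'
#' An alignment set is a data frame with one row per pairwise alignment and a
#' fixed column contract. All coordinates are 0-based, half-open
#' `[start, end)`, and query coordinates are always expressed on the forward
#' strand of the query regardless of the `strand` flag (the PAF convention).
#' Every parser in the package converts its input to this convention on
#' ingest, so downstream code never has to reason about format dialects.
#'
#' Columns:
#' \describe{
#'   \item{query_name}{character, name of the read or contig}
#'   \item{query_length}{numeric bp, full length of the query (> 0)}
#'   \item{query_start, query_end}{numeric bp, aligned query interval,
#'     forward frame, `0 <= start < end <= query_length`}
#'   \item{target_name}{character, name of the reference sequence}
#'   \item{target_length}{numeric bp, length of the target; 0 when the
#'     input format does not carry it}
#'   \item{target_start, target_end}{numeric bp, aligned target interval}
#'   \item{strand}{character, `"+"` or `"-"`}
#' }
#'
#' @param query_name,query_length,query_start,query_end query fields.
#' @param target_name,target_length,target_start,target_end target fields.
#' @param strand `"+"` or `"-"`, recycled as needed.
#' @param validate check the coordinate invariants (default `TRUE`).
#' @return An object of class `aln_set` (a data frame).
#' @examples
#' aln <- alignment_set(
#'   query_name = "q1", query_length = 1000, query_start = 0,
#'   query_end = 480, target_name = "T1", target_length = 5000,
#'   target_start = 100, target_end = 590, strand = "+"
#' )
#' query_span(aln)
#' @export
alignment_set <- function(query_name = character(), query_length = numeric(),
                          query_start = numeric(), query_end = numeric(),
                          target_name = character(), target_length = numeric(),
                          target_start = numeric(), target_end = numeric(),
                          strand = character(), validate = TRUE) {
  df <- data.frame(
    query_name = as.character(query_name),
    query_length = as.numeric(query_length),
    query_start = as.numeric(query_start),
    query_end = as.numeric(query_end),
    target_name = as.character(target_name),
    target_length = as.numeric(target_length),
    target_start = as.numeric(target_start),
    target_end = as.numeric(target_end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  new_aln_set(df, validate = validate)
}

ALN_COLS <- c(
  "query_name", "query_length", "query_start", "query_end",
  "target_name", "target_length", "target_start", "target_end", "strand"
)

#' @rdname alignment_set
#' @param df a data frame carrying the alignment-set columns.
#' @export
new_aln_set <- function(df, validate = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(ALN_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("alignment set is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, ALN_COLS, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("aln_set", "data.frame")
  if (validate) validate_alignments(df)
  df
}

#' Validate alignment-set invariants
#'
#' Checks every record against the coordinate contract: intervals 0-based
#' half-open with `start < end`, query interval inside `[0, query_length]`,
#' target interval inside `[0, target_length]` whenever the target length is
#' known (> 0), strand one of `+`/`-`. Errors name the first offending record.
#'
#' @param aln an `aln_set`.
#' @return `aln`, invisibly.
#' @export
validate_alignments <- function(aln) {
  if (nrow(aln) == 0) return(invisible(aln))
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0) {
      stop(sprintf(
        "invalid alignment record %d (query '%s'): %s",
        i[1], aln$query_name[i[1]], what
      ), call. = FALSE)
    }
  }
  bad(!aln$strand %in% c("+", "-"), "strand must be '+' or '-'")
  bad(!is.finite(aln$query_length) | aln$query_length <= 0, "query_length must be > 0")
  bad(aln$query_start < 0, "query_start must be >= 0")
  bad(aln$query_start >= aln$query_end, "query_start must be < query_end")
  bad(aln$query_end > aln$query_length, "query_end must be <= query_length")
  bad(aln$target_length < 0, "target_length must be >= 0")
  known <- aln$target_length > 0
  bad(aln$target_start < 0, "target_start must be >= 0")
  bad(aln$target_start >= aln$target_end, "target_start must be < target_end")
  bad(known & aln$target_end > aln$target_length, "target_end must be <= target_length")
  invisible(aln)
}

#' Aligned span lengths
#'
#' `query_span()` is the aligned block length on the query
#' (`query_end - query_start`); `target_span()` the analogue on the target.
#'
#' @param aln an `aln_set` or compatible data frame.
#' @return numeric vector of spans in bp.
#' @export
query_span <- function(aln) aln$query_end - aln$query_start

#' @rdname query_span
#' @export
target_span <- function(aln) aln$target_end - aln$target_start

#' Drop alignments shorter than a fraction of their query
#'
#' Noise filter applied before chimera detection and coverage computation:
#' an alignment is kept iff its query span is at least `min_fraction` of the
#' full query length. The default of 1% removes the short spurious hits that
#' long-read aligners emit, while leaving any real split alignment intact.
#' Input order is preserved and the operation is idempotent.
#'
#' @param aln an `aln_set`.
#' @param min_fraction fraction of query length in `[0, 1]`; default `0.01`.
#' @return filtered `aln_set`.
#' @export
filter_min_length <- function(aln, min_fraction = 0.01) {
  stopifnot(is.numeric(min_fraction), length(min_fraction) == 1,
            min_fraction >= 0, min_fraction <= 1)
  keep <- query_span(aln) >= min_fraction * aln$query_length
  new_aln_set(aln[keep, , drop = FALSE], validate = FALSE)
}

#' Partition alignments by query or target name
#'
#' Groups appear in order of first appearance in the set; within each group
#' the input record order is preserved, so concatenating the groups recovers
#' the input as a multiset.
#'
#' @param aln an `aln_set`.
#' @param axis `"query"` or `"target"`.
#' @return named list of `aln_set` objects.
#' @export
alignments_by <- function(aln, axis = c("query", "target")) {
  axis <- match.arg(axis)
  key <- if (axis == "query") aln$query_name else aln$target_name
  if (nrow(aln) == 0) return(structure(list(), names = character()))
  groups <- split(seq_len(nrow(aln)), factor(key, levels = unique(key)))
  lapply(groups, function(i) new_aln_set(aln[i, , drop = FALSE], validate = FALSE))
}

#' Discard overlapping alignments of one query, keeping the largest
#'
#' Used when building coverage tracks: a query contributing several mutually
#' overlapping alignments should count once per locus, not once per
#' alignment. Greedy selection: sort by target span, largest first (ties
#' broken by input order), and accept an alignment iff its target interval
#' overlaps no already-accepted alignment on the same target. Alignments to
#' different targets never conflict. Output preserves input order.
#'
#' @param records an `aln_set` whose rows all share one `query_name`.
#' @return `aln_set` with pairwise non-overlapping target intervals per target.
#' @export
dedup_overlaps <- function(records) {
  if (nrow(records) > 1 && length(unique(records$query_name)) != 1) {
    stop("dedup_overlaps expects records of a single query")
  }
  keep <- dedup_indices(records)
  new_aln_set(records[keep, , drop = FALSE], validate = FALSE)
}

# greedy largest-target-span selection; returns kept row indices, sorted
dedup_indices <- function(records) {
  n <- nrow(records)
  if (n <= 1) return(seq_len(n))
  ord <- order(-target_span(records), seq_len(n)) # stable: ties by input order
  accepted <- integer(0)
  for (i in ord) {
    same <- accepted[records$target_name[accepted] == records$target_name[i]]
    clash <- any(records$target_start[same] < records$target_end[i] &
                   records$target_end[same] > records$target_start[i])
    if (!clash) accepted <- c(accepted, i)
  }
  sort(accepted)
}

#' @export
print.aln_set <- function(x, ...) {
  cat(sprintf(
    "<aln_set> %d alignment(s), %d query(s), %d target(s)\n",
    nrow(x), length(unique(x$query_name)), length(unique(x$target_name))
  ))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more\n", sep = "")
  invisible(x)
}

#' @export
`[.aln_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(ALN_COLS %in% names(out))) {
    class(out) <- c("aln_set", "data.frame")
    rownames(out) <- NULL
  }
  out
}

#' Combine alignment sets
#' @param ... `aln_set` objects.
#' @return a single `aln_set` in argument order.
#' @export
bind_alignments <- function(...) {
  new_aln_set(do.call(rbind, lapply(list(...), as.data.frame)), validate = FALSE)
}
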