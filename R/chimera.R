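#' Thresholds for the chimera classification rule
#'
#' A query is called chimeric when exactly two non-overlapping alignments
#' together cover at least `min_total_coverage` of the query and each covers
#' at least `min_each_fraction` of it. Defaults are 90% combined and 10%
#' each; both may be adjusted.
#'
#' @param min_total_coverage fraction of the query the two alignments must
#'   jointly cover (default 0.9).
#' @param min_each_fraction minimum fraction of the query each alignment
#'   must cover on its own (default 0.1). Must satisfy
#'   `0 < min_each_fraction <= 0.5` and
#'   `2 * min_each_fraction <= min_total_coverage <= 1`.
#' @return a `chimera_params` list.
#' @export
chimera_params <- function(min_total_coverage = 0.9, min_each_fraction = 0.1) {
  stopifnot(
    is.numeric(min_total_coverage), length(min_total_coverage) == 1,
    is.numeric(min_each_fraction), length(min_each_fraction) == 1
  )
  if (min_each_fraction <= 0 || min_each_fraction > 0.5) {
    stop("min_each_fraction must be in (0, 0.5]")
  }
  if (min_total_coverage > 1 || 2 * min_each_fraction > min_total_coverage) {
    stop("min_total_coverage must satisfy 2*min_each_fraction <= min_total_coverage <= 1")
  }
  structure(
    list(min_total_coverage = min_total_coverage,
         min_each_fraction = min_each_fraction),
    class = "chimera_params"
  )
}

default_chimera_params <- function() chimera_params()

empty_chimera_calls <- function() {
  data.frame(
    query_name = character(), query_length = numeric(),
    join_position = numeric(),
    left_target = character(), right_target = character(),
    left_query_start = numeric(), left_query_end = numeric(),
    right_query_start = numeric(), right_query_end = numeric(),
    same_target = logical(), stringsAsFactors = FALSE
  )
}

#' Classify one query as chimeric or not
#'
#' Implements the geometric rule on the (already length-filtered) alignments
#' of a single query. A call is returned iff:
#' \enumerate{
#'   \item exactly two alignments exist;
#'   \item their query intervals do not overlap (an intersection of length 0
#'     -- abutting intervals -- is allowed);
#'   \item when both alignments hit the same target, their target intervals
#'     do not overlap either (the two pieces must come from different
#'     sections of that target);
#'   \item the combined query span is at least
#'     `min_total_coverage * query_length`;
#'   \item each query span is at least `min_each_fraction * query_length`.
#' }
#' The estimated join position is the midpoint of the unaligned gap between
#' the two alignments, `floor((left_end + right_start) / 2)` in query
#' coordinates.
#'
#' @param records an `aln_set` whose rows share one `query_name` and agree
#'   on `query_length`.
#' @param params a [chimera_params()] object.
#' @return a one-row data frame describing the call, or `NULL`.
#' @examples
#' aln <- alignment_set(
#'   query_name = c("q1", "q1"), query_length = 1000,
#'   query_start = c(0, 520), query_end = c(480, 1000),
#'   target_name = c("T1", "T2"), target_length = 5000,
#'   target_start = c(100, 2000), target_end = c(580, 2480),
#'   strand = "+"
#' )
#' classify_query(aln) # chimeric, join at 500
#' @export
classify_query <- function(records, params = chimera_params()) {
  stopifnot(inherits(params, "chimera_params"))
  if (nrow(records) != 2) return(NULL)
  if (length(unique(records$query_name)) != 1) {
    stop("classify_query expects records of a single query")
  }
  if (length(unique(records$query_length)) != 1) {
    stop(sprintf("records of query '%s' disagree on query_length",
                 records$query_name[1]))
  }
  ord <- order(records$query_start)
  left <- records[ord[1], ]
  right <- records[ord[2], ]
  if (right$query_start < left$query_end) return(NULL) # query overlap
  same_target <- left$target_name == right$target_name
  if (same_target &&
      left$target_start < right$target_end &&
      right$target_start < left$target_end) {
    return(NULL) # same section of the same target
  }
  qlen <- left$query_length
  span_l <- left$query_end - left$query_start
  span_r <- right$query_end - right$query_start
  if (span_l + span_r < params$min_total_coverage * qlen) return(NULL)
  if (min(span_l, span_r) < params$min_each_fraction * qlen) return(NULL)
  data.frame(
    query_name = left$query_name, query_length = qlen,
    join_position = floor((left$query_end + right$query_start) / 2),
    left_target = left$target_name, right_target = right$target_name,
    left_query_start = left$query_start, left_query_end = left$query_end,
    right_query_start = right$query_start, right_query_end = right$query_end,
    same_target = same_target, stringsAsFactors = FALSE
  )
}

#' Detect chimeric queries in an alignment set
#'
#' Applies [classify_query()] to every query of a (length-filtered)
#' alignment set. Calls are returned sorted by query name for deterministic
#' output. Same-target calls on references named in `exclude_targets` are
#' dropped: a read whose two alignments hit the two ends of a circular
#' reference (mitochondrion, chloroplast) is an artefact of representing a
#' circle as a line, not a chimera.
#'
#' @param aln an `aln_set`, already filtered with [filter_min_length()].
#' @param params a [chimera_params()] object.
#' @param exclude_targets character vector of (circular) reference names on
#'   which same-target calls are suppressed. Empty by default.
#' @return data frame of calls, one row per chimeric query, with columns
#'   `query_name`, `query_length`, `join_position`, `left_target`,
#'   `right_target`, the four query-interval bounds, and `same_target`.
#' @export
detect_chimeras <- function(aln, params = chimera_params(),
                            exclude_targets = character()) {
  groups <- alignments_by(aln, "query")
  calls <- lapply(groups, classify_query, params = params)
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (length(calls) == 0) return(empty_chimera_calls())
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  if (length(exclude_targets) > 0) {
    out <- out[!(out$same_target & out$left_target %in% exclude_targets), ,
               drop = FALSE]
  }
  out[order(out$query_name), , drop = FALSE]
}

#' Write the chimera report
#'
#' One tab-separated line per call, no header: query name, approximate join
#' position, and the target names of the left and right alignments.
#'
#' @param calls data frame from [detect_chimeras()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chimera_report <- function(calls, path) {
  df <- calls[, c("query_name", "join_position", "left_target", "right_target")]
  df$join_position <- format(df$join_position, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chimera report written by [write_chimera_report()]
#'
#' @param path report file path.
#' @return data frame with columns `query_name`, `join_position`,
#'   `left_target`, `right_target`.
#' @export
read_chimera_report <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(query_name = character(), join_position = numeric(),
                      left_target = character(), right_target = character(),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric",
                                         "character", "character"))
  names(df) <- c("query_name", "join_position", "left_target", "right_target")
  df
}

# sequence-name -> first whitespace token (FASTA headers carry descriptions)
name_token <- function(x) sub("[ \t].*$", "", x)

#' Read sequences for splitting
#'
#' Reads FASTA or FASTQ (gzip-transparent; format auto-detected from the
#' first record marker). FASTQ qualities are retained.
#'
#' @param path sequence file.
#' @return a `DNAStringSet` (FASTA) or `QualityScaledDNAStringSet` (FASTQ)
#'   with attribute `seq_format` set to `"fasta"` or `"fastq"`.
#' @export
read_reads <- function(path) {
  con <- gzfile(path, "r")
  first <- readLines(con, n = 1)
  close(con)
  if (length(first) == 0) stop("empty sequence file: ", path)
  if (startsWith(first, ">")) {
    out <- Biostrings::readDNAStringSet(path, format = "fasta")
    attr(out, "seq_format") <- "fasta"
  } else if (startsWith(first, "@")) {
    out <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      # harmless upstream notice about (empty) mcols being dropped
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    attr(out, "seq_format") <- "fastq"
  } else {
    stop("cannot detect sequence format of ", path,
         " (expected '>' or '@' on the first line)")
  }
  out
}

#' Write sequences in the same format they were read
#'
#' @param reads a `DNAStringSet` or `QualityScaledDNAStringSet`.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`; defaults to the `seq_format`
#'   attribute set by [read_reads()].
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = attr(reads, "seq_format")) {
  if (is.null(format)) {
    format <- if (methods::is(reads, "QualityScaledXStringSet")) "fastq" else "fasta"
  }
  if (format == "fastq") {
    Biostrings::writeQualityScaledXStringSet(reads, path)
  } else {
    Biostrings::writeXStringSet(reads, path, width = 80)
  }
  invisible(path)
}

#' Split chimeric reads at their estimated joins
#'
#' Each read named in a call is replaced, in place in the read order, by its
#' prefix `[0, join)` and suffix `[join, length)`, named `<name>_left` and
#' `<name>_right`; FASTQ qualities are split in register. All other reads
#' pass through unchanged. Re-assembling from the split read set is how a
#' chimera call translates into an assembly improvement: the two halves can
#' each be placed where they belong.
#'
#' @param reads a `DNAStringSet` or `QualityScaledDNAStringSet`; names are
#'   matched on their first whitespace-delimited token.
#' @param calls data frame with at least `query_name` and `join_position`
#'   ([detect_chimeras()] output or a report read back with
#'   [read_chimera_report()]).
#' @return a read set of the same class; attribute `seq_format` is carried
#'   over.
#' @export
split_chimeric_reads <- function(reads, calls) {
  tokens <- name_token(names(reads))
  join <- stats::setNames(calls$join_position, calls$query_name)
  missing <- setdiff(calls$query_name, tokens)
  if (length(missing) > 0) {
    warning("calls for reads absent from input skipped: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  }
  widths <- Biostrings::width(reads)
  hit <- tokens %in% names(join)
  jp <- rep(NA_real_, length(reads))
  jp[hit] <- join[tokens[hit]]
  bad <- hit & (jp <= 0 | jp >= widths)
  if (any(bad)) {
    stop(sprintf("join position %d outside read '%s' (length %d)",
                 jp[which(bad)[1]], tokens[which(bad)[1]], widths[which(bad)[1]]))
  }
  # expand: split reads contribute two rows, others one
  idx <- rep(seq_along(reads), ifelse(hit, 2L, 1L))
  side <- unlist(lapply(hit, function(h) if (h) c("left", "right") else ""),
                 use.names = FALSE)
  start <- ifelse(side == "right", jp[idx] + 1, 1)
  end <- ifelse(side == "left", jp[idx], widths[idx])
  out <- Biostrings::subseq(reads[idx], start = start, end = end)
  nm <- names(reads)[idx]
  nm[side != ""] <- paste0(name_token(nm[side != ""]), "_", side[side != ""])
  names(out) <- nm
  attr(out, "seq_format") <- attr(reads, "seq_format")
  out
}

#' File-level read splitting
#'
#' Convenience wrapper: read sequences, split them according to a chimera
#' report, and write the result in the input's format.
#'
#' @param reads_path input FASTA/FASTQ file.
#' @param report_path chimera report (four tab-separated columns).
#' @param out_path output sequence file.
#' @return `out_path`, invisibly.
#' @export
split_reads_file <- function(reads_path, report_path, out_path) {
  reads <- read_reads(reads_path)
  calls <- read_chimera_report(report_path)
  write_reads(split_chimeric_reads(reads, calls), out_path)
  invisible(out_path)
}
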