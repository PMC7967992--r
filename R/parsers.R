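#' Supported alignment input formats
#'
#' @return character vector of format names accepted by [read_alignments()].
#' @export
alignment_formats <- function() {
  c("paf", "sam", "blast", "psl", "coords", "tiling")
}

#' Read an alignment file in any supported format
#'
#' Dispatches to the format-specific reader and validates every record
#' against the alignment-set invariants before returning, so a malformed
#' file can never yield silently corrupt records.
#'
#' @param path path to the alignment file.
#' @param format one of `"paf"`, `"sam"`, `"blast"`, `"psl"`, `"coords"`,
#'   `"tiling"` (see [alignment_formats()]).
#' @return an [alignment_set()].
#' @export
read_alignments <- function(path, format) {
  if (length(format) != 1 || !format %in% alignment_formats()) {
    stop("unknown input format '", paste(format, collapse = ","),
         "'; expected one of: ", paste(alignment_formats(), collapse = ", "))
  }
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  aln <- switch(format,
    paf = parse_paf(lines),
    sam = parse_sam(lines),
    blast = parse_blast_tab(lines),
    psl = parse_psl(lines),
    coords = parse_coords(lines),
    tiling = parse_tiling(lines)
  )
  validate_alignments(aln)
  aln
}

parse_error <- function(lineno, msg) {
  stop(sprintf("parse error at line %d: %s", lineno, msg), call. = FALSE)
}

num_field <- function(x, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) parse_error(lineno, paste0("non-numeric ", what, " '", x[is.na(v)][1], "'"))
  v
}

#' Parse PAF lines (minimap2 pairwise alignment format)
#'
#' PAF is already in the package's internal convention: 0-based half-open
#' coordinates with query coordinates on the forward strand, so fields 1-9
#' are stored unchanged.
#'
#' @param lines character vector of file lines.
#' @return an [alignment_set()].
#' @export
parse_paf <- function(lines) {
  keep <- which(nzchar(lines))
  if (length(keep) == 0) return(alignment_set())
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) parse_error(i, sprintf("PAF line has %d fields, expected >= 12", length(f)))
    if (!f[5] %in% c("+", "-")) parse_error(i, paste0("bad strand field '", f[5], "'"))
    co <- num_field(f[c(2, 3, 4, 7, 8, 9)], i, "coordinate")
    data.frame(
      query_name = f[1], query_length = co[1],
      query_start = co[2], query_end = co[3],
      target_name = f[6], target_length = co[4],
      target_start = co[5], target_end = co[6],
      strand = f[5], stringsAsFactors = FALSE
    )
  })
  new_aln_set(do.call(rbind, rows), validate = FALSE)
}

# CIGAR helpers -----------------------------------------------------------

cigar_ops <- function(cigar) {
  lens <- as.numeric(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0) return(NULL)
  list(len = lens, op = ops)
}

#' Parse SAM lines
#'
#' Header lines provide target lengths (`@SQ`/`LN`); alignment lines are
#' normalised as follows. Unmapped (flag 0x4) and secondary (0x100) records
#' are skipped -- secondaries would double-count a locus -- while
#' supplementary records (0x800) are kept, because a chimeric read shows up
#' precisely as a primary plus a supplementary alignment. The target span is
#' the reference-consuming CIGAR length (M/=/X/D/N); the query interval and
#' full query length are derived from the CIGAR, with soft *and* hard clips
#' counting towards the query length so that split pieces of one read agree
#' on it. For reverse-strand records (flag 0x10) the clip-derived interval,
#' which is in the reversed read frame, is reflected onto the forward
#' strand: `start' = length - end`.
#'
#' @param lines character vector of file lines.
#' @return an [alignment_set()].
#' @export
parse_sam <- function(lines) {
  target_len <- list()
  rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line)) next
    if (startsWith(line, "@")) {
      if (startsWith(line, "@SQ")) {
        f <- strsplit(line, "\t", fixed = TRUE)[[1]]
        sn <- sub("^SN:", "", grep("^SN:", f, value = TRUE)[1])
        ln <- sub("^LN:", "", grep("^LN:", f, value = TRUE)[1])
        if (!is.na(sn) && !is.na(ln)) target_len[[sn]] <- as.numeric(ln)
      }
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) parse_error(i, sprintf("SAM line has %d fields, expected >= 11", length(f)))
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) parse_error(i, paste0("non-integer FLAG '", f[2], "'"))
    if (bitwAnd(flag, 0x4) != 0 || bitwAnd(flag, 0x100) != 0) next
    pos <- suppressWarnings(as.numeric(f[4]))
    if (is.na(pos)) parse_error(i, paste0("non-numeric POS '", f[4], "'"))
    if (f[6] == "*") {
      warning(sprintf("line %d: mapped record '%s' without CIGAR skipped", i, f[1]))
      next
    }
    cig <- cigar_ops(f[6])
    if (is.null(cig)) parse_error(i, paste0("unparseable CIGAR '", f[6], "'"))
    q_consumed <- sum(cig$len[cig$op %in% c("M", "I", "=", "X")])
    t_consumed <- sum(cig$len[cig$op %in% c("M", "D", "N", "=", "X")])
    clips <- cig$len[cig$op %in% c("S", "H")]
    lead_clip <- if (cig$op[1] %in% c("S", "H")) cig$len[1] else 0
    qlen <- q_consumed + sum(clips)
    qs <- lead_clip
    qe <- lead_clip + q_consumed
    reverse <- bitwAnd(flag, 0x10) != 0
    if (reverse) { # clip frame -> forward query frame
      tmp <- qs
      qs <- qlen - qe
      qe <- qlen - tmp
    }
    tname <- f[3]
    tlen <- if (!is.null(target_len[[tname]])) target_len[[tname]] else 0
    rows[[length(rows) + 1]] <- data.frame(
      query_name = f[1], query_length = qlen,
      query_start = qs, query_end = qe,
      target_name = tname, target_length = tlen,
      target_start = pos - 1, target_end = pos - 1 + t_consumed,
      strand = if (reverse) "-" else "+", stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(alignment_set())
  new_aln_set(do.call(rbind, rows), validate = FALSE)
}

#' Parse BLAST tabular (outfmt 6) lines
#'
#' The standard 12 columns are read; optional columns 13 and 14 are taken as
#' `qlen` and `slen`. Query/subject coordinates are converted from 1-based
#' inclusive to 0-based half-open, and a descending subject interval
#' (`sstart > send`) is normalised ascending with `strand = "-"`. Without a
#' `qlen` column the query length falls back to the maximum `qend` observed
#' for that query anywhere in the file; the returned set is then flagged
#' approximate (attribute `approximate_query_length`) and a warning is
#' emitted, because chimera coverage fractions computed on such lengths are
#' lower bounds.
#'
#' @param lines character vector of file lines.
#' @return an [alignment_set()].
#' @export
parse_blast_tab <- function(lines) {
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0) return(alignment_set())
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) parse_error(i, sprintf("BLAST line has %d columns, expected >= 12", length(f)))
    co <- num_field(f[7:10], i, "coordinate")
    qs <- co[1] - 1; qe <- co[2]
    ss <- co[3]; se <- co[4]
    if (ss <= se) {
      strand <- "+"; ts <- ss - 1; te <- se
    } else {
      strand <- "-"; ts <- se - 1; te <- ss
    }
    qlen <- if (length(f) >= 13) num_field(f[13], i, "qlen") else NA_real_
    slen <- if (length(f) >= 14) num_field(f[14], i, "slen") else 0
    data.frame(
      query_name = f[1], query_length = qlen,
      query_start = qs, query_end = qe,
      target_name = f[2], target_length = slen,
      target_start = ts, target_end = te,
      strand = strand, stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  approx <- anyNA(df$query_length)
  if (approx) {
    max_end <- tapply(df$query_end, df$query_name, max)
    na <- is.na(df$query_length)
    df$query_length[na] <- as.numeric(max_end[df$query_name[na]])
    warning("BLAST input lacks a qlen column; query lengths approximated by max observed qend")
  }
  out <- new_aln_set(df, validate = FALSE)
  if (approx) attr(out, "approximate_query_length") <- TRUE
  out
}

#' Parse PSL (BLAT) lines
#'
#' PSL is 0-based half-open and its `qStart`/`qEnd` are always in the
#' forward query frame, so the 21-column rows map directly. The optional
#' 5-line `psLayout` header block is skipped.
#'
#' @param lines character vector of file lines.
#' @return an [alignment_set()].
#' @export
parse_psl <- function(lines) {
  start <- 1
  if (length(lines) > 0 && grepl("^psLayout", lines[1])) {
    start <- 6 # "psLayout version 3", blank, two column-name lines, dashes
  }
  idx <- seq.int(start, length.out = max(0, length(lines) - start + 1))
  keep <- idx[nzchar(lines[idx])]
  if (length(keep) == 0) return(alignment_set())
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 21) parse_error(i, sprintf("PSL line has %d columns, expected 21", length(f)))
    strand <- substr(f[9], 1, 1)
    if (!strand %in% c("+", "-")) parse_error(i, paste0("bad strand '", f[9], "'"))
    co <- num_field(f[c(11, 12, 13, 15, 16, 17)], i, "coordinate")
    data.frame(
      query_name = f[10], query_length = co[1],
      query_start = co[2], query_end = co[3],
      target_name = f[14], target_length = co[4],
      target_start = co[5], target_end = co[6],
      strand = strand, stringsAsFactors = FALSE
    )
  })
  new_aln_set(do.call(rbind, rows), validate = FALSE)
}

#' Parse MUMmer show-coords output (tab-delimited, with lengths)
#'
#' Expects the `show-coords -l -T` dialect: tab-separated data rows
#' `S1 E1 S2 E2 LEN1 LEN2 %IDY LENR LENQ refID qryID`, preceded by a file
#' banner, a program name line and optional `=====` separators, all of which
#' are skipped. The reference is the target. Coordinates are 1-based
#' inclusive; a descending query interval (`E2 < S2`) means reverse strand
#' and is normalised ascending.
#'
#' @param lines character vector of file lines.
#' @return an [alignment_set()].
#' @export
parse_coords <- function(lines) {
  rows <- list()
  in_data <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    numeric_row <- length(f) >= 11 &&
      !anyNA(suppressWarnings(as.numeric(f[1:9])))
    if (!numeric_row) {
      if (!in_data) next # banner / NUCMER / [S1] header / ===== lines
      parse_error(i, "non-numeric row inside data section")
    }
    in_data <- TRUE
    co <- as.numeric(f[1:9])
    s1 <- co[1]; e1 <- co[2]; s2 <- co[3]; e2 <- co[4]
    if (s2 <= e2) {
      strand <- "+"; qs <- s2 - 1; qe <- e2
    } else {
      strand <- "-"; qs <- e2 - 1; qe <- s2
    }
    rows[[length(rows) + 1]] <- data.frame(
      query_name = f[11], query_length = co[9],
      query_start = qs, query_end = qe,
      target_name = f[10], target_length = co[8],
      target_start = s1 - 1, target_end = e1,
      strand = strand, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(alignment_set())
  new_aln_set(do.call(rbind, rows), validate = FALSE)
}

#' Parse MUMmer show-tiling output
#'
#' `>` lines name the current reference and give its length; data rows carry
#' `start end gap contig_length coverage identity orientation contig_id`.
#' The format has no query coordinates, so the query interval is set to
#' `[0, contig_length)` and the returned set is flagged approximate
#' (attribute `approximate_query_interval`).
#'
#' @param lines character vector of file lines.
#' @return an [alignment_set()].
#' @export
parse_tiling <- function(lines) {
  rows <- list()
  ref <- NULL
  ref_len <- 0
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      f <- strsplit(sub("^>", "", line), "[ \t]+")[[1]]
      ref <- f[1]
      ref_len <- suppressWarnings(as.numeric(f[2]))
      if (is.na(ref_len)) ref_len <- 0
      next
    }
    if (is.null(ref)) parse_error(i, "tiling data row before any '>' reference line")
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) parse_error(i, sprintf("tiling row has %d columns, expected 8", length(f)))
    co <- num_field(f[c(1, 2, 4)], i, "coordinate")
    if (!f[7] %in% c("+", "-")) parse_error(i, paste0("bad orientation '", f[7], "'"))
    rows[[length(rows) + 1]] <- data.frame(
      query_name = f[8], query_length = co[3],
      query_start = 0, query_end = co[3],
      target_name = ref, target_length = ref_len,
      target_start = max(0, co[1] - 1), target_end = co[2],
      strand = f[7], stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(alignment_set())
  out <- new_aln_set(do.call(rbind, rows), validate = FALSE)
  attr(out, "approximate_query_interval") <- TRUE
  out
}
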