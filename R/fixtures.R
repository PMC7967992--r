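# Deterministic synthetic data: reference sequences, reads with planted
# chimeras, and alignment files in every supported format. Everything the
# test suite and the acceptance checks consume is generated here, so the
# whole pipeline is exercised without external datasets.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate a synthetic read set with planted chimeras
#'
#' Emulates the reference-guided long-read setting the chimera detector is
#' built for. References are uniform-random nucleotide sequences; each
#' ordinary read is a (possibly reverse-complemented) segment of one
#' reference, carrying a single alignment that covers the read apart from
#' small unaligned ends. A fraction of reads are chimeric: the
#' concatenation of segments from two distinct references. The two
#' alignments of a chimeric read are trimmed back from the junction on
#' either side (an aligner cannot anchor right up against a chimeric
#' breakpoint), leaving an unaligned gap that contains the true breakpoint.
#' By construction each chimeric alignment covers at least ~18% of the read
#' and the pair covers at least ~96%, so every planted read satisfies the
#' default detection thresholds, while every ordinary read fails them
#' (one real alignment, plus optional spurious alignments shorter than 1%
#' of the read that the default length filter removes).
#'
#' No sequencing-error model is applied: alignments are written from the
#' true read provenance, not recomputed by an aligner.
#'
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param n_targets number of reference sequences (default 3).
#' @param target_length_range min/max reference length in bp.
#' @param n_reads number of reads (default 200).
#' @param read_length_range min/max read length in bp.
#' @param chimera_fraction fraction of reads that are chimeric (default 0.1).
#' @param noise_rate per-read probability of one extra spurious alignment
#'   shorter than 1% of the read (default 0.2).
#' @param with_quality also generate per-base Phred qualities (FASTQ-style).
#' @return list with `reads` (a `DNAStringSet`, or
#'   `QualityScaledDNAStringSet` when `with_quality`), `alignments` (an
#'   `aln_set` including the noise records), `truth` (data frame of planted
#'   chimeras: `query_name`, `join_position` = the concatenation breakpoint,
#'   `gap_start`/`gap_end` bounding the unaligned junction gap,
#'   `left_target`, `right_target`), `targets` (data frame `name`/`length`)
#'   and `seed`.
#' @export
generate_fixture <- function(seed = 1, n_targets = 3,
                             target_length_range = c(30000, 60000),
                             n_reads = 200,
                             read_length_range = c(1000, 5000),
                             chimera_fraction = 0.1,
                             noise_rate = 0.2,
                             with_quality = FALSE) {
  stopifnot(n_targets >= 1, n_reads >= 0,
            chimera_fraction >= 0, chimera_fraction <= 1,
            noise_rate >= 0, noise_rate <= 1,
            diff(range(target_length_range)) >= 0,
            read_length_range[1] >= 200)
  if (chimera_fraction > 0 && n_targets < 2) {
    stop("planting chimeras needs at least two targets")
  }
  with_seed(seed, {
    tlen <- sample(target_length_range[1]:target_length_range[2], n_targets,
                   replace = TRUE)
    tnames <- sprintf("ref%02d", seq_len(n_targets))
    tseq <- vapply(tlen, random_dna, character(1))
    names(tseq) <- tnames
    if (max(tlen) < read_length_range[2]) {
      stop("targets shorter than the longest read; increase target_length_range")
    }

    n_chim <- round(chimera_fraction * n_reads)
    is_chim <- seq_len(n_reads) %in% sample.int(max(n_reads, 1), n_chim)
    seqs <- character(n_reads)
    aln_rows <- list()
    truth_rows <- list()

    for (i in seq_len(n_reads)) {
      rname <- sprintf("read%05d", i)
      rlen <- sample(read_length_range[1]:read_length_range[2], 1)
      if (!is_chim[i]) {
        ti <- sample.int(n_targets, 1)
        start <- sample.int(tlen[ti] - rlen + 1, 1) - 1 # 0-based
        strand <- sample(c("+", "-"), 1)
        seg <- substr(tseq[ti], start + 1, start + rlen)
        seqs[i] <- if (strand == "+") seg else revcomp_chr(seg)
        # unaligned read ends, up to 2% each
        d1 <- sample.int(max(1, floor(0.02 * rlen)), 1) - 1
        d2 <- sample.int(max(1, floor(0.02 * rlen)), 1) - 1
        ts <- if (strand == "+") start + d1 else start + d2
        te <- if (strand == "+") start + rlen - d2 else start + rlen - d1
        aln_rows[[length(aln_rows) + 1]] <- data.frame(
          query_name = rname, query_length = rlen,
          query_start = d1, query_end = rlen - d2,
          target_name = tnames[ti], target_length = tlen[ti],
          target_start = ts, target_end = te,
          strand = strand, stringsAsFactors = FALSE
        )
      } else {
        pair <- sample.int(n_targets, 2)
        f1 <- stats::runif(1, 0.2, 0.8) # each side >= 20% of the read
        l1 <- round(f1 * rlen)
        l2 <- rlen - l1
        s1 <- sample.int(tlen[pair[1]] - l1 + 1, 1) - 1
        s2 <- sample.int(tlen[pair[2]] - l2 + 1, 1) - 1
        seqs[i] <- paste0(substr(tseq[pair[1]], s1 + 1, s1 + l1),
                          substr(tseq[pair[2]], s2 + 1, s2 + l2))
        # trim back from the junction: 0.1-2% of read length each side
        d1 <- max(1, sample.int(floor(0.02 * rlen), 1))
        d2 <- max(1, sample.int(floor(0.02 * rlen), 1))
        aln_rows[[length(aln_rows) + 1]] <- data.frame(
          query_name = rname, query_length = rlen,
          query_start = 0, query_end = l1 - d1,
          target_name = tnames[pair[1]], target_length = tlen[pair[1]],
          target_start = s1, target_end = s1 + l1 - d1,
          strand = "+", stringsAsFactors = FALSE
        )
        aln_rows[[length(aln_rows) + 1]] <- data.frame(
          query_name = rname, query_length = rlen,
          query_start = l1 + d2, query_end = rlen,
          target_name = tnames[pair[2]], target_length = tlen[pair[2]],
          target_start = s2 + d2, target_end = s2 + l2,
          strand = "+", stringsAsFactors = FALSE
        )
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          query_name = rname, join_position = l1,
          gap_start = l1 - d1, gap_end = l1 + d2,
          left_target = tnames[pair[1]], right_target = tnames[pair[2]],
          stringsAsFactors = FALSE
        )
      }
      if (stats::runif(1) < noise_rate) {
        # spurious alignment, strictly shorter than 1% of the read
        span <- max(1, ceiling(0.01 * rlen) - 1)
        ti <- sample.int(n_targets, 1)
        qs <- sample.int(rlen - span + 1, 1) - 1
        ts <- sample.int(tlen[ti] - span + 1, 1) - 1
        aln_rows[[length(aln_rows) + 1]] <- data.frame(
          query_name = rname, query_length = rlen,
          query_start = qs, query_end = qs + span,
          target_name = tnames[ti], target_length = tlen[ti],
          target_start = ts, target_end = ts + span,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE
        )
      }
    }

    reads <- Biostrings::DNAStringSet(stats::setNames(
      seqs, sprintf("read%05d", seq_len(n_reads))))
    if (with_quality) {
      quals <- vapply(Biostrings::width(reads), function(w) {
        paste(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1]], w,
                     replace = TRUE), collapse = "")
      }, character(1))
      reads <- Biostrings::QualityScaledDNAStringSet(
        reads, Biostrings::PhredQuality(quals))
      attr(reads, "seq_format") <- "fastq"
    } else {
      attr(reads, "seq_format") <- "fasta"
    }
    aln <- if (length(aln_rows) > 0) {
      new_aln_set(do.call(rbind, aln_rows))
    } else alignment_set()
    truth <- if (length(truth_rows) > 0) {
      do.call(rbind, truth_rows)
    } else data.frame(query_name = character(), join_position = numeric(),
                      gap_start = numeric(), gap_end = numeric(),
                      left_target = character(), right_target = character(),
                      stringsAsFactors = FALSE)
    list(reads = reads, alignments = aln,
         truth = truth[order(truth$query_name), , drop = FALSE],
         targets = data.frame(name = tnames, length = as.numeric(tlen),
                              stringsAsFactors = FALSE),
         seed = seed)
  })
}

# Serialisers --------------------------------------------------------------
# Round-trip oracles for the parsers, and writers for fixture directories.
# Only the lossless formats are supported; MUMmer coords/tiling drop query
# detail and cannot represent an arbitrary record.

#' Write an alignment set in a supported format
#'
#' Serialises records such that the corresponding parser recovers them
#' exactly (the round-trip property the parser tests rely on). Supported:
#' `"paf"`, `"sam"`, `"blast"` (extended outfmt 6 with qlen/slen columns),
#' `"psl"`. The lossy MUMmer formats are refused.
#'
#' @param aln an `aln_set`.
#' @param format output format name.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, format, path) {
  switch(format,
    paf = write_paf(aln, path),
    sam = write_sam(aln, path),
    blast = write_blast_tab(aln, path),
    psl = write_psl(aln, path),
    stop("cannot serialise to lossy/unsupported format '", format, "'")
  )
}

fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' @rdname write_alignments
#' @export
write_paf <- function(aln, path) {
  span <- query_span(aln)
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t60",
                   aln$query_name, fmt_int(aln$query_length),
                   fmt_int(aln$query_start), fmt_int(aln$query_end),
                   aln$strand, aln$target_name, fmt_int(aln$target_length),
                   fmt_int(aln$target_start), fmt_int(aln$target_end),
                   fmt_int(pmin(span, target_span(aln))),
                   fmt_int(pmax(span, target_span(aln))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_alignments
#' @export
write_sam <- function(aln, path) {
  targets <- unique(aln[, c("target_name", "target_length")])
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%s", targets$target_name,
                      fmt_int(targets$target_length)))
  seen <- character()
  lines <- vapply(seq_len(nrow(aln)), function(i) {
    r <- aln[i, ]
    supplementary <- r$query_name %in% seen
    seen <<- c(seen, r$query_name)
    reverse <- r$strand == "-"
    flag <- 0L + if (reverse) 16L else 0L
    if (supplementary) flag <- flag + 2048L
    qspan <- r$query_end - r$query_start
    tspan <- r$target_end - r$target_start
    # clip lengths in the stored (reversed for '-') read frame
    lead <- if (reverse) r$query_length - r$query_end else r$query_start
    trail <- r$query_length - qspan - lead
    m <- min(qspan, tspan)
    mid <- if (tspan > qspan) {
      sprintf("%sM%sD%sM", fmt_int(floor(m / 2)), fmt_int(tspan - qspan),
              fmt_int(m - floor(m / 2)))
    } else if (qspan > tspan) {
      sprintf("%sM%sI%sM", fmt_int(floor(m / 2)), fmt_int(qspan - tspan),
              fmt_int(m - floor(m / 2)))
    } else {
      sprintf("%sM", fmt_int(m))
    }
    cigar <- paste0(if (lead > 0) paste0(fmt_int(lead), "S") else "",
                    mid,
                    if (trail > 0) paste0(fmt_int(trail), "S") else "")
    paste(r$query_name, flag, r$target_name, fmt_int(r$target_start + 1),
          "60", cigar, "*", "0", "0", "*", "*", sep = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_alignments
#' @export
write_blast_tab <- function(aln, path) {
  fwd <- aln$strand == "+"
  ss <- ifelse(fwd, aln$target_start + 1, aln$target_end)
  se <- ifelse(fwd, aln$target_end, aln$target_start + 1)
  lines <- sprintf("%s\t%s\t100.00\t%s\t0\t0\t%s\t%s\t%s\t%s\t0.0\t100\t%s\t%s",
                   aln$query_name, aln$target_name, fmt_int(query_span(aln)),
                   fmt_int(aln$query_start + 1), fmt_int(aln$query_end),
                   fmt_int(ss), fmt_int(se),
                   fmt_int(aln$query_length), fmt_int(aln$target_length))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_alignments
#' @param header write the 5-line `psLayout` header block (PSL only).
#' @export
write_psl <- function(aln, path, header = FALSE) {
  span <- query_span(aln)
  # block coordinates: qStarts are in the strand frame per the PSL spec
  qstart_frame <- ifelse(aln$strand == "+", aln$query_start,
                         aln$query_length - aln$query_end)
  lines <- sprintf(
    "%s\t0\t0\t0\t0\t0\t0\t0\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t1\t%s,\t%s,\t%s,",
    fmt_int(span), aln$strand,
    aln$query_name, fmt_int(aln$query_length),
    fmt_int(aln$query_start), fmt_int(aln$query_end),
    aln$target_name, fmt_int(aln$target_length),
    fmt_int(aln$target_start), fmt_int(aln$target_end),
    fmt_int(span), fmt_int(qstart_frame), fmt_int(aln$target_start)
  )
  if (header) {
    lines <- c(
      "psLayout version 3",
      "",
      paste0("match\tmis- \trep. \tN's\tQ gap\tQ gap\tT gap\tT gap\tstrand\tQ",
             "        \tQ   \tQ    \tQ  \tT        \tT   \tT    \tT  \tblock\tblockSizes \tqStarts\t tStarts"),
      paste0("     \tmatch\tmatch\t   \tcount\tbases\tcount\tbases\t      \tname",
             "     \tsize\tstart\tend\tname     \tsize\tstart\tend\tcount"),
      paste(rep("-", 100), collapse = ""),
      lines
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete fixture directory
#'
#' Materialises a generated fixture on disk: reads (FASTA, or FASTQ when the
#' fixture carries qualities), the alignments in each lossless format, the
#' planted-chimera truth table, and a manifest recording the seed.
#'
#' @param fixture output of [generate_fixture()].
#' @param dir output directory (created if needed).
#' @param formats alignment formats to write (default all lossless ones).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir,
                          formats = c("paf", "sam", "blast", "psl")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- attr(fixture$reads, "seq_format")
  ext <- if (identical(fmt, "fastq")) "fastq" else "fasta"
  paths <- c(reads = file.path(dir, paste0("reads.", ext)))
  write_reads(fixture$reads, paths[["reads"]])
  for (f in formats) {
    p <- file.path(dir, paste0("alignments.", f))
    write_alignments(fixture$alignments, f, p)
    paths[[f]] <- p
  }
  paths[["truth"]] <- file.path(dir, "truth.tsv")
  utils::write.table(fixture$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths[["manifest"]] <- file.path(dir, "manifest.txt")
  writeLines(c(sprintf("seed\t%d", fixture$seed),
               sprintf("n_reads\t%d", length(fixture$reads)),
               sprintf("n_chimeras\t%d", nrow(fixture$truth))),
             paths[["manifest"]])
  invisible(paths)
}
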