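two_aln <- function(qlen, s1, e1, s2, e2, t1 = "R1", t2 = "R2",
                    ts1 = NULL, ts2 = NULL) {
  span1 <- e1 - s1; span2 <- e2 - s2
  ts1 <- if (is.null(ts1)) 0 else ts1
  ts2 <- if (is.null(ts2)) 0 else ts2
  alignment_set(
    query_name = "read", query_length = qlen,
    query_start = c(s1, s2), query_end = c(e1, e2),
    target_name = c(t1, t2), target_length = 1e6,
    target_start = c(ts1, ts2), target_end = c(ts1 + span1, ts2 + span2),
    strand = "+"
  )
}

test_that("parameter invariants are enforced", {
  p <- chimera_params()
  expect_equal(p$min_total_coverage, 0.9)
  expect_equal(p$min_each_fraction, 0.1)
  expect_error(chimera_params(min_each_fraction = 0.6), "0, 0.5")
  expect_error(chimera_params(0.15, 0.1), "2\\*min_each_fraction")
  expect_error(chimera_params(1.2, 0.1), "<= 1")
})

test_that("the four textbook geometries classify as the rule dictates", {
  # two large alignments to different references covering nearly the whole
  # read: chimeric
  expect_false(is.null(classify_query(two_aln(10000, 100, 5000, 5100, 9950))))
  # overlapping query intervals: not chimeric
  expect_null(classify_query(two_aln(10000, 0, 6000, 5000, 10000)))
  # combined coverage too small: not chimeric
  expect_null(classify_query(two_aln(10000, 1000, 3000, 6000, 8000)))
  # one alignment under 10% of the read: not chimeric
  expect_null(classify_query(two_aln(10000, 0, 500, 600, 10000)))
})

test_that("the join is the floor midpoint of the unaligned gap", {
  call <- classify_query(two_aln(1000, 0, 480, 520, 1000, "T1", "T2"))
  expect_equal(call$join_position, 500) # floor((480 + 520) / 2)
  expect_equal(call$left_target, "T1")
  expect_equal(call$right_target, "T2")
  expect_false(call$same_target)

  # abutting intervals are non-overlapping; the join is the shared boundary
  abut <- classify_query(two_aln(1000, 0, 500, 500, 1000))
  expect_equal(abut$join_position, 500)

  # order of the records must not matter
  flipped <- two_aln(1000, 520, 1000, 0, 480, "T2", "T1")
  expect_equal(classify_query(flipped)$join_position, 500)
  expect_equal(classify_query(flipped)$left_target, "T1")
})

test_that("exactly-two is literal and same-target needs distinct sections", {
  three <- bind_alignments(two_aln(1000, 0, 480, 520, 1000),
                           alignment_set("read", 1000, 100, 200, "R3", 1e6,
                                         0, 100, "+"))
  expect_null(classify_query(three))
  expect_null(classify_query(two_aln(1000, 0, 480, 520, 1000)[1, ]))

  # same target, disjoint sections: called, flagged same_target
  st <- classify_query(two_aln(1000, 0, 480, 520, 1000, "R1", "R1",
                               ts1 = 0, ts2 = 10000))
  expect_true(st$same_target)
  # same target, overlapping sections: not a chimera
  expect_null(classify_query(two_aln(1000, 0, 480, 520, 1000, "R1", "R1",
                                     ts1 = 0, ts2 = 100)))

  bad <- two_aln(1000, 0, 480, 520, 1000)
  bad$query_length[2] <- 900
  expect_error(classify_query(bad), "disagree on query_length")
})

test_that("detection agrees with a per-base brute-force checker on random geometries", {
  set.seed(2024)
  n_checked <- 0
  for (rep in 1:25) {
    aln <- random_aln(80, n_queries = 40, qlen_range = c(200, 3000))
    got <- detect_chimeras(aln)
    want <- oracle_detect(aln)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$query_name,
                   vapply(want, function(x) x$query_name, character(1)))
      expect_equal(got$join_position,
                   vapply(want, function(x) x$join, numeric(1)))
      expect_equal(got$left_target,
                   vapply(want, function(x) x$targets[1], character(1)))
    }
    n_checked <- n_checked + 40
  }
  expect_gte(n_checked, 1000)
})

test_that("raising either threshold never increases the number of calls", {
  set.seed(77)
  aln <- random_aln(200, n_queries = 100, qlen_range = c(200, 2000))
  base <- nrow(detect_chimeras(aln, chimera_params(0.7, 0.05)))
  for (p in list(chimera_params(0.8, 0.05), chimera_params(0.9, 0.05),
                 chimera_params(0.7, 0.2), chimera_params(0.9, 0.3))) {
    expect_lte(nrow(detect_chimeras(aln, p)), base)
  }
})

test_that("same-target calls on excluded (circular) references are dropped", {
  circ <- two_aln(1000, 0, 480, 520, 1000, "chloro", "chloro",
                  ts1 = 0, ts2 = 10000)
  other <- alignment_set(
    query_name = "read2", query_length = 1000,
    query_start = c(0, 520), query_end = c(480, 1000),
    target_name = c("A", "B"), target_length = 1e6,
    target_start = c(0, 0), target_end = c(480, 480), strand = "+"
  )
  aln <- bind_alignments(circ, other)
  expect_equal(nrow(detect_chimeras(aln)), 2)
  kept <- detect_chimeras(aln, exclude_targets = "chloro")
  expect_equal(kept$query_name, "read2")
})

test_that("the report is four tab-separated columns and round-trips", {
  call <- classify_query(two_aln(1000, 0, 480, 520, 1000, "T1", "T2"))
  p <- withr::local_tempfile(fileext = ".txt")
  write_chimera_report(call, p)
  expect_equal(readLines(p), "read\t500\tT1\tT2")

  same <- classify_query(two_aln(1000, 0, 480, 520, 1000, "T", "T",
                                 ts1 = 0, ts2 = 10000))
  write_chimera_report(same, p)
  f <- strsplit(readLines(p), "\t")[[1]]
  expect_equal(f[3:4], c("T", "T"))

  write_chimera_report(detect_chimeras(alignment_set()), p)
  expect_length(readLines(p), 0)
  expect_equal(nrow(read_chimera_report(p)), 0)
})

test_that("splitting conserves bases and leaves unnamed reads untouched", {
  fix <- generate_fixture(seed = 31, n_reads = 60, chimera_fraction = 0.15,
                          with_quality = TRUE)
  calls <- detect_chimeras(filter_min_length(fix$alignments))
  out <- split_chimeric_reads(fix$reads, calls)

  expect_equal(length(out), length(fix$reads) + nrow(calls))
  expect_equal(sum(Biostrings::width(out)), sum(Biostrings::width(fix$reads)))
  # each split pair re-concatenates to the original read
  for (q in calls$query_name) {
    left <- as.character(out[[paste0(q, "_left")]])
    right <- as.character(out[[paste0(q, "_right")]])
    expect_equal(paste0(left, right), as.character(fix$reads[[q]]))
  }
  # untouched reads are identical, qualities stay in register
  untouched <- setdiff(names(fix$reads), calls$query_name)
  expect_equal(as.character(out[untouched]), as.character(fix$reads[untouched]))
  expect_equal(unname(Biostrings::width(Biostrings::quality(out))),
               unname(Biostrings::width(out)))
})

test_that("split error paths: absent reads warn, out-of-range joins abort", {
  reads <- Biostrings::DNAStringSet(c(r1 = "ACGTACGTAC"))
  ghost <- data.frame(query_name = "nope", join_position = 5)
  expect_warning(out <- split_chimeric_reads(reads, ghost), "absent")
  expect_equal(as.character(out), as.character(reads))

  bad <- data.frame(query_name = "r1", join_position = 10)
  expect_error(split_chimeric_reads(reads, bad), "outside read")
})

test_that("file-level splitting preserves the FASTQ format byte layout", {
  fix <- generate_fixture(seed = 13, n_reads = 30, chimera_fraction = 0.2,
                          with_quality = TRUE)
  dir <- withr::local_tempdir()
  reads_p <- file.path(dir, "reads.fastq")
  write_reads(fix$reads, reads_p)
  report_p <- file.path(dir, "chimeras.txt")
  write_chimera_report(detect_chimeras(filter_min_length(fix$alignments)),
                       report_p)
  out_p <- file.path(dir, "split.fastq")
  split_reads_file(reads_p, report_p, out_p)

  out_lines <- readLines(out_p)
  expect_equal(length(out_lines) %% 4, 0)
  # non-chimeric reads appear byte-identical in their four-line blocks
  orig <- readLines(reads_p)
  calls <- read_chimera_report(report_p)
  keep <- !(sub("^@", "", orig[seq(1, length(orig), 4)]) %in% calls$query_name)
  orig_blocks <- split(orig, rep(seq_len(length(orig) / 4), each = 4))
  out_blocks <- split(out_lines, rep(seq_len(length(out_lines) / 4), each = 4))
  orig_keep <- unlist(orig_blocks[keep], use.names = FALSE)
  expect_true(all(vapply(orig_blocks[keep], function(b) {
    any(vapply(out_blocks, identical, logical(1), y = b))
  }, logical(1))))
})
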