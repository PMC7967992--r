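# Independent oracles: deliberately naive re-implementations of the rules,
# written against per-base masks or exhaustive loops so they share no code
# with the package internals they check.

random_aln <- function(n, n_queries = max(1, n %/% 2), n_targets = 3,
                       qlen_range = c(100, 5000)) {
  qn <- sprintf("q%03d", sample.int(n_queries, n, replace = TRUE))
  qlen <- stats::setNames(
    sample(qlen_range[1]:qlen_range[2], n_queries, replace = TRUE),
    sprintf("q%03d", seq_len(n_queries)))
  tlen <- stats::setNames(sample(5000:20000, n_targets, replace = TRUE),
                          sprintf("t%02d", seq_len(n_targets)))
  tn <- sample(names(tlen), n, replace = TRUE)
  qs <- qe <- ts <- te <- numeric(n)
  for (i in seq_len(n)) {
    b <- sort(sample.int(qlen[qn[i]] + 1, 2) - 1)
    while (b[1] == b[2]) b <- sort(sample.int(qlen[qn[i]] + 1, 2) - 1)
    qs[i] <- b[1]; qe[i] <- b[2]
    span <- min(qe[i] - qs[i], tlen[tn[i]])
    ts[i] <- sample.int(tlen[tn[i]] - span + 1, 1) - 1
    te[i] <- ts[i] + span
  }
  alignment_set(
    query_name = qn, query_length = as.numeric(qlen[qn]),
    query_start = qs, query_end = qe,
    target_name = tn, target_length = as.numeric(tlen[tn]),
    target_start = ts, target_end = te,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

# chimera rule via per-base query masks
oracle_classify <- function(df, min_total = 0.9, min_each = 0.1) {
  if (nrow(df) != 2) return(NULL)
  L <- df$query_length[1]
  mask <- function(s, e) { m <- logical(L); if (e > s) m[(s + 1):e] <- TRUE; m }
  m1 <- mask(df$query_start[1], df$query_end[1])
  m2 <- mask(df$query_start[2], df$query_end[2])
  if (any(m1 & m2)) return(NULL)
  if (df$target_name[1] == df$target_name[2]) {
    TL <- max(df$target_end)
    tmask <- function(s, e) { m <- logical(TL); m[(s + 1):e] <- TRUE; m }
    if (any(tmask(df$target_start[1], df$target_end[1]) &
            tmask(df$target_start[2], df$target_end[2]))) return(NULL)
  }
  if (sum(m1) + sum(m2) < min_total * L) return(NULL)
  if (min(sum(m1), sum(m2)) < min_each * L) return(NULL)
  first <- which.min(df$query_start)
  left <- df[first, ]; right <- df[-first, ]
  list(query_name = df$query_name[1],
       join = floor((left$query_end + right$query_start) / 2),
       targets = c(left$target_name, right$target_name))
}

oracle_detect <- function(aln, min_total = 0.9, min_each = 0.1) {
  res <- lapply(unique(aln$query_name), function(q) {
    oracle_classify(as.data.frame(aln[aln$query_name == q, ]),
                    min_total, min_each)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  res[order(vapply(res, function(x) x$query_name, character(1)))]
}

oracle_filter <- function(aln, min_fraction) {
  keep <- logical(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    keep[i] <- (aln$query_end[i] - aln$query_start[i]) >=
      min_fraction * aln$query_length[i]
  }
  as.data.frame(aln)[keep, ]
}

# exhaustive greedy dedup: repeatedly take the largest remaining target
# span (earliest on ties) that clashes with nothing accepted
oracle_dedup <- function(df) {
  remaining <- seq_len(nrow(df))
  accepted <- integer()
  while (length(remaining) > 0) {
    spans <- df$target_end[remaining] - df$target_start[remaining]
    pick <- remaining[which.max(spans)] # which.max takes the first on ties
    clash <- FALSE
    for (a in accepted) {
      if (df$target_name[a] == df$target_name[pick] &&
          df$target_start[a] < df$target_end[pick] &&
          df$target_end[a] > df$target_start[pick]) clash <- TRUE
    }
    if (!clash) accepted <- c(accepted, pick)
    remaining <- setdiff(remaining, pick)
  }
  sort(accepted)
}

# per-base pileup depth over one target
oracle_pileup <- function(df, target_length) {
  depth <- integer(target_length)
  for (i in seq_len(nrow(df))) {
    idx <- (df$target_start[i] + 1):df$target_end[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

expect_same_records <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b),
               ignore_attr = TRUE)
}

svg_elements <- function(svg, name) {
  xml2::xml_find_all(xml2::read_xml(svg),
                     sprintf("//*[local-name()='%s']", name))
}
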