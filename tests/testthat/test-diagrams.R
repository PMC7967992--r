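census <- function(cmds) {
  tab <- command_census(cmds)
  stats::setNames(as.integer(tab), names(tab))
}

test_that("alignment diagram census: one bar, one rectangle and line per alignment", {
  aln <- alignment_set(
    query_name = c("qa", "qb"), query_length = c(2000, 3000),
    query_start = c(100, 0), query_end = c(600, 2900),
    target_name = "T1", target_length = 10000,
    target_start = c(500, 4000), target_end = c(1000, 6900), strand = "+"
  )
  lay <- layout_alignment_diagram(aln)
  expect_named(lay, "T1")
  cs <- census(lay$T1)
  expect_equal(cs[["target_bar"]], 1)
  expect_equal(cs[["alignment"]], 2)
  expect_equal(cs[["query_line"]], 2)

  expect_length(layout_alignment_diagram(alignment_set()), 0)
})

test_that("rows are ordered by query then by target start position", {
  aln <- alignment_set(
    query_name = "qa", query_length = 5000,
    query_start = c(0, 2500), query_end = c(2000, 4500),
    target_name = "T", target_length = 10000,
    target_start = c(5000, 1000), target_end = c(7000, 3000), strand = "+"
  )
  cmds <- layout_alignment_diagram(aln)$T
  rects <- cmds[cmds$role == "alignment", ]
  # the record starting at 1000 on the target is drawn in the first row
  expect_lt(rects$x[1], rects$x[2])
  expect_lt(rects$y[1], rects$y[2])
})

test_that("query-extent lines are clipped to the canvas with a marker", {
  # a huge query aligned to a tiny interval would extend far off-canvas
  aln <- alignment_set("q", 1e6, 499000, 500000, "T", 2000, 500, 1500, "+")
  cmds <- layout_alignment_diagram(aln)$T
  line <- cmds[cmds$role == "query_line", ]
  canvas <- attr(cmds, "canvas")
  expect_gte(line$x, 0)
  expect_lte(line$x2, canvas[["width"]])
  expect_equal(census(cmds)[["clip_marker"]], 2)
})

test_that("contig diagram draws at most ten alignments and flags chimeras", {
  twelve <- alignment_set(
    query_name = "big", query_length = 13000,
    query_start = (0:11) * 1000, query_end = (0:11) * 1000 + 500 + (0:11),
    target_name = sprintf("t%02d", 1:12), target_length = 20000,
    target_start = 0, target_end = 500 + (0:11), strand = "+"
  )
  cs <- census(layout_contig_alignment_diagram(twelve))
  expect_equal(cs[["alignment"]], 10)
  # the ten longest survive: spans 502..511, not 500/501
  cmds <- layout_contig_alignment_diagram(twelve)
  widths <- sort(cmds$w[cmds$role == "alignment"])
  expect_equal(widths, sort((502:511) * 1000 / 13000), tolerance = 1e-9)

  fix <- generate_fixture(seed = 21, n_reads = 12, chimera_fraction = 0.1)
  aln <- filter_min_length(fix$alignments)
  calls <- detect_chimeras(aln)
  expect_equal(nrow(calls), 1)
  cs2 <- census(layout_contig_alignment_diagram(aln, calls))
  expect_equal(cs2[["chimera_mark"]], 1)
  expect_equal(cs2[["query_box"]], 12)

  only <- layout_contig_alignment_diagram(aln, calls, chimeras_only = TRUE)
  cs3 <- census(only)
  expect_equal(cs3[["query_box"]], 1)
  expect_false("chimera_mark" %in% names(cs3))

  none <- layout_contig_alignment_diagram(aln, detect_chimeras(alignment_set()),
                                          chimeras_only = TRUE)
  expect_equal(nrow(none), 0)
})

test_that("gradient shading encodes orientation", {
  aln <- alignment_set(
    query_name = "q", query_length = 1000,
    query_start = c(0, 520), query_end = c(480, 1000),
    target_name = "T", target_length = 5000,
    target_start = c(0, 1000), target_end = c(480, 1480),
    strand = c("+", "-")
  )
  cmds <- layout_contig_alignment_diagram(aln)
  rects <- cmds[cmds$role == "alignment", ]
  # forward runs light-to-dark, reverse dark-to-light: mirrored pairs
  expect_equal(rects$grad_from[1], rects$grad_to[2])
  expect_equal(rects$grad_to[1], rects$grad_from[2])
})

test_that("coverage map cells wrap square and stay in bin order when long", {
  track <- coverage_track(alignment_set(), 1000, 100, target_name = "T")
  track$counts <- c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L)

  long <- layout_coverage_map(track, "long")
  cells <- long[long$role == "cell", ]
  expect_equal(nrow(cells), 10)
  expect_true(all(diff(cells$x) > 0))
  # max count is full red, zero count white
  expect_equal(cells$fill[10], "#FF0000")
  expect_equal(cells$fill[1], "#FFFFFF")

  sq <- layout_coverage_map(track, "square")
  sq_cells <- sq[sq$role == "cell", ]
  expect_equal(nrow(sq_cells), 10) # 4x4 grid, last 6 cells absent
  expect_equal(length(unique(sq_cells$y)), 3) # ceil(10/4) rows
  expect_equal(sum(sq_cells$y == min(sq_cells$y)), 4)

  # uniform counts paint every cell the same colour
  track$counts <- rep(3L, 10)
  uni <- layout_coverage_map(track, "long")
  expect_length(unique(uni$fill[uni$role == "cell"]), 1)

  # all-zero track renders in the zero colour without dividing by zero
  track$counts <- rep(0L, 10)
  zero <- layout_coverage_map(track, "long")
  expect_equal(unique(zero$fill[zero$role == "cell"]), "#FFFFFF")
})

test_that("genome coverage draws one constant-size cell per bin plus labels", {
  aln <- alignment_set(
    query_name = c("a", "b"), query_length = 10000,
    query_start = 0, query_end = c(500, 700),
    target_name = c("T1", "T2"), target_length = 1000,
    target_start = c(0, 100), target_end = c(500, 800), strand = "+"
  )
  gc <- genome_coverage(aln, data.frame(name = c("T1", "T2"),
                                        length = c(1000, 1000)),
                        total_bins = 20)
  cmds <- layout_genome_coverage(gc)
  cs <- census(cmds)
  expect_equal(cs[["cell"]], 20)
  expect_equal(cs[["target_label"]], 2)
  cells <- cmds[cmds$role == "cell", ]
  expect_length(unique(round(cells$w, 9)), 1)

  empty <- genome_coverage(alignment_set(),
                           data.frame(name = character(), length = numeric()))
  expect_equal(nrow(layout_genome_coverage(empty)), 0)
})

test_that("all geometry stays inside the declared canvas on random inputs", {
  set.seed(404)
  for (rep in 1:5) {
    aln <- random_aln(30, n_queries = 10)
    layouts <- c(
      layout_alignment_diagram(aln),
      list(layout_contig_alignment_diagram(aln, detect_chimeras(aln))),
      lapply(coverage_map_tracks(aln, bins = 64), layout_coverage_map, shape = "square"),
      list(layout_genome_coverage(genome_coverage(aln, total_bins = 50)))
    )
    for (cmds in layouts) {
      canvas <- attr(cmds, "canvas")
      rect <- cmds[cmds$kind == "rectangle", ]
      expect_true(all(rect$x >= 0 & rect$x + rect$w <= canvas[["width"]] + 1e-9))
      expect_true(all(rect$y >= 0 & rect$y + rect$h <= canvas[["height"]] + 1e-9))
      lines <- cmds[cmds$kind == "line", ]
      expect_true(all(c(lines$x, lines$x2) >= 0 &
                        c(lines$x, lines$x2) <= canvas[["width"]]))
    }
  }
})

test_that("SVG output is well-formed, censused and byte-deterministic", {
  fix <- generate_fixture(seed = 77, n_reads = 25, chimera_fraction = 0.2)
  aln <- filter_min_length(fix$alignments)
  cmds <- layout_contig_alignment_diagram(aln, detect_chimeras(aln))
  svg <- render_svg(cmds)
  doc <- xml2::read_xml(svg) # parses as XML
  expect_equal(xml2::xml_name(doc), "svg")
  n_rect_cmds <- sum(cmds$kind == "rectangle")
  expect_length(svg_elements(svg, "rect"), n_rect_cmds)
  expect_identical(render_svg(cmds), svg)

  one <- layout_coverage_map(coverage_track(alignment_set(), 100, 100,
                                            target_name = "t"), "long")
  expect_length(svg_elements(render_svg(one), "rect"), 1)
})

test_that("TeX output is a standalone TikZ document with matched environments", {
  fix <- generate_fixture(seed = 77, n_reads = 10, chimera_fraction = 0.2)
  aln <- filter_min_length(fix$alignments)
  cmds <- layout_contig_alignment_diagram(aln, detect_chimeras(aln))
  tex <- render_tex(cmds)
  expect_match(tex, "\\\\documentclass\\[tikz\\]\\{standalone\\}")
  expect_match(tex, "\\\\begin\\{tikzpicture\\}")
  expect_equal(lengths(regmatches(tex, gregexpr("\\\\begin\\{", tex))),
               lengths(regmatches(tex, gregexpr("\\\\end\\{", tex))))
  expect_identical(render_tex(cmds), tex)
  # underscores in sequence names must be escaped for TeX
  expect_false(grepl("[^\\\\]_", gsub("\\\\_", "", tex)))
})
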