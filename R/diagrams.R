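# Backend-neutral drawing primitives ------------------------------------
#
# A layout produces a data frame of draw commands; a renderer (SVG or TikZ)
# turns them into a document. Command order is paint order. Geometry is in
# abstract canvas units; the canvas size travels as an attribute.

CMD_COLS <- c("kind", "role", "x", "y", "w", "h", "x2", "y2",
              "text", "fill", "stroke", "grad_from", "grad_to",
              "font_size", "points")

empty_commands <- function(width = 1040, height = 40) {
  df <- data.frame(
    kind = character(), role = character(),
    x = numeric(), y = numeric(), w = numeric(), h = numeric(),
    x2 = numeric(), y2 = numeric(), text = character(),
    fill = character(), stroke = character(),
    grad_from = character(), grad_to = character(),
    font_size = numeric(), points = character(),
    stringsAsFactors = FALSE
  )
  set_canvas(df, width, height)
}

set_canvas <- function(cmds, width, height) {
  attr(cmds, "canvas") <- c(width = width, height = height)
  class(cmds) <- c("draw_commands", "data.frame")
  cmds
}

cmd_row <- function(kind, role, x = NA, y = NA, w = NA, h = NA,
                    x2 = NA, y2 = NA, text = NA, fill = NA, stroke = NA,
                    grad_from = NA, grad_to = NA, font_size = NA,
                    points = NA) {
  data.frame(
    kind = kind, role = role,
    x = as.numeric(x), y = as.numeric(y),
    w = as.numeric(w), h = as.numeric(h),
    x2 = as.numeric(x2), y2 = as.numeric(y2),
    text = as.character(text), fill = as.character(fill),
    stroke = as.character(stroke),
    grad_from = as.character(grad_from), grad_to = as.character(grad_to),
    font_size = as.numeric(font_size), points = as.character(points),
    stringsAsFactors = FALSE
  )
}

cmd_rect <- function(role, x, y, w, h, fill = NA, stroke = NA,
                     grad_from = NA, grad_to = NA) {
  cmd_row("rectangle", role, x = x, y = y, w = w, h = h, fill = fill,
          stroke = stroke, grad_from = grad_from, grad_to = grad_to)
}

cmd_line <- function(role, x, y, x2, y2, stroke = "#000000") {
  cmd_row("line", role, x = x, y = y, x2 = x2, y2 = y2, stroke = stroke)
}

cmd_text <- function(role, x, y, text, font_size = 11, fill = "#000000") {
  cmd_row("text", role, x = x, y = y, text = text, font_size = font_size,
          fill = fill)
}

cmd_polygon <- function(role, points, fill = "#000000") {
  cmd_row("polygon", role, points = points, fill = fill)
}

bind_commands <- function(cmds, width, height) {
  cmds <- cmds[!vapply(cmds, is.null, logical(1))]
  if (length(cmds) == 0) return(empty_commands(width, height))
  set_canvas(do.call(rbind, cmds), width, height)
}

#' Count draw commands by role
#'
#' Layout output carries a semantic `role` per primitive (`target_bar`,
#' `alignment`, `query_line`, `cell`, `chimera_mark`, ...); this tabulates
#' them, which is how the layout tests assert an exact census.
#'
#' @param cmds a `draw_commands` data frame.
#' @return named integer vector of counts.
#' @export
command_census <- function(cmds) {
  table(cmds$role)
}

# visual constants --------------------------------------------------------

DIAGRAM_X0 <- 20      # left margin, canvas units
DIAGRAM_SPAN <- 1000  # drawable width representing the scaled sequence
DIAGRAM_W <- 1040

TARGET_BAR_COLOUR <- "#CC0000"
ALIGNMENT_COLOUR <- "#4878A8"

# 12-colour qualitative palette for target identity, recycled beyond 12
TARGET_PALETTE <- c(
  "#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD", "#8C564B",
  "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF", "#AA40FC", "#B5BD61"
)

target_colour <- function(target, all_targets) {
  TARGET_PALETTE[(match(target, all_targets) - 1) %% length(TARGET_PALETTE) + 1]
}

# mix a hex colour with white (amount in [0,1], 1 = white)
lighten <- function(hex, amount = 0.6) {
  rgb <- grDevices::col2rgb(hex)
  mixed <- round(rgb + (255 - rgb) * amount)
  grDevices::rgb(mixed[1, ], mixed[2, ], mixed[3, ], maxColorValue = 255)
}

# white -> red heat scale; max_count 0 renders the zero colour everywhere
heat_colour <- function(count, max_count) {
  f <- if (max_count > 0) count / max_count else 0
  g <- round(255 * (1 - f))
  grDevices::rgb(255, g, g, maxColorValue = 255)
}

# Alignment diagram -------------------------------------------------------

#' Lay out the alignment diagram (alignments along each target)
#'
#' One diagram per target: the target is a red bar at the top, scaled to the
#' drawable width; each alignment is a rectangle below it, in line with its
#' position on the target. Rows are ordered by query name and, within one
#' query, by the alignment's start position on the target. Through each
#' rectangle runs a line showing the full extent of the query sequence,
#' placed so that the aligned query interval coincides with the rectangle;
#' where that line would leave the canvas it is clipped and terminated with
#' an arrow marker.
#'
#' @param aln an `aln_set`.
#' @return named list (one entry per target, in order of first appearance)
#'   of `draw_commands` data frames.
#' @export
layout_alignment_diagram <- function(aln) {
  lapply(alignments_by(aln, "target"), layout_alignment_one_target)
}

layout_alignment_one_target <- function(recs) {
  tinfo <- observed_targets(recs)
  tlen <- tinfo$length[1]
  scale <- DIAGRAM_SPAN / tlen
  recs <- recs[order(recs$query_name, recs$target_start), , drop = FALSE]
  n <- nrow(recs)
  row_h <- 16
  y0 <- 56
  height <- y0 + n * row_h + 20
  cmds <- list(
    cmd_text("title", DIAGRAM_X0, 18, tinfo$name[1], font_size = 13),
    cmd_rect("target_bar", DIAGRAM_X0, 28, DIAGRAM_SPAN, 14,
             fill = TARGET_BAR_COLOUR)
  )
  for (i in seq_len(n)) {
    r <- recs[i, ]
    y <- y0 + (i - 1) * row_h
    rx <- DIAGRAM_X0 + r$target_start * scale
    rw <- (r$target_end - r$target_start) * scale
    cmds[[length(cmds) + 1]] <- cmd_rect("alignment", rx, y, rw, 8,
                                         fill = ALIGNMENT_COLOUR)
    # query-extent line at the rectangle's bp-per-unit scale
    ppu <- rw / (r$query_end - r$query_start)
    left_bp <- if (r$strand == "+") r$query_start else r$query_length - r$query_end
    right_bp <- if (r$strand == "+") r$query_length - r$query_end else r$query_start
    lx <- rx - left_bp * ppu
    rx2 <- rx + rw + right_bp * ppu
    ly <- y + 4
    clip_l <- lx < DIAGRAM_X0
    clip_r <- rx2 > DIAGRAM_X0 + DIAGRAM_SPAN
    lx <- max(lx, DIAGRAM_X0)
    rx2 <- min(rx2, DIAGRAM_X0 + DIAGRAM_SPAN)
    cmds[[length(cmds) + 1]] <- cmd_line("query_line", lx, ly, rx2, ly)
    if (clip_l) {
      cmds[[length(cmds) + 1]] <- cmd_polygon("clip_marker", arrow_points(lx, ly, -1))
    }
    if (clip_r) {
      cmds[[length(cmds) + 1]] <- cmd_polygon("clip_marker", arrow_points(rx2, ly, 1))
    }
  }
  bind_commands(cmds, DIAGRAM_W, height)
}

arrow_points <- function(x, y, dir) {
  tip <- x + dir * 6
  sprintf("%s,%s %s,%s %s,%s",
          fmt_num(x), fmt_num(y - 3), fmt_num(tip), fmt_num(y),
          fmt_num(x), fmt_num(y + 3))
}

# Contig alignment diagram -------------------------------------------------

#' Lay out the contig alignment diagram (alignments inside each query)
#'
#' Each query sequence is an outlined rectangle scaled to its length; inside
#' it, up to the ten longest alignments (by query span; ties by input order)
#' are drawn at their query intervals, filled with a colour keyed to the
#' target sequence and shaded by a gradient that encodes target position and
#' orientation: the light end of the gradient sits at the lower target
#' coordinate, so a forward alignment runs light-to-dark left-to-right and a
#' reverse alignment the other way. Queries flagged as chimeric carry a `C`
#' next to their rectangle; with `chimeras_only` every other query is
#' omitted and the `C` is suppressed.
#'
#' @param aln an `aln_set`.
#' @param chimera_calls data frame from [detect_chimeras()], or `NULL`.
#' @param chimeras_only draw only the flagged queries.
#' @param max_alignments alignments drawn per query (default 10).
#' @return a `draw_commands` data frame.
#' @export
layout_contig_alignment_diagram <- function(aln, chimera_calls = NULL,
                                            chimeras_only = FALSE,
                                            max_alignments = 10) {
  chimeric <- if (is.null(chimera_calls)) character() else chimera_calls$query_name
  groups <- alignments_by(aln, "query")
  if (chimeras_only) groups <- groups[names(groups) %in% chimeric]
  if (length(groups) == 0) return(empty_commands(DIAGRAM_W, 40))

  all_targets <- unique(aln$target_name)
  max_qlen <- max(vapply(groups, function(g) g$query_length[1], numeric(1)))
  scale <- DIAGRAM_SPAN / max_qlen
  box_h <- 24
  sec_h <- box_h + 26
  cmds <- list()
  y <- 20
  for (qname in names(groups)) {
    g <- groups[[qname]]
    qlen <- g$query_length[1]
    cmds[[length(cmds) + 1]] <- cmd_text("query_label", DIAGRAM_X0, y + 12, qname)
    box_y <- y + 18
    cmds[[length(cmds) + 1]] <- cmd_rect("query_box", DIAGRAM_X0, box_y,
                                         qlen * scale, box_h,
                                         stroke = "#000000")
    ord <- order(-query_span(g), seq_len(nrow(g)))
    show <- sort(ord[seq_len(min(max_alignments, nrow(g)))])
    for (i in show) {
      r <- g[i, ]
      base <- target_colour(r$target_name, all_targets)
      light <- lighten(base)
      from <- if (r$strand == "+") light else base
      to <- if (r$strand == "+") base else light
      cmds[[length(cmds) + 1]] <- cmd_rect(
        "alignment",
        DIAGRAM_X0 + r$query_start * scale, box_y + 3,
        (r$query_end - r$query_start) * scale, box_h - 6,
        grad_from = from, grad_to = to
      )
    }
    if (!chimeras_only && qname %in% chimeric) {
      cmds[[length(cmds) + 1]] <- cmd_text(
        "chimera_mark", DIAGRAM_X0 + qlen * scale + 8, box_y + box_h - 7,
        "C", font_size = 14, fill = TARGET_BAR_COLOUR
      )
    }
    y <- y + sec_h
  }
  # legend: one swatch + label per target, in palette order
  y <- y + 6
  x <- DIAGRAM_X0
  for (t in all_targets) {
    cmds[[length(cmds) + 1]] <- cmd_rect("legend_swatch", x, y, 14, 10,
                                         fill = target_colour(t, all_targets))
    cmds[[length(cmds) + 1]] <- cmd_text("legend_label", x + 18, y + 9, t,
                                         font_size = 10)
    x <- x + 22 + 7 * nchar(t)
    if (x > DIAGRAM_X0 + DIAGRAM_SPAN - 80) {
      x <- DIAGRAM_X0
      y <- y + 16
    }
  }
  bind_commands(cmds, DIAGRAM_W, y + 30)
}

# Coverage diagrams --------------------------------------------------------

#' Lay out a coverage heat map for one target
#'
#' One filled cell per bin, coloured on a white-to-red scale normalised to
#' the track's maximum count (an all-zero track renders in the zero colour).
#' The `square` shape wraps the bins row-major into an n-by-n grid with
#' `n = ceiling(sqrt(bins))`; the `long` shape is a single row.
#'
#' @param track a [coverage_track()].
#' @param shape `"square"` or `"long"`.
#' @return a `draw_commands` data frame.
#' @export
layout_coverage_map <- function(track, shape = c("square", "long")) {
  shape <- match.arg(shape)
  n_bins <- length(track$counts)
  stopifnot(n_bins >= 1)
  max_c <- max(track$counts)
  cmds <- list(cmd_text("title", DIAGRAM_X0, 18, track$target_name,
                        font_size = 13))
  y0 <- 28
  if (shape == "square") {
    n <- ceiling(sqrt(n_bins))
    cell <- DIAGRAM_SPAN / n
    for (b in seq_len(n_bins)) {
      row <- (b - 1) %/% n
      col <- (b - 1) %% n
      cmds[[length(cmds) + 1]] <- cmd_rect(
        "cell", DIAGRAM_X0 + col * cell, y0 + row * cell, cell, cell,
        fill = heat_colour(track$counts[b], max_c)
      )
    }
    height <- y0 + ceiling(n_bins / n) * cell + 20
  } else {
    cell <- DIAGRAM_SPAN / n_bins
    bar_h <- 40
    for (b in seq_len(n_bins)) {
      cmds[[length(cmds) + 1]] <- cmd_rect(
        "cell", DIAGRAM_X0 + (b - 1) * cell, y0, cell, bar_h,
        fill = heat_colour(track$counts[b], max_c)
      )
    }
    height <- y0 + bar_h + 20
  }
  bind_commands(cmds, DIAGRAM_W, height)
}

#' Lay out the whole-genome coverage heat map
#'
#' All targets are rendered in order as one contiguous run of constant-size
#' cells (one per bin, shared bin size), with a label under each target's
#' segment. The heat scale is normalised jointly over all targets, so the
#' same colour means the same coverage on every chromosome.
#'
#' @param gc a [genome_coverage()].
#' @return a `draw_commands` data frame.
#' @export
layout_genome_coverage <- function(gc) {
  if (length(gc$tracks) == 0) return(empty_commands(DIAGRAM_W, 40))
  total_bins <- sum(vapply(gc$tracks, function(t) length(t$counts), numeric(1)))
  max_c <- max(vapply(gc$tracks, function(t) max(t$counts, 0), numeric(1)))
  cell <- DIAGRAM_SPAN / total_bins
  y0 <- 28
  bar_h <- 30
  cmds <- list()
  offset <- 0
  for (k in seq_along(gc$tracks)) {
    t <- gc$tracks[[k]]
    nb <- length(t$counts)
    for (b in seq_len(nb)) {
      cmds[[length(cmds) + 1]] <- cmd_rect(
        "cell", DIAGRAM_X0 + (offset + b - 1) * cell, y0, cell, bar_h,
        fill = heat_colour(t$counts[b], max_c)
      )
    }
    mid <- DIAGRAM_X0 + (offset + nb / 2) * cell
    lab_y <- y0 + bar_h + 14 + 12 * ((k - 1) %% 2) # alternate rows
    cmds[[length(cmds) + 1]] <- cmd_text("target_label", mid, lab_y,
                                         t$target_name, font_size = 10)
    offset <- offset + nb
  }
  bind_commands(cmds, DIAGRAM_W, y0 + bar_h + 50)
}
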