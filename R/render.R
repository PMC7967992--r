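# Renderers: draw commands -> SVG or TikZ documents.
# Both are byte-deterministic for a fixed command list.

fmt_num <- function(x) {
  s <- sprintf("%.2f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render draw commands
#'
#' @param cmds a `draw_commands` data frame from one of the `layout_*`
#'   functions.
#' @param backend `"svg"` or `"tex"` (a standalone TikZ document).
#' @param file optional output path; written atomically (temp file then
#'   rename) when given.
#' @return the document as a single character string, invisibly when `file`
#'   is given.
#' @export
render_diagram <- function(cmds, backend = c("svg", "tex"), file = NULL) {
  backend <- match.arg(backend)
  doc <- if (backend == "svg") render_svg(cmds) else render_tex(cmds)
  if (!is.null(file)) {
    write_atomic(doc, file)
    return(invisible(doc))
  }
  doc
}

# write-to-temp-then-rename so no error path leaves a partial file behind
write_atomic <- function(text, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  con <- file(tmp, "wb") # binary mode: identical bytes on every platform
  ok <- FALSE
  tryCatch({
    writeLines(text, con, sep = "")
    close(con)
    ok <- TRUE
  }, finally = {
    if (!ok) {
      try(close(con), silent = TRUE)
      unlink(tmp)
    }
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("cannot write output file ", path)
  }
  invisible(path)
}

#' @rdname render_diagram
#' @export
render_svg <- function(cmds, file = NULL) {
  canvas <- attr(cmds, "canvas")
  stopifnot(!is.null(canvas))
  w <- fmt_num(canvas[["width"]])
  h <- fmt_num(canvas[["height"]])
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    sprintf(paste0(
      "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\" height=\"%s\"",
      " viewBox=\"0 0 %s %s\">\n"), w, h, w, h)
  )
  grads <- unique(stats::na.omit(cmds[, c("grad_from", "grad_to")]))
  if (nrow(grads) > 0) {
    out <- c(out, "<defs>\n")
    for (i in seq_len(nrow(grads))) {
      out <- c(out, sprintf(paste0(
        "<linearGradient id=\"grad%d\" x1=\"0\" y1=\"0\" x2=\"1\" y2=\"0\">",
        "<stop offset=\"0\" stop-color=\"%s\"/>",
        "<stop offset=\"1\" stop-color=\"%s\"/>",
        "</linearGradient>\n"),
        i, grads$grad_from[i], grads$grad_to[i]))
    }
    out <- c(out, "</defs>\n")
  }
  grad_id <- function(from, to) {
    which(grads$grad_from == from & grads$grad_to == to)[1]
  }
  for (i in seq_len(nrow(cmds))) {
    r <- cmds[i, ]
    out <- c(out, switch(r$kind,
      rectangle = {
        fill <- if (!is.na(r$grad_from)) {
          sprintf("url(#grad%d)", grad_id(r$grad_from, r$grad_to))
        } else if (!is.na(r$fill)) r$fill else "none"
        stroke <- if (!is.na(r$stroke)) {
          sprintf(" stroke=\"%s\" stroke-width=\"1\"", r$stroke)
        } else ""
        sprintf("<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"%s/>\n",
                fmt_num(r$x), fmt_num(r$y), fmt_num(r$w), fmt_num(r$h),
                fill, stroke)
      },
      line = sprintf(
        "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"1.5\"/>\n",
        fmt_num(r$x), fmt_num(r$y), fmt_num(r$x2), fmt_num(r$y2), r$stroke),
      text = sprintf(
        "<text x=\"%s\" y=\"%s\" font-family=\"Helvetica,sans-serif\" font-size=\"%s\" fill=\"%s\">%s</text>\n",
        fmt_num(r$x), fmt_num(r$y), fmt_num(r$font_size), r$fill,
        xml_escape(r$text)),
      polygon = sprintf("<polygon points=\"%s\" fill=\"%s\"/>\n",
                        r$points, r$fill)
    ))
  }
  doc <- paste(c(out, "</svg>\n"), collapse = "")
  if (!is.null(file)) {
    write_atomic(doc, file)
    return(invisible(doc))
  }
  doc
}

tex_escape <- function(x) {
  x <- gsub("\\", "\u0001", x, fixed = TRUE) # placeholder, restored last
  for (ch in c("&", "%", "$", "#", "_", "{", "}")) {
    x <- gsub(ch, paste0("\\", ch), x, fixed = TRUE)
  }
  x <- gsub("~", "\\textasciitilde{}", x, fixed = TRUE)
  x <- gsub("^", "\\textasciicircum{}", x, fixed = TRUE)
  gsub("\u0001", "\\textbackslash{}", x, fixed = TRUE)
}

#' @rdname render_diagram
#' @export
render_tex <- function(cmds, file = NULL) {
  canvas <- attr(cmds, "canvas")
  stopifnot(!is.null(canvas))
  cols <- unique(stats::na.omit(c(cmds$fill, cmds$stroke,
                                  cmds$grad_from, cmds$grad_to)))
  col_name <- function(hex) sprintf("col%d", match(hex, cols))
  out <- c(
    "\\documentclass[tikz]{standalone}\n",
    "\\usepackage{tikz}\n",
    vapply(cols, function(hex) {
      sprintf("\\definecolor{%s}{HTML}{%s}\n", col_name(hex),
              toupper(sub("^#", "", hex)))
    }, character(1)),
    "\\begin{document}\n",
    "\\begin{tikzpicture}[x=0.025cm,y=-0.025cm]\n"
  )
  for (i in seq_len(nrow(cmds))) {
    r <- cmds[i, ]
    out <- c(out, switch(r$kind,
      rectangle = {
        coords <- sprintf("(%s,%s) rectangle (%s,%s)",
                          fmt_num(r$x), fmt_num(r$y),
                          fmt_num(r$x + r$w), fmt_num(r$y + r$h))
        if (!is.na(r$grad_from)) {
          sprintf("\\shade[left color=%s,right color=%s] %s;\n",
                  col_name(r$grad_from), col_name(r$grad_to), coords)
        } else if (!is.na(r$fill) && !is.na(r$stroke)) {
          sprintf("\\filldraw[fill=%s,draw=%s] %s;\n",
                  col_name(r$fill), col_name(r$stroke), coords)
        } else if (!is.na(r$fill)) {
          sprintf("\\fill[%s] %s;\n", col_name(r$fill), coords)
        } else {
          sprintf("\\draw[%s] %s;\n", col_name(r$stroke), coords)
        }
      },
      line = sprintf("\\draw[%s,thick] (%s,%s) -- (%s,%s);\n",
                     col_name(r$stroke), fmt_num(r$x), fmt_num(r$y),
                     fmt_num(r$x2), fmt_num(r$y2)),
      text = sprintf("\\node[anchor=west,text=%s,font=\\footnotesize] at (%s,%s) {%s};\n",
                     col_name(r$fill), fmt_num(r$x), fmt_num(r$y),
                     tex_escape(r$text)),
      polygon = {
        pts <- strsplit(r$points, " ", fixed = TRUE)[[1]]
        sprintf("\\fill[%s] %s -- cycle;\n", col_name(r$fill),
                paste(sprintf("(%s)", pts), collapse = " -- "))
      }
    ))
  }
  doc <- paste(c(out, "\\end{tikzpicture}\n\\end{document}\n"), collapse = "")
  if (!is.null(file)) {
    write_atomic(doc, file)
    return(invisible(doc))
  }
  doc
}
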