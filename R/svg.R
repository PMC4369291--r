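# Vector depiction. The output is pure SVG 1.1 primitives -- lines, paths,
# polygons and text -- so a record renders losslessly at any resolution.
# Output is deterministic for equal inputs: stable element order, fixed
# 2-decimal coordinate formatting.

svg_num <- function(v) {
  v <- round(v, 2)
  if (abs(v) < 0.005) v <- 0
  sprintf("%.2f", v)
}

xml_esc <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

scheme_colours <- function(scheme) {
  if (identical(scheme, "dark")) {
    list(bg = "#1F1F1F", fg = "#E0E0E0")
  } else {
    list(bg = "#FFFFFF", fg = "#000000")
  }
}

render_opts <- function(options = list()) {
  utils::modifyList(list(scale = 30, pad = 20, scheme = "light",
                         show_carbons = FALSE), options)
}

# label visibility: carbons are suppressed unless charged, isotopic,
# explicitly hydrogenated, unbonded, or the caller asked for them
atom_shows_label <- function(mol, i, opts) {
  a <- mol$atoms[[i]]
  if (a$element != "C") return(TRUE)
  if (isTRUE(opts$show_carbons)) return(TRUE)
  a$charge != 0L || atom_isotope(mol, i) != 0L || !is.na(a$hydrogens) ||
    a$unpaired > 0L || atom_degree(mol, i) == 0L
}

atom_label_text <- function(mol, i) {
  a <- mol$atoms[[i]]
  lab <- a$element
  iso <- atom_isotope(mol, i)
  if (iso != 0L) lab <- paste0(iso, lab)
  if (a$charge != 0L) {
    mag <- abs(a$charge)
    lab <- paste0(lab, if (mag > 1) mag else "", if (a$charge > 0) "+" else "-")
  }
  lab
}

# geometry of one rendered molecule: projected atom positions (y flipped so
# the chemistry convention "y up" maps onto SVG "y down") plus bounds
project_mol <- function(mol, opts, origin = c(0, 0)) {
  xs <- vapply(mol$atoms, `[[`, numeric(1), "x")
  ys <- vapply(mol$atoms, `[[`, numeric(1), "y")
  if (length(xs) == 0) xs <- ys <- numeric()
  px <- origin[1] + (xs - if (length(xs)) min(xs) else 0) * opts$scale
  py <- origin[2] + ((if (length(ys)) max(ys) else 0) - ys) * opts$scale
  list(x = px, y = py,
       width = if (length(xs)) diff(range(xs)) * opts$scale else 0,
       height = if (length(ys)) diff(range(ys)) * opts$scale else 0)
}

wavy_path <- function(x1, y1, x2, y2, waves = 4, amp = 3) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  if (len < 1e-9) return(sprintf("M %s %s", svg_num(x1), svg_num(y1)))
  ux <- dx / len; uy <- dy / len
  nx <- -uy; ny <- ux
  d <- sprintf("M %s %s", svg_num(x1), svg_num(y1))
  seg <- len / waves
  for (w in seq_len(waves)) {
    sgn <- if (w %% 2 == 1) 1 else -1
    mx <- x1 + ux * seg * (w - 0.5) + nx * amp * sgn
    my <- y1 + uy * seg * (w - 0.5) + ny * amp * sgn
    ex <- x1 + ux * seg * w
    ey <- y1 + uy * seg * w
    d <- paste0(d, sprintf(" Q %s %s %s %s", svg_num(mx), svg_num(my),
                           svg_num(ex), svg_num(ey)))
  }
  d
}

mol_svg_elements <- function(mol, opts, proj) {
  cols <- scheme_colours(opts$scheme)
  out <- character()
  shows <- vapply(seq_len(n_atoms(mol)), atom_shows_label, logical(1),
                  mol = mol, opts = opts)
  trim <- 0.3 * opts$scale
  for (j in seq_len(n_bonds(mol))) {
    b <- mol$bonds[[j]]
    x1 <- proj$x[b$from]; y1 <- proj$y[b$from]
    x2 <- proj$x[b$to]; y2 <- proj$y[b$to]
    dx <- x2 - x1; dy <- y2 - y1
    len <- sqrt(dx^2 + dy^2)
    if (len < 1e-9) next
    ux <- dx / len; uy <- dy / len
    # shorten towards labelled atoms so text stays legible
    if (shows[b$from]) { x1 <- x1 + ux * trim; y1 <- y1 + uy * trim }
    if (shows[b$to]) { x2 <- x2 - ux * trim; y2 <- y2 - uy * trim }
    nx <- -uy; ny <- ux
    line <- function(off, dash = FALSE) {
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1.5"%s/>',
              svg_num(x1 + nx * off), svg_num(y1 + ny * off),
              svg_num(x2 + nx * off), svg_num(y2 + ny * off), cols$fg,
              if (dash) ' stroke-dasharray="4,3" class="zero-order"' else "")
    }
    if (b$stereo == "inclined") {
      w <- 0.12 * opts$scale
      out <- c(out, sprintf(
        '<polygon points="%s,%s %s,%s %s,%s" fill="%s" class="wedge-up"/>',
        svg_num(x1), svg_num(y1), svg_num(x2 + nx * w), svg_num(y2 + ny * w),
        svg_num(x2 - nx * w), svg_num(y2 - ny * w), cols$fg))
    } else if (b$stereo == "declined") {
      hatches <- 6
      w <- 0.12 * opts$scale
      for (h in seq_len(hatches)) {
        tpar <- h / hatches
        hx <- x1 + (x2 - x1) * tpar; hy <- y1 + (y2 - y1) * tpar
        out <- c(out, sprintf(
          '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1.2" class="wedge-down"/>',
          svg_num(hx + nx * w * tpar), svg_num(hy + ny * w * tpar),
          svg_num(hx - nx * w * tpar), svg_num(hy - ny * w * tpar), cols$fg))
      }
    } else if (b$stereo == "unknown") {
      out <- c(out, sprintf('<path d="%s" fill="none" stroke="%s" stroke-width="1.5" class="squiggle"/>',
                            wavy_path(x1, y1, x2, y2), cols$fg))
    } else if (b$order == 0L) {
      out <- c(out, line(0, dash = TRUE))
    } else if (b$order == 2L) {
      out <- c(out, line(2.5), line(-2.5))
    } else if (b$order == 3L) {
      out <- c(out, line(0), line(3.5), line(-3.5))
    } else {
      out <- c(out, line(0))
      if (b$order %in% c(4L, 5L)) {
        out <- c(out, sprintf('<text x="%s" y="%s" font-size="9" fill="%s">%d</text>',
                              svg_num((x1 + x2) / 2 + nx * 5),
                              svg_num((y1 + y2) / 2 + ny * 5), cols$fg, b$order))
      }
    }
  }
  for (i in seq_len(n_atoms(mol))) {
    if (!shows[i]) next
    out <- c(out, sprintf(
      '<text x="%s" y="%s" text-anchor="middle" dominant-baseline="middle" font-family="sans-serif" font-size="%s" fill="%s" class="atom-label">%s</text>',
      svg_num(proj$x[i]), svg_num(proj$y[i]), svg_num(0.45 * opts$scale),
      cols$fg, xml_esc(atom_label_text(mol, i))))
  }
  out
}

svg_document <- function(body, width, height, opts) {
  cols <- scheme_colours(opts$scheme)
  paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">\n',
            svg_num(width), svg_num(height), svg_num(width), svg_num(height)),
    sprintf('<rect width="%s" height="%s" fill="%s"/>\n',
            svg_num(width), svg_num(height), cols$bg),
    paste(body, collapse = "\n"),
    if (length(body)) "\n" else "",
    "</svg>\n")
}

#' Render a molecule as SVG
#'
#' Pure vector primitives: lines for bonds (parallel lines for double and
#' triple, dashed for zero-order), a filled polygon for an inclined wedge,
#' hash marks for a declined wedge, a wavy path for unknown stereo, and text
#' for element labels, charges, isotope prefixes and abbreviation labels.
#' Carbon labels are suppressed unless the atom is charged, isotopic,
#' explicitly hydrogenated, a radical or unbonded (or `show_carbons` is
#' set). Output is deterministic for equal inputs.
#'
#' @param mol A [molecule()] with 2D coordinates.
#' @param options List: `scale` (pixels per coordinate unit, default 30),
#'   `pad` (margin in pixels), `scheme` (`"light"` or `"dark"`),
#'   `show_carbons`.
#' @return SVG text.
#' @export
render_molecule_svg <- function(mol, options = list()) {
  opts <- render_opts(options)
  if (n_atoms(mol) == 0) return(svg_document(character(), 2 * opts$pad, 2 * opts$pad, opts))
  proj <- project_mol(mol, opts, origin = c(opts$pad, opts$pad))
  body <- mol_svg_elements(mol, opts, proj)
  svg_document(body, proj$width + 2 * opts$pad, proj$height + 2 * opts$pad, opts)
}

#' Render a reaction scheme as SVG
#'
#' Takes the component table of [assemble_reaction_scheme()] and draws each
#' step as one coherent graphical object: reactants left of the arrow
#' (joined by plus signs), products right, reagent/text/number components
#' above the arrow. Multiple steps stack vertically.
#'
#' @param components Tibble from [assemble_reaction_scheme()].
#' @param options See [render_molecule_svg()].
#' @return SVG text.
#' @export
render_reaction_svg <- function(components, options = list()) {
  opts <- render_opts(options)
  if (is.null(components) || nrow(components) == 0) abort("empty reaction scheme")
  cols <- scheme_colours(opts$scheme)
  body <- character()
  y0 <- opts$pad
  total_w <- 0
  for (stp in unique(components$step)) {
    comp <- components[components$step == stp, , drop = FALSE]
    row_h <- opts$scale * 2
    placed <- list()
    for (side in c("reactant", "product")) {
      idx <- which(comp$role == side & comp$type == "molecule")
      items <- list()
      for (ii in idx) {
        m <- comp$value[[ii]]
        if (is.null(m)) next
        items[[length(items) + 1L]] <- m
        row_h <- max(row_h, project_mol(m, opts)$height + opts$scale)
      }
      placed[[side]] <- items
    }
    texts <- character()
    for (ii in which(comp$type != "molecule")) {
      value <- comp$value[[ii]]
      if (is.null(value)) next
      qty <- comp$quantity[[ii]]
      lab <- as.character(value)
      if (!is.na(qty)) lab <- paste0(lab, " (", qty, ")")
      texts <- c(texts, lab)
    }
    x <- opts$pad
    ymid <- y0 + row_h / 2
    emit_mol <- function(m, x) {
      pr <- project_mol(m, opts, origin = c(x, ymid - project_mol(m, opts)$height / 2))
      body <<- c(body, mol_svg_elements(m, opts, pr))
      x + pr$width + opts$scale
    }
    first <- TRUE
    for (m in placed$reactant) {
      if (!first) {
        body <- c(body, sprintf(
          '<text x="%s" y="%s" text-anchor="middle" dominant-baseline="middle" font-size="%s" fill="%s">+</text>',
          svg_num(x - opts$scale / 2), svg_num(ymid), svg_num(0.5 * opts$scale), cols$fg))
      }
      x <- emit_mol(m, x)
      first <- FALSE
    }
    arrow_len <- max(3 * opts$scale, 10 + 8 * max(0, max(nchar(texts), 0)))
    ax1 <- x; ax2 <- x + arrow_len
    body <- c(body, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1.5" class="rxn-arrow"/>',
      svg_num(ax1), svg_num(ymid), svg_num(ax2), svg_num(ymid), cols$fg))
    body <- c(body, sprintf(
      '<polygon points="%s,%s %s,%s %s,%s" fill="%s"/>',
      svg_num(ax2), svg_num(ymid), svg_num(ax2 - 7), svg_num(ymid - 4),
      svg_num(ax2 - 7), svg_num(ymid + 4), cols$fg))
    for (ti in seq_along(texts)) {
      body <- c(body, sprintf(
        '<text x="%s" y="%s" text-anchor="middle" font-size="%s" fill="%s" class="reagent">%s</text>',
        svg_num((ax1 + ax2) / 2), svg_num(ymid - 8 - 14 * (ti - 1)),
        svg_num(0.4 * opts$scale), cols$fg, xml_esc(texts[[ti]])))
    }
    x <- ax2 + opts$scale
    first <- TRUE
    for (m in placed$product) {
      if (!first) {
        body <- c(body, sprintf(
          '<text x="%s" y="%s" text-anchor="middle" dominant-baseline="middle" font-size="%s" fill="%s">+</text>',
          svg_num(x - opts$scale / 2), svg_num(ymid), svg_num(0.5 * opts$scale), cols$fg))
      }
      x <- emit_mol(m, x)
      first <- FALSE
    }
    total_w <- max(total_w, x + opts$pad)
    y0 <- y0 + row_h + opts$pad
  }
  svg_document(body, total_w, y0, opts)
}

#' Rasterize an SVG depiction to PNG
#'
#' A convenience wrapper for callers that must hand a bitmap to legacy
#' software: the SVG stays the source of truth and the PNG is produced at a
#' caller-chosen resolution by drawing the same primitives onto an R
#' graphics device.
#'
#' @param mol A [molecule()].
#' @param path Output PNG path.
#' @param width,height Pixel dimensions.
#' @param options See [render_molecule_svg()].
#' @return `path`, invisibly.
#' @export
render_molecule_png <- function(mol, path, width = 400, height = 400,
                                options = list()) {
  opts <- render_opts(options)
  cols <- scheme_colours(opts$scheme)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), bg = cols$bg)
  xs <- vapply(mol$atoms, `[[`, numeric(1), "x")
  ys <- vapply(mol$atoms, `[[`, numeric(1), "y")
  if (length(xs) == 0) { graphics::plot.new(); return(invisible(path)) }
  graphics::plot(NA, xlim = range(xs) + c(-1, 1), ylim = range(ys) + c(-1, 1),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  shows <- vapply(seq_len(n_atoms(mol)), atom_shows_label, logical(1),
                  mol = mol, opts = opts)
  for (b in mol$bonds) {
    lty <- if (b$order == 0L) 2 else 1
    graphics::segments(xs[b$from], ys[b$from], xs[b$to], ys[b$to],
                       lwd = 1.5 + (b$order > 1), lty = lty, col = cols$fg)
  }
  for (i in which(shows)) {
    graphics::points(xs[i], ys[i], pch = 21, cex = 2.4, col = NA, bg = cols$bg)
    graphics::text(xs[i], ys[i], atom_label_text(mol, i), col = cols$fg)
  }
  invisible(path)
}
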