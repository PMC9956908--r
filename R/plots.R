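karyo_offsets <- function(karyo) {
  tibble(
    chrom = karyo$chrom,
    length = karyo$length,
    offset = cumsum(c(0, head(karyo$length, -1L)))
  )
}

#' Dot-plot mark data for a pairwise alignment
#'
#' Lays the two genomes out on concatenated axes (chromosomes in karyotype
#' order, with cumulative offsets) and turns each alignment block into one
#' short stroke whose slope encodes strand: '+' blocks rise, '-' blocks
#' fall (the anti-diagonal signature of an inversion).
#'
#' @param blocks Filtered alignment blocks.
#' @param karyotype_x Karyotype of the query (horizontal) genome.
#' @param karyotype_y Karyotype of the target (vertical) genome.
#' @return A list with `marks` (one row per block: `x0`, `x1`, `y0`, `y1`,
#'   `strand`, chromosome names) and `axes` (per-chromosome offsets for
#'   both genomes).
#' @export
dotplot_data <- function(blocks, karyotype_x, karyotype_y) {
  ox <- karyo_offsets(karyotype_x)
  oy <- karyo_offsets(karyotype_y)
  ix <- match(blocks$query_name, ox$chrom)
  iy <- match(blocks$target_name, oy$chrom)
  if (anyNA(ix)) {
    abort(paste0("unknown query chromosome: ", blocks$query_name[which(is.na(ix))[1]]))
  }
  if (anyNA(iy)) {
    abort(paste0("unknown target chromosome: ", blocks$target_name[which(is.na(iy))[1]]))
  }
  marks <- tibble(
    query_chrom = blocks$query_name,
    target_chrom = blocks$target_name,
    strand = blocks$strand,
    x0 = ox$offset[ix] + blocks$query_start,
    x1 = ox$offset[ix] + blocks$query_end,
    y0 = oy$offset[iy] + ifelse(blocks$strand == "+", blocks$target_start,
                                blocks$target_end),
    y1 = oy$offset[iy] + ifelse(blocks$strand == "+", blocks$target_end,
                                blocks$target_start)
  )
  list(marks = marks,
       axes = list(x = ox, y = oy))
}

#' Pairwise genomic dot plot
#'
#' @inheritParams dotplot_data
#' @param highlight Optional inversion calls to annotate (red arrows over
#'   the called query intervals).
#' @return A ggplot object.
#' @export
plot_dotplot <- function(blocks, karyotype_x, karyotype_y, highlight = NULL) {
  d <- dotplot_data(blocks, karyotype_x, karyotype_y)
  p <- ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = c(d$axes$x$offset, sum(d$axes$x$length)),
                        colour = "grey85", linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = c(d$axes$y$offset, sum(d$axes$y$length)),
                        colour = "grey85", linewidth = 0.2)
  if (nrow(d$marks) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = d$marks,
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y0,
                   yend = .data$y1, colour = .data$strand),
      linewidth = 0.6
    ) +
      ggplot2::scale_colour_manual(values = c("+" = "grey20", "-" = "steelblue"))
  }
  if (!is.null(highlight) && nrow(highlight) > 0L) {
    ox <- d$axes$x; oy <- d$axes$y
    hx <- ox$offset[match(highlight$query_chrom, ox$chrom)]
    hy <- oy$offset[match(highlight$target_chrom, oy$chrom)]
    ann <- tibble(
      x0 = hx + highlight$query_start, x1 = hx + highlight$query_end,
      y = hy + highlight$target_end
    )
    p <- p + ggplot2::geom_segment(
      data = ann,
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y, yend = .data$y),
      colour = "red", linewidth = 0.8,
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"), ends = "both")
    )
  }
  p +
    ggplot2::scale_x_continuous(
      breaks = d$axes$x$offset + d$axes$x$length / 2,
      labels = d$axes$x$chrom, expand = c(0.01, 0)
    ) +
    ggplot2::scale_y_continuous(
      breaks = d$axes$y$offset + d$axes$y$length / 2,
      labels = d$axes$y$chrom, expand = c(0.01, 0)
    ) +
    ggplot2::labs(x = karyotype_x$species[1], y = karyotype_y$species[1]) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6),
                   legend.position = "none")
}

#' Paired-ideogram data with homology coloring
#'
#' Lays the two karyotypes out as two rows of size-scaled chromosome boxes
#' and colours each target-side chromosome by its query-side homology
#' partners: a fusion product shows one coloured segment per ancestral
#' partner, each spanning the target interval its partner's blocks cover.
#'
#' @param karyotype_a Query-side (lower row, reference colours) karyotype.
#' @param karyotype_b Target-side (upper row) karyotype.
#' @param blocks Filtered alignment blocks of the pair.
#' @param relations Relations from [classify_relations()]; segments are
#'   drawn only for retained homology partners.
#' @return A list with `chromosomes` (layout boxes for both rows) and
#'   `segments` (coloured homology segments of the upper row, colour keyed
#'   by `fill_chrom`, the query-side partner).
#' @export
ideogram_data <- function(karyotype_a, karyotype_b, blocks, relations) {
  gap_frac <- 0.1
  layout_row <- function(k, row) {
    gap <- gap_frac * mean(k$length)
    off <- cumsum(c(0, head(k$length + gap, -1L)))
    tibble(species = k$species[1], row = row, chrom = k$chrom,
           length = k$length, x0 = off, x1 = off + k$length)
  }
  chr_a <- layout_row(karyotype_a, 1)
  chr_b <- layout_row(karyotype_b, 2)
  retained <- bind_rows(purrr::map2(
    relations$query_members, relations$target_members,
    ~ tidyr::expand_grid(query_name = .x, target_name = .y)
  ))
  seg <- blocks %>%
    dplyr::semi_join(retained, by = c("query_name", "target_name")) %>%
    group_by(.data$target_name, .data$query_name) %>%
    summarise(t0 = min(.data$target_start), t1 = max(.data$target_end),
              .groups = "drop")
  ib <- match(seg$target_name, chr_b$chrom)
  segments <- tibble(
    chrom = seg$target_name,
    fill_chrom = seg$query_name,
    x0 = chr_b$x0[ib] + seg$t0,
    x1 = chr_b$x0[ib] + seg$t1
  )
  missing <- setdiff(chr_b$chrom, segments$chrom)
  missing <- missing[!chr_b$length[match(missing, chr_b$chrom)] == 0]
  if (length(missing) > 0L) {
    warn(paste0("no homology segments for: ", paste(missing, collapse = ", "),
                " (rendered uncoloured)"))
  }
  list(chromosomes = bind_rows(chr_a, chr_b), segments = segments)
}

#' Paired ideogram plot
#'
#' @inheritParams ideogram_data
#' @param highlight Optional inversion calls, annotated on the lower row.
#' @return A ggplot object.
#' @export
plot_ideogram <- function(karyotype_a, karyotype_b, blocks, relations,
                          highlight = NULL) {
  d <- ideogram_data(karyotype_a, karyotype_b, blocks, relations)
  chr <- d$chromosomes
  h <- 0.3
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = d$segments,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1, ymin = 2 - h,
                   ymax = 2 + h, fill = .data$fill_chrom)
    ) +
    ggplot2::geom_rect(
      data = chr[chr$row == 1, ],
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1, ymin = 1 - h,
                   ymax = 1 + h, fill = .data$chrom)
    ) +
    ggplot2::geom_rect(
      data = chr,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                   ymin = .data$row - h, ymax = .data$row + h),
      fill = NA, colour = "grey30", linewidth = 0.3
    ) +
    ggplot2::geom_text(
      data = chr,
      ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                   y = .data$row + ifelse(.data$row == 1, -h - 0.15, h + 0.15),
                   label = sub(".*_", "", .data$chrom)),
      size = 2.5
    )
  if (!is.null(highlight) && nrow(highlight) > 0L) {
    lower <- chr[chr$row == 1, ]
    hx <- lower$x0[match(highlight$query_chrom, lower$chrom)]
    ann <- tibble(x0 = hx + highlight$query_start,
                  x1 = hx + highlight$query_end)
    p <- p + ggplot2::geom_segment(
      data = ann,
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = 1 + h + 0.08,
                   yend = 1 + h + 0.08),
      colour = "red", linewidth = 1
    )
  }
  p +
    ggplot2::scale_y_continuous(
      breaks = c(1, 2),
      labels = c(karyotype_a$species[1], karyotype_b$species[1]),
      limits = c(0.4, 2.6)
    ) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none",
                   axis.text.y = ggplot2::element_text(size = 9))
}

#' Circular synteny-plot data
#'
#' Arranges both karyotypes as arcs on one circle (query species on the
#' right half, target on the left) and turns each alignment block into one
#' link between its two positions, coloured by the query chromosome.
#'
#' @param blocks Filtered alignment blocks.
#' @param karyotype_a,karyotype_b The two karyotypes.
#' @return A list with `arcs` (per-chromosome angular spans, radians) and
#'   `links` (one row per block: `theta_q`, `theta_t`, `colour_chrom`).
#' @export
circos_data <- function(blocks, karyotype_a, karyotype_b) {
  gap <- 0.005
  total <- sum(karyotype_a$length) + sum(karyotype_b$length)
  k <- bind_rows(
    mutate(karyotype_a, side = "query"),
    mutate(karyotype_b[rev(seq_len(nrow(karyotype_b))), ], side = "target")
  )
  n <- nrow(k)
  ang_len <- (2 * pi - n * gap) * k$length / total
  theta0 <- cumsum(c(0, head(ang_len + gap, -1L)))
  arcs <- tibble(species = k$species, side = k$side, chrom = k$chrom,
                 length = k$length, theta0 = theta0,
                 theta1 = theta0 + ang_len)
  pos_theta <- function(chrom, pos) {
    i <- match(chrom, arcs$chrom)
    if (anyNA(i)) {
      abort(paste0("unknown chromosome: ", chrom[which(is.na(i))[1]]))
    }
    arcs$theta0[i] + (arcs$theta1[i] - arcs$theta0[i]) * pos / arcs$length[i]
  }
  links <- if (nrow(blocks) > 0L) {
    tibble(
      colour_chrom = blocks$query_name,
      theta_q = pos_theta(blocks$query_name,
                          (blocks$query_start + blocks$query_end) / 2),
      theta_t = pos_theta(blocks$target_name,
                          (blocks$target_start + blocks$target_end) / 2)
    )
  } else {
    tibble(colour_chrom = character(), theta_q = numeric(), theta_t = numeric())
  }
  list(arcs = arcs, links = links)
}

#' Circular synteny plot
#'
#' @inheritParams circos_data
#' @return A ggplot object; links are quadratic curves through the circle
#'   centre, one per syntenic block.
#' @export
plot_circos <- function(blocks, karyotype_a, karyotype_b) {
  d <- circos_data(blocks, karyotype_a, karyotype_b)
  arc_paths <- d$arcs %>%
    mutate(.arc = row_number()) %>%
    group_by(.data$.arc) %>%
    dplyr::reframe(theta = seq(.data$theta0, .data$theta1, length.out = 32),
                   chrom = .data$chrom[1]) %>%
    mutate(x = cos(.data$theta), y = sin(.data$theta))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(
      data = arc_paths,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$.arc),
      linewidth = 2, colour = "grey40", lineend = "butt"
    )
  if (nrow(d$links) > 0L) {
    tseq <- seq(0, 1, length.out = 21)
    bez <- d$links %>%
      mutate(.link = row_number()) %>%
      group_by(.data$.link) %>%
      dplyr::reframe(
        colour_chrom = .data$colour_chrom[1],
        x = (1 - tseq)^2 * cos(.data$theta_q) + tseq^2 * cos(.data$theta_t),
        y = (1 - tseq)^2 * sin(.data$theta_q) + tseq^2 * sin(.data$theta_t)
      )
    p <- p + ggplot2::geom_path(
      data = bez,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$.link,
                   colour = .data$colour_chrom),
      linewidth = 0.2, alpha = 0.5
    )
  }
  lab <- d$arcs %>%
    mutate(mid = (.data$theta0 + .data$theta1) / 2)
  p +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = 1.12 * cos(.data$mid), y = 1.12 * sin(.data$mid),
                   label = sub(".*_", "", .data$chrom)),
      size = 2
    ) +
    ggplot2::coord_equal(xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25)) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' Write a plot to a PNG or SVG file
#'
#' @param plot A ggplot object.
#' @param path Output path; format follows the extension (.png or .svg).
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
render_plot <- function(plot, path, width = 8, height = 6) {
  ggplot2::ggsave(path, plot = plot, width = width, height = height, dpi = 150)
  invisible(path)
}
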