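#' Plot profile tracks for a region
#'
#' Genome-browser-style stacked tracks: coverage, mismatch composition
#' (non-reference base fractions stacked by base), arrest rate and CSA.
#' Positions exceeding a per-track threshold carry a marker glyph
#' (triangle) above the track.  Reference base letters are drawn when the
#' horizontal resolution allows at least `min_px_per_base` pixels per
#' base (estimated from `width_px`), mirroring automatic sequence display
#' at sufficient plot width.
#'
#' @param rows Profile data frame (e.g. from [read_region()]).
#' @param tracks Subset of `c("coverage", "mismatch", "arrest", "csa")`.
#' @param thresholds Named list of marker thresholds per track, e.g.
#'   `list(mismatch = 0.1, arrest = 0.2, csa = 10)`.
#' @param csa_r,csa_pseudocount CSA parameters (used when `rows` has no
#'   `csa` column).
#' @param show_sequence `"auto"` (default), `"always"` or `"never"`.
#' @param min_px_per_base Minimum pixels per base for sequence letters
#'   (default 7).
#' @param width_px Assumed image width in pixels for the auto decision
#'   (default 1200).
#' @param title Optional plot title.
#' @return A `ggplot` object (class `rtsig_plot`); the marker positions
#'   are attached as `attr(p, "markers")` (data frame with `pos`,
#'   `track`, `value`), and the long track data as `attr(p, "tracks")`.
#' @export
plot_profile_region <- function(rows,
                                tracks = c("coverage", "mismatch",
                                           "arrest", "csa"),
                                thresholds = list(),
                                csa_r = 5L, csa_pseudocount = 0.001,
                                show_sequence = c("auto", "always",
                                                  "never"),
                                min_px_per_base = 7, width_px = 1200,
                                title = NULL) {
  show_sequence <- match.arg(show_sequence)
  tracks <- match.arg(tracks, several.ok = TRUE)
  if (!("csa" %in% names(rows)) && "csa" %in% tracks) {
    rows <- add_csa(rows, r = csa_r, pseudocount = csa_pseudocount)
  }

  track_value <- function(tr) {
    switch(tr,
           coverage = rows$coverage,
           mismatch = rows$mismatch_rate,
           arrest = rows$arrest_rate,
           csa = rows$csa)
  }
  long <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(pos = rows$pos, track = tr, value = track_value(tr),
               stringsAsFactors = FALSE)
  }))
  long$track <- factor(long$track, levels = tracks)

  # stacked mismatch composition by non-reference base
  comp <- NULL
  if ("mismatch" %in% tracks) {
    parts <- lapply(c(A = "n_A", C = "n_C", G = "n_G", T = "n_T"),
                    function(col) rows[[col]])
    comp <- do.call(rbind, lapply(names(parts), function(b) {
      frac <- ifelse(rows$coverage > 0, parts[[b]] / rows$coverage, 0)
      frac[toupper(rows$ref_base) == b] <- 0
      data.frame(pos = rows$pos, track = "mismatch", base = b,
                 frac = frac, stringsAsFactors = FALSE)
    }))
    comp$track <- factor(comp$track, levels = tracks)
  }

  markers <- do.call(rbind, lapply(names(thresholds), function(tr) {
    if (!(tr %in% tracks)) return(NULL)
    v <- track_value(tr)
    hit <- !is.na(v) & v >= thresholds[[tr]]
    if (!any(hit)) return(NULL)
    data.frame(pos = rows$pos[hit], track = tr, value = v[hit],
               stringsAsFactors = FALSE)
  }))
  if (is.null(markers)) {
    markers <- data.frame(pos = integer(), track = character(),
                          value = numeric(), stringsAsFactors = FALSE)
  }
  markers$track <- factor(markers$track, levels = tracks)

  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$value))
  if (!is.null(comp)) {
    p <- p + ggplot2::geom_col(
      data = comp,
      mapping = ggplot2::aes(x = .data$pos, y = .data$frac,
                             fill = .data$base),
      width = 1, inherit.aes = FALSE)
  }
  p <- p +
    ggplot2::geom_step(
      data = long[long$track != "mismatch", , drop = FALSE],
      colour = "grey25") +
    ggplot2::facet_grid(track ~ ., scales = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(A = "#33a02c", C = "#1f78b4", G = "#ff7f00",
                 T = "#e31a1c"),
      name = "base") +
    ggplot2::labs(x = "position", y = NULL, title = title) +
    ggplot2::theme_bw()

  if (nrow(markers) > 0L) {
    p <- p + ggplot2::geom_point(
      data = markers,
      mapping = ggplot2::aes(x = .data$pos, y = .data$value),
      shape = 24, fill = "gold", colour = "black", size = 2.5,
      inherit.aes = FALSE)
  }

  draw_seq <- show_sequence == "always" ||
    (show_sequence == "auto" &&
       width_px / max(1L, nrow(rows)) >= min_px_per_base)
  if (draw_seq && nrow(rows) > 0L) {
    seqdat <- data.frame(pos = rows$pos, base = rows$ref_base,
                         track = factor(tracks[1L], levels = tracks))
    p <- p + ggplot2::geom_text(
      data = seqdat,
      mapping = ggplot2::aes(x = .data$pos, y = 0, label = .data$base),
      vjust = 1.2, size = 2.5, inherit.aes = FALSE)
  }

  attr(p, "markers") <- markers
  attr(p, "tracks") <- long
  class(p) <- c("rtsig_plot", class(p))
  p
}

#' Plot a differential comparison
#'
#' Tracks of the per-position deltas (sample 2 minus sample 1) with
#' above-threshold markers on the absolute delta.
#'
#' @param diff Differential rows from [pair_profiles()].
#' @param tracks Subset of `c("d_mism", "d_A", "d_CSA")`.
#' @param thresholds Named list of absolute-delta marker thresholds.
#' @param title Optional title.
#' @return A `ggplot` object with a `markers` attribute.
#' @export
plot_differential_region <- function(diff,
                                     tracks = c("d_mism", "d_A"),
                                     thresholds = list(), title = NULL) {
  long <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(pos = diff$pos, track = tr, value = diff[[tr]],
               stringsAsFactors = FALSE)
  }))
  long$track <- factor(long$track, levels = tracks)
  markers <- do.call(rbind, lapply(names(thresholds), function(tr) {
    if (!(tr %in% tracks)) return(NULL)
    v <- diff[[tr]]
    hit <- !is.na(v) & abs(v) >= thresholds[[tr]]
    if (!any(hit)) return(NULL)
    data.frame(pos = diff$pos[hit], track = tr, value = v[hit],
               stringsAsFactors = FALSE)
  }))
  if (is.null(markers)) {
    markers <- data.frame(pos = integer(), track = character(),
                          value = numeric(), stringsAsFactors = FALSE)
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pos,
                                          y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_step(colour = "grey25") +
    ggplot2::facet_grid(track ~ ., scales = "free_y") +
    ggplot2::labs(x = "position", y = NULL, title = title) +
    ggplot2::theme_bw()
  if (nrow(markers) > 0L) {
    p <- p + ggplot2::geom_point(
      data = markers,
      mapping = ggplot2::aes(x = .data$pos, y = .data$value),
      shape = 24, fill = "gold", colour = "black", size = 2.5,
      inherit.aes = FALSE)
  }
  attr(p, "markers") <- markers
  class(p) <- c("rtsig_plot", class(p))
  p
}

#' Render a plot to an image file
#'
#' @param p A `ggplot` object.
#' @param path Output path; the format is taken from the extension when
#'   `format` is `NULL`.
#' @param width,height Image size in pixels.
#' @param format `"png"`, `"pdf"` or `"svg"` (PNG and SVG require the
#'   corresponding graphics capability of the R build).
#' @param dpi Resolution used to convert pixels to inches (default 100).
#' @return Invisibly, `path`.
#' @export
render_plot <- function(p, path, width = 1200, height = 800,
                        format = NULL, dpi = 100) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  w_in <- width / dpi
  h_in <- height / dpi
  switch(format,
    png = {
      if (!capabilities("png")) stop("this R build cannot render PNG")
      grDevices::png(path, width = width, height = height, res = dpi)
    },
    pdf = grDevices::pdf(path, width = w_in, height = h_in),
    svg = {
      if (!capabilities("cairo")) stop("this R build cannot render SVG")
      grDevices::svg(path, width = w_in, height = h_in)
    },
    stop("unsupported image format: ", format)
  )
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Batch-plot candidate regions
#'
#' Renders one image per candidate position, a region of `flank`
#' positions on each side, files named `<ref>_<pos>.<format>`.
#'
#' @param candidates Candidate data frame (needs `ref_index` and `pos`).
#' @param profile_dir Profile block directory.
#' @param out_dir Output directory for the images.
#' @param flank Flank size in nt (default 50).
#' @param thresholds Marker thresholds passed to
#'   [plot_profile_region()].
#' @param format Image format (default `"pdf"`).
#' @param width,height Image size in pixels.
#' @param block_size Profile block size (default 1000).
#' @return Invisibly, the written file paths.
#' @export
plot_candidate_batch <- function(candidates, profile_dir, out_dir,
                                 flank = 50L, thresholds = list(),
                                 format = "pdf", width = 1200,
                                 height = 800, block_size = 1000L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  index <- read_profile_index(profile_dir)
  paths <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ri <- candidates$ref_index[i]
    pos <- candidates$pos[i]
    len <- index$length[index$ref_index == ri]
    lo <- max(1L, pos - flank)
    hi <- min(len, pos + flank)
    rows <- read_region(ri, lo, hi, profile_dir, block_size)
    p <- plot_profile_region(rows, thresholds = thresholds,
                             title = sprintf("ref %d : %d", ri, pos))
    paths[i] <- file.path(out_dir, sprintf("%d_%d.%s", ri, pos, format))
    render_plot(p, paths[i], width = width, height = height,
                format = format)
  }
  invisible(paths)
}
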