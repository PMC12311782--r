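# Declarative plot builders: every numeric value in a PlotData object comes
# from profile_stats/screen operations; plotting is a pure presentation
# layer and deleting it changes no statistic.

#' @rdname build_plot
#' @export
PLOT_KINDS <- c("aligned_reads_freq", "base_coverage", "mut_per_read",
                "mutation_fraction", "compare_profiles", "fraction_identity",
                "variable_across_samples", "fraction_delta",
                "correlation_by_reference")

# Fixed base color semantics shared by every per-base plot.
BASE_COLORS <- c(A = "orange", C = "purple", T = "lightblue", G = "yellow")

# How many (sample, reference) rows each kind needs: one, two, or "1+".
plot_cardinality <- function(kind) {
  switch(kind,
    aligned_reads_freq = , base_coverage = , mut_per_read = ,
    mutation_fraction = , fraction_identity = 1L,
    compare_profiles = , fraction_delta = 2L,
    correlation_by_reference = , variable_across_samples = NA_integer_)
}

#' Build a declarative plot-data object
#'
#' Computes the numeric content of one of the nine supported plot kinds from
#' a study and a selection, and returns it as data plus annotations; nothing
#' is computed at render time. Kinds needing exactly one selected
#' (sample, reference) row reject selections resolving to more; comparison
#' kinds need exactly two.
#'
#' @param kind One of `PLOT_KINDS`.
#' @param s A `dms_study`.
#' @param spec A [selection_spec()] resolving to the rows the kind needs.
#' @param ... Kind-specific options: `n_bins` (aligned_reads_freq),
#'   `position` and `variable` (variable_across_samples), `normalization`
#'   and `screen_cfg` (correlation_by_reference), `normalize`
#'   (compare_profiles, fraction_delta).
#' @return A `dms_plotdata` list: `kind`, `series` (named list of tibbles),
#'   `annotations`, `base_colors`, `title`.
#' @export
build_plot <- function(kind, s, spec = selection_spec(), ...) {
  kind <- match.arg(kind, PLOT_KINDS)
  extra <- list(...)
  need <- plot_cardinality(kind)
  views <- select_views(s, spec)
  if (!is.na(need) && length(views) != need) {
    stop("plot kind '", kind, "' requires exactly ", need,
         " selected row(s), selection resolved to ", length(views),
         call. = FALSE)
  }
  series <- list(); ann <- list(); title <- kind
  if (kind == "aligned_reads_freq") {
    smp <- attr(views[[1]], "sample")
    h <- reads_per_reference_distribution(s$samples[[smp]],
                                          extra$n_bins %||% 30)
    series$histogram <- tibble::tibble(
      bin_lo = utils::head(h$breaks, -1), bin_hi = utils::tail(h$breaks, -1),
      count = h$counts)
    title <- paste0("Aligned reads per reference (", smp, ")")
  } else if (kind == "base_coverage") {
    v <- views[[1]]
    series$coverage <- tibble::tibble(position = v$position, base = v$base,
                                      coverage = v$coverage)
  } else if (kind == "mut_per_read") {
    smp <- attr(views[[1]], "sample"); ref <- attr(views[[1]], "reference")
    h <- s$samples[[smp]]$read_hists[[ref]]
    if (is.null(h)) {
      stop("no per-read histogram stored for ", smp, "/", ref, call. = FALSE)
    }
    series$histogram <- tibble::tibble(
      bin_lo = utils::head(h$bin_edges, -1),
      bin_hi = utils::tail(h$bin_edges, -1), count = h$counts)
  } else if (kind == "mutation_fraction") {
    v <- views[[1]]
    series$fraction <- tibble::tibble(position = v$position, base = v$base,
                                      fraction = v$fraction)
  } else if (kind == "compare_profiles") {
    v2 <- if (isTRUE(extra$normalize)) {
      normalize_profiles(views[[1]], views[[2]])$normalized
    } else views[[2]]
    cmp <- compare_profiles(views[[1]], v2)
    series$pairs <- cmp$pairs
    ann$identity_line <- TRUE
    ann$fit <- list(slope = cmp$slope, intercept = cmp$intercept)
    ann$stats <- list(n = cmp$n, pearson_r = cmp$pearson_r,
                      r_squared = cmp$r_squared, rmse = cmp$rmse)
    title <- sprintf("Compare profiles (N = %d; Pearson R = %.3f, RMSE = %.4f)",
                     cmp$n, cmp$pearson_r, cmp$rmse)
  } else if (kind == "fraction_identity") {
    v <- views[[1]]
    prof <- get_profile(s, attr(v, "sample"), attr(v, "reference"),
                        attr(v, "section"))
    fi <- fraction_identity(prof)
    fi[is.na(v$fraction), c("to_A", "to_C", "to_G", "to_T")] <- NA_real_
    series$identity <- fi
  } else if (kind == "variable_across_samples") {
    if (is.null(extra$position) || is.null(extra$variable)) {
      stop("variable_across_samples needs 'position' and 'variable' options",
           call. = FALSE)
    }
    ref <- attr(views[[1]], "reference")
    series$series <- variable_series(s, ref, extra$position, extra$variable,
                                     section = spec$section)
    title <- paste0(extra$variable, " across samples at position ",
                    extra$position)
  } else if (kind == "fraction_delta") {
    v2 <- if (isTRUE(extra$normalize)) {
      normalize_profiles(views[[1]], views[[2]])$normalized
    } else views[[2]]
    d <- delta_profile(views[[1]], v2)
    series$delta <- d
  } else if (kind == "correlation_by_reference") {
    smp <- unique(vapply(views, attr, "", "sample"))
    if (length(smp) != 2L) {
      stop("plot kind 'correlation_by_reference' requires exactly 2 ",
           "selected samples, selection resolved to ", length(smp),
           call. = FALSE)
    }
    scr <- per_reference_correlation(s, smp[1], smp[2],
                                     extra$screen_cfg %||% screen_config())
    tab <- scr$table[scr$table$pass_qc & !is.na(scr$table$r_squared), ]
    series$correlation <- tibble::tibble(reference = tab$reference,
                                         rank = tab$rank,
                                         r_squared = tab$r_squared)
    ann$threshold_line <- scr$threshold_r2
  }
  structure(list(kind = kind, series = series, annotations = ann,
                 base_colors = BASE_COLORS, title = title),
            class = "dms_plotdata")
}

plotdata_frame <- function(plot) {
  # single tidy frame per plot for CSV export; bit-identical to the series
  nm <- names(plot$series)[1]
  as.data.frame(plot$series[[nm]])
}

render_plot <- function(plot) {
  df <- plotdata_frame(plot)
  colors <- plot$base_colors
  g <- switch(plot$kind,
    aligned_reads_freq = , mut_per_read =
      ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                       y = .data$count)) +
        ggplot2::geom_col(width = (df$bin_hi - df$bin_lo) * 0.95) +
        ggplot2::labs(x = "bin", y = "frequency"),
    base_coverage =
      ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                       y = .data$coverage,
                                       fill = .data$base)) +
        ggplot2::geom_col() +
        ggplot2::scale_fill_manual(values = colors),
    mutation_fraction =
      ggplot2::ggplot(df[!is.na(df$fraction), ],
                      ggplot2::aes(x = .data$position, y = .data$fraction,
                                   fill = .data$base)) +
        ggplot2::geom_col() +
        ggplot2::scale_fill_manual(values = colors),
    compare_profiles = {
      gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
        ggplot2::geom_point(color = "darkgreen") +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
        ggplot2::labs(x = "sample 2 mutation fraction",
                      y = "sample 1 mutation fraction")
      fit <- plot$annotations$fit
      if (!is.null(fit) && !is.na(fit$slope)) {
        gg <- gg + ggplot2::geom_abline(slope = fit$slope,
                                        intercept = fit$intercept,
                                        color = "red")
      }
      gg
    },
    fraction_identity = {
      long <- stats::reshape(df, direction = "long",
                             varying = c("to_A", "to_C", "to_G", "to_T"),
                             v.names = "fraction", timevar = "target",
                             times = c("A", "C", "G", "T"))
      ggplot2::ggplot(long[!is.na(long$fraction), ],
                      ggplot2::aes(x = .data$position, y = .data$fraction,
                                   fill = .data$target)) +
        ggplot2::geom_col() +
        ggplot2::scale_fill_manual(values = colors)
    },
    variable_across_samples =
      ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$fraction)) +
        ggplot2::geom_point() + ggplot2::geom_line(),
    fraction_delta =
      ggplot2::ggplot(df[!is.na(df$delta), ],
                      ggplot2::aes(x = .data$position, y = .data$delta,
                                   fill = .data$base)) +
        ggplot2::geom_col() +
        ggplot2::scale_fill_manual(values = colors),
    correlation_by_reference = {
      gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                             y = .data$r_squared)) +
        ggplot2::geom_point(color = "red") +
        ggplot2::labs(x = "reference rank", y = "Pearson R²")
      thr <- plot$annotations$threshold_line
      if (!is.null(thr)) {
        gg <- gg + ggplot2::geom_hline(yintercept = thr,
                                       linetype = "dashed")
      }
      gg
    })
  g + ggplot2::ggtitle(plot$title) + ggplot2::theme_minimal()
}

#' Export a plot-data object
#'
#' `csv` writes the plot's numeric series exactly as held in the object
#' (parsing it back reproduces the series); `png` renders it; `html` writes
#' a self-contained page embedding the rendered image.
#'
#' @param plot A `dms_plotdata` from [build_plot()].
#' @param format One of `"csv"`, `"png"`, `"html"`.
#' @param path Output path.
#' @param width,height Device size in inches (png/html).
#' @return `path`, invisibly.
#' @export
export_plot <- function(plot, format = c("csv", "png", "html"), path,
                        width = 7, height = 5) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- plotdata_frame(plot)
    # %.17g so the CSV parses back to the exact doubles held in the series
    for (cn in names(df)) {
      if (is.double(df[[cn]])) {
        v <- df[[cn]]
        whole <- !is.na(v) & v == round(v) & abs(v) < 1e15
        out <- sprintf("%.17g", v)
        out[whole] <- sprintf("%.1f", v[whole])  # keep the double type on re-parse
        out[is.na(v)] <- NA
        df[[cn]] <- out
      }
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  png_path <- if (format == "png") path else tempfile(fileext = ".png")
  grDevices::png(png_path, width = width, height = height, units = "in",
                 res = 120)
  print(render_plot(plot))
  grDevices::dev.off()
  if (format == "html") {
    b64 <- jsonlite::base64_enc(readBin(png_path, "raw",
                                        file.info(png_path)$size))
    html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
              paste0("<title>", plot$title, "</title></head><body>"),
              paste0("<h3>", plot$title, "</h3>"),
              paste0("<img alt='", plot$kind, "' src='data:image/png;base64,",
                     gsub("\n", "", b64), "'/>"),
              "</body></html>")
    writeLines(html, path)
    unlink(png_path)
  }
  invisible(path)
}

#' Conventional export file name for a plot
#'
#' @param sample,reference,section Selection identifiers.
#' @param kind Plot kind.
#' @param ext File extension without dot.
#' @return `"<sample>__<reference>__<section>__<kind>.<ext>"`.
#' @export
plot_file_name <- function(sample, reference, section, kind, ext) {
  paste0(paste(sample, reference, section, kind, sep = "__"), ".", ext)
}
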