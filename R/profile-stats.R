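# Statistics core: fractions, histograms, pairwise comparison, deltas,
# cross-sample normalization, substitution-identity breakdown and
# variable-across-samples series. Every statistic is computed only over
# positions unmasked in all of its inputs.

#' Mutation fraction from counts
#'
#' The per-position reactivity signal: mutated reads / covering reads,
#' masked (`NA`) where coverage is zero.
#'
#' @param mutated,coverage Non-negative integer vectors, `mutated <=
#'   coverage` position-wise.
#' @return Numeric vector of fractions with `NA` at zero-coverage positions.
#' @export
mutation_fraction <- function(mutated, coverage) {
  if (length(mutated) != length(coverage)) {
    stop("mutated and coverage must have equal length", call. = FALSE)
  }
  if (any(mutated < 0) || any(coverage < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  bad <- which(mutated > coverage)
  if (length(bad)) {
    stop("mutated exceeds coverage at index ", bad[1], call. = FALSE)
  }
  ifelse(coverage > 0, mutated / coverage, NA_real_)
}

#' Frequency distribution of aligned reads per reference
#'
#' @param rec A `dms_sample` record.
#' @param n_bins Number of equal-width bins over the observed range.
#' @return List with `breaks` (length `n_bins + 1`), `counts`, and the raw
#'   per-reference `values`; empty input yields empty components.
#' @export
reads_per_reference_distribution <- function(rec, n_bins = 30) {
  values <- rec$aligned_reads
  if (!length(values)) {
    return(list(breaks = numeric(0), counts = integer(0),
                values = integer(0)))
  }
  rng <- range(values)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(as.numeric(values), breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(breaks = h$breaks, counts = h$counts, values = values)
}

#' Histogram of mutations per read
#'
#' Contiguous integer bins of the given width starting at 0, with a final
#' overflow bin collecting reads with at least `cap` mutations.
#'
#' @param read_counts Integer vector, one mutation count per read.
#' @param bin_width Width of each bin in mutations (default 1).
#' @param cap Counts `>= cap` go to the overflow bin (default 10).
#' @return A [read_mut_histogram()].
#' @export
mutations_per_read_histogram <- function(read_counts, bin_width = 1L,
                                         cap = 10L) {
  read_counts <- as.integer(read_counts)
  if (length(read_counts) && any(read_counts < 0L)) {
    stop("read mutation counts must be >= 0", call. = FALSE)
  }
  bin_width <- as.integer(bin_width); cap <- as.integer(cap)
  lower <- seq.int(0L, cap - 1L, by = bin_width)
  edges <- c(lower, cap, cap + bin_width)  # final [cap, cap+w) bin = overflow
  capped <- pmin(read_counts, cap)
  idx <- pmin(capped %/% bin_width + 1L, length(lower) + 1L)
  idx[capped >= cap] <- length(lower) + 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  read_mut_histogram(edges, counts, length(read_counts))
}

shared_unmasked <- function(v1, v2) {
  if (!identical(attr(v1, "reference"), attr(v2, "reference")) ||
      !identical(attr(v1, "section"), attr(v2, "section"))) {
    stop("profiles cover different reference/section (",
         attr(v1, "reference"), "/", attr(v1, "section"), " vs ",
         attr(v2, "reference"), "/", attr(v2, "section"), ")",
         call. = FALSE)
  }
  if (!identical(v1$position, v2$position)) {
    stop("profile views are not position-parallel", call. = FALSE)
  }
  which(!is.na(v1$fraction) & !is.na(v2$fraction))
}

as_view <- function(x) {
  if (inherits(x, "dms_profile")) {
    apply_selection(x, selection_spec(bases = c("A", "C", "G", "T")))
  } else x
}

#' Compare two mutation profiles
#'
#' Pairwise statistics over positions unmasked in both inputs: Pearson
#' correlation `r`, its square, the root-mean-square difference of fractions,
#' and an ordinary-least-squares fit of the first profile's fractions
#' (y-axis) on the second's (x-axis) — the plotting convention in which the
#' identity line x = y is the null model of no difference.
#'
#' With a constant input vector `r` is undefined and reported as `NA` with
#' `degenerate_reason`, never coerced to 0.
#'
#' @param v1,v2 Profile views ([apply_selection()]) or `dms_profile`s over
#'   the same reference and section.
#' @return A `dms_comparison` list: `n`, `pearson_r`, `r_squared`, `rmse`,
#'   `slope`, `intercept`, `pairs` (tibble of position, base, x, y),
#'   `degenerate_reason`.
#' @export
compare_profiles <- function(v1, v2) {
  v1 <- as_view(v1); v2 <- as_view(v2)
  idx <- shared_unmasked(v1, v2)
  if (length(idx) < 2L) {
    stop("insufficient data: need >= 2 shared unmasked positions, have ",
         length(idx), call. = FALSE)
  }
  y <- v1$fraction[idx]  # sample 1 on the y-axis
  x <- v2$fraction[idx]  # sample 2 on the x-axis
  n <- length(idx)
  degenerate <- NULL
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_; slope <- NA_real_; intercept <- NA_real_
    degenerate <- "constant input vector: correlation undefined"
  } else {
    r <- stats::cor(x, y)
    slope <- stats::cov(x, y) / stats::var(x)
    intercept <- mean(y) - slope * mean(x)
  }
  structure(list(
    n = n, pearson_r = r, r_squared = r^2,
    rmse = sqrt(mean((y - x)^2)),
    slope = slope, intercept = intercept,
    pairs = tibble::tibble(position = v1$position[idx], base = v1$base[idx],
                           x = x, y = y),
    degenerate_reason = degenerate,
    reference = attr(v1, "reference"), section = attr(v1, "section")),
    class = "dms_comparison")
}

#' Per-position difference of two profiles
#'
#' `delta = sample1 - sample2` per position; masked wherever either input is
#' masked.
#'
#' @param v1,v2 Profile views over the same reference/section.
#' @return A tibble (`position`, `base`, `delta`) with attributes
#'   `reference`, `section`.
#' @export
delta_profile <- function(v1, v2) {
  v1 <- as_view(v1); v2 <- as_view(v2)
  shared_unmasked(v1, v2)  # validates alignment
  out <- tibble::tibble(position = v1$position, base = v1$base,
                        delta = v1$fraction - v2$fraction)
  attr(out, "reference") <- attr(v1, "reference")
  attr(out, "section") <- attr(v1, "section")
  out
}

#' Scale one profile onto another
#'
#' Computes a single positive factor applied to the second profile's
#' fractions so the two samples live on a common reactivity scale (used when
#' comparing across chemistry conditions). Methods:
#'
#' * `"ls_origin"` (default): least-squares scaling through the origin,
#'   `factor = sum(x * y) / sum(y^2)` over shared unmasked positions, which
#'   minimizes `sum((x - k * y)^2)` in `k`.
#' * `"median_ratio"`: median of `x / y` over positions with `y > 0`.
#' * `"none"`: factor 1.
#'
#' Normalized fractions are clipped at 1; the number of clipped positions is
#' reported in `n_clipped`.
#'
#' @param v1 Target profile view (x).
#' @param v2 Profile view to be scaled (y).
#' @param method One of `"ls_origin"`, `"median_ratio"`, `"none"`.
#' @return A `dms_normalization` list: `factor`, `method`, `normalized`
#'   (view like `v2` with scaled fractions), `n_clipped`.
#' @export
normalize_profiles <- function(v1, v2, method = c("ls_origin",
                                                  "median_ratio", "none")) {
  method <- match.arg(method)
  v1 <- as_view(v1); v2 <- as_view(v2)
  idx <- shared_unmasked(v1, v2)
  if (length(idx) < 2L) {
    stop("insufficient data: need >= 2 shared unmasked positions",
         call. = FALSE)
  }
  x <- v1$fraction[idx]; y <- v2$fraction[idx]
  factor <- switch(method,
    ls_origin = {
      if (sum(y^2) == 0) {
        stop("scaling factor undefined: second profile is all zero",
             call. = FALSE)
      }
      sum(x * y) / sum(y^2)
    },
    median_ratio = {
      pos <- y > 0
      if (!any(pos)) {
        stop("scaling factor undefined: second profile is all zero",
             call. = FALSE)
      }
      stats::median(x[pos] / y[pos])
    },
    none = 1)
  if (!is.finite(factor) || factor <= 0) {
    stop("normalization produced a non-positive factor (", factor, ")",
         call. = FALSE)
  }
  scaled <- v2$fraction * factor
  n_clipped <- sum(scaled > 1, na.rm = TRUE)
  if (n_clipped > 0) {
    warning(n_clipped, " normalized fraction(s) exceeded 1 and were clipped",
            call. = FALSE)
  }
  normalized <- v2
  normalized$fraction <- pmin(scaled, 1)
  structure(list(factor = factor, method = method, normalized = normalized,
                 n_clipped = n_clipped),
            class = "dms_normalization")
}

#' Substitution-identity breakdown
#'
#' Per position, the fraction of reads mutated to each target base:
#' `sub_counts[B] / coverage` for B in A/C/G/T. The stack sum is at most the
#' mutation fraction (deletions count as mutated but have no target base).
#' Converted data without a substitution breakdown raises an error rather
#' than reporting zeros.
#'
#' @param profile A `dms_profile` with `sub_counts`.
#' @return Tibble with `position`, `base`, `to_A`, `to_C`, `to_G`, `to_T`.
#' @export
fraction_identity <- function(profile) {
  if (is.null(profile$sub_counts)) {
    stop("substitution breakdown unavailable for ", profile$reference, "/",
         profile$section,
         " (converted data carries no sub_counts)", call. = FALSE)
  }
  cov <- profile$coverage
  frac_to <- lapply(profile$sub_counts, function(cnt) {
    ifelse(cov > 0L, cnt / cov, NA_real_)
  })
  tibble::tibble(position = profile$positions, base = profile$base,
                 to_A = frac_to$A, to_C = frac_to$C,
                 to_G = frac_to$G, to_T = frac_to$T)
}

#' Mutation fraction at one position across samples, ordered by a variable
#'
#' Collects the fraction at a single base across all samples that define a
#' numeric experimental variable (e.g. MgCl2 concentration) and returns the
#' series sorted ascending by the variable's value. Samples lacking the
#' variable are excluded with a warning.
#'
#' @param s A `dms_study`.
#' @param reference Reference name.
#' @param position 1-based position.
#' @param variable Variable name to order by.
#' @param section Section to read the fraction from (default `"full"`).
#' @return Tibble with `sample`, `value`, `unit`, `fraction`, sorted by
#'   `value`.
#' @export
variable_series <- function(s, reference, position, variable,
                            section = "full") {
  rows <- list(); skipped <- character(0)
  for (smp in names(s$samples)) {
    var <- s$samples[[smp]]$variables[[variable]]
    if (is.null(var) || !is.numeric(var$value)) {
      skipped <- c(skipped, smp); next
    }
    prof <- tryCatch(get_profile(s, smp, reference, section),
                     error = function(e) NULL)
    if (is.null(prof)) { skipped <- c(skipped, smp); next }
    i <- match(position, prof$positions)
    if (is.na(i)) { skipped <- c(skipped, smp); next }
    rows <- c(rows, list(tibble::tibble(
      sample = smp, value = as.numeric(var$value),
      unit = var$unit %||% NA_character_, fraction = prof$fraction[i])))
  }
  if (length(skipped)) {
    warning("excluded sample(s) without variable '", variable, "': ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out) || all(is.na(out$fraction))) {
    stop("position ", position, " of ", reference,
         " is masked in every sample defining '", variable, "'",
         call. = FALSE)
  }
  dplyr::arrange(out, .data$value)
}

#' Export a comparison, delta or identity result as tidy CSV
#'
#' One row per position or per pair, matching the numbers held in the
#' result exactly.
#'
#' @param x A `dms_comparison`, delta tibble, or any data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  df <- if (inherits(x, "dms_comparison")) x$pairs else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
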