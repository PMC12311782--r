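# Composable data selections and the quality-control gate.
# Selection only ever masks; it never drops positions or touches counts, so
# the position axis of every downstream plot is preserved.

#' Selection specification
#'
#' Describes a subset of a study to analyse or plot: which samples,
#' references and section, which bases to keep (DMS reports on A and C, the
#' default), an optional position range, and a per-position coverage floor.
#'
#' @param samples,references Optional character vectors (default: all).
#' @param section Section name (default `"full"`).
#' @param bases Non-empty subset of A/C/G/T. Default `c("A", "C")`.
#' @param position_range Optional 1-based inclusive `c(lo, hi)`.
#' @param min_coverage Positions with coverage below this are masked
#'   (comparison is `>=`, i.e. a position exactly at the floor is kept).
#' @return A `dms_selection` list.
#' @export
selection_spec <- function(samples = NULL, references = NULL,
                           section = "full", bases = c("A", "C"),
                           position_range = NULL, min_coverage = 0L) {
  bases <- toupper(bases)
  if (!length(bases) || !all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be a non-empty subset of A, C, G, T", call. = FALSE)
  }
  if (!is.null(position_range)) {
    position_range <- as.integer(position_range)
    if (length(position_range) != 2L || position_range[1] > position_range[2]) {
      stop("position_range must be c(lo, hi) with lo <= hi", call. = FALSE)
    }
  }
  structure(list(samples = samples, references = references,
                 section = section, bases = bases,
                 position_range = position_range,
                 min_coverage = as.integer(min_coverage)),
            class = "dms_selection")
}

#' Quality-control specification
#'
#' Thresholds for the per-reference QC gate applied before screening. The
#' defaults (median ROI coverage of at least 1000 reads and at least 10
#' unmasked A/C positions) reflect common practice for stable mutational
#' profiling fractions; both are overridable.
#'
#' @param min_median_coverage Median coverage floor over the section.
#' @param min_informative_positions Minimum count of unmasked A/C positions.
#' @return A `dms_qcspec` list.
#' @export
qc_spec <- function(min_median_coverage = 1000, min_informative_positions = 10) {
  if (min_median_coverage < 0 || min_informative_positions < 0) {
    stop("QC thresholds must be >= 0", call. = FALSE)
  }
  structure(list(min_median_coverage = min_median_coverage,
                 min_informative_positions = min_informative_positions),
            class = "dms_qcspec")
}

#' Apply a selection to one profile
#'
#' Returns a profile view: a tibble with one row per position of the
#' section, where positions excluded by the base filter, position range or
#' coverage floor have `fraction = NA`. Counts are untouched.
#'
#' @param profile A `dms_profile`.
#' @param spec A [selection_spec()].
#' @return A tibble (`dms_view`) with columns `position`, `base`,
#'   `coverage`, `mutated`, `fraction` and attributes `reference`,
#'   `section`.
#' @export
apply_selection <- function(profile, spec = selection_spec()) {
  keep <- profile$base %in% spec$bases
  if (!is.null(spec$position_range)) {
    keep <- keep & profile$positions >= spec$position_range[1] &
      profile$positions <= spec$position_range[2]
  }
  keep <- keep & profile$coverage >= spec$min_coverage
  frac <- profile$fraction
  frac[!keep] <- NA_real_
  view <- tibble::tibble(position = profile$positions, base = profile$base,
                         coverage = profile$coverage,
                         mutated = profile$mutated, fraction = frac)
  attr(view, "reference") <- profile$reference
  attr(view, "section") <- profile$section
  class(view) <- c("dms_view", class(view))
  view
}

#' Select profile views from a study
#'
#' Resolves a [selection_spec()] against a study and returns one view per
#' (sample, reference) pair, each restricted to the requested section,
#' bases, range and coverage floor by masking.
#'
#' @param s A `dms_study`.
#' @param spec A [selection_spec()].
#' @return Named list of views, keyed `sample::reference`.
#' @export
select_views <- function(s, spec = selection_spec()) {
  samples <- spec$samples %||% names(s$samples)
  unknown <- setdiff(samples, names(s$samples))
  if (length(unknown)) {
    stop("unknown sample(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(s$samples), collapse = ", "),
         call. = FALSE)
  }
  references <- spec$references %||% names(s$references)
  unknown <- setdiff(references, names(s$references))
  if (length(unknown)) {
    stop("unknown reference(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(s$references), collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (smp in samples) {
    for (ref in references) {
      if (is.null(find_section(s, ref, spec$section))) {
        stop("unknown section '", spec$section, "' for reference ", ref,
             "; available: ",
             paste(vapply(s$sections[[ref]], `[[`, "", "name"),
               collapse = ", "), call. = FALSE)
      }
      prof <- get_profile(s, smp, ref, spec$section)
      view <- apply_selection(prof, spec)
      attr(view, "sample") <- smp
      out[[paste(smp, ref, sep = "::")]] <- view
    }
  }
  out
}

roi_section_name <- function(s, reference) {
  for (sec in s$sections[[reference]]) {
    if (sec$role == "roi") return(sec$name)
  }
  NULL
}

#' Per-reference quality-control gate for a sample pair
#'
#' A reference passes only if, in both samples, the ROI median coverage
#' meets `min_median_coverage` and at least `min_informative_positions`
#' unmasked A/C positions remain. Failures carry a reason code
#' (`"coverage"`, `"positions"`, or `"absent"` for references missing from a
#' sample). The gate is symmetric in the two samples.
#'
#' @param s A `dms_study`.
#' @param sample_a,sample_b Sample names.
#' @param spec A [qc_spec()].
#' @return A tibble with columns `reference`, `pass`, `reason`.
#' @export
qc_filter <- function(s, sample_a, sample_b, spec = qc_spec()) {
  for (smp in c(sample_a, sample_b)) {
    if (!smp %in% names(s$samples)) {
      stop("unknown sample '", smp, "'", call. = FALSE)
    }
  }
  rows <- lapply(sort(names(s$references)), function(ref) {
    roi <- roi_section_name(s, ref)
    if (is.null(roi)) {
      stop("reference ", ref, " has no section with role 'roi'; ",
           "QC is defined over the region of interest", call. = FALSE)
    }
    reason <- NA_character_
    for (smp in c(sample_a, sample_b)) {
      prof <- tryCatch(get_profile(s, smp, ref, roi), error = function(e) NULL)
      if (is.null(prof)) { reason <- "absent"; break }
      if (stats::median(prof$coverage) < spec$min_median_coverage) {
        reason <- "coverage"; break
      }
      n_ac <- sum(prof$base %in% c("A", "C") & !is.na(prof$fraction))
      if (n_ac < spec$min_informative_positions) {
        reason <- "positions"; break
      }
    }
    tibble::tibble(reference = ref, pass = is.na(reason), reason = reason)
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
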