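# Riboswitch screen: per-reference correlation between two samples over the
# region of interest, ranked ascending by r-squared, with responder calling
# below a strict threshold and binding-site protection summaries.

#' Screen configuration
#'
#' @param threshold_r2 Responder cutoff; a reference is a responder when its
#'   between-condition r-squared is strictly below this (default 0.6).
#' @param bases Bases entering the correlation (default A and C, the bases
#'   DMS reports on).
#' @param section_role Section role screened (default `"roi"`).
#' @param qc A [qc_spec()].
#' @param normalization `"none"` (default, appropriate for technical
#'   replicates) or a [normalize_profiles()] method applied to sample 2
#'   before correlating (use for cross-chemistry comparisons).
#' @param min_coverage Per-position coverage floor applied when selecting.
#' @return A `dms_screenconfig` list.
#' @export
screen_config <- function(threshold_r2 = 0.6, bases = c("A", "C"),
                          section_role = "roi", qc = qc_spec(),
                          normalization = "none", min_coverage = 0L) {
  if (!(threshold_r2 > 0 && threshold_r2 < 1)) {
    stop("threshold_r2 must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(threshold_r2 = threshold_r2, bases = bases,
                 section_role = section_role, qc = qc,
                 normalization = normalization,
                 min_coverage = as.integer(min_coverage)),
            class = "dms_screenconfig")
}

section_by_role <- function(s, reference, role) {
  for (sec in s$sections[[reference]]) {
    if (sec$role == role) return(sec)
  }
  NULL
}

#' Per-reference correlation between two samples
#'
#' For every reference common to both samples and passing QC, correlates the
#' two samples' mutation fractions over the screened section (A/C positions
#' by default, optional scaling of sample 2 onto sample 1 first) and records
#' the squared Pearson correlation. References are ranked ascending by
#' r-squared — the strongest condition-dependent conformational changes rank
#' first — with ties broken lexicographically by reference name. References
#' failing QC carry a reason and no rank; references present in only one
#' sample are reported as `"absent"`.
#'
#' @param s A `dms_study`.
#' @param sample_a,sample_b Sample names (sample_a is sample 1 / y-axis).
#' @param config A [screen_config()].
#' @return A `dms_screen` object wrapping a tibble `table` with columns
#'   `reference`, `r_squared`, `n`, `pass_qc`, `reason`, `responder`,
#'   `rank`.
#' @export
per_reference_correlation <- function(s, sample_a, sample_b,
                                      config = screen_config()) {
  common <- intersect(
    unique(vapply(s$samples[[sample_a]]$profiles, `[[`, "", "reference")),
    unique(vapply(s$samples[[sample_b]]$profiles, `[[`, "", "reference")))
  if (!length(s$samples[[sample_a]]$profiles) ||
      !length(s$samples[[sample_b]]$profiles) || !length(common)) {
    stop("samples ", sample_a, " and ", sample_b,
         " share no references", call. = FALSE)
  }
  qc <- qc_filter(s, sample_a, sample_b, config$qc)
  rows <- lapply(sort(names(s$references)), function(ref) {
    row <- tibble::tibble(reference = ref, r_squared = NA_real_,
                          n = NA_integer_, pass_qc = FALSE,
                          reason = NA_character_)
    if (!ref %in% common) { row$reason <- "absent"; return(row) }
    qrow <- qc[qc$reference == ref, ]
    if (!qrow$pass) { row$reason <- qrow$reason; return(row) }
    sec <- section_by_role(s, ref, config$section_role)
    if (is.null(sec)) { row$reason <- "no_section"; return(row) }
    spec <- selection_spec(section = sec$name, bases = config$bases,
                           min_coverage = config$min_coverage)
    v1 <- apply_selection(get_profile(s, sample_a, ref, sec$name), spec)
    v2 <- apply_selection(get_profile(s, sample_b, ref, sec$name), spec)
    if (config$normalization != "none") {
      v2 <- normalize_profiles(v1, v2, config$normalization)$normalized
    }
    cmp <- tryCatch(compare_profiles(v1, v2), error = function(e) NULL)
    if (is.null(cmp) || is.na(cmp$pearson_r)) {
      row$reason <- "degenerate"; return(row)
    }
    row$r_squared <- cmp$r_squared
    row$n <- cmp$n
    row$pass_qc <- TRUE
    row
  })
  table <- dplyr::bind_rows(rows)
  table$responder <- table$pass_qc & !is.na(table$r_squared) &
    table$r_squared < config$threshold_r2
  table <- rank_screen(table)
  structure(list(table = table, threshold_r2 = config$threshold_r2,
                 sample_a = sample_a, sample_b = sample_b,
                 normalization = config$normalization),
            class = "dms_screen")
}

rank_screen <- function(table) {
  table$rank <- NA_integer_
  idx <- which(table$pass_qc & !is.na(table$r_squared))
  ord <- idx[order(table$r_squared[idx], table$reference[idx])]
  table$rank[ord] <- seq_along(ord)
  table
}

#' Re-call responders at a different threshold
#'
#' Responder means: passed QC and r-squared strictly below the threshold
#' (a reference sitting exactly at the threshold is not a responder).
#' Calling is monotone: raising the threshold never removes a responder.
#'
#' @param screen A `dms_screen`.
#' @param threshold New r-squared cutoff.
#' @return The screen with `responder` flags and threshold updated.
#' @export
call_responders <- function(screen, threshold) {
  stopifnot(inherits(screen, "dms_screen"))
  screen$table$responder <- screen$table$pass_qc &
    !is.na(screen$table$r_squared) & screen$table$r_squared < threshold
  screen$threshold_r2 <- threshold
  screen
}

#' Ligand-binding-site protection summary
#'
#' Compares the mutation fraction at stated binding-site positions between
#' the no-ligand and with-ligand profiles. `delta = with - without`; a site
#' base is protected when its reactivity decreases with ligand
#' (`delta < 0`).
#'
#' @param v_minus Profile view without ligand.
#' @param v_plus Profile view with ligand.
#' @param site Integer vector of 1-based binding-site positions.
#' @return Tibble with `position`, `base`, `without`, `with`, `delta`,
#'   `protected`.
#' @export
binding_site_protection <- function(v_minus, v_plus, site) {
  v_minus <- as_view(v_minus); v_plus <- as_view(v_plus)
  shared_unmasked(v_minus, v_plus)
  i <- match(as.integer(site), v_minus$position)
  if (any(is.na(i))) {
    stop("binding-site position(s) ",
         paste(site[is.na(i)], collapse = ", "),
         " outside the profiled section", call. = FALSE)
  }
  without <- v_minus$fraction[i]
  with_ <- v_plus$fraction[i]
  if (all(is.na(without) | is.na(with_))) {
    stop("insufficient data: all binding-site positions are masked",
         call. = FALSE)
  }
  tibble::tibble(position = v_minus$position[i], base = v_minus$base[i],
                 without = without, with = with_,
                 delta = with_ - without,
                 protected = !is.na(with_) & !is.na(without) &
                   with_ < without)
}

#' Combine a replicate screen and a condition screen
#'
#' Joins the two ranked tables over the same reference universe: per
#' reference, the replicate r-squared (reproducibility floor), the
#' condition r-squared, and the condition responder call.
#'
#' @param replicate_screen `dms_screen` from a replicate-vs-replicate run.
#' @param condition_screen `dms_screen` from a condition-vs-control run.
#' @return Tibble with `reference`, `replicate_r2`, `condition_r2`,
#'   `responder`, `rank` (condition rank). Zero passing references yields an
#'   empty table with a message.
#' @export
screen_report <- function(replicate_screen, condition_screen) {
  a <- replicate_screen$table; b <- condition_screen$table
  if (!length(intersect(a$reference, b$reference))) {
    stop("screens cover disjoint reference sets", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::select(a, "reference", replicate_r2 = "r_squared"),
    dplyr::select(b, "reference", condition_r2 = "r_squared",
                  "responder", "rank"),
    by = "reference")
  keep <- !is.na(joined$replicate_r2) | !is.na(joined$condition_r2)
  out <- joined[keep, ]
  if (!nrow(out)) message("no references passed QC in either screen")
  dplyr::arrange(out, .data$rank)
}
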