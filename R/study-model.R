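# Hierarchical study container: samples -> references -> sections -> profiles.
# Coordinates are 1-based inclusive everywhere; masked values are NA in memory
# and null in the JSON dialect (schema_version "1").

SCHEMA_VERSION <- "1"

#' Section annotation
#'
#' A named sub-interval of a reference sequence. Roles follow the amplicon
#' layout used for pooled probing libraries: amplification primers, a
#' demultiplexing barcode, unstructured flanks, and the region of interest
#' (ROI) carrying the biological sequence under study.
#'
#' @param name Section name (unique within a reference).
#' @param role One of `"primer5"`, `"barcode"`, `"flank5"`, `"roi"`,
#'   `"flank3"`, `"primer3"`, `"full"`.
#' @param start,end 1-based inclusive coordinates on the reference.
#' @return A `dms_section` list.
#' @export
section_annotation <- function(name, role, start, end) {
  roles <- c("primer5", "barcode", "flank5", "roi", "flank3", "primer3", "full")
  if (!role %in% roles) {
    stop("unknown section role '", role, "' (expected one of: ",
         paste(roles, collapse = ", "), ")", call. = FALSE)
  }
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid section coordinates for '", name, "': start=", start,
         " end=", end, " (need 1 <= start <= end)", call. = FALSE)
  }
  structure(list(name = as.character(name), role = role,
                 start = start, end = end),
            class = "dms_section")
}

#' Per-position mutation profile
#'
#' Position-parallel arrays of coverage, mutated-read counts, optional
#' substitution breakdown by target base, and the mutation fraction
#' (mutated/coverage; `NA` where coverage is zero). "Mutated" counts any
#' non-reference call (substitution or deletion); `sub_counts` covers
#' substitutions only, so `colSums(sub_counts) <= mutated` position-wise.
#'
#' @param reference Reference name.
#' @param section Section name the profile spans.
#' @param positions Integer vector of 1-based positions.
#' @param base Reference base per position (A/C/G/T/N).
#' @param coverage,mutated Non-negative integer count vectors.
#' @param sub_counts `NULL` (unavailable, e.g. converted data) or a named list
#'   with integer vectors `A`, `C`, `G`, `T` of substitution counts.
#' @param fraction Optional; recomputed from counts when missing.
#' @return A `dms_profile` list.
#' @export
position_profile <- function(reference, section, positions, base, coverage,
                             mutated, sub_counts = NULL, fraction = NULL) {
  positions <- as.integer(positions)
  coverage <- as.integer(coverage)
  mutated <- as.integer(mutated)
  base <- toupper(as.character(base))
  n <- length(positions)
  lens <- c(length(base), length(coverage), length(mutated))
  if (any(lens != n)) {
    stop("profile arrays for ", reference, "/", section,
         " have unequal lengths", call. = FALSE)
  }
  if (any(coverage < 0L) || any(mutated < 0L)) {
    stop("negative counts in profile ", reference, "/", section, call. = FALSE)
  }
  bad <- which(mutated > coverage)
  if (length(bad)) {
    stop("mutated > coverage in profile ", reference, "/", section,
         " at position ", positions[bad[1]], call. = FALSE)
  }
  if (!is.null(sub_counts)) {
    sub_counts <- lapply(sub_counts[c("A", "C", "G", "T")], as.integer)
    if (any(vapply(sub_counts, length, 1L) != n)) {
      stop("sub_counts length mismatch in profile ", reference, "/", section,
           call. = FALSE)
    }
    tot <- Reduce(`+`, sub_counts)
    bad <- which(tot > mutated)
    if (length(bad)) {
      stop("sum of sub_counts exceeds mutated in ", reference, "/", section,
           " at position ", positions[bad[1]], call. = FALSE)
    }
  }
  prof <- structure(list(reference = as.character(reference),
                         section = as.character(section),
                         positions = positions, base = base,
                         coverage = coverage, mutated = mutated,
                         sub_counts = sub_counts, fraction = NULL),
                    class = "dms_profile")
  prof$fraction <- compute_fraction(prof, fraction)
  prof
}

# fraction = mutated/coverage, masked (NA) at coverage 0 and at N bases.
compute_fraction <- function(prof, given = NULL) {
  frac <- ifelse(prof$coverage > 0L, prof$mutated / prof$coverage, NA_real_)
  frac[prof$base == "N"] <- NA_real_
  if (!is.null(given)) {
    given <- as.numeric(given)
    # a stored fraction may carry extra masking (e.g. QC), but where both are
    # defined it must equal the count ratio
    ok <- !is.na(given) & !is.na(frac)
    if (any(abs(given[ok] - frac[ok]) > 1e-9)) {
      stop("stored fraction disagrees with mutated/coverage in ",
           prof$reference, "/", prof$section, call. = FALSE)
    }
    frac[is.na(given)] <- NA_real_
  }
  frac
}

#' Per-read mutation-count histogram
#'
#' @param bin_edges Integer bin boundaries (length = number of bins + 1);
#'   bin i covers counts in `[bin_edges[i], bin_edges[i+1])`; the final bin is
#'   an overflow bin.
#' @param counts Reads per bin.
#' @param total_reads Total retained reads; must equal `sum(counts)`.
#' @return A `dms_readhist` list.
#' @export
read_mut_histogram <- function(bin_edges, counts, total_reads = sum(counts)) {
  bin_edges <- as.integer(bin_edges); counts <- as.integer(counts)
  total_reads <- as.integer(total_reads)
  if (length(bin_edges) != length(counts) + 1L) {
    stop("bin_edges must have length(counts) + 1", call. = FALSE)
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  if (sum(counts) != total_reads) {
    stop("sum(counts) != total_reads in read histogram", call. = FALSE)
  }
  structure(list(bin_edges = bin_edges, counts = counts,
                 total_reads = total_reads),
            class = "dms_readhist")
}

profile_key <- function(reference, section) paste(reference, section, sep = "::")

#' Construct a study
#'
#' The top-level container: reference sequences, their section annotations,
#' and per-sample records (experimental variables, profiles, per-read
#' histograms, aligned-read counts).
#'
#' @param references Named character vector of reference sequences (DNA
#'   alphabet; U is accepted and stored as T).
#' @param sections Named list (by reference) of lists of
#'   [section_annotation()] objects. A `full` section is added per reference
#'   if absent.
#' @param samples Named list of sample records as built by [sample_record()].
#' @param provenance Free-form list of source records.
#' @return A validated `dms_study` object.
#' @export
study <- function(references = character(), sections = list(),
                  samples = list(), provenance = list()) {
  references <- vapply(references, function(s) {
    gsub("U", "T", toupper(as.character(s)))
  }, character(1))
  for (ref in names(references)) {
    secs <- sections[[ref]]
    if (is.null(secs)) secs <- list()
    has_full <- any(vapply(secs, function(s) s$role == "full", logical(1)))
    if (!has_full) {
      secs <- c(secs, list(section_annotation("full", "full", 1L,
                                              nchar(references[[ref]]))))
    }
    sections[[ref]] <- secs
  }
  s <- structure(list(schema_version = SCHEMA_VERSION,
                      references = references,
                      sections = sections[names(references)],
                      samples = samples,
                      provenance = provenance),
                 class = "dms_study")
  validate_study(s)
  s
}

#' Sample record
#'
#' @param variables Named list of experimental variables; each entry is a
#'   `list(value = , unit = )` pair (e.g. `MgCl2 = list(value = 10, unit =
#'   "mM")`).
#' @param profiles List of [position_profile()] objects.
#' @param read_hists Named list (by reference) of [read_mut_histogram()]s.
#' @param aligned_reads Named integer vector of aligned reads per reference.
#' @return A `dms_sample` list.
#' @export
sample_record <- function(variables = list(), profiles = list(),
                          read_hists = list(), aligned_reads = integer()) {
  keyed <- list()
  for (p in profiles) {
    stopifnot(inherits(p, "dms_profile"))
    keyed[[profile_key(p$reference, p$section)]] <- p
  }
  structure(list(variables = variables, profiles = keyed,
                 read_hists = read_hists,
                 aligned_reads = vapply(aligned_reads, as.integer, 1L)),
            class = "dms_sample")
}

#' Validate a study against its invariants
#'
#' Checks that every profile names a known reference and section, that
#' profile array lengths match the section length, that the base arrays agree
#' with the reference subsequence, and that count inequalities hold.
#'
#' @param s A `dms_study`.
#' @return Invisibly `TRUE`; stops with a contextual message otherwise.
#' @export
validate_study <- function(s) {
  stopifnot(inherits(s, "dms_study"))
  for (ref in names(s$sections)) {
    L <- nchar(s$references[[ref]])
    secs <- s$sections[[ref]]
    nm <- vapply(secs, `[[`, "", "name")
    if (anyDuplicated(nm)) {
      stop("duplicate section name '", nm[duplicated(nm)][1],
           "' for reference ", ref, call. = FALSE)
    }
    for (sec in secs) {
      if (sec$end > L) {
        stop("section '", sec$name, "' of ", ref, " ends at ", sec$end,
             " beyond reference length ", L, call. = FALSE)
      }
      if (sec$role == "full" && !(sec$start == 1L && sec$end == L)) {
        stop("role=full section of ", ref, " must span the entire reference",
             call. = FALSE)
      }
    }
  }
  for (smp in names(s$samples)) {
    rec <- s$samples[[smp]]
    for (p in rec$profiles) {
      if (!p$reference %in% names(s$references)) {
        stop("sample ", smp, ": profile reference '", p$reference,
             "' not in study references", call. = FALSE)
      }
      sec <- find_section(s, p$reference, p$section)
      if (is.null(sec)) {
        stop("sample ", smp, ": profile section '", p$section,
             "' not annotated for reference ", p$reference, call. = FALSE)
      }
      want_len <- sec$end - sec$start + 1L
      if (length(p$positions) != want_len) {
        stop("sample ", smp, ": profile ", p$reference, "/", p$section,
             " has ", length(p$positions), " positions, section length is ",
             want_len, call. = FALSE)
      }
      if (!identical(p$positions, seq.int(sec$start, sec$end))) {
        stop("sample ", smp, ": profile ", p$reference, "/", p$section,
             " positions do not match section coordinates", call. = FALSE)
      }
      refseq <- strsplit(s$references[[p$reference]], "")[[1]]
      if (!identical(p$base, refseq[sec$start:sec$end])) {
        stop("sample ", smp, ": profile ", p$reference, "/", p$section,
             " base array disagrees with the reference sequence",
             call. = FALSE)
      }
    }
    for (ref in names(rec$read_hists)) {
      h <- rec$read_hists[[ref]]
      ar <- rec$aligned_reads[[ref]]
      if (!is.null(ar) && !is.na(ar) && ar < h$total_reads) {
        stop("sample ", smp, ": aligned_reads for ", ref,
             " below histogram total_reads", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

find_section <- function(s, reference, section_name) {
  for (sec in s$sections[[reference]]) {
    if (sec$name == section_name) return(sec)
  }
  NULL
}

#' Extract a profile, slicing a stored wider section when needed
#'
#' Looks for a stored profile matching `(reference, section)` exactly; when
#' absent, slices it out of any stored profile that covers the requested
#' coordinates (typically the `full` profile). Slices keep 1-based reference
#' coordinates.
#'
#' @param s A `dms_study`.
#' @param sample Sample name.
#' @param reference Reference name.
#' @param section Section name (default `"full"`).
#' @return A `dms_profile`.
#' @export
get_profile <- function(s, sample, reference, section = "full") {
  rec <- s$samples[[sample]]
  if (is.null(rec)) {
    stop("unknown sample '", sample, "'; available: ",
         paste(names(s$samples), collapse = ", "), call. = FALSE)
  }
  p <- rec$profiles[[profile_key(reference, section)]]
  if (!is.null(p)) return(p)
  sec <- find_section(s, reference, section)
  if (is.null(sec)) {
    stop("unknown section '", section, "' for reference ", reference,
         call. = FALSE)
  }
  for (stored in rec$profiles) {
    if (stored$reference != reference) next
    lo <- stored$positions[1]; hi <- stored$positions[length(stored$positions)]
    if (sec$start >= lo && sec$end <= hi) {
      idx <- match(seq.int(sec$start, sec$end), stored$positions)
      sub <- if (is.null(stored$sub_counts)) NULL else
        lapply(stored$sub_counts, `[`, idx)
      return(position_profile(reference, section,
                              positions = stored$positions[idx],
                              base = stored$base[idx],
                              coverage = stored$coverage[idx],
                              mutated = stored$mutated[idx],
                              sub_counts = sub,
                              fraction = stored$fraction[idx]))
    }
  }
  stop("no stored profile covers ", reference, "/", section,
       " in sample ", sample, call. = FALSE)
}

# ---- JSON dialect ----------------------------------------------------------

json_arr <- function(x) if (length(x)) I(x) else I(list())

study_to_list <- function(s) {
  refs <- as.list(s$references)
  secs <- lapply(s$sections, function(lst) {
    lapply(lst, function(sec) list(name = sec$name, role = sec$role,
                                   start = sec$start, end = sec$end))
  })
  samples <- lapply(s$samples, function(rec) {
    pkeys <- sort(names(rec$profiles))
    profs <- lapply(pkeys, function(k) {
      p <- rec$profiles[[k]]
      out <- list(reference = p$reference, section = p$section,
                  positions = json_arr(p$positions),
                  base = json_arr(p$base),
                  coverage = json_arr(p$coverage),
                  mutated = json_arr(p$mutated),
                  sub_counts = if (is.null(p$sub_counts)) NULL else
                    lapply(p$sub_counts, json_arr),
                  fraction = json_arr(p$fraction))
      out
    })
    hists <- lapply(rec$read_hists, function(h) {
      list(bin_edges = json_arr(h$bin_edges), counts = json_arr(h$counts),
           total_reads = h$total_reads)
    })
    list(variables = rec$variables, profiles = profs,
         read_hists = hists, aligned_reads = as.list(rec$aligned_reads))
  })
  list(schema_version = s$schema_version, references = refs, sections = secs,
       samples = samples, provenance = s$provenance)
}

#' Write a study to its JSON dialect
#'
#' Field ordering is fixed (profiles sorted by reference then section) so the
#' output is byte-stable for a given study; masked fractions are encoded as
#' `null`; numbers are written at full precision.
#'
#' @param s A `dms_study`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study <- function(s, path) {
  validate_study(s)
  json <- jsonlite::toJSON(study_to_list(s), auto_unbox = TRUE, na = "null",
                           digits = NA, null = "null", pretty = TRUE)
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("cannot write study to '", path, "'", call. = FALSE)
  invisible(path)
}

null_na <- function(x) {
  vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 1)
}

#' Load a study from its JSON dialect
#'
#' Parses and validates the file; masked fractions (`null`) become `NA`;
#' fractions are recomputed from counts when absent. Unknown top-level keys
#' are preserved under `provenance$extra_keys` rather than rejected.
#'
#' @param path Path to a study JSON file.
#' @return A validated `dms_study`.
#' @export
load_study <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("cannot parse '", path, "' as study JSON: ",
                         conditionMessage(e), call. = FALSE)
                  })
  for (key in c("schema_version", "references", "samples")) {
    if (is.null(raw[[key]])) {
      stop("study JSON is missing required key '", key, "'", call. = FALSE)
    }
  }
  refs <- vapply(raw$references, as.character, "")
  secs <- lapply(raw$sections, function(lst) {
    lapply(lst, function(x) {
      section_annotation(x$name, x$role, x$start, x$end)
    })
  })
  samples <- lapply(raw$samples, function(rec) {
    profs <- lapply(rec$profiles, function(p) {
      for (key in c("reference", "section", "positions", "coverage", "mutated")) {
        if (is.null(p[[key]])) {
          stop("profile entry is missing required key '", key, "'",
               call. = FALSE)
        }
      }
      ref <- as.character(p$reference)
      base <- if (is.null(p$base)) {
        chars <- strsplit(refs[[ref]], "")[[1]]
        chars[unlist(p$positions, use.names = FALSE)]
      } else unlist(p$base, use.names = FALSE)
      position_profile(
        ref, as.character(p$section),
        positions = unlist(p$positions, use.names = FALSE),
        base = base,
        coverage = unlist(p$coverage, use.names = FALSE),
        mutated = unlist(p$mutated, use.names = FALSE),
        sub_counts = if (is.null(p$sub_counts)) NULL else
          lapply(p$sub_counts, function(v) unlist(v, use.names = FALSE)),
        fraction = if (is.null(p$fraction)) NULL else null_na(p$fraction))
    })
    hists <- lapply(rec$read_hists, function(h) {
      read_mut_histogram(unlist(h$bin_edges, use.names = FALSE),
                         unlist(h$counts, use.names = FALSE),
                         h$total_reads)
    })
    sample_record(variables = rec$variables, profiles = profs,
                  read_hists = hists,
                  aligned_reads = vapply(rec$aligned_reads, as.integer, 1L))
  })
  prov <- if (is.null(raw$provenance)) list() else raw$provenance
  known <- c("schema_version", "references", "sections", "samples",
             "provenance")
  extra <- setdiff(names(raw), known)
  if (length(extra)) prov$extra_keys <- raw[extra]
  study(references = refs, sections = secs, samples = samples,
        provenance = prov)
}

#' Read a sections annotation table
#'
#' CSV with columns `reference, section, start, end, role`; coordinates are
#' 1-based inclusive. An implicit `full` section is added for every reference
#' that lacks one.
#'
#' @param path CSV path.
#' @param references Named character vector of reference sequences used to
#'   validate coordinates.
#' @return Named list (by reference) of [section_annotation()] lists.
#' @export
read_sections_table <- function(path, references) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reference", "section", "start", "end", "role")
  names(df) <- tolower(names(df))
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("sections table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    ref <- df$reference[i]
    if (!ref %in% names(references)) {
      stop("sections table row ", i, ": unknown reference '", ref, "'",
           call. = FALSE)
    }
    sec <- section_annotation(df$section[i], df$role[i], df$start[i],
                              df$end[i])
    if (sec$end > nchar(references[[ref]])) {
      stop("section '", sec$name, "' of ", ref,
           " exceeds reference length ", nchar(references[[ref]]),
           call. = FALSE)
    }
    nm <- vapply(out[[ref]], `[[`, "", "name")
    if (sec$name %in% nm) {
      stop("duplicate section '", sec$name, "' for reference ", ref,
           call. = FALSE)
    }
    out[[ref]] <- c(out[[ref]], list(sec))
  }
  for (ref in names(references)) {
    has_full <- any(vapply(out[[ref]], function(s) s$role == "full",
                           logical(1)))
    if (!has_full) {
      out[[ref]] <- c(out[[ref]],
                      list(section_annotation("full", "full", 1L,
                                              nchar(references[[ref]]))))
    }
  }
  out
}

#' Read reference sequences from FASTA
#'
#' @param path FASTA path (wrapped or unwrapped). U is converted to T.
#' @return Named character vector of sequences.
#' @export
read_fasta_references <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- gsub("U", "T", toupper(as.character(set)))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' @export
print.dms_study <- function(x, ...) {
  cat("dms_study (schema ", x$schema_version, "): ",
      length(x$references), " reference(s), ",
      length(x$samples), " sample(s)\n", sep = "")
  invisible(x)
}
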