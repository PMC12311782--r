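# Converters harmonizing third-party probing outputs into the study model.
# Counts are preserved exactly; fractions are always recomputed by the single
# code path in position_profile(). Converters never invent a substitution
# breakdown: sub_counts stays NULL and identity plots report "unavailable".

#' Convert a ShapeMapper2-style profile table
#'
#' Reads a tab-separated `*_profile.txt`-style table. Only the modified
#' channel is used: `mutated = Modified_mutations`, `coverage =
#' Modified_effective_depth`. Untreated/denatured columns, when present, are
#' kept in provenance but take no part in any statistic (the target workflow
#' is DMS mutational profiling without background subtraction).
#'
#' @param profile_path Path to the TSV table. Must contain (case-insensitive)
#'   columns `Nucleotide`, `Sequence`, `Modified_mutations`,
#'   `Modified_effective_depth`.
#' @param sample Sample name to file the profile under.
#' @param reference Reference name.
#' @return A `dms_study` fragment with one sample and one reference.
#' @export
from_shapemapper <- function(profile_path, sample, reference) {
  df <- utils::read.delim(profile_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("nucleotide", "sequence", "modified_mutations",
            "modified_effective_depth")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("ShapeMapper profile is missing column(s) ",
         paste(missing, collapse = ", "), "; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  pos <- as.integer(df$nucleotide)
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("ShapeMapper profile positions must be strictly increasing",
         call. = FALSE)
  }
  seq_chars <- gsub("U", "T", toupper(df$sequence))
  if (pos[1] != 1L || !identical(pos, seq.int(1L, length(pos)))) {
    stop("ShapeMapper profile must cover positions 1..n contiguously",
         call. = FALSE)
  }
  refseq <- paste(seq_chars, collapse = "")
  prof <- position_profile(reference, "full", pos, seq_chars,
                           coverage = df$modified_effective_depth,
                           mutated = df$modified_mutations)
  extra <- setdiff(names(df), need)
  prov <- list(list(source = "shapemapper2", file = basename(profile_path),
                    unused_columns = extra))
  study(references = stats::setNames(refseq, reference),
        samples = stats::setNames(
          list(sample_record(profiles = list(prof))), sample),
        provenance = prov)
}

#' Convert RNA Framework-style count files
#'
#' Accepts either of two documented plain-text dialects, both count-based
#' (raw per-position mutation and coverage counts, one record per
#' transcript):
#'
#' * XML: `<data><transcript id="..."><sequence>...</sequence>
#'   <counts>c,c,...</counts><coverage>c,c,...</coverage></transcript></data>`
#' * TSV: blocks of three lines per transcript: `>id`, then the sequence,
#'   then two tab-separated lines `counts:<tab>c<tab>c...` and
#'   `coverage:<tab>c<tab>c...`
#'
#' Files carrying only normalized reactivities (non-integer values) are
#' rejected: the study model is count-based and normalization cannot be
#' undone.
#'
#' @param counts_path Path to the count file.
#' @param sample Sample name.
#' @return A `dms_study` fragment with one profile per transcript.
#' @export
from_rnaframework <- function(counts_path, sample) {
  lines <- readLines(counts_path, warn = FALSE)
  recs <- if (length(lines) && grepl("^\\s*<", lines[1])) {
    parse_rnaf_xml(counts_path)
  } else {
    parse_rnaf_tsv(lines)
  }
  refs <- character(0); profs <- list()
  for (r in recs) {
    n <- nchar(r$sequence)
    if (length(r$counts) != n || length(r$coverage) != n) {
      stop("RNA Framework record '", r$id, "': sequence length ", n,
           " does not match count vector length", call. = FALSE)
    }
    if (any(r$counts != round(r$counts)) || any(r$coverage != round(r$coverage))) {
      stop("RNA Framework record '", r$id, "' holds non-integer values; ",
           "raw counts are required (normalized reactivities are rejected)",
           call. = FALSE)
    }
    seq_chars <- strsplit(gsub("U", "T", toupper(r$sequence)), "")[[1]]
    refs[[r$id]] <- paste(seq_chars, collapse = "")
    profs <- c(profs, list(position_profile(r$id, "full", seq_len(n),
                                            seq_chars,
                                            coverage = r$coverage,
                                            mutated = r$counts)))
  }
  if (!length(recs)) {
    return(study(provenance = list(list(source = "rnaframework",
                                        file = basename(counts_path)))))
  }
  study(references = refs,
        samples = stats::setNames(list(sample_record(profiles = profs)),
                                  sample),
        provenance = list(list(source = "rnaframework",
                               file = basename(counts_path))))
}

parse_rnaf_xml <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//transcript")
  lapply(nodes, function(nd) {
    num <- function(tag) {
      txt <- xml2::xml_text(xml2::xml_find_first(nd, paste0("./", tag)))
      as.numeric(strsplit(trimws(txt), "[,\\s]+")[[1]])
    }
    list(id = xml2::xml_attr(nd, "id"),
         sequence = gsub("\\s", "",
                         xml2::xml_text(xml2::xml_find_first(nd, "./sequence"))),
         counts = num("counts"), coverage = num("coverage"))
  })
}

parse_rnaf_tsv <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">")) {
      stop("RNA Framework TSV dialect: expected '>id' at line ", i,
           call. = FALSE)
    }
    id <- trimws(sub("^>", "", lines[i]))
    if (i + 3L > length(lines)) {
      stop("RNA Framework TSV dialect: truncated record '", id, "'",
           call. = FALSE)
    }
    seqline <- trimws(lines[i + 1L])
    grab <- function(line, label) {
      parts <- strsplit(line, "\t")[[1]]
      if (tolower(sub(":$", "", parts[1])) != label) {
        stop("RNA Framework TSV dialect: expected '", label,
             ":' line in record '", id, "'", call. = FALSE)
      }
      as.numeric(parts[-1])
    }
    recs <- c(recs, list(list(id = id, sequence = seqline,
                              counts = grab(lines[i + 2L], "counts"),
                              coverage = grab(lines[i + 3L], "coverage"))))
    i <- i + 4L
  }
  recs
}

#' Merge study fragments
#'
#' Combines converted fragments (and simulated studies) into one study;
#' references shared between fragments must have identical sequences, and a
#' supplied FASTA, when given, must agree with every fragment's own
#' sequences.
#'
#' @param ... `dms_study` fragments.
#' @param fasta Optional path to a reference FASTA cross-checked against the
#'   fragments' sequence columns.
#' @return A merged `dms_study`.
#' @export
merge_studies <- function(..., fasta = NULL) {
  frags <- list(...)
  refs <- character(0); secs <- list(); samples <- list(); prov <- list()
  for (fr in frags) {
    for (ref in names(fr$references)) {
      if (!is.null(refs[ref]) && !is.na(refs[ref]) &&
          refs[[ref]] != fr$references[[ref]]) {
        stop("reference '", ref, "' has conflicting sequences across inputs",
             call. = FALSE)
      }
      refs[[ref]] <- fr$references[[ref]]
      if (is.null(secs[[ref]])) secs[[ref]] <- fr$sections[[ref]]
    }
    for (smp in names(fr$samples)) {
      if (is.null(samples[[smp]])) {
        samples[[smp]] <- fr$samples[[smp]]
      } else {
        samples[[smp]]$profiles <- c(samples[[smp]]$profiles,
                                     fr$samples[[smp]]$profiles)
        samples[[smp]]$read_hists <- c(samples[[smp]]$read_hists,
                                       fr$samples[[smp]]$read_hists)
        samples[[smp]]$aligned_reads <- c(samples[[smp]]$aligned_reads,
                                          fr$samples[[smp]]$aligned_reads)
      }
    }
    prov <- c(prov, fr$provenance)
  }
  if (!is.null(fasta)) {
    fa <- read_fasta_references(fasta)
    for (ref in intersect(names(fa), names(refs))) {
      if (fa[[ref]] != refs[[ref]]) {
        stop("FASTA sequence for '", ref,
             "' does not match the converted file's own sequence",
             call. = FALSE)
      }
    }
  }
  study(references = refs, sections = secs, samples = samples,
        provenance = prov)
}
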