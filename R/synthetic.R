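# Barcoded amplicon library designer and read-level DMS signal simulator.
# The designer follows the pooled-probing layout: common amplification
# primers at both ends, a reference-specific barcode inside the 5' primer,
# C/U-only unstructured flanks sized so every member has the same total
# length, and a variable region of interest (ROI) in the middle.

DEFAULT_FWD_PRIMER <- "TTAAACCGGCCAACATACC"
DEFAULT_REV_PRIMER <- "TCGAAAGGAACGAGTAGCG"

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b Character scalars of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hamming distance requires equal-length sequences (",
         nchar(a), " vs ", nchar(b), ")", call. = FALSE)
  }
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Design a barcode set with a minimum pairwise Hamming distance
#'
#' Greedy rejection sampling over random DNA words: a candidate is kept only
#' if it is at distance `>= min_hamming` from every accepted barcode.
#' Deterministic for a fixed seed. Requests that exceed the alphabet's
#' capacity outright, or exhaust the attempt budget, raise a feasibility
#' error suggesting longer barcodes.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nt.
#' @param min_hamming Minimum pairwise distance (default 4, a strict reading
#'   of "distance greater than 3").
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget.
#' @return Character vector of `n` barcodes.
#' @export
design_barcodes <- function(n, length = 8L, min_hamming = 4L, seed = 1L,
                            max_attempts = 500000L) {
  if (min_hamming < 1L) stop("min_hamming must be >= 1", call. = FALSE)
  if (min_hamming > length) {
    stop("min_hamming cannot exceed barcode length", call. = FALSE)
  }
  if (n > 4^length) {
    stop("infeasible: ", n, " barcodes of length ", length,
         " exceed the 4^", length, " possible words; use longer barcodes",
         call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  acc <- matrix(integer(0), nrow = 0, ncol = length)
  withr::local_seed(seed)
  attempts <- 0L
  while (nrow(acc) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("barcode design exhausted its sampling budget at ", nrow(acc),
           " of ", n, " barcodes; use longer barcodes or a smaller ",
           "distance bound", call. = FALSE)
    }
    cand <- sample.int(4L, length, replace = TRUE)
    if (nrow(acc) == 0L ||
        all(rowSums(acc != matrix(cand, nrow(acc), length,
                                  byrow = TRUE)) >= min_hamming)) {
      acc <- rbind(acc, cand)
    }
  }
  unname(apply(acc, 1, function(row) paste(bases[row], collapse = "")))
}

#' Design an unstructured C/U flanking sequence
#'
#' Draws C/U (emitted as C/T in DNA context) uniformly at random and
#' regenerates whenever the draw contains a run of identical bases longer
#' than `max_run`, so no emitted flank ever carries such a run.
#'
#' @param length Flank length in nt (0 gives an empty string).
#' @param max_run Longest allowed run of identical bases (default 3).
#' @param seed Integer seed.
#' @param max_attempts Regeneration cap.
#' @return A character scalar over the alphabet C/T.
#' @export
design_flank <- function(length, max_run = 3L, seed = 1L,
                         max_attempts = 10000L) {
  if (length == 0L) return("")
  withr::local_seed(seed)
  for (attempt in seq_len(max_attempts)) {
    draw <- sample(c("C", "T"), length, replace = TRUE)
    if (max(rle(draw)$lengths) <= max_run) {
      return(paste(draw, collapse = ""))
    }
  }
  stop("flank generation failed: no run-free draw of length ", length,
       " with max_run ", max_run, " within ", max_attempts, " attempts",
       call. = FALSE)
}

#' Library design specification
#'
#' @param roi_seqs Named character vector of region-of-interest sequences.
#' @param total_length Common member length in nt (default 170).
#' @param forward_primer,reverse_primer Amplification primers; members start
#'   with the forward primer verbatim and end with the reverse complement of
#'   the reverse primer (the primer anneals to the transcript's 3' end).
#' @param barcode_length Barcode length in nt (default 8, placed immediately
#'   inside the forward primer).
#' @param min_barcode_hamming Minimum pairwise barcode distance (default 4).
#' @param max_cu_run Longest allowed C/U run in flanks (default 3).
#' @param seed Integer seed.
#' @return A `dms_libraryspec` list.
#' @export
library_design_spec <- function(roi_seqs, total_length = 170L,
                                forward_primer = DEFAULT_FWD_PRIMER,
                                reverse_primer = DEFAULT_REV_PRIMER,
                                barcode_length = 8L,
                                min_barcode_hamming = 4L,
                                max_cu_run = 3L, seed = 1L) {
  roi_seqs <- vapply(roi_seqs, function(s) gsub("U", "T", toupper(s)),
                     character(1))
  fixed <- nchar(forward_primer) + barcode_length + nchar(reverse_primer)
  overflow <- names(roi_seqs)[fixed + nchar(roi_seqs) > total_length]
  if (length(overflow)) {
    stop("ROI(s) too long for total_length ", total_length, ": ",
         paste(overflow, collapse = ", "), call. = FALSE)
  }
  structure(list(roi_seqs = roi_seqs, total_length = as.integer(total_length),
                 forward_primer = forward_primer,
                 reverse_primer = reverse_primer,
                 barcode_length = as.integer(barcode_length),
                 min_barcode_hamming = as.integer(min_barcode_hamming),
                 max_cu_run = as.integer(max_cu_run),
                 seed = as.integer(seed)),
            class = "dms_libraryspec")
}

#' Assemble a barcoded equal-length library
#'
#' Lays out every member as primer5 | barcode | flank5 | roi | flank3 |
#' primer3, with flank lengths computed per member so all members share
#' `total_length`. Returns members with per-segment coordinates, the
#' matching sections annotation table, and the references.
#'
#' @param spec A [library_design_spec()].
#' @return A `dms_library` list: `members` (list of name, segments tibble,
#'   sequence), `references` (named character), `sections` (annotation
#'   lists), `barcodes`.
#' @export
assemble_library <- function(spec) {
  n <- length(spec$roi_seqs)
  barcodes <- design_barcodes(n, spec$barcode_length,
                              spec$min_barcode_hamming, seed = spec$seed)
  p5 <- spec$forward_primer
  p3 <- revcomp(spec$reverse_primer)
  members <- list(); references <- character(0); sections <- list()
  for (i in seq_len(n)) {
    name <- names(spec$roi_seqs)[i]
    roi <- spec$roi_seqs[[i]]
    flank_total <- spec$total_length - nchar(p5) - spec$barcode_length -
      nchar(roi) - nchar(p3)
    f5_len <- flank_total %/% 2L
    f3_len <- flank_total - f5_len
    f5 <- design_flank(f5_len, spec$max_cu_run, seed = spec$seed + 2L * i)
    f3 <- design_flank(f3_len, spec$max_cu_run,
                       seed = spec$seed + 2L * i + 1L)
    segs <- c(primer5 = p5, barcode = barcodes[i], flank5 = f5, roi = roi,
              flank3 = f3, primer3 = p3)
    seq_full <- paste(segs, collapse = "")
    stopifnot(nchar(seq_full) == spec$total_length)
    ends <- cumsum(nchar(segs))
    starts <- ends - nchar(segs) + 1L
    seg_tbl <- tibble::tibble(name = names(segs), role = names(segs),
                              start = as.integer(starts),
                              end = as.integer(ends))
    seg_tbl <- seg_tbl[nchar(segs) > 0L, ]
    members[[name]] <- list(name = name, segments = seg_tbl,
                            sequence = seq_full)
    references[[name]] <- seq_full
    sections[[name]] <- c(
      lapply(seq_len(nrow(seg_tbl)), function(j) {
        section_annotation(seg_tbl$name[j], seg_tbl$role[j],
                           seg_tbl$start[j], seg_tbl$end[j])
      }),
      list(section_annotation("full", "full", 1L, spec$total_length)))
  }
  structure(list(members = members, references = references,
                 sections = sections, barcodes = barcodes, spec = spec),
            class = "dms_library")
}

#' Write a library as FASTA plus sections CSV
#'
#' @param library A `dms_library`.
#' @param fasta_path,sections_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_library <- function(library, fasta_path, sections_path) {
  set <- Biostrings::DNAStringSet(library$references)
  Biostrings::writeXStringSet(set, fasta_path)
  rows <- do.call(rbind, lapply(names(library$sections), function(ref) {
    do.call(rbind, lapply(library$sections[[ref]], function(sec) {
      data.frame(reference = ref, section = sec$name, start = sec$start,
                 end = sec$end, role = sec$role)
    }))
  }))
  utils::write.csv(rows, sections_path, row.names = FALSE, quote = FALSE)
  invisible(c(fasta_path, sections_path))
}

#' Toy region-of-interest generator with known pairing
#'
#' Builds an ROI as alternating stems and loops (no thermodynamic folding:
#' the pairing state is the planted ground truth, not a prediction). Stems
#' are complementary A/C-rich duplex arms; loops are unpaired. Regenerates
#' until the ROI carries at least `min_paired_ac` paired and
#' `min_unpaired_ac` unpaired A/C positions, so a simulated profile always
#' has genuine signal variance.
#'
#' @param length ROI length in nt.
#' @param seed Integer seed.
#' @param min_paired_ac,min_unpaired_ac Composition floors.
#' @return List with `sequence` and logical `paired` mask.
#' @export
toy_roi <- function(length, seed = 1L, min_paired_ac = 6L,
                    min_unpaired_ac = 10L) {
  withr::local_seed(seed)
  for (attempt in 1:200) {
    seq_chars <- character(0); paired <- logical(0)
    while (length(seq_chars) < length) {
      stem_len <- sample(4:7, 1)
      loop_len <- sample(3:6, 1)
      arm <- sample(c("A", "C", "G", "T"), stem_len, replace = TRUE)
      loop <- sample(c("A", "C", "G", "T"), loop_len, replace = TRUE,
                     prob = c(0.35, 0.35, 0.15, 0.15))
      arm2 <- strsplit(revcomp(paste(arm, collapse = "")), "")[[1]]
      seq_chars <- c(seq_chars, arm, loop, arm2)
      paired <- c(paired, rep(TRUE, stem_len), rep(FALSE, loop_len),
                  rep(TRUE, stem_len))
    }
    seq_chars <- seq_chars[seq_len(length)]
    paired <- paired[seq_len(length)]
    ac <- seq_chars %in% c("A", "C")
    if (sum(ac & paired) >= min_paired_ac &&
        sum(ac & !paired) >= min_unpaired_ac) {
      return(list(sequence = paste(seq_chars, collapse = ""),
                  paired = paired))
    }
  }
  stop("could not generate an ROI meeting the composition floors",
       call. = FALSE)
}

#' Planted simulation ground truth for a library
#'
#' Marks `n_responders` members as ligand responders and plants a binding
#' site on `site_size` unpaired A/C positions of each responder's ROI.
#' Pairing over the whole member: primers and barcodes are treated as paired
#' (amplicon stem context), C/U flanks as unpaired, and the ROI uses the
#' supplied per-member pairing mask.
#'
#' @param library A `dms_library`.
#' @param roi_pairing Named list of logical ROI pairing masks (as from
#'   [toy_roi()]).
#' @param n_responders Number of planted responders (default 4).
#' @param site_size Binding-site positions per responder (default 8
#'   unpaired A/C bases, the scale of a purine-aptamer ligand pocket).
#' @param p_unpaired,p_paired,p_background Per-read mutation probabilities
#'   for unpaired A/C, paired A/C, and G/T positions.
#' @param protection_factor Multiplier applied to binding-site probabilities
#'   with ligand (default 0.1, a 10-fold protection).
#' @param depth Reads per member per condition (default 5000).
#' @param deletion_rate Fraction of mutation events that are deletions
#'   rather than substitutions (default 0.1).
#' @param seed Integer seed (responder choice and site placement).
#' @return A `dms_truth` list with per-member `pairing`, `responder`,
#'   `site`, and the global rate parameters.
#' @export
simulation_truth <- function(library, roi_pairing, n_responders = 4L,
                             site_size = 8L, p_unpaired = 0.02,
                             p_paired = 0.002, p_background = 0.002,
                             protection_factor = 0.1, depth = 5000L,
                             deletion_rate = 0.1, seed = 1L) {
  stopifnot(all(c(p_unpaired, p_paired, p_background) > 0),
            all(c(p_unpaired, p_paired, p_background) < 1),
            protection_factor > 0)
  withr::local_seed(seed)
  member_names <- names(library$members)
  responders <- sort(sample(member_names, n_responders))
  per_member <- list()
  for (name in member_names) {
    m <- library$members[[name]]
    segs <- m$segments
    chars <- strsplit(m$sequence, "")[[1]]
    paired <- logical(nchar(m$sequence))
    for (j in seq_len(nrow(segs))) {
      span <- segs$start[j]:segs$end[j]
      paired[span] <- switch(segs$role[j],
        primer5 = , primer3 = , barcode = TRUE,
        flank5 = , flank3 = FALSE,
        roi = roi_pairing[[name]])
    }
    site <- integer(0)
    if (name %in% responders) {
      roi_row <- segs[segs$role == "roi", ]
      roi_span <- roi_row$start:roi_row$end
      cand <- roi_span[!paired[roi_span] & chars[roi_span] %in% c("A", "C")]
      if (length(cand) < site_size) {
        stop("responder ", name, " has only ", length(cand),
             " unpaired A/C ROI positions; cannot place a site of ",
             site_size, call. = FALSE)
      }
      site <- sort(sample(cand, site_size))
    }
    per_member[[name]] <- list(pairing = paired,
                               responder = name %in% responders,
                               site = site)
  }
  structure(list(members = per_member, responders = responders,
                 p_unpaired = p_unpaired, p_paired = p_paired,
                 p_background = p_background,
                 protection_factor = protection_factor,
                 depth = as.integer(depth),
                 deletion_rate = deletion_rate),
            class = "dms_truth")
}

#' Condition specification for the simulator
#'
#' @param name Sample name.
#' @param ligand Whether the ligand is present (responders' binding sites
#'   are protected).
#' @param variables Experimental-variable metadata for the sample record.
#' @param pairing_override Optional named list of full-length pairing masks
#'   replacing the truth's masks (models a chemistry change such as
#'   pseudouridylation refolding a subset of members).
#' @return A `dms_condition` list.
#' @export
condition_spec <- function(name, ligand = FALSE, variables = list(),
                           pairing_override = NULL) {
  structure(list(name = name, ligand = ligand, variables = variables,
                 pairing_override = pairing_override),
            class = "dms_condition")
}

# Per-position mutation probabilities for one member under one condition.
member_rates <- function(chars, info, truth, ligand) {
  ac <- chars %in% c("A", "C")
  p <- ifelse(ac & !info$pairing, truth$p_unpaired,
              ifelse(ac, truth$p_paired, truth$p_background))
  if (ligand && info$responder && length(info$site)) {
    p[info$site] <- p[info$site] * truth$protection_factor
  }
  p
}

#' Simulate a probing study at the signal level
#'
#' Emulates amplicon DMS mutational profiling: for each condition and
#' member, `depth` reads are simulated; each read mutates independently at
#' each position with the position's probability (unpaired A/C high, paired
#' A/C and G/T background, ligand multiplying responders' binding-site
#' probabilities by the protection factor). Mutation events are deletions at
#' `deletion_rate`, otherwise substitutions to a uniformly random
#' non-reference base. Per-position counts are drawn as
#' Binomial(depth, p) with mutated reads assigned uniformly at random —
#' exactly the joint distribution of independent per-read coin flips — so
#' the per-read mutation histograms are genuine. Deterministic for a fixed
#' seed.
#'
#' @param library A `dms_library`.
#' @param truth A [simulation_truth()].
#' @param conditions List of [condition_spec()]s (one sample each).
#' @param seed Integer seed.
#' @return A `dms_study` with full-length profiles, per-read histograms and
#'   aligned-read counts for every member under every condition.
#' @export
simulate_study <- function(library, truth, conditions, seed = 1L) {
  withr::local_seed(seed)
  bases <- c("A", "C", "G", "T")
  samples <- list()
  for (cond in conditions) {
    profs <- list(); hists <- list(); aligned <- integer(0)
    for (name in names(library$members)) {
      m <- library$members[[name]]
      chars <- strsplit(m$sequence, "")[[1]]
      L <- length(chars)
      info <- truth$members[[name]]
      if (!is.null(cond$pairing_override[[name]])) {
        info$pairing <- cond$pairing_override[[name]]
      }
      p <- member_rates(chars, info, truth, cond$ligand)
      depth <- truth$depth
      if (depth == 0L) {
        profs <- c(profs, list(position_profile(
          name, "full", seq_len(L), chars,
          coverage = integer(L), mutated = integer(L),
          sub_counts = stats::setNames(rep(list(integer(L)), 4), bases))))
        hists[[name]] <- mutations_per_read_histogram(integer(0))
        aligned[[name]] <- 0L
        next
      }
      k <- stats::rbinom(L, depth, p)
      hot <- which(k > 0L)
      reads_all <- unlist(lapply(hot, function(j) sample.int(depth, k[j])),
                          use.names = FALSE)
      per_read <- tabulate(reads_all, nbins = depth)
      n_events <- length(reads_all)
      sub_mat <- integer(4L * L)  # target-within-position layout
      if (n_events > 0L) {
        pos_all <- rep.int(hot, k[hot])
        is_del <- stats::runif(n_events) < truth$deletion_rate
        # target base uniform among the 3 non-reference bases
        non_ref <- matrix(c(2L, 3L, 4L, 1L, 3L, 4L,
                            1L, 2L, 4L, 1L, 2L, 3L), nrow = 4, byrow = TRUE)
        base_idx <- match(chars, bases)
        pick <- sample.int(3L, n_events, replace = TRUE)
        target <- non_ref[cbind(base_idx[pos_all], pick)]
        keep <- !is_del
        sub_mat <- tabulate((pos_all[keep] - 1L) * 4L + target[keep],
                            nbins = 4L * L)
      }
      sub <- stats::setNames(
        lapply(1:4, function(b) sub_mat[seq.int(b, 4L * L, by = 4L)]), bases)
      profs <- c(profs, list(position_profile(
        name, "full", seq_len(L), chars,
        coverage = rep(depth, L), mutated = k, sub_counts = sub)))
      hists[[name]] <- mutations_per_read_histogram(per_read)
      aligned[[name]] <- depth
    }
    samples[[cond$name]] <- sample_record(variables = cond$variables,
                                          profiles = profs,
                                          read_hists = hists,
                                          aligned_reads = aligned)
  }
  study(references = library$references, sections = library$sections,
        samples = samples,
        provenance = list(list(source = "dmscreen_simulator", seed = seed)))
}

# Smallest barcode length whose Gilbert-Varshamov bound guarantees n words
# at pairwise distance >= d over the 4-letter alphabet.
gv_barcode_length <- function(n, d = 4L, floor_len = 8L) {
  for (L in floor_len:32L) {
    radius <- 0:(d - 1L)
    ball <- sum(choose(L, radius) * 3^radius)
    if (4^L / ball >= n) return(L)
  }
  stop("no feasible barcode length for n = ", n, call. = FALSE)
}

#' One-call synthetic study builder
#'
#' Convenience wrapper used throughout the test-suite and examples:
#' designs `n_members` toy ROIs, assembles the barcoded library, plants
#' `n_responders` ligand responders, and simulates the requested
#' conditions.
#'
#' @param n_members Number of library members (default 81).
#' @param n_responders Planted responders (default 4).
#' @param depth Reads per member per condition (default 5000).
#' @param conditions List of [condition_spec()]s; default two replicates
#'   without ligand plus one with-ligand sample.
#' @param roi_length ROI length in nt (default 73).
#' @param seed Integer seed.
#' @param ... Passed to [simulation_truth()].
#' @return List with `study`, `library`, `truth`.
#' @export
simulate_synthetic_study <- function(n_members = 81L, n_responders = 4L,
                                     depth = 5000L,
                                     conditions = NULL, roi_length = 73L,
                                     seed = 1L, ...) {
  withr::local_seed(seed)
  roi_seeds <- sample.int(.Machine$integer.max, n_members)
  rois <- lapply(roi_seeds, function(s) toy_roi(roi_length, seed = s))
  names(rois) <- sprintf("member_%03d", seq_len(n_members))
  # 8 nt covers libraries up to ~100 members comfortably; beyond that use
  # the smallest length the Gilbert-Varshamov bound guarantees outright
  bc_len <- if (n_members <= 100L) 8L else gv_barcode_length(n_members)
  spec <- library_design_spec(vapply(rois, `[[`, "", "sequence"),
                              barcode_length = bc_len,
                              seed = seed)
  lib <- assemble_library(spec)
  truth <- simulation_truth(lib, lapply(rois, `[[`, "paired"),
                            n_responders = n_responders, depth = depth,
                            seed = seed, ...)
  if (is.null(conditions)) {
    conditions <- list(
      condition_spec("rep1", ligand = FALSE,
                     variables = list(adenine = list(value = 0, unit = "mM"))),
      condition_spec("rep2", ligand = FALSE,
                     variables = list(adenine = list(value = 0, unit = "mM"))),
      condition_spec("ligand", ligand = TRUE,
                     variables = list(adenine = list(value = 5, unit = "mM"))))
  }
  st <- simulate_study(lib, truth, conditions, seed = seed + 1L)
  list(study = st, library = lib, truth = truth)
}
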