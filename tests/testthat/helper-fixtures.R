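# Shared fixtures and independent oracles, all built in code.

# A tiny two-sample study over one 10-nt reference with a hand-chosen ROI.
tiny_study <- function() {
  refseq <- "ACGTACGTAC"
  chars <- strsplit(refseq, "")[[1]]
  p1 <- position_profile("ref1", "full", 1:10, chars,
                         coverage = c(200L, 200L, 200L, 200L, 0L, 200L,
                                      200L, 200L, 200L, 200L),
                         mutated = c(5L, 10L, 2L, 1L, 0L, 20L, 4L, 0L, 6L, 8L))
  p2 <- position_profile("ref1", "full", 1:10, chars,
                         coverage = rep(100L, 10),
                         mutated = c(2L, 6L, 1L, 0L, 1L, 11L, 2L, 1L, 3L, 4L))
  study(
    references = c(ref1 = refseq),
    sections = list(ref1 = list(section_annotation("roi", "roi", 3L, 8L))),
    samples = list(
      s1 = sample_record(
        variables = list(MgCl2 = list(value = 0, unit = "mM")),
        profiles = list(p1),
        read_hists = list(ref1 = read_mut_histogram(0:3, c(150L, 40L, 10L))),
        aligned_reads = c(ref1 = 250L)),
      s2 = sample_record(
        variables = list(MgCl2 = list(value = 10, unit = "mM")),
        profiles = list(p2),
        read_hists = list(ref1 = read_mut_histogram(0:3, c(60L, 30L, 10L))),
        aligned_reads = c(ref1 = 100L))))
}

# Bare profile view for statistics tests (no study needed).
make_view <- function(fraction, base = rep("A", length(fraction)),
                      position = seq_along(fraction),
                      coverage = rep(1000L, length(fraction)),
                      reference = "r", section = "roi") {
  v <- tibble::tibble(position = as.integer(position), base = base,
                      coverage = as.integer(coverage),
                      mutated = as.integer(round(fraction * coverage)),
                      fraction = fraction)
  attr(v, "reference") <- reference
  attr(v, "section") <- section
  class(v) <- c("dms_view", class(v))
  v
}

# Direct-summation comparison oracle, independent of compare_profiles():
# textbook formulas computed with explicit accumulators.
oracle_compare <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0; sq <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; syy <- syy + y[i]^2; sxy <- sxy + x[i] * y[i]
    sq <- sq + (y[i] - x[i])^2
  }
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  list(r = r, r2 = r^2, rmse = sqrt(sq / n), slope = slope,
       intercept = (sy - slope * sx) / n)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <=
                    rel_tol * pmax(1, abs(expected))),
              label = paste0("relative difference within ", rel_tol))
}

# Run-length oracle: longest run of identical characters.
longest_run <- function(seq) {
  if (!nchar(seq)) return(0L)
  max(rle(strsplit(seq, "")[[1]])$lengths)
}

# Brute-force pairwise minimum Hamming distance.
min_pairwise_hamming <- function(codes) {
  m <- do.call(rbind, strsplit(codes, ""))
  best <- ncol(m)
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      best <- min(best, sum(m[i, ] != m[j, ]))
    }
  }
  best
}

write_shapemapper_fixture <- function(path) {
  lines <- c(
    paste("Nucleotide", "Sequence", "Modified_mutations",
          "Modified_effective_depth", "Untreated_mutations", sep = "\t"),
    "1\tA\t50\t1000\t3",
    "2\tC\t25\t500\t2",
    "3\tG\t0\t0\t0",
    "4\tT\t7\t700\t1",
    "5\tA\t33\t1100\t5")
  writeLines(lines, path)
  path
}

write_rnaframework_tsv_fixture <- function(path) {
  writeLines(c(
    ">tx1",
    "ACGT",
    "counts:\t1\t0\t2\t0",
    "coverage:\t100\t100\t100\t0"), path)
  path
}

write_rnaframework_xml_fixture <- function(path) {
  writeLines(c(
    "<data>",
    "  <transcript id=\"tx2\">",
    "    <sequence>ACCA</sequence>",
    "    <counts>4,0,1,2</counts>",
    "    <coverage>200,200,50,100</coverage>",
    "  </transcript>",
    "</data>"), path)
  path
}

# One small simulated study cached per test run (12 members keeps every
# plot/screen test fast).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_synthetic_study(n_members = 12L, n_responders = 2L,
                                         depth = 2000L, seed = 101L)
    }
    cache
  }
})

# Standard arguments to build each plot kind from the cached simulation.
plot_args <- function(kind, sim) {
  ref <- names(sim$study$references)[1]
  roi_prof <- get_profile(sim$study, "rep1", ref, "roi")
  ac_pos <- roi_prof$positions[roi_prof$base %in% c("A", "C")][1]
  switch(kind,
    aligned_reads_freq = ,
    base_coverage = ,
    mut_per_read = ,
    mutation_fraction = ,
    fraction_identity = list(
      spec = selection_spec(samples = "rep1", references = ref,
                            bases = c("A", "C", "G", "T"))),
    compare_profiles = ,
    fraction_delta = list(
      spec = selection_spec(samples = c("rep1", "ligand"), references = ref,
                            section = "roi")),
    variable_across_samples = list(
      spec = selection_spec(references = ref,
                            bases = c("A", "C", "G", "T")),
      position = ac_pos, variable = "adenine"),
    correlation_by_reference = list(
      spec = selection_spec(samples = c("rep1", "rep2"))))
}
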