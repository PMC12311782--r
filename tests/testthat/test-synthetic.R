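test_that("hamming counts mismatches and rejects unequal lengths", {
  expect_equal(hamming("ACGT", "ACGT"), 0L)
  expect_equal(hamming("AAAA", "TTTT"), 4L)
  expect_error(hamming("AC", "ACG"), "equal-length")
  withr::with_seed(3, {
    for (i in 1:20) {
      a <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                 collapse = "")
      tally <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      expect_equal(hamming(a, b), tally)
    }
  })
})

test_that("barcode sets satisfy the pairwise distance contract", {
  two <- design_barcodes(2, length = 4, min_hamming = 4, seed = 2)
  expect_equal(hamming(two[1], two[2]), 4L)
  one <- design_barcodes(1, length = 6, seed = 2)
  expect_equal(nchar(one), 6L)
  set <- design_barcodes(20, length = 8, min_hamming = 4, seed = 7)
  expect_gte(min_pairwise_hamming(set), 4L)
  # deterministic for a fixed seed
  expect_identical(set, design_barcodes(20, length = 8, min_hamming = 4,
                                        seed = 7))
  expect_error(design_barcodes(20, length = 2, min_hamming = 2, seed = 1),
               "infeasible|budget")
})

test_that("flank sequences are C/T-only with bounded runs", {
  expect_identical(design_flank(0), "")
  withr::with_seed(1, {
    for (i in 1:200) {
      fl <- design_flank(30, seed = i)
      expect_true(grepl("^[CT]+$", fl))
      expect_lte(longest_run(fl), 3L)
    }
  })
  # a length-4 flank can never be a homopolymer
  for (i in 1:50) expect_false(design_flank(4, seed = i) %in%
                                 c("CCCC", "TTTT"))
})

test_that("assembled members are equal length with primers at both ends", {
  spec <- library_design_spec(
    c(short = paste(rep("AC", 30), collapse = ""),   # 60 nt
      long = paste(rep("GCA", 24), collapse = "")),  # 72 nt
    seed = 4)
  lib <- assemble_library(spec)
  lens <- nchar(lib$references)
  expect_true(all(lens == 170L))
  fwd <- dmscreen:::DEFAULT_FWD_PRIMER
  rev3 <- dmscreen:::revcomp(dmscreen:::DEFAULT_REV_PRIMER)
  for (seq in lib$references) {
    expect_identical(substr(seq, 1, nchar(fwd)), fwd)
    expect_identical(substr(seq, 171 - nchar(rev3), 170), rev3)
  }
  # differing ROI lengths are absorbed by the flanks
  segs_short <- lib$members$short$segments
  segs_long <- lib$members$long$segments
  f5 <- function(s) s$end[s$role == "flank5"] - s$start[s$role == "flank5"] + 1
  expect_gt(f5(segs_short), f5(segs_long))
})

test_that("segment coordinates partition each member exactly", {
  lib <- small_sim()$library
  for (m in lib$members) {
    segs <- m$segments
    expect_equal(segs$start[1], 1L)
    expect_equal(segs$end[nrow(segs)], nchar(m$sequence))
    expect_true(all(segs$start[-1] == utils::head(segs$end, -1) + 1L))
    rebuilt <- paste(substring(m$sequence, segs$start, segs$end),
                     collapse = "")
    expect_identical(rebuilt, m$sequence)
  }
})

test_that("ROIs too long for the layout are reported by name", {
  expect_error(
    library_design_spec(c(ok = "ACGT", bad = paste(rep("A", 160),
                                                   collapse = ""))),
    "too long.*bad")
})

test_that("library FASTA and sections CSV feed back into the study model", {
  lib <- small_sim()$library
  fa <- withr::local_tempfile(fileext = ".fasta")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, fa, cs)
  refs <- read_fasta_references(fa)
  expect_identical(refs, lib$references)
  secs <- read_sections_table(cs, refs)
  expect_setequal(names(secs), names(refs))
  roles <- vapply(secs[[1]], `[[`, "", "role")
  expect_true(all(c("primer5", "barcode", "roi", "primer3", "full") %in%
                    roles))
})

test_that("the simulator is bit-deterministic for a fixed seed", {
  lib <- small_sim()$library
  truth <- small_sim()$truth
  conds <- list(condition_spec("a"), condition_spec("b", ligand = TRUE))
  s1 <- simulate_study(lib, truth, conds, seed = 55)
  s2 <- simulate_study(lib, truth, conds, seed = 55)
  expect_identical(s1, s2)
  s3 <- simulate_study(lib, truth, conds, seed = 56)
  expect_false(identical(s1, s3))
})

test_that("empirical fractions stay within 3 binomial SEs of the truth", {
  withr::with_seed(12, {
    roi <- toy_roi(60, seed = 31)
    spec <- library_design_spec(c(m1 = roi$sequence), seed = 31)
    lib <- assemble_library(spec)
    truth <- simulation_truth(lib, list(m1 = roi$paired), n_responders = 0,
                              depth = 10000L, seed = 31)
    st <- simulate_study(lib, truth, list(condition_spec("s")), seed = 31)
    prof <- get_profile(st, "s", "m1", "full")
    p_true <- dmscreen:::member_rates(strsplit(lib$references[["m1"]], "")[[1]],
                                      truth$members$m1, truth, ligand = FALSE)
    se <- sqrt(p_true * (1 - p_true) / 10000)
    expect_true(all(abs(prof$fraction - p_true) <= 3 * se))
  })
})

test_that("ligand protection lowers site fractions by construction", {
  sim <- small_sim()
  for (resp in sim$truth$responders) {
    site <- sim$truth$members[[resp]]$site
    f_minus <- get_profile(sim$study, "rep1", resp, "full")$fraction[site]
    f_plus <- get_profile(sim$study, "ligand", resp, "full")$fraction[site]
    expect_true(all(f_plus < f_minus))
  }
})

test_that("substitution counts respect the deletion margin and histograms tally", {
  sim <- small_sim()
  st <- sim$study
  ref <- names(st$references)[1]
  prof <- get_profile(st, "rep1", ref, "full")
  subs <- Reduce(`+`, prof$sub_counts)
  expect_true(all(subs <= prof$mutated))
  expect_true(any(subs < prof$mutated))  # deletions leave a gap
  h <- st$samples$rep1$read_hists[[ref]]
  expect_equal(h$total_reads, st$samples$rep1$aligned_reads[[ref]])
  # mean mutations per read ~ sum of per-position probabilities
  lib <- sim$library; truth <- sim$truth
  p_true <- dmscreen:::member_rates(strsplit(lib$references[[ref]], "")[[1]],
                                    truth$members[[ref]], truth,
                                    ligand = FALSE)
  mu <- sum(p_true)
  mids <- utils::head(h$bin_edges, -1)
  mean_obs <- sum(mids * h$counts) / h$total_reads
  se <- sqrt(sum(p_true * (1 - p_true)) / h$total_reads)
  expect_lt(abs(mean_obs - mu), 3 * se + 1e-6)
})

test_that("zero depth yields fully masked profiles", {
  roi <- toy_roi(60, seed = 5)
  spec <- library_design_spec(c(m1 = roi$sequence), seed = 5)
  lib <- assemble_library(spec)
  truth <- simulation_truth(lib, list(m1 = roi$paired), n_responders = 0,
                            depth = 0L, seed = 5)
  st <- simulate_study(lib, truth, list(condition_spec("s")), seed = 5)
  prof <- get_profile(st, "s", "m1", "full")
  expect_true(all(is.na(prof$fraction)))
  expect_true(all(prof$coverage == 0L))
})
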