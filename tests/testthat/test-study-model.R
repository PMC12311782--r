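test_that("fractions are computed from counts and masked at zero coverage", {
  s <- tiny_study()
  p <- get_profile(s, "s1", "ref1", "full")
  expect_equal(p$fraction[1], 5 / 200)
  expect_true(is.na(p$fraction[5]))       # coverage 0 -> masked
  expect_equal(p$fraction[6], 20 / 200)
  # recomputation is idempotent
  expect_equal(dmscreen:::compute_fraction(p), p$fraction)
})

test_that("count invariants are enforced with positional context", {
  expect_error(position_profile("r", "full", 1:2, c("A", "C"),
                                coverage = c(10L, 10L),
                                mutated = c(11L, 0L)),
               "mutated > coverage.*position 1")
  expect_error(position_profile("r", "full", 1:2, c("A", "C"),
                                coverage = c(10L, 10L), mutated = c(1L, 1L),
                                sub_counts = list(A = c(2L, 0L), C = c(0L, 0L),
                                                  G = c(0L, 0L),
                                                  T = c(0L, 0L))),
               "sub_counts exceeds mutated")
  expect_error(position_profile("r", "full", 1:3, c("A", "C"),
                                coverage = rep(1L, 3), mutated = rep(0L, 3)),
               "unequal lengths")
})

test_that("study JSON round-trips exactly, masked positions included", {
  s <- tiny_study()
  f <- withr::local_tempfile(fileext = ".json")
  write_study(s, f)
  s2 <- load_study(f)
  expect_equal(s2, s)
  # byte-stable: writing the reloaded study reproduces the file
  f2 <- withr::local_tempfile(fileext = ".json")
  write_study(s2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("an empty study and a simulated study both round-trip", {
  f <- withr::local_tempfile(fileext = ".json")
  empty <- study()
  write_study(empty, f)
  expect_equal(load_study(f), empty)

  sim <- small_sim()$study
  write_study(sim, f)
  expect_equal(load_study(f), sim)
})

test_that("masked fractions are encoded as null and preserved on reload", {
  s <- tiny_study()
  f <- withr::local_tempfile(fileext = ".json")
  write_study(s, f)
  raw <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  frac <- raw$samples$s1$profiles[[1]]$fraction
  expect_null(frac[[5]])
  expect_true(is.na(load_study(f)$samples$s1$profiles[["ref1::full"]]$fraction[5]))
})

test_that("load errors name the offending key; unknown keys are preserved", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version": "1", "references": {"r": "ACG"}}', f)
  expect_error(load_study(f), "missing required key 'samples'")
  writeLines("{not json", f)
  expect_error(load_study(f), "cannot parse")
  writeLines(paste0('{"schema_version":"1","references":{},"samples":{},',
                    '"exporter_build":"xyz"}'), f)
  st <- load_study(f)
  expect_equal(st$provenance$extra_keys$exporter_build, "xyz")
})

test_that("write_study rejects an unwritable path", {
  expect_error(write_study(tiny_study(), "/nonexistent-dir/x/y.json"),
               "cannot write")
})

test_that("sections table is validated and gains an implicit full section", {
  refs <- c(ref1 = paste(rep("ACGTA", 34), collapse = ""))  # 170 nt
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("reference,section,start,end,role",
               "ref1,variable,40,112,roi"), f)
  secs <- read_sections_table(f, refs)
  roi <- secs$ref1[[1]]
  expect_equal(roi$end - roi$start + 1L, 73L)
  roles <- vapply(secs$ref1, `[[`, "", "role")
  expect_true("full" %in% roles)
  full <- secs$ref1[[which(roles == "full")]]
  expect_equal(c(full$start, full$end), c(1L, 170L))

  writeLines(c("reference,section,start,end,role",
               "ref1,bad,50,40,roi"), f)
  expect_error(read_sections_table(f, refs), "start")
  writeLines(c("reference,section,start,end,role",
               "ref1,huge,1,9999,roi"), f)
  expect_error(read_sections_table(f, refs), "exceeds reference length")
  writeLines(c("reference,section,start,end,role",
               "ref1,a,1,10,roi", "ref1,a,5,20,roi"), f)
  expect_error(read_sections_table(f, refs), "duplicate section")
  writeLines(c("reference,section,start,end,role",
               "ref1,whole,1,170,full"), f)
  expect_equal(read_sections_table(f, refs)$ref1[[1]]$role, "full")
})

test_that("section slicing returns the reference subsequence at 1-based coords", {
  s <- tiny_study()
  p <- get_profile(s, "s1", "ref1", "roi")  # roi = 3..8
  expect_length(p$positions, 6L)
  expect_identical(p$positions, 3:8)
  expect_identical(paste(p$base, collapse = ""),
                   substr(s$references[["ref1"]], 3, 8))
  full <- get_profile(s, "s1", "ref1", "full")
  expect_equal(p$fraction, full$fraction[3:8])
})

test_that("FASTA references load with U converted and names trimmed", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1 some description", "ACGU", ">r2", "GGCC"), f)
  refs <- read_fasta_references(f)
  expect_identical(refs, c(r1 = "ACGT", r2 = "GGCC"))
})
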