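test_that("reference construction honors requested lengths and records truth", {
  sim <- sim_reference(c(chrA = 200000, chrB = 100000), seed = 1)
  expect_equal(unname(Biostrings::width(sim$genome)), c(200000L, 100000L))
  expect_equal(names(sim$genome), c("chrA", "chrB"))
  expect_equal(nrow(sim$truth), 0L)

  ev <- tibble(sample_id = "S1", chrom = "chrA", start = 50000L, end = 70000L,
               kind = "duplication", cn = 4)
  sim2 <- sim_reference(c(chrA = 200000, chrB = 100000), events = ev, seed = 1)
  expect_equal(nrow(sim2$truth), 1L)
  expect_equal(sim2$truth$cn, 4)
  expect_equal(sim2$truth$kind, "duplication")
  # CN events do not alter the sequence
  expect_identical(as.character(sim2$genome), as.character(sim$genome))
})

test_that("generation is byte-identical under a fixed seed", {
  ev <- bind_rows(
    tibble(sample_id = "S1", chrom = "chr1", start = 10000L, end = 20000L,
           kind = "deletion", cn = 1),
    tibble(kind = "satellite_array", chrom = "chr1", start = 40000L,
           monomer_length = 107L, n_copies = 30L, divergence = 0.02,
           family_id = "sat1")
  )
  run <- function() sim_reference(c(chr1 = 60000), events = ev,
                                  masked_fraction = 0.1, seed = 99)
  s1 <- run(); s2 <- run()
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(s1$genome, f1); write_fasta(s2$genome, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$mask, s2$mask)
})

test_that("invalid event requests are rejected with clear errors", {
  expect_error(
    sim_reference(c(chr1 = 50000),
                  events = tibble(sample_id = "S1", chrom = "chr1",
                                  start = 40000L, end = 60000L,
                                  kind = "duplication", cn = 4)),
    "exceeds chromosome"
  )
  ev <- bind_rows(
    tibble(kind = "satellite_array", chrom = "chr1", start = 1000L,
           monomer_length = 100L, n_copies = 20L, family_id = "a"),
    tibble(kind = "satellite_array", chrom = "chr1", start = 1500L,
           monomer_length = 100L, n_copies = 20L, family_id = "b")
  )
  expect_error(sim_reference(c(chr1 = 50000), events = ev), "overlapping")
  expect_error(sim_reference(c(chr1 = 0)), "lengths must be > 0")
  expect_error(sim_reference(c(chr1 = 1000), masked_fraction = 1), "masked_fraction")
})

test_that("sample CN tracks override the diploid baseline inside events only", {
  ev <- tibble(sample_id = "S1", chrom = "chr1", start = 3000L, end = 5000L,
               kind = "deletion", cn = 1)
  sim <- sim_reference(c(chr1 = 10000), events = ev, samples = c("S1", "S2"), seed = 2)
  tr <- derive_sample(sim, "S1")
  expect_equal(tr$cn, c(2, 1, 2))
  expect_equal(tr$start, c(0L, 3000L, 5000L))
  expect_equal(tr$end, c(3000L, 5000L, 10000L))
  # a sample with no events is flat diploid
  tr2 <- derive_sample(sim, "S2")
  expect_equal(tr2$cn, 2)
  expect_error(derive_sample(sim, "nope"), "unknown sample_id")
})

test_that("implanted-event bases equal bases where the CN track departs from 2", {
  ev <- bind_rows(
    tibble(sample_id = "S1", chrom = "chr1", start = 10000L, end = 30000L,
           kind = "duplication", cn = 4),
    tibble(sample_id = "S1", chrom = "chr2", start = 5000L, end = 20000L,
           kind = "deletion", cn = 0.5)
  )
  sim <- sim_reference(c(chr1 = 100000, chr2 = 50000), events = ev, seed = 3)
  tr <- derive_sample(sim, "S1")
  cn_event_truth <- sim$truth[sim$truth$kind %in% c("duplication", "deletion"), ]
  expect_equal(sum(tr$end[tr$cn != 2] - tr$start[tr$cn != 2]),
               sum(cn_event_truth$end - cn_event_truth$start))
})

test_that("read-start totals follow the Poisson expectation and scale with CN", {
  track <- tibble(chrom = "chr1", start = 0L, end = 100000L, cn = 2)
  expected <- 30 * 100000 / 100   # 30000 reads
  totals <- vapply(1:5, function(s)
    sum(sim_read_starts(track, coverage = 30, read_length = 100, seed = s)$n),
    double(1))
  expect_true(all(abs(totals - expected) < 4 * sqrt(expected)))

  # CN 4 doubles the diploid start rate
  track4 <- tibble(chrom = "chr1", start = 0L, end = 100000L, cn = 4)
  t4 <- sum(sim_read_starts(track4, coverage = 30, read_length = 100, seed = 1)$n)
  expect_gt(t4 / totals[1], 2 * 0.95)
  expect_lt(t4 / totals[1], 2 * 1.05)

  # reproducible under a fixed seed
  a <- sim_read_starts(track, coverage = 30, read_length = 100, seed = 7)
  b <- sim_read_starts(track, coverage = 30, read_length = 100, seed = 7)
  expect_identical(a, b)
  expect_error(sim_read_starts(track, coverage = 0), "coverage")
})

test_that("mean depth in a CN=k region approaches k/2 of background at 60x", {
  ev <- tibble(sample_id = "S1", chrom = "chr1", start = 200000L, end = 300000L,
               kind = "duplication", cn = 4)
  sim <- sim_reference(c(chr1 = 600000), events = ev, seed = 4)
  rs <- sim_read_starts(derive_sample(sim, "S1"), coverage = 60,
                        read_length = 100, seed = 11)
  inside <- rs$pos >= 200000 & rs$pos < 300000
  rate_in <- sum(rs$n[inside]) / 100000
  rate_out <- sum(rs$n[!inside]) / 500000
  expect_lt(abs(rate_in / rate_out - 2), 2 * 0.05)
})

test_that("simulated reads are faithful substrings at zero error rate", {
  sim <- sim_reference(c(chr1 = 20000), seed = 5)
  reads <- sim_reads(sim, n_reads = 200, read_length = 100, error_rate = 0, seed = 6)
  seqs <- as.character(sim$genome)
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    ref <- substr(seqs[[reads$chrom[i]]], reads$pos[i] + 1, reads$pos[i] + 100)
    obs <- reads$sequence[i]
    if (reads$strand[i] == "-")
      obs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(obs)))
    obs == ref
  }, logical(1))
  expect_true(all(ok))
  expect_true(all(nchar(reads$quality) == nchar(reads$sequence)))
})

test_that("read sampling represents a dispersed family at its genomic fraction", {
  ev <- tibble(kind = "dispersed_family", family_id = "fam",
               element_length = 5000L, proportion = 0.1, divergence = 0.02)
  sim <- sim_reference(c(chr1 = 500000, chr2 = 500000), events = ev, seed = 7)
  reads <- sim_reads(sim, n_reads = 20000, read_length = 100, seed = 8)
  fam <- sim$truth[sim$truth$kind == "dispersed_family", ]
  in_fam <- vapply(seq_len(nrow(reads)), function(i) {
    f <- fam[fam$chrom == reads$chrom[i], ]
    any(f$start < reads$pos[i] + 100 & reads$pos[i] < f$end)
  }, logical(1))
  p_hat <- mean(in_fam)
  # true overlap probability, with read-length edge inflation
  expect_lt(abs(p_hat - 0.1), 0.02)
})

test_that("read simulation rejects impossible requests", {
  sim <- sim_reference(c(chr1 = 1000), seed = 9)
  expect_error(sim_reads(sim, n_reads = 10, read_length = 2000), "shortest chromosome")
  expect_error(sim_reads(sim, n_reads = 10, read_length = 100, error_rate = 0.5),
               "error_rate")
})

test_that("low-quality tails appear at the configured rate and encode Q10", {
  sim <- sim_reference(c(chr1 = 50000), seed = 10)
  reads <- sim_reads(sim, n_reads = 2000, read_length = 100,
                     low_q_tail_frac = 0.3, max_tail = 10, seed = 11)
  has_tail <- grepl("\\+$", reads$quality)
  expect_gt(mean(has_tail), 0.25)
  expect_lt(mean(has_tail), 0.35)
  expect_true(all(nchar(reads$quality) == 100))
})
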