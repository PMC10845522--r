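test_that("WSSD calling applies the five-consecutive-window rule literally", {
  p <- profile_from_cn(c(2, 2, 3, 3, 3, 3, 3, 2))
  calls <- call_wssd(p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "duplication")
  expect_equal(calls$start, p$start[3])
  expect_equal(calls$end, p$end[7])
  expect_equal(calls$n_windows, 5L)
  expect_equal(calls$mean_cn, 3)

  # four consecutive windows are not enough
  expect_equal(nrow(call_wssd(profile_from_cn(c(3, 3, 3, 3, 2, 2, 2, 2)))), 0L)
  # flat diploid: no calls
  expect_equal(nrow(call_wssd(profile_from_cn(rep(2, 50)))), 0L)
  # deletions mirror the rule
  del <- call_wssd(profile_from_cn(c(2, 1, 1, 1, 1, 1, 2)))
  expect_equal(del$kind, "deletion")
  expect_equal(del$n_windows, 5L)
})

test_that("one sub-threshold window splits a run and flanks never shift calls", {
  split <- call_wssd(profile_from_cn(c(3, 3, 3, 3, 3, 2, 3, 3, 3, 3, 3)))
  expect_equal(nrow(split), 2L)

  base <- profile_from_cn(c(2, 2, 3, 3, 3, 3, 3, 3, 2))
  calls0 <- call_wssd(base)
  padded <- profile_from_cn(c(rep(2, 10), c(2, 2, 3, 3, 3, 3, 3, 3, 2), rep(2, 10)))
  calls1 <- call_wssd(padded)
  expect_equal(calls1$n_windows, calls0$n_windows)
  expect_equal(calls1$mean_cn, calls0$mean_cn)
  expect_equal(calls1$start - 10000L, calls0$start)
})

test_that("log2 ratios follow the defining identities", {
  s <- profile_from_cn(c(4, 2, 1, 0.05))
  r <- profile_from_cn(c(2, 2, 2, 2))
  l2r <- compute_l2r(s, r)
  expect_equal(l2r$l2r[1], 1)
  expect_equal(l2r$l2r[2], 0)
  expect_equal(l2r$l2r[3], -1)
  expect_true(is.na(l2r$l2r[4]))  # CN below floor -> undefined

  expect_error(compute_l2r(s, profile_from_cn(c(2, 2, 2))), "identical windows")
})

test_that("digital CGH emits runs longer than 10 kb and splits mixed signs", {
  # 12 windows of 1,033 bp span each: genomic length 12,396 > 10 kb
  mk <- function(l2r, span) {
    n <- length(l2r)
    tibble(chrom = "chr1", start = (seq_len(n) - 1L) * span,
           end = seq_len(n) * span, l2r = l2r)
  }
  g <- call_cgh(mk(rep(0.6, 12), 1033L))
  expect_equal(nrow(g), 1L)
  expect_equal(g$kind, "gain")
  expect_equal(g$length, 12L * 1033L)

  # 9 windows spanning 9,000 bp: below the length floor
  expect_equal(nrow(call_cgh(mk(rep(0.6, 9), 1000L))), 0L)

  # +0.6 run, one near-zero window, -0.6 run -> one gain and one loss
  both <- call_cgh(mk(c(rep(0.6, 11), 0.01, rep(-0.6, 11)), 1000L))
  expect_equal(both$kind, c("gain", "loss"))
  expect_equal(nrow(both), 2L)
})

test_that("digital CGH of a profile against itself is silent and antisymmetric", {
  sim <- sim_reference(c(chr1 = 300000), samples = "S", seed = 40)
  w <- define_windows(sim)
  rs <- sim_read_starts(derive_sample(sim, "S"), coverage = 30, seed = 41)
  prof <- calibrate_cn(window_depth(w, rs, read_length = 100))
  expect_equal(nrow(call_cgh(compute_l2r(prof, prof))), 0L)

  rs2 <- sim_read_starts(derive_sample(sim, "S"), coverage = 30, seed = 42)
  prof2 <- calibrate_cn(window_depth(w, rs2, read_length = 100))
  ab <- compute_l2r(prof, prof2)
  ba <- compute_l2r(prof2, prof)
  expect_equal(ba$l2r, -ab$l2r)
})

test_that("shared CNVRs are the base-wise intersection across samples", {
  r <- tibble(sample_id = c("A", "B"), chrom = "chr1",
              start = c(100L, 150L), end = c(200L, 300L), kind = "gain")
  res <- intersect_cnvrs(r)
  shared <- res[res$status == "shared", ]
  expect_equal(shared$start, 150L)
  expect_equal(shared$end, 200L)
  expect_equal(nrow(res[res$status == "sample-specific", ]), 0L)

  disjoint <- tibble(sample_id = c("A", "B"), chrom = "chr1",
                     start = c(100L, 500L), end = c(200L, 700L), kind = "gain")
  res2 <- intersect_cnvrs(disjoint)
  expect_equal(nrow(res2[res2$status == "shared", ]), 0L)
  expect_equal(nrow(res2[res2$status == "sample-specific", ]), 2L)

  mixed <- tibble(sample_id = c("A", "B"), chrom = "chr1",
                  start = c(0L, 0L), end = c(10L, 10L),
                  kind = c("gain", "loss"))
  expect_error(intersect_cnvrs(mixed), "one kind")
})

test_that("random region sets match the per-base intersection oracle", {
  for (seed in 1:10) {
    regions <- withr::with_seed(seed, {
      n_samp <- sample(2:4, 1)
      bind_rows(lapply(seq_len(n_samp), function(s) {
        n_reg <- sample(1:6, 1)
        starts <- sort(sample.int(90000L, n_reg))
        tibble(sample_id = paste0("S", s), chrom = "chr1",
               start = starts,
               end = pmin(starts + sample(500:8000, n_reg, replace = TRUE), 100000L),
               kind = "gain")
      }))
    })
    # merge per-sample overlaps implicitly through the oracle's boolean cover
    res <- intersect_cnvrs(regions)
    shared <- res[res$status == "shared", c("start", "end")]
    oracle <- oracle_shared(regions, 100000L)
    expect_equal(as.integer(shared$start), oracle$start)
    expect_equal(as.integer(shared$end), oracle$end)
  }
})

test_that("regions are annotated with every overlapping gene", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gene1",
    "chr1\tsrc\tgene\t2501\t3500\t.\t-\t.\tID=gene2",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=rna1;Parent=gene1",
    "chr2\tsrc\tgene\t100\t200\t.\t+\t.\tID=gene3"
  ), gff)
  regions <- tibble(chrom = "chr1", start = c(500L, 9000L), end = c(3000L, 9500L))
  ann <- annotate_regions(regions, gff)
  expect_equal(sort(ann$genes[[1]]), c("gene1", "gene2"))
  expect_equal(ann$n_genes, c(2L, 0L))
  expect_equal(gene_fraction(ann), 0.5)

  # 7 of 10 regions with genes -> fraction 0.7
  regions10 <- tibble(chrom = "chr1",
                      start = c(rep(1500L, 7), rep(8000L, 3)),
                      end = c(rep(1600L, 7), rep(8100L, 3)))
  expect_equal(gene_fraction(annotate_regions(regions10, gff)), 0.7)

  bad <- tempfile(fileext = ".gff3")
  writeLines(c("chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\tx"), bad)
  expect_error(annotate_regions(regions, bad), "line 2")
})
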