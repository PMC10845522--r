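test_that("read standardization trims, filters, truncates and subsamples", {
  reads <- tibble(
    id = c("a", "b", "c"),
    sequence = c(strrep("ACGT", 38)[1], strrep("AC", 40), strrep("ACGTT", 30)),
    quality = c(strrep("I", 152), strrep("I", 80), paste0(strrep("I", 120), strrep("+", 30)))
  )
  reads$sequence[1] <- substr(strrep("ACGT", 40), 1, 152)
  out <- prepare_reads(reads, n_sample = 10, final_n = 10)
  # 152-nt Q30 read kept and cut to 100; 80-nt read dropped;
  # 150-nt read with Q10 tail trimmed to 120 then cut to 100
  expect_equal(out$id, c("a", "c"))
  expect_true(all(nchar(out$sequence) == 100))
  expect_true(all(nchar(out$quality) == 100))

  short <- tibble(id = "x", sequence = strrep("A", 80), quality = strrep("I", 80))
  expect_error(prepare_reads(short), "no reads survive")
})

test_that("read standardization is reproducible under its seed", {
  sim <- sim_reference(c(chr1 = 100000), seed = 50)
  raw <- sim_reads(sim, n_reads = 5000, read_length = 110,
                   low_q_tail_frac = 0.2, max_tail = 15, seed = 51)
  a <- prepare_reads(raw, n_sample = 4000, final_n = 2000, seed = 100)
  b <- prepare_reads(raw, n_sample = 4000, final_n = 2000, seed = 100)
  expect_identical(a$id, b$id)
  expect_equal(nrow(a), 2000L)
  c <- prepare_reads(raw, n_sample = 4000, final_n = 2000, seed = 101)
  expect_false(identical(a$id, c$id))
})

test_that("reads from one repeat form a dominant cluster of the right size", {
  fix <- make_array(5000, 1, divergence = 0, seed = 60)
  withr::with_seed(61, {
    rep_reads <- vapply(seq_len(1000), function(i) {
      s <- sample.int(4901, 1)
      substr(fix$array, s, s + 99)
    }, character(1))
    unique_reads <- vapply(seq_len(9000), function(i)
      vitiscan:::random_dna(100, gc = 0.5), character(1))
  })
  cl <- cluster_reads(c(rep_reads, unique_reads))
  expect_gte(nrow(cl), 1L)
  expect_lt(abs(cl$size[1] - 1000) / 1000, 0.05)
  # proportion conservation
  expect_equal(sum(cl$proportion) + attr(cl, "singleton_proportion"), 1)
})

test_that("k-mer clustering is strand-agnostic and needs shared k-mers", {
  fix <- make_array(300, 1, divergence = 0, seed = 62)
  fwd <- substr(fix$array, 1, 100)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  cl <- cluster_reads(c(fwd, rc), min_cluster_proportion = 0)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size[1], 2L)

  # k-mer-disjoint homopolymer reads never cluster
  cl2 <- cluster_reads(c(strrep("A", 100), strrep("C", 100), strrep("G", 100)),
                       min_cluster_proportion = 0)
  expect_equal(nrow(cl2), 0L)

  expect_error(cluster_reads(c("ACGT", "ACGT"), k = 17), "read length")
  expect_error(cluster_reads(tibble(id = c("a", "b"),
                                    sequence = c(strrep("A", 100), strrep("A", 90)))),
               "same length")
})

test_that("clusters inherit the majority family label with a strict tie rule", {
  famA <- make_array(2000, 1, divergence = 0, seed = 63)$array
  famB <- make_array(2000, 1, divergence = 0, seed = 64)$array
  reference <- tibble(family = c("Gypsy/Athila", "Copia/Ale"),
                      sequence = c(famA, famB))
  withr::with_seed(65, {
    reads <- tibble(
      id = paste0("r", 1:60),
      sequence = c(
        vapply(1:40, function(i) { s <- sample.int(1901, 1); substr(famA, s, s + 99) },
               character(1)),
        vapply(1:20, function(i) vitiscan:::random_dna(100), character(1))
      )
    )
  })
  cl <- cluster_reads(reads, min_cluster_proportion = 0)
  lab <- classify_clusters(cl, reads, reference)
  expect_equal(lab$label[1], "Gypsy/Athila")
  expect_gte(lab$label_support[1], 0.5)

  # a cluster of random sequence stays unclassified
  rnd <- withr::with_seed(66, tibble(
    id = c("x1", "x2"),
    sequence = rep(vitiscan:::random_dna(100), 2)
  ))
  cl_rnd <- cluster_reads(rnd, min_cluster_proportion = 0)
  lab_rnd <- classify_clusters(cl_rnd, rnd, reference)
  expect_equal(lab_rnd$label, "unclassified")

  # 50/50 conflicting membership -> unclassified
  half <- tibble(id = c("h1", "h2"),
                 sequence = c(substr(famA, 1, 100), substr(famB, 1, 100)))
  cl_half <- tibble(cluster_id = "CL1", size = 2L, proportion = 1,
                    read_ids = list(c("h1", "h2")))
  lab_half <- classify_clusters(cl_half, half, reference)
  expect_equal(lab_half$label, "unclassified")
})

test_that("abundance cells are percentages of sampled reads", {
  labeled <- tibble(sample_id = c("S1", "S1", "S2"),
                    label = c("Athila", "Ale", "Athila"),
                    size = c(2500L, 1000L, 5000L))
  totals <- tibble(sample_id = c("S1", "S2", "S3"),
                   total_reads = c(250000L, 250000L, 250000L))
  ab <- abundance_table(labeled, totals)
  expect_equal(ab$Athila[ab$sample_id == "S1"], 1.0)
  expect_equal(ab$Ale[ab$sample_id == "S2"], 0)
  # a sample with no clusters gets an all-zero row
  expect_equal(unlist(ab[ab$sample_id == "S3", c("Athila", "Ale")], use.names = FALSE),
               c(0, 0))
  expect_true(all(rowSums(ab[, -1]) <= 100))
})

test_that("landscape comparison separates constructed groups and flags the
           differing family", {
  withr::with_seed(70, {
    base <- matrix(rnorm(16 * 4, 5, 0.3), nrow = 16)
    colnames(base) <- paste0("fam", 1:4)
    ab <- as_tibble(base)
    ab$fam1[1:8] <- rnorm(8, 10, 0.3)   # block 1 at 10%, block 2 at 1%
    ab$fam1[9:16] <- rnorm(8, 1, 0.3)
    ab$fam2[1:8] <- rnorm(8, 8, 0.3)    # a second differing family
    ab$fam2[9:16] <- rnorm(8, 2, 0.3)
    ab <- bind_cols(tibble(sample_id = paste0("S", 1:16)), ab)
  })
  cmp <- compare_landscapes(ab, seed = 7)
  grp <- cmp$scores$group
  expect_equal(length(unique(grp[1:8])), 1L)
  expect_equal(length(unique(grp[9:16])), 1L)
  expect_false(grp[1] == grp[9])
  expect_true(cmp$tests$significant[cmp$tests$family == "fam1"])
  expect_true(cmp$tests$significant[cmp$tests$family == "fam2"])

  # permuting samples gives the same partition up to label swap
  perm <- withr::with_seed(71, sample(16))
  cmp2 <- compare_landscapes(ab[perm, ], seed = 7)
  g1 <- cmp$scores$group[match(cmp2$scores$sample_id, cmp$scores$sample_id)]
  g2 <- cmp2$scores$group
  agreement <- mean(g1 == g2)
  expect_true(agreement %in% c(0, 1))  # identical or fully label-swapped

  # identical rows have no variance to analyze
  flat <- ab; flat[, -1] <- 1
  expect_error(compare_landscapes(flat), "zero variance")

  expect_error(compare_landscapes(ab[1, ]), "fewer samples than groups")
})

test_that("tidy, glance and autoplot work on a landscape comparison", {
  withr::with_seed(72, {
    ab <- bind_cols(
      tibble(sample_id = paste0("S", 1:8)),
      as_tibble(matrix(rnorm(8 * 4, 5), nrow = 8,
                       dimnames = list(NULL, paste0("f", 1:4))))
    )
  })
  cmp <- compare_landscapes(ab, seed = 1)
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(nrow(glance(cmp)), 1L)
  expect_s3_class(autoplot(cmp), "ggplot")
})
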