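#' Subsample, quality-trim and standardize reads for repeatome profiling
#'
#' Mirrors the standard read preparation for graph-based repeat clustering:
#' draw a random subset of reads, trim low-quality 3' tails, drop reads that
#' become shorter than the target length, cut survivors to exactly that
#' length, and finally subsample to the working read count. All randomness is
#' governed by `seed`, so the surviving read-id list is reproducible.
#'
#' @param reads tibble with `id`, `sequence`, `quality` (Phred+33), e.g. from
#'   [read_fastq()] or [sim_reads()].
#' @param n_sample initial random sample size (all reads if fewer); default
#'   one million.
#' @param seed integer seed (default 100).
#' @param min_quality 3' bases with quality below this are trimmed.
#' @param target_length reads shorter than this after trimming are dropped;
#'   survivors are truncated to exactly this length (nt).
#' @param final_n size of the final uniform subsample.
#' @return tibble of standardized reads (`id`, `sequence`, `quality`).
#' @export
prepare_reads <- function(reads, n_sample = 1e6, seed = 100, min_quality = 20,
                          target_length = 100, final_n = 250000) {
  check_reads(reads)
  if (!nrow(reads)) abort("`reads` is empty")
  withr::local_seed(seed)
  if (nrow(reads) > n_sample)
    reads <- reads[sort(sample.int(nrow(reads), n_sample)), ]
  # strip the maximal 3' suffix whose qualities are all below min_quality
  low <- sprintf("[\\x21-\\x%x]+$", 32 + min_quality)  # Phred+33: Q < min_quality
  trimmed_q <- sub(low, "", reads$quality, perl = TRUE)
  new_len <- nchar(trimmed_q)
  keep <- new_len >= target_length
  if (!any(keep)) abort("no reads survive trimming and the length filter")
  out <- tibble(
    id = reads$id[keep],
    sequence = substr(reads$sequence[keep], 1L, target_length),
    quality = substr(trimmed_q[keep], 1L, target_length)
  )
  if (nrow(out) > final_n) out <- out[sort(sample.int(nrow(out), final_n)), ]
  out
}

#' Cluster reads by shared canonical k-mers
#'
#' Builds a graph with reads as nodes and an edge whenever two reads share at
#' least `min_shared_kmers` canonical k-mers (strand-agnostic), then takes
#' connected components as repeat clusters. Components smaller than
#' `min_cluster_proportion` of the input are dissolved to singletons, the
#' reporting floor of read-clustering repeat profilers. The component search
#' generates candidate read pairs from k-mer occurrence buckets and verifies
#' each candidate's exact shared-k-mer count, which keeps the search
#' near-linear in the number of reads.
#'
#' @param reads tibble with `id` and `sequence` (all sequences the same
#'   length) or a character vector of sequences.
#' @param k k-mer length (must not exceed the read length).
#' @param min_shared_kmers minimal shared canonical k-mers for an edge.
#' @param min_cluster_proportion minimal cluster size as a fraction of reads.
#' @return a `repeat_clusters` tibble: `cluster_id`, `size`, `proportion`
#'   (of input reads), `read_ids` (list-column), sorted by size; attributes
#'   `n_reads` and `singleton_proportion`.
#' @examples
#' \donttest{
#' sim <- sim_reference(c(chr1 = 20000),
#'   events = tibble::tibble(kind = "satellite_array", chrom = "chr1",
#'     start = 1000L, monomer_length = 107L, n_copies = 20L, family_id = "sat1"),
#'   seed = 1)
#' reads <- sim_reads(sim, n_reads = 2000, seed = 1)
#' cluster_reads(reads)
#' }
#' @export
cluster_reads <- function(reads, k = 17, min_shared_kmers = 10,
                          min_cluster_proportion = 1e-4) {
  if (is.character(reads)) reads <- tibble(id = paste0("read", seq_along(reads)),
                                           sequence = reads)
  lens <- nchar(reads$sequence)
  if (length(unique(lens)) > 1) abort("all reads must have the same length")
  if (k > lens[1]) abort("`k` exceeds the read length")
  comp <- .kmer_components(reads$sequence, as.integer(k), as.integer(min_shared_kmers))
  n <- nrow(reads)
  sizes <- table(comp)
  min_size <- max(2L, ceiling(min_cluster_proportion * n))
  keep_comp <- as.integer(names(sizes)[sizes >= min_size])
  clusters <- tibble(comp = comp, id = reads$id) |>
    filter(.data$comp %in% keep_comp) |>
    group_by(.data$comp) |>
    summarise(size = dplyr::n(), read_ids = list(.data$id), .groups = "drop") |>
    arrange(dplyr::desc(.data$size)) |>
    mutate(cluster_id = paste0("CL", dplyr::row_number()),
           proportion = .data$size / n) |>
    select("cluster_id", "size", "proportion", "read_ids")
  attr(clusters, "n_reads") <- n
  attr(clusters, "singleton_proportion") <- 1 - sum(clusters$proportion)
  class(clusters) <- c("repeat_clusters", class(clusters))
  clusters
}

#' Classify read clusters against a labeled repeat reference
#'
#' Each member read is matched to reference sequences through shared
#' canonical k-mers; its sequence identity to a family is estimated from
#' k-mer containment (`identity = containment^(1/k)`, the standard sketching
#' estimator), and the read is assigned to the best family reaching
#' `min_identity`. A cluster is labeled with the majority family when at
#' least half of its matched members agree (a 50/50 tie or no matches leaves
#' it `unclassified`).
#'
#' @param clusters a `repeat_clusters` tibble from [cluster_reads()].
#' @param reads the read tibble the clusters were built from.
#' @param reference tibble with columns `family`, `sequence`, or a path to a
#'   FASTA whose headers carry the family label (text after the last `#`, as
#'   in REXdb-style headers, or the full header).
#' @param k k-mer length for matching.
#' @param min_identity minimal estimated identity for a read-family match.
#' @param max_members per-cluster cap on members used for classification
#'   (larger clusters are subsampled deterministically).
#' @return `clusters` with added columns `label` and `label_support` (fraction
#'   of matched members agreeing).
#' @export
classify_clusters <- function(clusters, reads, reference, k = 17,
                              min_identity = 0.8, max_members = 200) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference))
    reference <- read_repeat_reference(reference)
  stopifnot(all(c("family", "sequence") %in% names(reference)))
  if (!nrow(reference)) abort("`reference` is empty")
  fam <- as.character(reference$family)
  seq_of <- stats::setNames(reads$sequence, reads$id)
  labels <- character(nrow(clusters))
  support <- numeric(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    ids <- clusters$read_ids[[i]]
    if (length(ids) > max_members) ids <- ids[seq(1, length(ids), length.out = max_members)]
    mem <- unname(seq_of[ids])
    res <- .kmer_ref_counts(mem, reference$sequence, as.integer(k))
    containment <- res$counts / pmax(res$n_kmers, 1L)
    ident <- containment^(1 / k)
    ident[containment == 0] <- 0
    best <- max.col(ident, ties.method = "first")
    matched <- ident[cbind(seq_along(best), best)] >= min_identity
    if (!any(matched)) { labels[i] <- "unclassified"; next }
    votes <- table(fam[best[matched]])
    top <- votes[votes == max(votes)]
    frac <- max(votes) / sum(votes)
    if (length(top) == 1 && frac >= 0.5) {
      labels[i] <- names(top)
      support[i] <- frac
    } else {
      labels[i] <- "unclassified"
    }
  }
  clusters$label <- labels
  clusters$label_support <- support
  clusters
}

#' Read a labeled repeat reference FASTA
#'
#' The family label is taken from the header text after the last `#`
#' (REXdb-style `name#Class/Lineage` headers) or, failing that, the whole
#' header.
#'
#' @param path FASTA file path.
#' @return tibble with `family`, `sequence`.
#' @export
read_repeat_reference <- function(path) {
  x <- read_fasta(path)
  nm <- names(x)
  fam <- ifelse(grepl("#", nm), sub(".*#", "", nm), nm)
  tibble(family = fam, sequence = unname(x))
}

#' Genome-proportion abundance matrix across samples
#'
#' The cell for (sample, family) is the percentage of that sample's sampled
#' reads falling in clusters labeled with the family; families absent from a
#' sample are 0.
#'
#' @param labeled tibble with columns `sample_id`, `label`, `size` — one row
#'   per (sample, cluster), e.g. labeled clusters bound across samples with
#'   their sample id attached.
#' @param totals tibble with `sample_id`, `total_reads` (reads sampled per
#'   sample).
#' @return wide tibble: one row per sample, one column per family, values in
#'   percent of sampled reads.
#' @export
abundance_table <- function(labeled, totals) {
  stopifnot(all(c("sample_id", "label", "size") %in% names(labeled)),
            all(c("sample_id", "total_reads") %in% names(totals)))
  long <- labeled |>
    group_by(.data$sample_id, .data$label) |>
    summarise(reads = sum(.data$size), .groups = "drop") |>
    left_join(totals, by = "sample_id") |>
    mutate(percent = 100 * .data$reads / .data$total_reads)
  wide <- tidyr::pivot_wider(
    long |> select("sample_id", "label", "percent"),
    names_from = "label", values_from = "percent", values_fill = 0
  )
  # samples with no clusters still get an all-zero row
  missing <- setdiff(totals$sample_id, wide$sample_id)
  if (length(missing)) {
    zero <- wide[rep(NA_integer_, length(missing)), ]
    zero$sample_id <- missing
    zero[setdiff(names(zero), "sample_id")] <- 0
    wide <- bind_rows(wide, zero)
  }
  arrange(wide, .data$sample_id)
}

#' Compare repeat landscapes across samples
#'
#' Centers and scales the abundance matrix, summarizes it by PCA, partitions
#' the samples by K-means on the principal-component scores, and tests each
#' repeat family for abundance differences between the two groups with a
#' two-sided Wilcoxon rank-sum test (exact p where the implementation allows).
#' No multiple-testing correction is applied by default; set `correct = TRUE`
#' for Benjamini-Hochberg q values used in the significance flags.
#'
#' @param abundance wide tibble from [abundance_table()] (`sample_id` +
#'   one numeric column per family).
#' @param n_groups number of K-means groups.
#' @param alpha per-family significance threshold.
#' @param groups optional factor/vector of known group labels (overrides
#'   K-means for the tests).
#' @param correct apply Benjamini-Hochberg before flagging.
#' @param seed seed for K-means initialization.
#' @return object of class `landscape_comparison` with elements `pca`
#'   ([stats::prcomp]), `scores` (tibble of sample coordinates and group),
#'   `tests` (per-family tibble `family`, `p`, `q`, `significant`), `alpha`.
#'   [tidy()] returns `tests`, [glance()] a one-row summary; [autoplot()]
#'   draws the PCA.
#' @export
compare_landscapes <- function(abundance, n_groups = 2, alpha = 0.05,
                               groups = NULL, correct = FALSE, seed = 1) {
  stopifnot("sample_id" %in% names(abundance))
  m <- as.matrix(abundance[, setdiff(names(abundance), "sample_id"), drop = FALSE])
  rownames(m) <- abundance$sample_id
  if (nrow(m) < n_groups) abort("fewer samples than groups")
  keep <- apply(m, 2, function(x) stats::var(x) > 0)
  if (!any(keep))
    abort("all families have zero variance across samples; PCA is undefined")
  if (any(!keep))
    warn(paste0("dropping ", sum(!keep), " zero-variance families before PCA"))
  pca <- prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  scores <- pca$x
  withr::local_seed(seed)
  km <- kmeans(scores, centers = n_groups, nstart = 25)
  grp <- if (is.null(groups)) factor(km$cluster) else factor(groups)
  if (length(unique(grp)) < 2) abort("need at least two groups to test")
  tests <- purrr::map_dfr(colnames(m), function(f) {
    p <- tryCatch(
      suppressWarnings(wilcox.test(m[, f] ~ grp)$p.value),
      error = function(e) NA_real_
    )
    tibble(family = f, p = p)
  })
  tests$q <- p.adjust(tests$p, method = "BH")
  crit <- if (correct) tests$q else tests$p
  tests$significant <- !is.na(crit) & crit <= alpha
  structure(
    list(
      pca = pca,
      scores = tibble(sample_id = rownames(scores),
                      as_tibble(scores[, seq_len(min(3, ncol(scores))), drop = FALSE]),
                      group = grp),
      tests = arrange(tests, .data$p),
      alpha = alpha
    ),
    class = "landscape_comparison"
  )
}

#' @export
print.landscape_comparison <- function(x, ...) {
  ve <- summary(x$pca)$importance[2, seq_len(min(2, ncol(x$pca$x)))]
  cat("<landscape_comparison> ", nrow(x$scores), " samples, ",
      nrow(x$tests), " families; PC1/PC2 variance ",
      paste(signif(100 * ve, 3), collapse = "/"), "%; ",
      sum(x$tests$significant), " families at p <= ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' @rdname compare_landscapes
#' @param x a `landscape_comparison` object.
#' @param ... unused.
#' @export
tidy.landscape_comparison <- function(x, ...) x$tests

#' @rdname compare_landscapes
#' @export
glance.landscape_comparison <- function(x, ...) {
  ve <- summary(x$pca)$importance[2, ]
  tibble(
    n_samples = nrow(x$scores),
    n_families = nrow(x$tests),
    n_significant = sum(x$tests$significant),
    pc1_var = unname(ve[1]),
    pc2_var = if (length(ve) > 1) unname(ve[2]) else NA_real_
  )
}
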