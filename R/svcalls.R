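#' Call duplications and deletions from absolute copy number (WSSD rule)
#'
#' A window is in the duplicated state when its CN exceeds `dup_thr` and in
#' the deleted state when its CN is below `del_thr`. Maximal runs of at least
#' `min_windows` consecutive same-state windows on one chromosome become
#' regions; one sub-threshold window splits a run (no gap tolerance). Region
#' bounds are the genomic bounds of the first and last member window and
#' `mean_cn` is the mean over member windows.
#'
#' @param profile a `cn_profile` from [calibrate_cn()] (windows sorted per
#'   chromosome).
#' @param min_windows minimal run length (windows).
#' @param dup_thr duplication CN threshold (exclusive).
#' @param del_thr deletion CN threshold (exclusive).
#' @return tibble `chrom`, `start`, `end`, `kind` (`duplication`/`deletion`),
#'   `n_windows`, `mean_cn`.
#' @examples
#' # windows at CN 3 for >= 5 consecutive windows are called duplicated
#' @export
call_wssd <- function(profile, min_windows = 5, dup_thr = 2.5, del_thr = 1.5) {
  stopifnot(all(c("chrom", "start", "end", "cn") %in% names(profile)))
  out <- list()
  for (chrom in unique(profile$chrom)) {
    p <- profile[profile$chrom == chrom, ]
    p <- p[order(p$start), ]
    state <- ifelse(p$cn > dup_thr, "duplication",
                    ifelse(p$cn < del_thr, "deletion", "neutral"))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values != "neutral" & r$lengths >= min_windows)) {
      i1 <- starts[j]; i2 <- ends[j]
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom,
        start = p$start[i1],
        end = p$end[i2],
        kind = r$values[j],
        n_windows = i2 - i1 + 1L,
        mean_cn = mean(p$cn[i1:i2])
      )
    }
  }
  res <- bind_rows(out)
  if (!nrow(res))
    res <- tibble(chrom = character(), start = integer(), end = integer(),
                  kind = character(), n_windows = integer(), mean_cn = double())
  arrange(res, .data$chrom, .data$start)
}

#' Per-window log2 ratio between two copy-number profiles (digital CGH)
#'
#' `L2R_i = log2(CN_sample,i / CN_reference,i)` over the identical window set.
#' Windows where either CN falls below `min_cn` are flagged undefined (`NA`)
#' and excluded from segmentation.
#'
#' @param sample,reference `cn_profile` objects built on the same windows.
#' @param min_cn CN floor below which the ratio is undefined.
#' @return the window tibble with columns `cn_sample`, `cn_reference`, `l2r`.
#' @export
compute_l2r <- function(sample, reference, min_cn = 0.1) {
  same <- nrow(sample) == nrow(reference) &&
    all(sample$chrom == reference$chrom) &&
    all(sample$start == reference$start) &&
    all(sample$end == reference$end)
  if (!same) abort("`sample` and `reference` must be built on identical windows")
  out <- tibble(
    chrom = sample$chrom, start = sample$start, end = sample$end,
    cn_sample = sample$cn, cn_reference = reference$cn,
    l2r = ifelse(sample$cn < min_cn | reference$cn < min_cn, NA_real_,
                 log2(sample$cn / reference$cn))
  )
  out
}

#' Call gained and lost regions from a log2-ratio track
#'
#' Maximal runs of consecutive windows with `l2r > thr` (gain) or
#' `l2r < -thr` (loss); undefined windows break runs. Runs whose genomic
#' length exceeds `min_length` are emitted with their mean L2R.
#'
#' @param l2r window tibble from [compute_l2r()].
#' @param thr symmetric L2R threshold.
#' @param min_length minimal genomic length (bases, exclusive).
#' @return tibble `chrom`, `start`, `end`, `kind` (`gain`/`loss`), `n_windows`,
#'   `mean_l2r`, `length`.
#' @export
call_cgh <- function(l2r, thr = 0.25, min_length = 10000) {
  out <- list()
  for (chrom in unique(l2r$chrom)) {
    p <- l2r[l2r$chrom == chrom, ]
    p <- p[order(p$start), ]
    state <- ifelse(is.na(p$l2r), "undefined",
                    ifelse(p$l2r > thr, "gain",
                           ifelse(p$l2r < -thr, "loss", "neutral")))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values %in% c("gain", "loss"))) {
      i1 <- starts[j]; i2 <- ends[j]
      len <- p$end[i2] - p$start[i1]
      if (len <= min_length) next
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom, start = p$start[i1], end = p$end[i2],
        kind = r$values[j], n_windows = i2 - i1 + 1L,
        mean_l2r = mean(p$l2r[i1:i2]), length = len
      )
    }
  }
  res <- bind_rows(out)
  if (!nrow(res))
    res <- tibble(chrom = character(), start = integer(), end = integer(),
                  kind = character(), n_windows = integer(), mean_l2r = double(),
                  length = integer())
  arrange(res, .data$chrom, .data$start)
}

#' Intersect CNV regions across samples into shared CNVRs
#'
#' A shared CNVR is a maximal interval covered by a same-kind region in every
#' sample (base-wise intersection of the per-sample region sets, merged).
#' Input regions overlapping no same-kind region of any other sample are
#' flagged sample-specific.
#'
#' @param regions tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `kind`; all rows must share one kind.
#' @param profiles optional named list of `cn_profile` objects (names =
#'   sample ids); if given, each shared CNVR gains a mean-CN column per sample.
#' @return tibble of shared CNVRs (`status = "shared"`, `sample_id = NA`)
#'   followed by sample-specific input regions (`status = "sample-specific"`).
#' @examples
#' r <- tibble::tibble(sample_id = c("A", "B"), chrom = "chr1",
#'                     start = c(100L, 150L), end = c(200L, 300L), kind = "gain")
#' intersect_cnvrs(r)
#' @export
intersect_cnvrs <- function(regions, profiles = NULL) {
  stopifnot(all(c("sample_id", "chrom", "start", "end", "kind") %in% names(regions)))
  if (length(unique(regions$kind)) > 1)
    abort("all regions must share one kind; intersect kinds separately")
  samples <- unique(regions$sample_id)
  lvls <- unique(regions$chrom)
  per_sample <- lapply(samples, function(s)
    GenomicRanges::reduce(to_granges(regions[regions$sample_id == s, ], lvls)))
  names(per_sample) <- samples

  shared <- tibble(chrom = character(), start = integer(), end = integer())
  if (length(samples) >= 2) {
    acc <- per_sample[[1]]
    for (s in samples[-1]) {
      acc <- GenomicRanges::intersect(acc, per_sample[[s]])
    }
    acc <- GenomicRanges::reduce(acc)
    if (length(acc)) {
      shared <- tibble(
        chrom = as.character(GenomicRanges::seqnames(acc)),
        start = GenomicRanges::start(acc) - 1L,
        end = GenomicRanges::end(acc)
      )
    }
  }

  status <- vapply(seq_len(nrow(regions)), function(i) {
    others <- setdiff(samples, regions$sample_id[i])
    if (!length(others)) return("sample-specific")
    gr <- to_granges(regions[i, ], lvls)
    hit <- any(vapply(others, function(s)
      length(GenomicRanges::findOverlaps(gr, per_sample[[s]])) > 0, logical(1)))
    if (hit) "shared-overlap" else "sample-specific"
  }, character(1))

  shared_tbl <- if (nrow(shared)) {
    dplyr::mutate(shared, kind = regions$kind[1], status = "shared",
                  sample_id = NA_character_)
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           kind = character(), status = character(), sample_id = character())
  }
  if (!is.null(profiles) && nrow(shared_tbl)) {
    for (s in names(profiles)) {
      p <- profiles[[s]]
      shared_tbl[[paste0("cn_", s)]] <- vapply(seq_len(nrow(shared_tbl)), function(i) {
        sel <- p$chrom == shared_tbl$chrom[i] & p$start < shared_tbl$end[i] &
          shared_tbl$start[i] < p$end
        if (any(sel)) mean(p$cn[sel]) else NA_real_
      }, double(1))
    }
  }
  specific <- regions[status == "sample-specific",
                      c("chrom", "start", "end", "kind", "sample_id")]
  specific$status <- if (nrow(specific)) "sample-specific" else character(0)
  bind_rows(shared_tbl, specific) |>
    arrange(.data$status, .data$chrom, .data$start)
}

#' Annotate regions with overlapping genes
#'
#' A gene is assigned to a region when any part of it overlaps the region.
#'
#' @param regions tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genes tibble from [read_gff_genes()] (or any tibble with `chrom`,
#'   `start`, `end`, `gene_id`), or a path to a GFF3 file.
#' @return `regions` with list-column `genes` and count `n_genes`; the
#'   fraction of regions containing at least one gene is available via
#'   [gene_fraction()].
#' @export
annotate_regions <- function(regions, genes) {
  if (is.character(genes)) genes <- read_gff_genes(genes)
  hits <- GenomicRanges::findOverlaps(to_granges(regions), to_granges(genes))
  gl <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
              factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(regions))))
  regions$genes <- unname(lapply(gl, as.character))
  regions$n_genes <- lengths(regions$genes)
  regions
}

#' Fraction of annotated regions containing at least one gene
#'
#' @param annotated output of [annotate_regions()].
#' @return a single number in `[0, 1]`.
#' @export
gene_fraction <- function(annotated) {
  if (!nrow(annotated)) return(NA_real_)
  mean(annotated$n_genes > 0)
}
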