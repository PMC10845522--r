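#' Build a validated pipeline configuration
#'
#' Collects every stage parameter with defaults matching the analysis the
#' package implements (1-kb unmasked windows; duplications CN > 2.5 and
#' deletions CN < 1.5 over at least 5 consecutive windows; digital-CGH
#' regions > 10 kb at |L2R| > 0.25; read standardization sampling 1 M reads
#' at seed 100, Q20 trimming, 100-nt reads, 250,000 final reads; Wilcoxon
#' alpha 0.05; K-means k = 2). Unknown keys are rejected.
#'
#' @param ... overrides for any of the defaults (see `pipeline_defaults()`).
#' @return named list of class `run_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  if (cfg$window < 100) abort("`window` must be >= 100")
  if (cfg$min_windows < 1) abort("`min_windows` must be >= 1")
  if (cfg$coverage <= 0) abort("`coverage` must be > 0")
  structure(cfg, class = "run_config")
}

#' Default pipeline parameters
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1,
    # simulation
    chrom_lengths = c(chr1 = 6e5, chr2 = 4e5),
    masked_fraction = 0.05,
    coverage = 30,
    read_length = 100,
    samples = c("AGL", "FAL"),
    events = NULL,
    # windows / CN
    window = 1000,
    gc_correction = FALSE,
    # WSSD / digital CGH
    min_windows = 5,
    dup_threshold = 2.5,
    del_threshold = 1.5,
    l2r_threshold = 0.25,
    min_cgh_length = 10000,
    # repeatome
    n_sample_reads = 1e6,
    read_seed = 100,
    min_quality = 20,
    target_length = 100,
    final_reads = 250000,
    kmer = 17,
    min_shared_kmers = 10,
    wilcoxon_alpha = 0.05,
    kmeans_k = 2,
    # satellites
    sat_min_identity = 0.8,
    sat_min_hits = 5
  )
}

#' Run the full analysis pipeline on a simulated study
#'
#' Executes the stages in dependency order — simulate, window/profile CN,
#' WSSD and digital-CGH calling, shared-CNVR intersection, chi-square of the
#' per-chromosome call distribution, repeat clustering, and satellite
#' characterization — writing each stage's outputs under `outdir` and
#' returning an append-only manifest of the produced files with their md5
#' checksums and the effective parameter set. Rerunning with an identical
#' configuration reproduces identical checksums.
#'
#' @param config a [pipeline_config()] object.
#' @param outdir output directory (created if missing).
#' @return tibble manifest (`stage`, `file`, `md5`, `bytes`), invisibly also
#'   written to `manifest.tsv`; the effective config is echoed to
#'   `config.yaml`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("vitiscan_run_")) {
  if (!inherits(config, "run_config")) abort("`config` must come from pipeline_config()")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, file) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)), bytes = file.size(file)
    )
  }

  # default event set: one duplication + one deletion per sample (partly
  # shared), one satellite array and one dispersed family
  events <- config$events
  if (is.null(events)) {
    events <- bind_rows(
      tibble(sample_id = config$samples[1], chrom = "chr1", start = 100000L,
             end = 120000L, kind = "duplication", cn = 4),
      tibble(sample_id = config$samples[2], chrom = "chr1", start = 105000L,
             end = 125000L, kind = "duplication", cn = 4),
      tibble(sample_id = config$samples[1], chrom = "chr2", start = 200000L,
             end = 215000L, kind = "deletion", cn = 1),
      tibble(kind = "satellite_array", chrom = "chr1", start = 400000L,
             monomer_length = 107L, n_copies = 80L, divergence = 0.02,
             family_id = "VvSat1-like"),
      tibble(kind = "dispersed_family", family_id = "gypsy-like",
             element_length = 5000L, n_copies = 10L, divergence = 0.05)
    )
  }

  ## stage: simulate
  sim <- sim_reference(config$chrom_lengths, events = events,
                       samples = config$samples,
                       masked_fraction = config$masked_fraction,
                       seed = config$seed)
  f <- file.path(outdir, "reference.fasta"); write_fasta(sim$genome, f); note("simulate", f)
  f <- file.path(outdir, "mask.bed"); write_bed(sim$mask, f); note("simulate", f)
  f <- file.path(outdir, "truth.tsv"); readr::write_tsv(sim$truth, f); note("simulate", f)

  ## stage: profile-cn
  windows <- define_windows(sim, w = config$window)
  profiles <- list()
  for (s in c("reference", config$samples)) {
    track <- if (s == "reference") {
      dplyr::mutate(sim$chrom_lengths, start = 0L, end = .data$length, cn = 2)[,
        c("chrom", "start", "end", "cn")]
    } else {
      derive_sample(sim, s)
    }
    rs <- sim_read_starts(track, coverage = config$coverage,
                          read_length = config$read_length,
                          seed = config$seed + match(s, c("reference", config$samples)))
    prof <- window_depth(windows, rs, read_length = config$read_length)
    if (config$gc_correction) {
      prof <- gc_correct(prof)
    } else {
      prof <- gc_correct(prof, enabled = FALSE)
    }
    profiles[[s]] <- calibrate_cn(prof, sample_id = s)
    f <- file.path(outdir, paste0("cn_", s, ".tsv"))
    readr::write_tsv(as_tibble(profiles[[s]]), f); note("profile-cn", f)
  }

  ## stage: call-sv / dcgh / shared-cnvr
  all_wssd <- list(); all_gain <- list(); all_loss <- list()
  for (s in config$samples) {
    wssd <- call_wssd(profiles[[s]], min_windows = config$min_windows,
                      dup_thr = config$dup_threshold, del_thr = config$del_threshold)
    f <- file.path(outdir, paste0("wssd_", s, ".bed")); write_bed(wssd, f); note("call-sv", f)
    all_wssd[[s]] <- dplyr::mutate(wssd, sample_id = s)
    l2r <- compute_l2r(profiles[[s]], profiles[["reference"]])
    cgh <- call_cgh(l2r, thr = config$l2r_threshold, min_length = config$min_cgh_length)
    f <- file.path(outdir, paste0("cgh_", s, ".bed")); write_bed(cgh, f); note("dcgh", f)
    all_gain[[s]] <- dplyr::mutate(cgh[cgh$kind == "gain", ], sample_id = s)
    all_loss[[s]] <- dplyr::mutate(cgh[cgh$kind == "loss", ], sample_id = s)
  }
  for (kind in c("gain", "loss")) {
    rg <- bind_rows(if (kind == "gain") all_gain else all_loss)
    if (nrow(rg)) {
      shared <- intersect_cnvrs(rg)
      f <- file.path(outdir, paste0("cnvr_", kind, ".tsv"))
      readr::write_tsv(shared, f); note("shared-cnvr", f)
    }
  }

  ## stage: variant-chisq on per-chromosome WSSD call counts
  calls <- bind_rows(all_wssd)
  counts <- sim$chrom_lengths |>
    left_join(count(calls, .data$chrom, name = "observed"), by = "chrom") |>
    mutate(observed = tidyr::replace_na(.data$observed, 0L))
  if (sum(counts$observed) > 0) {
    chsq <- chisq_randomness(counts)
    f <- file.path(outdir, "chisq.tsv")
    readr::write_tsv(dplyr::mutate(tidy(chsq),
                                   statistic = chsq$statistic,
                                   p_value = chsq$p_value), f)
    note("variant-chisq", f)
  }

  ## stage: repeat-profile
  abunds <- list()
  for (s in config$samples) {
    raw <- sim_reads(sim, n_reads = min(config$n_sample_reads, 50000),
                     sample_id = s, read_length = config$read_length + 10,
                     low_q_tail_frac = 0.1,
                     seed = config$seed + 100 + match(s, config$samples))
    prep <- prepare_reads(raw, n_sample = config$n_sample_reads,
                          seed = config$read_seed,
                          min_quality = config$min_quality,
                          target_length = config$target_length,
                          final_n = config$final_reads)
    cl <- cluster_reads(prep, k = config$kmer,
                        min_shared_kmers = config$min_shared_kmers)
    cl$label <- cl$cluster_id   # no external repeat reference in a default run
    abunds[[s]] <- dplyr::mutate(
      tibble(label = cl$label, size = cl$size), sample_id = s,
      total = attr(cl, "n_reads")
    )
    f <- file.path(outdir, paste0("clusters_", s, ".tsv"))
    readr::write_tsv(select(cl, "cluster_id", "size", "proportion"), f)
    note("repeat-profile", f)
  }
  ab <- abundance_table(bind_rows(abunds),
                        totals = bind_rows(abunds) |>
                          dplyr::distinct(.data$sample_id, total_reads = .data$total))
  f <- file.path(outdir, "abundance.tsv"); readr::write_tsv(ab, f); note("repeat-profile", f)

  ## stage: satellite
  sat_events <- sim$truth[sim$truth$kind == "satellite_array", ]
  if (nrow(sat_events)) {
    seqs <- stats::setNames(as.character(sim$genome), names(sim$genome))
    sat_rows <- list()
    for (i in seq_len(nrow(sat_events))) {
      ev <- sat_events[i, ]
      arr <- substr(seqs[[ev$chrom]], ev$start + 1, ev$end)
      fam <- characterize_satellite(arr, id = ev$family_id %||% paste0("sat", i))
      hits <- map_monomer(fam$consensus, sim, min_identity = config$sat_min_identity)
      loci <- call_tandem_loci(hits, fam$monomer_length, min_hits = config$sat_min_hits)
      sat_rows[[i]] <- tibble(
        family = fam$id, monomer_length = fam$monomer_length,
        at_fraction = fam$at_fraction, n_loci = nrow(loci),
        chromosomes = paste(unique(loci$chrom), collapse = ",")
      )
    }
    f <- file.path(outdir, "satellites.tsv")
    readr::write_tsv(bind_rows(sat_rows), f); note("satellite", f)
  }

  cfgf <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(config), cfgf)
  note("config", cfgf)
  man <- bind_rows(manifest)
  manf <- file.path(outdir, "manifest.tsv")
  if (file.exists(manf)) {
    old <- readr::read_tsv(manf, show_col_types = FALSE)
    readr::write_tsv(bind_rows(old, man), manf)
  } else {
    readr::write_tsv(man, manf)
  }
  man
}
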