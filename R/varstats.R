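#' Length-proportional expected variant counts per chromosome
#'
#' Under a random distribution of variants along the genome the expected
#' count of a chromosome is the genome-wide rate (variants per kbp) times the
#' chromosome length in kbp, so expectations sum exactly to the observed
#' total.
#'
#' @param counts tibble with columns `chrom`, `length` (bp) and, unless
#'   `total` is given, `observed`.
#' @param total total variant count; defaults to `sum(counts$observed)`.
#' @return `counts` with an added `expected` column; the genome-wide rate
#'   (variants/kbp) is stored as attribute `rate`.
#' @examples
#' expected_counts(tibble::tibble(chrom = c("chr1", "chr2"),
#'                                length = c(1e5, 3e5)), total = 40)
#' @export
expected_counts <- function(counts, total = NULL) {
  stopifnot(all(c("chrom", "length") %in% names(counts)))
  if (any(counts$length <= 0)) abort("chromosome lengths must be > 0")
  if (is.null(total)) {
    if (!"observed" %in% names(counts)) abort("give `total` or an `observed` column")
    total <- sum(counts$observed)
  }
  if (total <= 0) abort("total variant count must be > 0")
  rate <- total / sum(counts$length / 1000)
  counts$expected <- rate * counts$length / 1000
  attr(counts, "rate") <- rate
  counts
}

#' Chi-square test of variant distribution across chromosomes
#'
#' Tests whether observed per-chromosome variant counts deviate from the
#' length-proportional expectation: `X^2 = sum (O - E)^2 / E` with
#' `df = n_chromosomes - 1` (the expectation is derived from the observed
#' total), and an upper-tail p value. Standardized residuals
#' `(O - E) / sqrt(E)` and one-df components `(O - E)^2 / E` are reported per
#' chromosome for descriptive use.
#'
#' @param counts tibble with `chrom`, `length`, `observed`; `expected` is
#'   computed with [expected_counts()] if absent.
#' @return object of class `variant_chisq` with elements `table` (tibble with
#'   `expected`, `residual`, `component`, `p_component`), `statistic`, `df`,
#'   `p_value`. [tidy()] returns the table, [glance()] the test summary.
#' @examples
#' x <- chisq_randomness(tibble::tibble(chrom = c("chr1", "chr2"),
#'                                      length = c(1e5, 3e5),
#'                                      observed = c(20L, 20L)))
#' glance(x)
#' @export
chisq_randomness <- function(counts) {
  stopifnot("observed" %in% names(counts))
  if (any(counts$observed < 0)) abort("observed counts must be non-negative")
  if (!"expected" %in% names(counts)) counts <- expected_counts(counts)
  if (any(counts$expected <= 0)) abort("all expected counts must be > 0")
  o <- counts$observed; e <- counts$expected
  comp <- (o - e)^2 / e
  stat <- sum(comp)
  df <- nrow(counts) - 1L
  tab <- dplyr::mutate(
    counts,
    residual = (o - e) / sqrt(e),
    component = comp,
    p_component = pchisq(comp, df = 1, lower.tail = FALSE)
  )
  structure(
    list(table = tab, statistic = stat, df = df,
         p_value = pchisq(stat, df = df, lower.tail = FALSE)),
    class = "variant_chisq"
  )
}

#' @export
print.variant_chisq <- function(x, ...) {
  cat("Chi-square test of per-chromosome variant distribution\n")
  cat(sprintf("  X^2 = %.4g, df = %d, p = %.4g\n", x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @rdname chisq_randomness
#' @param x a `variant_chisq` object.
#' @param ... unused.
#' @export
tidy.variant_chisq <- function(x, ...) as_tibble(x$table)

#' @rdname chisq_randomness
#' @export
glance.variant_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Flag chromosomes enriched or depleted in variants
#'
#' A chromosome is flagged enriched when its standardized residual exceeds
#' `residual_threshold` and depleted when it falls below the negated
#' threshold.
#'
#' @param result a `variant_chisq` object.
#' @param residual_threshold flagging threshold on the standardized residual.
#' @return tibble `chrom`, `residual`, `flag` in `enriched`/`depleted`/`none`.
#' @export
flag_enriched <- function(result, residual_threshold = 2) {
  stopifnot(inherits(result, "variant_chisq"))
  r <- result$table$residual
  tibble(
    chrom = result$table$chrom,
    residual = r,
    flag = ifelse(r > residual_threshold, "enriched",
                  ifelse(r < -residual_threshold, "depleted", "none"))
  )
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' For each term, the p value is the upper-tail hypergeometric probability of
#' drawing at least the observed overlap between the study set and the term's
#' genes when `length(study)` genes are sampled from the population without
#' replacement. q values are Benjamini-Hochberg over the tested terms.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of all gene ids.
#' @param term_map tibble with columns `term`, `gene`.
#' @return tibble `term`, `n_term`, `n_overlap`, `fold_enrichment`, `p`, `q`,
#'   sorted by `p`.
#' @export
hypergeom_enrich <- function(study, population, term_map) {
  stopifnot(all(c("term", "gene") %in% names(term_map)))
  study <- unique(study); population <- unique(population)
  missing <- setdiff(study, population)
  if (length(missing))
    abort(paste0("study genes absent from population: ",
                 paste(missing, collapse = ", ")))
  tm <- term_map[term_map$gene %in% population, ]
  N <- length(population); k <- length(study)
  res <- tm |>
    group_by(.data$term) |>
    summarise(
      n_term = dplyr::n_distinct(.data$gene),
      n_overlap = dplyr::n_distinct(intersect(.data$gene, study)),
      .groups = "drop"
    ) |>
    mutate(
      fold_enrichment = (.data$n_overlap / k) / (.data$n_term / N),
      p = phyper(.data$n_overlap - 1, .data$n_term, N - .data$n_term, k,
                 lower.tail = FALSE),
      q = p.adjust(.data$p, method = "BH")
    ) |>
    arrange(.data$p)
  res
}
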