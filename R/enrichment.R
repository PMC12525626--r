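#' Upper-tail hypergeometric probability
#'
#' Computes P(X >= k) for X ~ Hypergeometric(N, K, n): the probability
#' of drawing at least `k` annotated proteins when sampling `n` proteins
#' without replacement from a population of `N` containing `K` annotated
#' ones. The sum runs over the exact point masses in log space
#' (log-binomials combined by log-sum-exp) for numerical stability at
#' small p.
#'
#' @param k Observed study hits (vectorised).
#' @param n Study size.
#' @param K Population hits.
#' @param N Population size.
#' @return Probability in (0, 1]; `k = 0` gives exactly 1.
#' @export
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 20)   # 1 / choose(20, 5)
hypergeom_upper_tail <- function(k, n, K, N) {
  if (length(n) != 1 || length(K) != 1 || length(N) != 1) {
    stop_input("n, K and N must be scalars")
  }
  if (any(k < 0) || any(k > n) || n > N || K > N || K < 0) {
    stop_input("require 0 <= k <= n <= N and 0 <= K <= N")
  }
  vapply(k, function(ki) {
    if (ki <= max(0, n + K - N)) return(1)
    hi <- min(n, K)
    if (ki > hi) return(0)
    i <- ki:hi
    lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    min(1, exp(log_sum_exp(lp)))
  }, numeric(1))
}

#' Term over-representation analysis
#'
#' One-sided hypergeometric enrichment of a study protein set against a
#' population, for every term in an annotation table. The population
#' defaults to all proteins appearing in the annotation table. Fold
#' enrichment is (k/n)/(K/N); p-values are adjusted across all tested
#' terms by Benjamini-Hochberg.
#'
#' @param study Character vector of study protein ids (must be a subset
#'   of the population).
#' @param annotations Data frame with columns `protein_id`, `term_id`
#'   and optionally `term_name`.
#' @param population Character vector of population protein ids;
#'   defaults to the annotation table's proteins.
#' @param min_term_size Minimum population hits K for a term to be
#'   tested; default 1 (no minimum).
#' @return Data frame of class `enrichment_result` with columns
#'   `term_id`, `term_name`, `k`, `n`, `K`, `N`, `fold`, `p`, `fdr`,
#'   sorted by ascending p.
#' @export
enrich <- function(study, annotations, population = NULL,
                   min_term_size = 1L) {
  stopifnot(all(c("protein_id", "term_id") %in% names(annotations)))
  population <- unique(population %||% annotations$protein_id)
  study <- unique(study)
  if (!all(study %in% population)) {
    stop_input("study set must be a subset of the population; offending: ",
               paste(utils::head(setdiff(study, population), 5),
                     collapse = ", "))
  }
  ann <- annotations[annotations$protein_id %in% population, , drop = FALSE]
  ann <- unique(ann[, intersect(c("protein_id", "term_id", "term_name"),
                                names(ann))])
  if (!"term_name" %in% names(ann)) ann$term_name <- ann$term_id
  N <- length(population)
  n <- length(study)
  terms <- split(ann, ann$term_id)
  rows <- lapply(terms, function(t) {
    members <- unique(t$protein_id)
    K <- length(members)
    if (K < min_term_size) return(NULL)
    k <- sum(study %in% members)
    data.frame(term_id = t$term_id[1], term_name = t$term_name[1],
               k = k, n = n, K = K, N = N,
               fold = if (n > 0) (k * N) / (n * K) else NA_real_,
               p = hypergeom_upper_tail(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    res <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE)
    class(res) <- c("enrichment_result", class(res))
    return(res)
  }
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Display filter for enrichment results
#'
#' Keeps terms with -log10(p) strictly greater than `min_neglog10_p`
#' and fold enrichment of at least `min_fold` (the thresholds used for
#' reporting: -log10 p > 4 and at least fourfold enrichment).
#'
#' @param rows Data frame from [enrich()].
#' @param min_neglog10_p Strict lower bound on -log10(p); default 4.
#' @param min_fold Inclusive lower bound on fold enrichment; default 4.
#' @return The filtered rows.
#' @export
display_filter <- function(rows, min_neglog10_p = 4, min_fold = 4) {
  keep <- -log10(rows$p) > min_neglog10_p & rows$fold >= min_fold
  res <- rows[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write enrichment results to TSV
#'
#' Adds -log10 columns for p and FDR so the table can feed a
#' bubble/lollipop plot directly.
#'
#' @param rows Data frame from [enrich()].
#' @param path Output path.
#' @export
write_enrichment <- function(rows, path) {
  rows$neglog10_p <- -log10(rows$p)
  rows$neglog10_fdr <- -log10(rows$fdr)
  write_tsv(rows, path)
}

#' Read a protein-to-term annotation table
#'
#' TSV with columns `protein_id`, `term_id` and optionally `term_name`
#' (a GAF-like two/three-column dialect).
#'
#' @param path File path.
#' @return Data frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path)
  if (!all(c("protein_id", "term_id") %in% names(df))) {
    stop_input("annotation table needs protein_id and term_id columns")
  }
  df
}
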