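# Pathway over-representation: one-sided Fisher exact (hypergeometric
# upper-tail) test of each pathway's displayed-gene count against the
# genome background, with threshold-based red highlighting.

#' Hypergeometric upper-tail probability (one-sided Fisher exact test)
#'
#' Probability of drawing at least `k` pathway genes when `n` genes are
#' drawn without replacement from a genome of `N` genes of which `K` belong
#' to the pathway:
#' \deqn{p = \sum_{j=k}^{\min(K,n)} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}}
#' Computed by log-binomial-coefficient summation, numerically stable for
#' genome-scale `N`.
#'
#' @param N Universe (genome background) size.
#' @param K Pathway size within the universe.
#' @param n Input-list size within the universe.
#' @param k Input genes in the pathway.
#' @return The tail probability in `(0, 1]`; `k = 0` gives exactly 1.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  N <- as.integer(N); K <- as.integer(K); n <- as.integer(n); k <- as.integer(k)
  if (any(c(N, K, n, k) < 0L) || K > N || n > N || k > min(K, n))
    stop2("invalid counts: need 0 <= k <= min(K, n), K <= N, n <= N (got N=%d K=%d n=%d k=%d)",
          N, K, n, k)
  if (k == 0L) return(1)
  j <- max(k, n - (N - K)):min(K, n)
  p <- sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
  min(p, 1)
}

#' Test every populated pathway for over-representation
#'
#' One result per pathway containing at least one displayed gene (`k >= 1`).
#' Counts: `N` = universe size, `K` = pathway genes in the universe, `n` =
#' displayed genes, `k` = displayed genes in the pathway. A pathway is
#' highlighted iff its (raw, or BH-adjusted when `fdr = TRUE`) p-value is
#' strictly below `threshold`; a p-value exactly at the threshold is not
#' highlighted.
#'
#' @param catalog An `AnnotationCatalog` (supplies pathway memberships and
#'   the universe).
#' @param displayed Character vector of displayed entity ids; must be a
#'   subset of the universe.
#' @param threshold Highlight threshold on the p-value (default 0.05).
#' @param fdr Apply Benjamini-Hochberg adjustment before highlighting
#'   (off by default; the raw p is always reported in `p_value`).
#' @return A data frame of class `EnrichmentResult` with columns `pathway`,
#'   `N`, `K`, `n`, `k`, `p_value`, `highlighted`, sorted by ascending
#'   p-value then pathway name.
#' @export
test_all_pathways <- function(catalog, displayed, threshold = 0.05,
                              fdr = FALSE) {
  if (threshold <= 0 || threshold > 1)
    stop2("threshold must be in (0, 1]")
  displayed <- unique(as.character(displayed))
  outside <- setdiff(displayed, catalog$universe)
  if (length(outside))
    stop2("displayed entities outside the universe: %s",
          paste(utils::head(outside, 5L), collapse = ", "))
  N <- length(catalog$universe)
  n <- length(displayed)
  # pathway -> members, from the entity->pathway map
  members <- list()
  for (e in names(catalog$entity_pathways))
    for (p in catalog$entity_pathways[[e]])
      members[[p]] <- c(members[[p]], e)
  rows <- lapply(sort(names(members)), function(p) {
    mem <- unique(members[[p]])
    K <- length(intersect(mem, catalog$universe))
    k <- length(intersect(mem, displayed))
    if (k < 1L) return(NULL)
    data.frame(pathway = p, N = N, K = K, n = n, k = k,
               p_value = hypergeom_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    res <- data.frame(pathway = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p_value = numeric(0),
                      highlighted = logical(0), stringsAsFactors = FALSE)
    class(res) <- c("EnrichmentResult", "data.frame")
    return(res)
  }
  res <- do.call(rbind, rows)
  crit <- if (fdr) stats::p.adjust(res$p_value, method = "BH") else res$p_value
  res$highlighted <- crit < threshold
  res <- res[order(res$p_value, res$pathway, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Write an enrichment report as TSV
#' @param res An `EnrichmentResult` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(res, path) {
  header <- "pathway\tN\tK\tn\tk\tp_value\thighlighted"
  lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%s\t%s",
                   res$pathway, res$N, res$K, res$n, res$k,
                   formatC(res$p_value, format = "g", digits = 6),
                   ifelse(res$highlighted, "yes", "no"))
  write_lines_utf8(c(header, lines), path)
}
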