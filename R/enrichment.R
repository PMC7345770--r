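# Hypergeometric over-representation analysis with Bonferroni correction.

#' Build an annotation catalog for enrichment analysis
#'
#' @param table Data frame with columns `term_id`, `term_name`,
#'   `gene_symbol` (one row per term-gene pair), or a path to such a TSV.
#' @param universe Optional background gene set; defaults to every gene
#'   annotated in the catalog. Override with the platform's measured
#'   genes to test against the measured background instead.
#' @return An `AnnotationCatalog`: list with `terms` (term_id -> list of
#'   name, genes) and `universe`.
#' @export
annotation_catalog <- function(table, universe = NULL) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE,
                               colClasses = "character")
  }
  need <- c("term_id", "term_name", "gene_symbol")
  if (!all(need %in% names(table))) {
    stop_input("annotation_catalog: need columns ",
               paste(need, collapse = ", "))
  }
  terms <- lapply(split(table, table$term_id), function(chunk) {
    list(name = chunk$term_name[1], genes = unique(chunk$gene_symbol))
  })
  if (any(vapply(terms, function(t) length(t$genes) == 0L, logical(1)))) {
    stop_input("annotation_catalog: empty term gene set")
  }
  annotated <- unique(table$gene_symbol)
  if (is.null(universe)) {
    universe <- annotated
  } else {
    universe <- unique(as.character(universe))
    out <- setdiff(annotated, universe)
    if (length(out) > 0L) {
      stop_input("annotation_catalog: annotated gene(s) outside the ",
                 "universe: ", paste(utils::head(out, 10), collapse = ", "))
    }
  }
  structure(list(terms = terms, universe = universe),
            class = "AnnotationCatalog")
}

#' Over-representation of a gene set in annotation terms
#'
#' For every term, computes the one-sided hypergeometric tail probability
#' of observing at least the actual overlap between the query and the
#' term's gene set, given the query size, term size and universe size
#' (sampling without replacement). Raw p-values are Bonferroni-corrected
#' over the number of tested terms; a term is significant when the
#' corrected p-value is below `alpha`. Over-representation only — no
#' depletion test.
#'
#' @param query Character vector of gene symbols. Genes outside the
#'   universe are dropped with a message.
#' @param catalog An [annotation_catalog()].
#' @param alpha Significance level on the corrected p-value (default 0.05).
#' @return An `EnrichmentResult` data frame sorted by corrected p-value:
#'   term_id, term_name, term_size, overlap, overlap_genes
#'   (comma-separated), raw_p, corrected_p, significant.
#' @export
enrich <- function(query, catalog, alpha = 0.05) {
  query <- unique(as.character(query))
  outside <- setdiff(query, catalog$universe)
  if (length(outside) > 0L) {
    message("enrich: dropped ", length(outside),
            " query gene(s) outside the universe: ",
            paste(outside, collapse = ", "))
    query <- setdiff(query, outside)
  }
  if (length(query) == 0L) {
    stop_input("enrich: empty query after universe filtering")
  }
  N <- length(catalog$universe)
  n <- length(query)
  rows <- lapply(names(catalog$terms), function(id) {
    t <- catalog$terms[[id]]
    K <- length(t$genes)
    hit <- intersect(query, t$genes)
    k <- length(hit)
    # P(X >= k), X ~ Hypergeometric(N, K, n)
    raw_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = t$name, term_size = K,
               overlap = k,
               overlap_genes = paste(sort(hit), collapse = ","),
               raw_p = raw_p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$corrected_p <- pmin(1, res$raw_p * nrow(res))
  res$significant <- res$corrected_p < alpha
  res <- res[order(res$corrected_p, res$raw_p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("EnrichmentResult", "data.frame"),
            universe_size = N, query_size = n, alpha = alpha)
}
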