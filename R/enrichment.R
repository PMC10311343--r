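#' Read gene sets in GMT format
#'
#' Thin wrapper around `fgsea::gmtPathways()` returning a named list of
#' character vectors.
#'
#' @param path GMT file path (set name, description, tab-separated genes).
#' @return named list of gene sets.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("GMT file not found: %s", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric test of the overlap between the
#' inferred network genes and a gene set: \eqn{P(X \ge k)} with population
#' size \eqn{N = |universe|}, \eqn{K = |set \cap universe|} successes,
#' \eqn{n = |network|} draws and observed overlap \eqn{k}. Network genes
#' outside the universe are dropped with a warning.
#'
#' @param network_genes character vector of inferred network genes.
#' @param gene_set character vector, one gene set.
#' @param universe character vector, the background population (typically
#'   all proteins of the prior network).
#' @return a list with `p_value`, `overlap`, `set_size`, `network_size`,
#'   `universe_size`.
#' @examples
#' # N = 20, K = 5, n = 4, k = 3 -> p = 155/4845
#' ora(c("g1", "g2", "g3", "g11"), paste0("g", 1:5), paste0("g", 1:20))
#' @export
ora <- function(network_genes, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_input("empty universe")
  network_genes <- unique(network_genes)
  outside <- setdiff(network_genes, universe)
  if (length(outside)) {
    warning(sprintf("%d network gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    network_genes <- intersect(network_genes, universe)
  }
  if (length(network_genes) == 0L) stop_input("empty network gene set")
  K <- length(intersect(unique(gene_set), universe))
  n <- length(network_genes)
  k <- length(intersect(network_genes, gene_set))
  p <- stats::phyper(k - 1, K, length(universe) - K, n, lower.tail = FALSE)
  list(p_value = p, overlap = k, set_size = K, network_size = n,
       universe_size = length(universe))
}

#' Enrichment score from a p-value
#'
#' @param p p-value in (0, 1].
#' @return \eqn{-\log_{10}(p)}.
#' @export
enrichment_score <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_input("p-values must lie in (0, 1]")
  }
  -log10(p)
}

#' Over-representation analysis of a network against a gene-set collection
#'
#' Runs [ora()] for every set in the collection and reports raw p-values
#' and \eqn{-\log_{10} p} enrichment scores. No multiple-testing correction
#' is applied by default (score distributions are compared raw); a
#' Benjamini-Hochberg column is available for exploratory use.
#'
#' @param network_genes character vector of inferred network genes.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param universe background population; defaults to the union of the
#'   collection when not supplied.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame` with columns `set_name`, `overlap`, `set_size`,
#'   `network_size`, `universe_size`, `p_value`, `score` (and `p_adjust`
#'   when requested).
#' @export
ora_collection <- function(network_genes, collection, universe = NULL,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(collection) == 0L) stop_input("empty gene-set collection")
  if (is.null(universe)) universe <- unique(unlist(collection))
  rows <- lapply(names(collection), function(nm) {
    r <- suppressWarnings(ora(network_genes, collection[[nm]], universe))
    data.frame(set_name = nm, overlap = r$overlap, set_size = r$set_size,
               network_size = r$network_size,
               universe_size = r$universe_size, p_value = r$p_value,
               score = enrichment_score(r$p_value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjust <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
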