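#' Read a TF regulon table
#'
#' Reads a TSV with columns `tf`, `target`, and optionally `mode` (+1/-1,
#' unknown treated as +1) and `confidence` (class labels A-E). When a
#' confidence column exists, regulons are filtered to the requested classes
#' (default A-C). Duplicate (tf, target) pairs keep the first row.
#'
#' @param path TSV file path.
#' @param confidence confidence classes to keep when the column is present;
#'   `NULL` keeps everything.
#' @return a `data.frame` with columns `tf`, `target`, `mode` and (if
#'   present) `confidence`.
#' @export
read_regulons <- function(path, confidence = c("A", "B", "C")) {
  if (!file.exists(path)) stop_input("regulon file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_regulons(df, confidence = confidence)
}

validate_regulons <- function(df, confidence = c("A", "B", "C")) {
  req <- c("tf", "target")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop_input("regulon table missing column(s): %s",
               paste(missing, collapse = ", "))
  }
  if (!"mode" %in% names(df)) df$mode <- 1
  df$mode <- suppressWarnings(as.numeric(df$mode))
  df$mode[is.na(df$mode) | df$mode >= 0] <- 1
  df$mode[df$mode < 0] <- -1
  if ("confidence" %in% names(df) && !is.null(confidence)) {
    df <- df[df$confidence %in% confidence, , drop = FALSE]
  }
  df <- df[!duplicated(df[, c("tf", "target")]), , drop = FALSE]
  df <- df[nzchar(df$tf) & nzchar(df$target), , drop = FALSE]
  if (nrow(df) == 0L) stop_input("no regulon rows remain after filtering")
  rownames(df) <- NULL
  df
}

#' Read per-gene differential statistics
#'
#' @param path TSV with columns `gene` and `stat` (e.g. a moderated t
#'   statistic or signed -log10 p from upstream differential expression).
#' @return a named numeric vector of statistics.
#' @export
read_gene_stats <- function(path) {
  if (!file.exists(path)) stop_input("gene statistics file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "stat") %in% names(df))) {
    stop_input("gene statistics table needs columns 'gene' and 'stat'")
  }
  stats::setNames(as.numeric(df$stat), df$gene)
}

#' Score one regulon against gene statistics
#'
#' Signed, sqrt(k)-normalized mean of the target statistics:
#' \eqn{(1/\sqrt{k}) \sum_i mode_i \cdot stat_i} over the k regulon targets
#' present in `gene_stats`.
#'
#' @param targets character vector of target genes.
#' @param modes numeric vector of modes (+1/-1), recycled to `targets`.
#' @param gene_stats named numeric vector of per-gene statistics.
#' @return the enrichment score, or `NA_real_` when no target matches.
#' @export
score_tf <- function(targets, modes, gene_stats) {
  modes <- rep_len(modes, length(targets))
  hit <- targets %in% names(gene_stats)
  k <- sum(hit)
  if (k == 0L) return(NA_real_)
  sum(modes[hit] * gene_stats[targets[hit]]) / sqrt(k)
}

#' Estimate TF activities with an empirical permutation null
#'
#' Scores every regulon against the differential gene statistics and assigns
#' each score an empirical two-sided p-value by randomizing the bipartite
#' TF-to-target graph `n_perm` times. The default null preserves each TF's
#' out-degree: in every permutation a TF's matched targets are resampled
#' without replacement from the assayed gene universe (all genes carrying a
#' statistic), keeping the regulation modes. The alternative `"global"` null
#' shuffles the statistic labels over that universe instead. The p-value uses
#' add-one smoothing, \eqn{p = (1 + \#\{|s_{perm}| \ge |s_{obs}|\})/(n_{perm}+1)},
#' so it can never be zero.
#'
#' @param regulons regulon table (see [read_regulons()]) or a data frame with
#'   columns `tf`, `target`, `mode`.
#' @param gene_stats named numeric vector (or two-column `gene`/`stat` data
#'   frame) of differential statistics.
#' @param n_perm number of permutations (default 1000).
#' @param sig_threshold significance cutoff on the empirical p-value
#'   (default 0.05).
#' @param seed optional RNG seed; fixed seed gives bitwise-identical output.
#' @param null_model `"degree_preserving"` (default) or `"global"`.
#' @return a `data.frame` of class `tf_activity_table` with columns `tf`,
#'   `n_targets`, `score`, `empirical_p`, `significant`, `weight`
#'   (= `abs(score)`, the prize used by the network objective).
#' @export
tf_activity <- function(regulons, gene_stats, n_perm = 1000,
                        sig_threshold = 0.05, seed = NULL,
                        null_model = c("degree_preserving", "global")) {
  null_model <- match.arg(null_model)
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  regulons <- validate_regulons(as.data.frame(regulons,
                                              stringsAsFactors = FALSE),
                                confidence = NULL)
  if (is.data.frame(gene_stats)) {
    gene_stats <- stats::setNames(as.numeric(gene_stats$stat),
                                  gene_stats$gene)
  }
  reg <- split(regulons, regulons$tf)
  # null universe: the assayed (scored) gene space; resampling from it keeps
  # the null non-degenerate even for a single small regulon
  universe <- unique(names(gene_stats))
  su <- unname(gene_stats[universe])
  nu <- length(su)
  if (nu == 0L) stop_input("no regulon target carries a gene statistic")

  obs <- vapply(reg, function(g) score_tf(g$target, g$mode, gene_stats),
                numeric(1))
  dropped <- names(obs)[is.na(obs)]
  if (length(dropped)) {
    warning(sprintf("TF(s) with zero matched targets omitted: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  reg <- reg[!is.na(obs)]
  obs <- obs[!is.na(obs)]
  if (length(obs) == 0L) stop_input("no scorable TF")

  ks <- vapply(reg, function(g) sum(g$target %in% universe), integer(1))
  if (any(ks > nu)) {
    stop_input("regulon larger than the scored target universe")
  }
  modes <- lapply(reg, function(g) g$mode[g$target %in% universe])
  # index of each TF's matched targets in the universe (for the global null)
  idx0 <- lapply(reg, function(g) match(intersect(g$target, universe),
                                        universe))

  exceed <- integer(length(obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (null_model == "global") perm_stats <- sample(su)
      for (j in seq_along(obs)) {
        k <- ks[j]
        s <- if (null_model == "degree_preserving") {
          sum(modes[[j]] * su[sample.int(nu, k)]) / sqrt(k)
        } else {
          sum(modes[[j]] * perm_stats[idx0[[j]]]) / sqrt(k)
        }
        if (abs(s) >= abs(obs[j])) exceed[j] <- exceed[j] + 1L
      }
    }
  })
  empirical_p <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(tf = names(obs),
                    n_targets = unname(ks),
                    score = unname(obs),
                    empirical_p = unname(empirical_p),
                    significant = unname(empirical_p <= sig_threshold),
                    weight = unname(abs(obs)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$tf), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tf_activity_table", "data.frame")
  out
}

#' Write a TF activity table to TSV
#' @param tab a `tf_activity_table`.
#' @param path output file path.
#' @export
write_tf_activity <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
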