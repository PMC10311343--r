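#' Combine p-values with Fisher's method
#'
#' Aggregates a set of independent p-values into one combined p-value: the
#' survival probability of \eqn{X = -2 \sum \ln p_i} under a chi-square
#' distribution with \eqn{2k} degrees of freedom. With a single p-value the
#' aggregation is the identity.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return the combined p-value.
#' @examples
#' fisher_aggregate(0.05)          # 0.05
#' fisher_aggregate(c(0.01, 0.04)) # ~3.53e-3
#' @export
fisher_aggregate <- function(p_values) {
  if (length(p_values) == 0L) stop_input("fisher_aggregate: empty p-value list")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_input("fisher_aggregate: p-values must lie in (0, 1]")
  }
  if (length(p_values) == 1L) return(p_values)  # k = 1: exact identity
  x <- -2 * sum(log(p_values))
  stats::pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Mean effect size over matched splice features
#'
#' @param effects numeric vector of dPSI or logFC values.
#' @return arithmetic mean.
#' @export
mean_effect <- function(effects) {
  if (length(effects) == 0L) stop_input("mean_effect: empty effect list")
  mean(effects)
}

#' Read differential splice evidence
#'
#' Reads a TSV with columns `feature_id`, `feature_kind` (`exon` or
#' `transcript`), `effect` (dPSI for exons, log2 fold change for
#' transcripts) and `p_value`. dPSI effects are clipped to [-1, 1];
#' p-values of exactly zero are floored at 1e-300 before any log transform.
#'
#' @param path TSV file path.
#' @return a validated `data.frame` of feature-level evidence.
#' @export
read_splice_evidence <- function(path) {
  if (!file.exists(path)) stop_input("evidence file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_evidence(df)
}

validate_evidence <- function(df) {
  req <- c("feature_id", "feature_kind", "effect", "p_value")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop_input("evidence table missing column(s): %s",
               paste(missing, collapse = ", "))
  }
  df$effect <- as.numeric(df$effect)
  df$p_value <- as.numeric(df$p_value)
  bad <- is.na(df$p_value) | df$p_value < 0 | df$p_value > 1 |
    !df$feature_kind %in% c("exon", "transcript") | is.na(df$effect)
  if (any(bad)) {
    warning(sprintf("%d malformed evidence row(s) dropped", sum(bad)),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  zero <- df$p_value == 0
  if (any(zero)) df$p_value[zero] <- 1e-300
  ex <- df$feature_kind == "exon"
  df$effect[ex] <- pmin(pmax(df$effect[ex], -1), 1)
  rownames(df) <- NULL
  df[, req]
}

#' Call skipped protein domains from splice evidence
#'
#' Matches exon- and transcript-level differential evidence onto the
#' (protein, Pfam) domains of the prior through the domain mapping tables and
#' derives a per-domain skip call. Multiple features mapping to one domain
#' are pooled: the domain p-value is the Fisher aggregation of the matched
#' feature p-values, the domain effect is the arithmetic mean of the matched
#' effects. A domain is called skipped when its aggregated p-value is at or
#' below `p_threshold` and its mean effect is negative (exon exclusion or
#' decreased transcript abundance); an included exon or up-regulated
#' transcript cannot remove a domain. Domains without any matched feature are
#' absent from the table and never skipped.
#'
#' @param net a `prior_network`.
#' @param evidence feature-level evidence (see [read_splice_evidence()]).
#' @param p_threshold significance threshold on the aggregated p-value
#'   (default 0.05; ties count as skipped).
#' @param strict_all if `TRUE`, additionally require every matched feature's
#'   own p-value to pass `p_threshold` (a stricter per-feature reading of
#'   "all mapped exons skipped").
#' @return a `data.frame` of class `domain_skip_table` with columns
#'   `protein`, `domain`, `aggregated_p`, `mean_effect`, `n_features`,
#'   `skipped`.
#' @export
call_skipped_domains <- function(net, evidence, p_threshold = 0.05,
                                 strict_all = FALSE) {
  stopifnot(inherits(net, "prior_network"))
  evidence <- validate_evidence(as.data.frame(evidence,
                                              stringsAsFactors = FALSE))
  map <- net$domain_features
  m <- merge(map, evidence, by = c("feature_id", "feature_kind"))
  unmatched <- setdiff(evidence$feature_id, map$feature_id)
  if (length(unmatched)) {
    message(sprintf("%d evidence feature(s) matched no domain and were ignored",
                    length(unmatched)))
  }
  if (nrow(m) == 0L) {
    warning("no evidence feature matched any domain; empty skip table",
            call. = FALSE)
    return(empty_skip_table())
  }
  grp <- split(m, paste(m$protein, m$domain, sep = "\r"))
  rows <- lapply(grp, function(g) {
    ap <- fisher_aggregate(g$p_value)
    me <- mean_effect(g$effect)
    sk <- ap <= p_threshold && me < 0
    if (strict_all) sk <- sk && all(g$p_value <= p_threshold)
    data.frame(protein = g$protein[1L], domain = g$domain[1L],
               aggregated_p = ap, mean_effect = me,
               n_features = nrow(g), skipped = sk,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("domain_skip_table", "data.frame")
  out
}

empty_skip_table <- function() {
  out <- data.frame(protein = character(0), domain = character(0),
                    aggregated_p = numeric(0), mean_effect = numeric(0),
                    n_features = integer(0), skipped = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("domain_skip_table", "data.frame")
  out
}

#' Write a domain skip table to TSV
#' @param skips a `domain_skip_table`.
#' @param path output file path.
#' @export
write_domain_skips <- function(skips, path) {
  utils::write.table(as.data.frame(skips), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
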