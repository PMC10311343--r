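#' Splice-aware causal network inference
#'
#' End-to-end fit: estimates TF activities with a permutation null, derives
#' skipped protein domains from differential splice evidence, assembles the
#' network-selection ILP on the domain-resolved prior, enumerates a pool of
#' (near-)optimal subnetworks connecting the perturbation root(s) to the
#' significantly regulated TFs, and integrates the pool into a consensus
#' network with per-DDI frequency weights.
#'
#' @param records interaction records (see [read_interaction_table()]) or an
#'   already-built `prior_network`.
#' @param regulons regulon table with columns `tf`, `target`, optional
#'   `mode`/`confidence`; alternatively pass a precomputed
#'   `tf_activity_table` via `tf_table`.
#' @param gene_stats named numeric vector (or `gene`/`stat` data frame) of
#'   differential expression statistics.
#' @param splice_evidence feature-level splice evidence data frame, or
#'   `NULL`.
#' @param mode `"hard"` (skipped domains infeasible) or `"soft"` (penalized
#'   in the objective).
#' @param splice_aware set `FALSE` to ignore the splice evidence entirely
#'   (the splice-unaware analysis used as a comparison baseline).
#' @param roots optional explicit perturbation root proteins; otherwise
#'   auto-designated (see [attach_perturbation()]).
#' @param tf_table optional precomputed `tf_activity_table`, bypassing the
#'   permutation step.
#' @param p_skip skip-call threshold on the aggregated domain p-value.
#' @param p_tf TF significance threshold on the empirical p-value.
#' @param n_perm permutations for the TF null (default 1000).
#' @param lambda,alpha,beta,soft_p_cut ILP parameters (see [build_ilp()]).
#' @param k_max,objective_tolerance solution-pool controls (see
#'   [enumerate_solutions()]).
#' @param backend,time_limit solver controls (see [solve_ilp()]).
#' @param seed RNG seed for the permutation null (solving is deterministic).
#' @return an object of class `splinter_fit` with components `network`,
#'   `tf_activity`, `domain_skips`, `instance`, `pool`, `consensus` and
#'   `call`. Methods: `print`, `summary`, `plot`, `coef` (consensus DDI
#'   weights), `as.data.frame` (consensus edge table).
#' @examples
#' scn <- generate_scenario(seed = 7)
#' fit <- splinter(scn$records, scn$regulons, scn$gene_stats, scn$evidence,
#'                 roots = scn$roots, n_perm = 200, seed = 7)
#' fit
#' coef(fit)
#' @export
splinter <- function(records, regulons = NULL, gene_stats = NULL,
                     splice_evidence = NULL,
                     mode = c("hard", "soft"), splice_aware = TRUE,
                     roots = NULL, tf_table = NULL,
                     p_skip = 0.05, p_tf = 0.05, n_perm = 1000,
                     lambda = 0.01, alpha = NULL, beta = NULL,
                     soft_p_cut = 1, k_max = 100, objective_tolerance = 0,
                     backend = "bnb", time_limit = 3600, seed = NULL) {
  mode <- match.arg(mode)
  net <- if (inherits(records, "prior_network")) records else
    build_network(records)
  if (is.null(tf_table)) {
    if (is.null(regulons) || is.null(gene_stats)) {
      stop_input("supply either regulons + gene_stats or a tf_table")
    }
    tf_table <- tf_activity(regulons, gene_stats, n_perm = n_perm,
                            sig_threshold = p_tf, seed = seed)
  }
  if (length(net$perturbation_roots) == 0L) {
    net <- attach_perturbation(net, roots = roots, tfs = tf_table$tf)
  }
  skips <- if (splice_aware && !is.null(splice_evidence) &&
               nrow(splice_evidence)) {
    call_skipped_domains(net, splice_evidence, p_threshold = p_skip)
  } else {
    empty_skip_table()
  }
  instance <- build_ilp(net, tf_table, skips, mode = mode, lambda = lambda,
                        alpha = alpha, beta = beta, p_threshold = p_skip,
                        soft_p_cut = soft_p_cut)
  pool <- enumerate_solutions(instance, k_max = k_max,
                              objective_tolerance = objective_tolerance,
                              backend = backend, time_limit = time_limit)
  if (length(pool) == 0L) {
    stop("solver returned no solution (model bug: the empty network is ",
         "always feasible)")
  }
  cons <- consensus_network(pool)
  structure(list(network = net, tf_activity = tf_table,
                 domain_skips = skips, instance = instance, pool = pool,
                 consensus = cons, splice_aware = splice_aware,
                 call = match.call()),
            class = "splinter_fit")
}

#' @export
print.splinter_fit <- function(x, ...) {
  cat(sprintf("Splice-%s causal network fit (%s mode)\n",
              if (x$splice_aware) "aware" else "unaware", x$instance$mode))
  cat(sprintf("  significant TFs: %d of %d   skipped domains: %d\n",
              sum(x$tf_activity$significant), nrow(x$tf_activity),
              sum(x$domain_skips$skipped)))
  cat(sprintf("  solution pool: %d (optimum %.4g)\n", length(x$pool),
              attr(x$pool, "base_objective")))
  cat(sprintf("  consensus: %d DDIs over %d proteins\n",
              nrow(x$consensus$edges), nrow(x$consensus$proteins)))
  invisible(x)
}

#' @export
summary.splinter_fit <- function(object, ...) {
  x <- object
  cat("TF activity\n")
  print(as.data.frame(x$tf_activity), digits = 4)
  if (nrow(x$domain_skips)) {
    cat("\nDomain skip calls\n")
    print(as.data.frame(x$domain_skips), digits = 4)
  }
  cat("\nConsensus DDIs (weight = appearance frequency across",
      sprintf("%d solutions)\n", x$consensus$n_solutions))
  e <- x$consensus$edges
  if (nrow(e)) {
    print(e[order(-e$weight, e$key),
            c("protein_a", "domain_a", "protein_b", "domain_b", "weight")],
          digits = 3, row.names = FALSE)
  } else {
    cat("  (empty consensus network)\n")
  }
  invisible(x)
}

#' @export
coef.splinter_fit <- function(object, ...) {
  stats::setNames(object$consensus$edges$weight, object$consensus$edges$key)
}

#' @export
as.data.frame.splinter_fit <- function(x, ...) {
  as.data.frame(x$consensus$edges)
}

#' @export
plot.splinter_fit <- function(x, ...) {
  e <- x$consensus$edges
  if (nrow(e) == 0L) {
    plot.new()
    title(main = "empty consensus network")
    return(invisible(x))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$protein_a, to = e$protein_b),
    directed = FALSE,
    vertices = data.frame(name = x$consensus$proteins$protein))
  igraph::E(g)$width <- 1 + 3 * e$weight
  tf_col <- ifelse(igraph::V(g)$name %in%
                     x$tf_activity$tf[x$tf_activity$significant],
                   "tomato", "skyblue")
  plot(g, vertex.color = tf_col, edge.label = sprintf("%.2f", e$weight),
       ...)
  invisible(x)
}

#' Splice-aware versus splice-unaware comparison
#'
#' Runs the full inference twice on the same prior and TF activities — once
#' honouring the splice evidence, once ignoring it — and differences the two
#' consensus networks, flagging unaware-only DDIs with a skipped endpoint
#' as splice-abrogated.
#'
#' @inheritParams splinter
#' @param ... further arguments passed to [splinter()].
#' @return an object of class `splice_comparison`: list with the `aware`
#'   and `unaware` fits and the `diff` edge report of [diff_networks()].
#' @export
compare_splice_modes <- function(records, regulons = NULL,
                                 gene_stats = NULL, splice_evidence = NULL,
                                 mode = c("hard", "soft"), roots = NULL,
                                 tf_table = NULL, n_perm = 1000,
                                 seed = NULL, ...) {
  mode <- match.arg(mode)
  net <- if (inherits(records, "prior_network")) records else
    build_network(records)
  if (is.null(tf_table)) {
    tf_table <- tf_activity(regulons, gene_stats, n_perm = n_perm,
                            seed = seed)
  }
  if (length(net$perturbation_roots) == 0L) {
    net <- attach_perturbation(net, roots = roots, tfs = tf_table$tf)
  }
  aware <- splinter(net, tf_table = tf_table,
                    splice_evidence = splice_evidence, mode = mode,
                    splice_aware = TRUE, ...)
  unaware <- splinter(net, tf_table = tf_table,
                      splice_evidence = splice_evidence, mode = mode,
                      splice_aware = FALSE, ...)
  d <- diff_networks(aware$consensus, unaware$consensus,
                     skips = aware$domain_skips)
  structure(list(aware = aware, unaware = unaware, diff = d),
            class = "splice_comparison")
}

#' @export
print.splice_comparison <- function(x, ...) {
  cat("Splice-aware vs splice-unaware comparison\n")
  cat(sprintf("  aware consensus: %d DDIs   unaware consensus: %d DDIs\n",
              nrow(x$aware$consensus$edges),
              nrow(x$unaware$consensus$edges)))
  tab <- table(factor(x$diff$status,
                      levels = c("shared", "aware_only", "unaware_only")))
  cat(sprintf("  shared: %d  aware-only: %d  unaware-only: %d\n",
              tab[["shared"]], tab[["aware_only"]], tab[["unaware_only"]]))
  cat(sprintf("  splice-abrogated DDIs: %d\n", sum(x$diff$splice_abrogated)))
  invisible(x)
}
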