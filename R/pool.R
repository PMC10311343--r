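#' Enumerate diverse (near-)optimal solutions
#'
#' Repeatedly re-solves the instance, each time excluding the directed-edge
#' sets of all previously returned solutions (no-good cuts), until `k_max`
#' solutions are collected, the objective degrades beyond
#' `objective_tolerance` below the optimum, or no further solution exists.
#' All returned solutions are individually certified with
#' [validate_solution()].
#'
#' @param instance an `ilp_instance`.
#' @param k_max maximum pool size (default 100).
#' @param objective_tolerance admissible objective degradation relative to
#'   the optimum (default 0: optimal-only pool).
#' @param min_distance minimum Hamming distance (in directed edges) between
#'   pool members (default 1 = pairwise distinct).
#' @param backend,time_limit passed to [solve_ilp()]; a timeout mid-pool
#'   returns the solutions found so far with an attribute
#'   `truncated = TRUE`.
#' @return a list of `solution_network` objects of class `solution_pool`.
#' @export
enumerate_solutions <- function(instance, k_max = 100,
                                objective_tolerance = 0,
                                min_distance = 1L,
                                backend = "bnb", time_limit = 3600) {
  if (k_max < 1L) stop_input("k_max must be >= 1")
  pool <- list()
  exclude <- list()
  base_obj <- NULL
  truncated <- FALSE
  t0 <- proc.time()[["elapsed"]]
  while (length(pool) < k_max) {
    left <- time_limit - (proc.time()[["elapsed"]] - t0)
    if (left <= 0) {
      truncated <- TRUE
      break
    }
    sol <- solve_ilp(instance, backend = backend, time_limit = left,
                     exclude = exclude, min_distance = min_distance)
    if (sol$status == "infeasible") break
    if (sol$status == "feasible") truncated <- TRUE
    if (is.null(base_obj)) base_obj <- sol$objective
    if (sol$objective < base_obj - objective_tolerance - 1e-12) break
    viol <- validate_solution(instance$net, instance$domains, sol,
                              mode = instance$mode)
    if (length(viol)) {
      stop(sprintf("solver returned an invalid solution: %s",
                   paste(viol, collapse = "; ")))
    }
    pool[[length(pool) + 1L]] <- sol
    exclude[[length(exclude) + 1L]] <- sol$selected_ids
    if (truncated) break
  }
  structure(pool, class = "solution_pool", base_objective = base_obj,
            truncated = truncated)
}

#' Integrate a solution pool into a consensus network
#'
#' Takes the union of all elements across the pool and assigns every DDI
#' (and protein, domain, PPI) a weight in (0, 1]: the fraction of pool
#' members containing it. A weight of 1 marks an element present in every
#' solution. DDIs are counted by their undirected identity; the orientation
#' frequencies are reported alongside.
#'
#' @param pool a non-empty list of `solution_network` objects sharing one
#'   mode (as returned by [enumerate_solutions()]).
#' @return an object of class `consensus_network` with data frames `edges`
#'   (per-DDI weights), `proteins`, `domains`, `ppis`, plus `n_solutions`
#'   and the mode label.
#' @export
consensus_network <- function(pool) {
  pool <- Filter(function(s) inherits(s, "solution_network"), pool)
  if (length(pool) == 0L) stop_input("empty solution pool")
  modes <- unique(vapply(pool, function(s) s$mode, ""))
  if (length(modes) != 1L) stop_input("pool mixes modes: %s",
                                      paste(modes, collapse = ", "))
  n <- length(pool)
  all_ddis <- do.call(rbind, lapply(seq_along(pool), function(i) {
    d <- pool[[i]]$ddis
    if (nrow(d)) cbind(d, sol = i) else NULL
  }))
  count_tab <- function(values) {
    if (length(values) == 0L) return(data.frame(id = character(0),
                                                weight = numeric(0)))
    tt <- table(values)
    data.frame(id = names(tt), weight = as.numeric(tt) / n,
               stringsAsFactors = FALSE)
  }
  if (!is.null(all_ddis) && nrow(all_ddis)) {
    grp <- split(all_ddis, all_ddis$key)
    edges <- do.call(rbind, lapply(grp, function(g) {
      data.frame(key = g$key[1L],
                 protein_a = min(g$from_protein[1L], g$to_protein[1L]),
                 protein_b = max(g$from_protein[1L], g$to_protein[1L]),
                 domain_a = NA_character_, domain_b = NA_character_,
                 weight = length(unique(g$sol)) / n,
                 n_fwd = sum(g$direction == "fwd"),
                 n_rev = sum(g$direction == "rev"),
                 stringsAsFactors = FALSE)
    }))
    # recover canonical endpoint domains from the key
    sp <- strsplit(edges$key, "|", fixed = TRUE)
    edges$protein_a <- vapply(sp, `[`, "", 1L)
    edges$domain_a <- vapply(sp, `[`, "", 2L)
    edges$protein_b <- vapply(sp, `[`, "", 3L)
    edges$domain_b <- vapply(sp, `[`, "", 4L)
    edges <- edges[order(edges$key), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(key = character(0), protein_a = character(0),
                        protein_b = character(0), domain_a = character(0),
                        domain_b = character(0), weight = numeric(0),
                        n_fwd = integer(0), n_rev = integer(0),
                        stringsAsFactors = FALSE)
  }
  proteins <- count_tab(unlist(lapply(pool, function(s)
    unique(s$proteins))))
  names(proteins) <- c("protein", "weight")
  domains <- count_tab(unlist(lapply(pool, function(s) {
    if (nrow(s$domains)) paste(s$domains$protein, s$domains$domain,
                               sep = "|") else character(0)
  })))
  names(domains) <- c("domain_key", "weight")
  ppis <- count_tab(unlist(lapply(pool, function(s) unique(s$ppis$key))))
  names(ppis) <- c("ppi_key", "weight")
  structure(list(edges = edges, proteins = proteins, domains = domains,
                 ppis = ppis, n_solutions = n, mode = modes),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("Consensus network (%s mode, %d solution%s)\n", x$mode,
              x$n_solutions, if (x$n_solutions == 1L) "" else "s"))
  cat(sprintf("  DDIs: %d  proteins: %d  domains: %d  PPIs: %d\n",
              nrow(x$edges), nrow(x$proteins), nrow(x$domains),
              nrow(x$ppis)))
  if (nrow(x$edges)) {
    cat(sprintf("  DDI weights: %d at 1.0, min %.3g\n",
                sum(x$edges$weight == 1), min(x$edges$weight)))
  }
  invisible(x)
}

#' Compare splice-aware and splice-unaware consensus networks
#'
#' Partitions the union of DDIs into those exclusive to the splice-aware
#' consensus, exclusive to the splice-unaware consensus, and shared, with
#' both weights attached. Unaware-only DDIs with a skipped endpoint domain
#' are flagged `splice_abrogated`: interactions present without splice
#' information that disappear once domain skipping is enforced.
#'
#' @param aware consensus network from a splice-aware run.
#' @param unaware consensus network from a splice-unaware run on the same
#'   prior.
#' @param skips the `domain_skip_table` of the splice-aware run (or `NULL`).
#' @return a `data.frame` with one row per DDI: endpoints, `status`
#'   (`"aware_only"`, `"unaware_only"`, `"shared"`), `weight_aware`,
#'   `weight_unaware`, `endpoint_skipped`, `splice_abrogated`.
#' @export
diff_networks <- function(aware, unaware, skips = NULL) {
  stopifnot(inherits(aware, "consensus_network"),
            inherits(unaware, "consensus_network"))
  a <- aware$edges; u <- unaware$edges
  keys <- sort(union(a$key, u$key))
  if (length(keys) == 0L) {
    return(data.frame(key = character(0), protein_a = character(0),
                      domain_a = character(0), protein_b = character(0),
                      domain_b = character(0), status = character(0),
                      weight_aware = numeric(0), weight_unaware = numeric(0),
                      endpoint_skipped = logical(0),
                      splice_abrogated = logical(0),
                      stringsAsFactors = FALSE))
  }
  sp <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(key = keys,
                    protein_a = vapply(sp, `[`, "", 1L),
                    domain_a = vapply(sp, `[`, "", 2L),
                    protein_b = vapply(sp, `[`, "", 3L),
                    domain_b = vapply(sp, `[`, "", 4L),
                    stringsAsFactors = FALSE)
  out$weight_aware <- a$weight[match(keys, a$key)]
  out$weight_unaware <- u$weight[match(keys, u$key)]
  out$status <- ifelse(is.na(out$weight_aware), "unaware_only",
                       ifelse(is.na(out$weight_unaware), "aware_only",
                              "shared"))
  skipped_keys <- character(0)
  if (!is.null(skips) && nrow(skips)) {
    skipped_keys <- paste(skips$protein, skips$domain, sep = "|")[skips$skipped]
  }
  out$endpoint_skipped <-
    paste(out$protein_a, out$domain_a, sep = "|") %in% skipped_keys |
    paste(out$protein_b, out$domain_b, sep = "|") %in% skipped_keys
  out$splice_abrogated <- out$status == "unaware_only" & out$endpoint_skipped
  rownames(out) <- NULL
  out
}

#' Export a consensus network as TSV edge and node tables
#'
#' @param cons a `consensus_network`.
#' @param edge_path output edge TSV (source/target protein and domain,
#'   weight, splice flag).
#' @param node_path optional node attribute TSV.
#' @param skips optional `domain_skip_table` used to fill the splice flag.
#' @export
write_consensus <- function(cons, edge_path, node_path = NULL, skips = NULL) {
  e <- cons$edges
  skipped_keys <- character(0)
  if (!is.null(skips) && nrow(skips)) {
    skipped_keys <- paste(skips$protein, skips$domain, sep = "|")[skips$skipped]
  }
  tab <- data.frame(source_protein = e$protein_a, source_domain = e$domain_a,
                    target_protein = e$protein_b, target_domain = e$domain_b,
                    weight = e$weight,
                    splice_flag = ifelse(
                      paste(e$protein_a, e$domain_a, sep = "|") %in%
                        skipped_keys |
                        paste(e$protein_b, e$domain_b, sep = "|") %in%
                        skipped_keys, "skipped_endpoint", ""),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(node_path)) {
    utils::write.table(cons$proteins, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(edge_path)
}
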