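#' Solve the network-selection ILP exactly
#'
#' Finds a provably optimal subnetwork for an [build_ilp()] instance. The
#' built-in `"bnb"` backend is an exact depth-first branch-and-bound over
#' the orientation states of the candidate DDIs (absent / forward /
#' reverse), with incremental directed-cycle prevention, per-PPI orientation
#' consistency, and an admissible prize bound (total significant-TF prize
#' minus accumulated cost) for pruning. The empty network is always
#' feasible, so a genuinely infeasible status signals a model bug. Among
#' equal-objective optima (tolerance 1e-12) the solver deterministically
#' returns the lexicographically smallest selected directed-edge set under
#' canonical edge ordering.
#'
#' @param instance an `ilp_instance`.
#' @param backend `"bnb"` (built-in exact solver) or a function
#'   `function(instance, ...)` returning a `solution_network` (the pluggable
#'   backend contract). Naming an unavailable solver raises an error with an
#'   installation hint.
#' @param time_limit wall-clock limit in seconds (default 3600); on timeout
#'   the incumbent is returned with status `"feasible"`.
#' @param exclude list of previously selected directed-edge index sets to
#'   exclude (no-good cuts; used by [enumerate_solutions()]).
#' @param min_distance minimum Hamming distance (in directed edges) required
#'   from every excluded set (default 1 = merely distinct).
#' @return an object of class `solution_network` with the selected proteins,
#'   domains, directed DDIs and PPIs, active roots, reached TFs, objective
#'   value and solver status (`"optimal"`, `"feasible"`, `"infeasible"`).
#' @export
solve_ilp <- function(instance, backend = "bnb", time_limit = 3600,
                      exclude = list(), min_distance = 1L) {
  stopifnot(inherits(instance, "ilp_instance"))
  if (time_limit <= 0) stop_input("time_limit must be > 0")
  if (is.function(backend)) {
    return(backend(instance, time_limit = time_limit, exclude = exclude,
                   min_distance = min_distance))
  }
  if (!identical(backend, "bnb")) {
    stop_input(paste0(
      "solver backend '%s' is not available; the built-in exact backend is ",
      "'bnb', or pass a function implementing the backend contract"),
      backend)
  }
  solve_bnb(instance, time_limit = time_limit, exclude = exclude,
            min_distance = min_distance)
}

# Lexicographic comparison of sorted directed-edge index vectors; shorter
# prefix wins. Used for deterministic tie-breaking.
edge_set_less <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- min(la, lb)
  if (n > 0L) {
    d <- which(a[seq_len(n)] != b[seq_len(n)])
    if (length(d)) return(a[d[1L]] < b[d[1L]])
  }
  la < lb
}

solve_bnb <- function(inst, time_limit = 3600, exclude = list(),
                      min_distance = 1L) {
  ed <- inst$edges
  m <- nrow(ed)
  pr <- inst$proteins
  dm <- inst$domains
  lam <- inst$params$lambda
  bet <- if (inst$mode == "soft") inst$params$beta else 0
  sig_idx <- which(pr$significant & pr$weight > 0)
  w <- pr$weight
  total_w <- sum(w[sig_idx])
  tol <- 1e-12
  t0 <- proc.time()[["elapsed"]]

  n_ppi <- nrow(inst$ppis)
  env <- new.env(parent = emptyenv())
  env$state <- integer(m)            # 0 absent, 1 fwd (p1->p2), 2 rev
  env$ppi_dir <- integer(n_ppi)
  env$ppi_cnt <- integer(n_ppi)
  env$dom_cnt <- integer(nrow(dm))
  env$pro_cnt <- integer(nrow(pr))
  env$in_cnt <- integer(nrow(pr))
  env$dedge_from <- integer(0)       # selected protein-level directed edges
  env$dedge_to <- integer(0)
  env$cost <- 0
  env$nodes <- 0L
  env$timed_out <- FALSE
  env$best_obj <- -Inf
  env$best_ids <- NULL
  env$best_state <- NULL

  excl_sorted <- lapply(exclude, function(e) sort(as.integer(e)))

  # directed protein edge reachability (cycle test): does `from` already
  # reach back from `to` via selected edges?
  reaches <- function(src, dst) {
    if (src == dst) return(TRUE)
    seen <- src
    frontier <- src
    while (length(frontier)) {
      nxt <- env$dedge_to[env$dedge_from %in% frontier]
      nxt <- setdiff(nxt, seen)
      if (dst %in% nxt) return(TRUE)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    FALSE
  }

  try_add <- function(i, dir) {
    ppi <- ed$ppi[i]
    if (env$ppi_cnt[ppi] > 0L && env$ppi_dir[ppi] != dir) return(FALSE)
    from <- if (dir == 1L) ed$prot1[i] else ed$prot2[i]
    to <- if (dir == 1L) ed$prot2[i] else ed$prot1[i]
    new_pedge <- env$ppi_cnt[ppi] == 0L
    if (new_pedge && reaches(to, from)) return(FALSE)
    delta <- lam  # the DDI orientation variable itself
    if (new_pedge) delta <- delta + lam
    for (dd in c(ed$dom1[i], ed$dom2[i])) {
      if (env$dom_cnt[dd] == 0L) {
        delta <- delta + lam + bet * dm$s[dd]
      }
      env$dom_cnt[dd] <- env$dom_cnt[dd] + 1L
    }
    for (pp in unique(c(ed$prot1[i], ed$prot2[i]))) {
      if (env$pro_cnt[pp] == 0L) delta <- delta + lam
      env$pro_cnt[pp] <- env$pro_cnt[pp] + 1L
    }
    if (new_pedge) {
      env$ppi_dir[ppi] <- dir
      env$dedge_from <- c(env$dedge_from, from)
      env$dedge_to <- c(env$dedge_to, to)
      env$in_cnt[to] <- env$in_cnt[to] + 1L
    }
    env$ppi_cnt[ppi] <- env$ppi_cnt[ppi] + 1L
    env$cost <- env$cost + delta
    env$state[i] <- dir
    TRUE
  }

  undo_add <- function(i, dir) {
    ppi <- ed$ppi[i]
    env$ppi_cnt[ppi] <- env$ppi_cnt[ppi] - 1L
    was_last <- env$ppi_cnt[ppi] == 0L
    from <- if (dir == 1L) ed$prot1[i] else ed$prot2[i]
    to <- if (dir == 1L) ed$prot2[i] else ed$prot1[i]
    delta <- lam
    if (was_last) {
      delta <- delta + lam
      env$ppi_dir[ppi] <- 0L
      k <- length(env$dedge_from)
      env$dedge_from <- env$dedge_from[-k]
      env$dedge_to <- env$dedge_to[-k]
      env$in_cnt[to] <- env$in_cnt[to] - 1L
    }
    for (dd in c(ed$dom1[i], ed$dom2[i])) {
      env$dom_cnt[dd] <- env$dom_cnt[dd] - 1L
      if (env$dom_cnt[dd] == 0L) delta <- delta + lam + bet * dm$s[dd]
    }
    for (pp in unique(c(ed$prot1[i], ed$prot2[i]))) {
      env$pro_cnt[pp] <- env$pro_cnt[pp] - 1L
      if (env$pro_cnt[pp] == 0L) delta <- delta + lam
    }
    env$cost <- env$cost - delta
    env$state[i] <- 0L
  }

  # Canonical objective of the current leaf (recomputed from scratch so the
  # reported value does not inherit accumulation error from the bound).
  leaf_objective <- function() {
    reached <- sig_idx[env$in_cnt[sig_idx] > 0L]
    np <- sum(env$pro_cnt > 0L)
    nd <- sum(env$dom_cnt > 0L)
    nu <- sum(env$state > 0L)
    nv <- sum(env$ppi_cnt > 0L)
    pen <- if (bet > 0) bet * sum(dm$s[env$dom_cnt > 0L]) else 0
    sum(w[reached]) - lam * (np + nd + nu + nv) - pen
  }

  leaf <- function() {
    sel <- which(env$state > 0L)
    # feasibility: every selected protein has an incoming edge or is a root
    on_prot <- which(env$pro_cnt > 0L)
    orphan <- on_prot[env$in_cnt[on_prot] == 0L]
    if (any(!pr$candidate_root[orphan])) return(invisible())
    ids <- sort(2L * sel - (env$state[sel] == 1L))
    if (length(excl_sorted)) {
      for (e in excl_sorted) {
        hd <- length(setdiff(ids, e)) + length(setdiff(e, ids))
        if (hd < min_distance) return(invisible())
      }
    }
    obj <- leaf_objective()
    better <- obj > env$best_obj + tol ||
      (abs(obj - env$best_obj) <= tol && !is.null(env$best_ids) &&
         edge_set_less(ids, env$best_ids))
    if (is.infinite(env$best_obj) || better) {
      env$best_obj <- obj
      env$best_ids <- ids
      env$best_state <- env$state
    }
    invisible()
  }

  rec <- function(i) {
    if (env$timed_out) return(invisible())
    env$nodes <- env$nodes + 1L
    if (env$nodes %% 8192L == 0L &&
        proc.time()[["elapsed"]] - t0 > time_limit) {
      env$timed_out <- TRUE
      return(invisible())
    }
    # admissible bound: no future benefit beyond the unreached prizes,
    # future selections only add cost
    if (total_w - env$cost < env$best_obj - 1e-9) return(invisible())
    if (i > m) { leaf(); return(invisible()) }
    rec(i + 1L)                       # edge absent
    for (dir in 1:2) {
      if (try_add(i, dir)) {
        rec(i + 1L)
        undo_add(i, dir)
      }
    }
    invisible()
  }

  rec(1L)

  if (is.null(env$best_ids)) {
    return(make_solution(inst, integer(0), integer(0), status = "infeasible",
                         objective = NA_real_))
  }
  sel <- which(env$best_state > 0L)
  status <- if (env$timed_out) "feasible" else "optimal"
  make_solution(inst, sel, env$best_state[sel], status = status,
                objective = env$best_obj)
}

# Assemble the user-facing solution object from selected edge indices and
# their directions (1 = canonical a->b, 2 = reverse).
make_solution <- function(inst, sel, dirs, status, objective) {
  ed <- inst$edges
  pr <- inst$proteins
  if (length(sel)) {
    from_p <- ifelse(dirs == 1L, ed$protein_a[sel], ed$protein_b[sel])
    to_p <- ifelse(dirs == 1L, ed$protein_b[sel], ed$protein_a[sel])
    ddis <- data.frame(
      key = ed$key[sel],
      from_protein = from_p,
      from_domain = ifelse(dirs == 1L, ed$domain_a[sel], ed$domain_b[sel]),
      to_protein = to_p,
      to_domain = ifelse(dirs == 1L, ed$domain_b[sel], ed$domain_a[sel]),
      ppi_key = ed$ppi_key[sel],
      direction = ifelse(dirs == 1L, "fwd", "rev"),
      stringsAsFactors = FALSE)
    ppis <- unique(data.frame(key = ddis$ppi_key, from = ddis$from_protein,
                              to = ddis$to_protein, stringsAsFactors = FALSE))
    doms <- unique(rbind(
      data.frame(protein = ddis$from_protein, domain = ddis$from_domain,
                 stringsAsFactors = FALSE),
      data.frame(protein = ddis$to_protein, domain = ddis$to_domain,
                 stringsAsFactors = FALSE)))
    doms <- doms[order(doms$protein, doms$domain), , drop = FALSE]
    proteins <- sort(unique(c(ddis$from_protein, ddis$to_protein)))
    has_in <- proteins %in% ppis$to
    roots <- proteins[!has_in]
    reached <- intersect(inst$tfs$tf[inst$tfs$significant], ppis$to)
  } else {
    ddis <- data.frame(key = character(0), from_protein = character(0),
                       from_domain = character(0), to_protein = character(0),
                       to_domain = character(0), ppi_key = character(0),
                       direction = character(0), stringsAsFactors = FALSE)
    ppis <- data.frame(key = character(0), from = character(0),
                       to = character(0), stringsAsFactors = FALSE)
    doms <- data.frame(protein = character(0), domain = character(0),
                       stringsAsFactors = FALSE)
    proteins <- character(0)
    roots <- character(0)
    reached <- character(0)
  }
  rownames(ddis) <- rownames(ppis) <- rownames(doms) <- NULL
  structure(list(
    proteins = proteins, domains = doms, ddis = ddis, ppis = ppis,
    roots = roots, reached_tfs = sort(reached),
    objective = if (length(sel) || status != "infeasible") objective else NA_real_,
    mode = inst$mode, status = status,
    selected_ids = sort(2L * sel - (dirs == 1L))
  ), class = "solution_network")
}

#' @export
print.solution_network <- function(x, ...) {
  cat(sprintf("Inferred subnetwork (%s mode, status %s)\n", x$mode, x$status))
  cat(sprintf("  objective: %s\n",
              if (is.na(x$objective)) "NA" else format(x$objective)))
  cat(sprintf("  proteins: %d  domains: %d  DDIs: %d  PPIs: %d\n",
              length(x$proteins), nrow(x$domains), nrow(x$ddis),
              nrow(x$ppis)))
  if (length(x$reached_tfs)) {
    cat(sprintf("  reached TFs: %s\n", paste(x$reached_tfs, collapse = ", ")))
  }
  if (length(x$roots)) {
    cat(sprintf("  active roots: %s\n", paste(x$roots, collapse = ", ")))
  }
  invisible(x)
}

#' Certify a solution against the model rules
#'
#' Post-solve certification, independent of the solver: checks that (a)
#' every selected DDI's endpoint domains lie on selected proteins, (b) every
#' selected PPI has at least one selected constituent DDI, (c) every
#' selected protein is reachable from an active root through the selected
#' directed PPIs, (d) in hard mode no selected domain is skipped, and (e)
#' the selected directed PPIs are acyclic.
#'
#' @param net the `prior_network` the solution was inferred on.
#' @param skips the `domain_skip_table` used (or `NULL`).
#' @param sol a `solution_network`.
#' @param mode `"hard"` or `"soft"` (defaults to the solution's own mode).
#' @return a character vector of violation descriptions; empty when valid.
#' @export
validate_solution <- function(net, skips, sol, mode = sol$mode) {
  stopifnot(inherits(sol, "solution_network"))
  v <- character(0)
  if (nrow(sol$ddis) == 0L) return(v)
  dk <- function(p, d) paste(p, d, sep = "|")
  dom_keys <- dk(sol$domains$protein, sol$domains$domain)
  bad <- !(dk(sol$ddis$from_protein, sol$ddis$from_domain) %in% dom_keys &
             dk(sol$ddis$to_protein, sol$ddis$to_domain) %in% dom_keys)
  if (any(bad)) v <- c(v, sprintf("ddi_endpoint_not_selected: %s",
                                  sol$ddis$key[bad]))
  if (!all(sol$domains$protein %in% sol$proteins)) {
    v <- c(v, "domain_on_unselected_protein")
  }
  if (!all(sol$ddis$key %in% net$ddis$key)) {
    v <- c(v, "ddi_not_in_prior")
  }
  orphan_ppi <- !sol$ppis$key %in% sol$ddis$ppi_key
  if (any(orphan_ppi)) v <- c(v, sprintf("ppi_without_constituent_ddi: %s",
                                         sol$ppis$key[orphan_ppi]))
  if (mode == "hard" && !is.null(skips) && nrow(skips)) {
    skipped <- dk(skips$protein, skips$domain)[skips$skipped]
    hit <- dom_keys %in% skipped
    if (any(hit)) v <- c(v, sprintf("skipped_domain_selected: %s",
                                    dom_keys[hit]))
  }
  # acyclicity and root-reachability on the directed protein graph
  g <- igraph::graph_from_data_frame(
    sol$ppis[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = sol$proteins))
  if (!igraph::is_dag(g)) v <- c(v, "cycle")
  sources <- sol$proteins[!sol$proteins %in% sol$ppis$to]
  bad_root <- setdiff(sources, net$perturbation_roots)
  if (length(bad_root)) {
    v <- c(v, sprintf("source_not_candidate_root: %s", bad_root))
  }
  roots <- intersect(sources, net$perturbation_roots)
  if (length(roots) == 0L) {
    v <- c(v, "no_active_root")
  } else {
    reach <- unique(unlist(lapply(roots, function(r) {
      names(igraph::subcomponent(g, r, mode = "out"))
    })))
    unreachable <- setdiff(sol$proteins, reach)
    if (length(unreachable)) {
      v <- c(v, sprintf("unreachable_protein: %s", unreachable))
    }
  }
  v
}
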