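#' Exhaustive-enumeration reference solver
#'
#' Brute-force optimum for small [build_ilp()] instances: every assignment
#' of an orientation state (absent / forward / reverse) to every candidate
#' DDI is enumerated on a flat base-3 grid and checked feasible from the
#' model definitions (per-PPI orientation consistency, parent-or-root rule,
#' acyclicity); the best objective is kept. This is an independent code path
#' from [solve_ilp()]'s branch-and-bound and exists to certify it; it is
#' intentionally unoptimized and refuses instances with more than
#' `max_edges` candidate DDIs. Ties are broken by the same rule as the
#' solver (lexicographically smallest selected directed-edge set).
#'
#' @param instance an `ilp_instance`.
#' @param max_edges refusal threshold (default 10).
#' @return a `solution_network` with status `"optimal"`.
#' @export
solve_exhaustive <- function(instance, max_edges = 10L) {
  stopifnot(inherits(instance, "ilp_instance"))
  ed <- instance$edges
  m <- nrow(ed)
  if (m > max_edges) {
    stop_input("instance too large for exhaustive enumeration (%d > %d edges)",
               m, max_edges)
  }
  pr <- instance$proteins
  dm <- instance$domains
  lam <- instance$params$lambda
  bet <- if (instance$mode == "soft") instance$params$beta else 0
  sig <- which(pr$significant & pr$weight > 0)
  w <- pr$weight
  tol <- 1e-12

  best_obj <- -Inf
  best_ids <- NULL
  best_sel <- integer(0)
  best_dirs <- integer(0)

  n_assign <- 3L^m
  st <- integer(m)
  for (code in seq_len(n_assign) - 1L) {
    cc <- code
    for (i in seq_len(max(m, 1L))) {
      if (m == 0L) break
      st[i] <- cc %% 3L
      cc <- cc %/% 3L
    }
    sel <- which(st > 0L)
    dirs <- st[sel]
    feas <- TRUE
    if (length(sel)) {
      # per-PPI orientation consistency
      for (pp in unique(ed$ppi[sel])) {
        if (length(unique(dirs[ed$ppi[sel] == pp])) > 1L) {
          feas <- FALSE
          break
        }
      }
      if (feas) {
        from <- ifelse(dirs == 1L, ed$prot1[sel], ed$prot2[sel])
        to <- ifelse(dirs == 1L, ed$prot2[sel], ed$prot1[sel])
        prots <- unique(c(from, to))
        # parent-or-root
        for (q in prots) {
          if (!q %in% to && !pr$candidate_root[q]) {
            feas <- FALSE
            break
          }
        }
        if (feas) {
          # acyclicity by repeated source removal (Kahn)
          ef <- from; et <- to
          nodes <- prots
          repeat {
            srcs <- nodes[!nodes %in% et]
            if (length(srcs) == 0L) break
            keep <- !ef %in% srcs
            ef <- ef[keep]; et <- et[keep]
            nodes <- nodes[!nodes %in% srcs]
          }
          if (length(nodes) > 0L) feas <- FALSE
        }
        if (feas) {
          reached <- sig[sig %in% to]
          doms <- unique(c(ed$dom1[sel], ed$dom2[sel]))
          doms <- sort(doms)
          nu <- length(sel)
          nv <- length(unique(ed$ppi[sel]))
          pen <- if (bet > 0) bet * sum(dm$s[doms]) else 0
          obj <- sum(w[sort(reached)]) -
            lam * (length(prots) + length(doms) + nu + nv) - pen
        }
      }
    } else {
      obj <- 0
    }
    if (!feas) next
    ids <- sort(2L * sel - (dirs == 1L))
    better <- obj > best_obj + tol ||
      (abs(obj - best_obj) <= tol && !is.null(best_ids) &&
         edge_set_less(ids, best_ids))
    if (is.infinite(best_obj) || better) {
      best_obj <- obj
      best_ids <- ids
      best_sel <- sel
      best_dirs <- dirs
    }
  }
  make_solution(instance, best_sel, best_dirs, status = "optimal",
                objective = best_obj)
}
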