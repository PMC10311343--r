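#' Build the network-selection integer linear program
#'
#' Assembles the ILP instance that selects a connected, splice-consistent
#' subnetwork of the prior reaching significantly active TFs at minimal
#' cost. Every protein, (protein, domain) pair, directed DDI orientation,
#' directed PPI orientation, perturbation root link and reached-TF terminal
#' gets a binary variable; integer depth variables encode acyclic
#' reachability from the perturbation roots.
#'
#' The objective (maximized) is
#' \deqn{\sum_{T \in sig} w_T t_T - \alpha \sum_{T \notin sig} t_T
#'   - \lambda (\sum y + \sum z + \sum u + \sum v)
#'   - \beta \sum_{(P,m)} s_{P,m} z_{P,m} \ [soft\ mode\ only]}
#' with TF prizes \eqn{w_T} = |activity score|, a size regularization
#' \eqn{\lambda}, and (soft mode) per-domain skip penalties
#' \eqn{s_{P,m} = -\log_{10}(aggregated\ p)} capped at 300, applied to
#' domains whose splice evidence points in the exclusion direction
#' (negative mean effect). The constraints realize: a domain implies its
#' protein; a DDI implies both endpoint domains; a PPI is selected iff at
#' least one constituent DDI is, in the same orientation; at most one
#' orientation per edge; every selected protein has a selected incoming
#' directed PPI or an active root link; depth variables forbid directed
#' cycles; a TF terminal requires the TF protein with an incoming PPI. In
#' hard mode the domain variables of skipped domains are fixed to zero, so
#' any DDI with a skipped endpoint is infeasible; in soft mode that
#' constraint is dropped and the penalty term is active instead.
#'
#' @param net a `prior_network` with the perturbation attached.
#' @param tf_table a `tf_activity_table`; only TFs present as proteins of the
#'   prior enter the model.
#' @param skips a `domain_skip_table` (or `NULL` for a splice-unaware model).
#' @param mode `"hard"` or `"soft"`.
#' @param lambda size regularization weight (default 0.01).
#' @param alpha penalty for reaching a non-significant TF terminal; default
#'   half the median prize of the significant TFs (0.1 when none).
#' @param beta soft-mode skip penalty scale; default `lambda`.
#' @param p_threshold skip-call threshold recorded with the instance.
#' @param soft_p_cut soft mode only: domains with aggregated p-value above
#'   this cut receive no penalty (default 1, i.e. penalize all
#'   exclusion-direction evidence in proportion to its significance).
#' @return an object of class `ilp_instance`.
#' @export
build_ilp <- function(net, tf_table, skips = NULL,
                      mode = c("hard", "soft"),
                      lambda = 0.01, alpha = NULL, beta = NULL,
                      p_threshold = 0.05, soft_p_cut = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "prior_network"))
  if (length(net$perturbation_roots) == 0L) {
    stop_input("no perturbation roots: call attach_perturbation() first")
  }
  if (lambda < 0) stop_input("lambda must be >= 0")
  if (!is.null(alpha) && alpha < 0) stop_input("alpha must be >= 0")
  if (is.null(skips)) skips <- empty_skip_table()

  tfs <- tf_table[tf_table$tf %in% net$proteins, , drop = FALSE]
  if (nrow(tfs) == 0L) stop_input("no regulon TF is present in the prior")
  if (is.null(alpha)) {
    sw <- tfs$weight[tfs$significant]
    alpha <- if (length(sw)) 0.5 * stats::median(sw) else 0.1
  }
  if (is.null(beta)) beta <- lambda
  if (beta < 0) stop_input("beta must be >= 0")

  proteins <- data.frame(name = net$proteins, stringsAsFactors = FALSE)
  proteins$candidate_root <- proteins$name %in% net$perturbation_roots
  proteins$is_tf <- proteins$name %in% tfs$tf
  proteins$significant <- FALSE
  proteins$weight <- 0
  mt <- match(tfs$tf, proteins$name)
  proteins$significant[mt] <- tfs$significant
  proteins$weight[mt] <- tfs$weight

  doms <- net$domains
  doms$key <- paste(doms$protein, doms$domain, sep = "|")
  doms$prot_idx <- match(doms$protein, proteins$name)
  sk <- as.data.frame(skips)
  skey <- if (nrow(sk)) paste(sk$protein, sk$domain, sep = "|") else character(0)
  mi <- match(doms$key, skey)
  doms$aggregated_p <- ifelse(is.na(mi), NA_real_, sk$aggregated_p[mi])
  doms$mean_eff <- ifelse(is.na(mi), NA_real_, sk$mean_effect[mi])
  doms$skipped <- !is.na(mi) & sk$skipped[mi]
  doms$penalized <- mode == "soft" & !is.na(mi) &
    doms$mean_eff < 0 & doms$aggregated_p <= soft_p_cut
  doms$s <- ifelse(doms$penalized, pmin(-log10(doms$aggregated_p), 300), 0)

  ed <- net$ddis[!net$ddis$self_interaction, , drop = FALSE]
  blocked <- character(0)
  if (mode == "hard" && any(doms$skipped)) {
    skipped_keys <- doms$key[doms$skipped]
    blk <- paste(ed$protein_a, ed$domain_a, sep = "|") %in% skipped_keys |
      paste(ed$protein_b, ed$domain_b, sep = "|") %in% skipped_keys
    blocked <- ed$key[blk]
    ed <- ed[!blk, , drop = FALSE]
  }
  edges <- data.frame(
    key = ed$key,
    protein_a = ed$protein_a, domain_a = ed$domain_a,
    protein_b = ed$protein_b, domain_b = ed$domain_b,
    ppi_key = ed$ppi,
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$key), , drop = FALSE]
  rownames(edges) <- NULL
  edges$prot1 <- match(edges$protein_a, proteins$name)
  edges$prot2 <- match(edges$protein_b, proteins$name)
  edges$dom1 <- match(paste(edges$protein_a, edges$domain_a, sep = "|"),
                      doms$key)
  edges$dom2 <- match(paste(edges$protein_b, edges$domain_b, sep = "|"),
                      doms$key)
  ppi_keys <- sort(unique(edges$ppi_key))
  edges$ppi <- match(edges$ppi_key, ppi_keys)
  ppis <- data.frame(key = ppi_keys, stringsAsFactors = FALSE)
  if (nrow(ppis)) {
    sp <- strsplit(ppis$key, "|", fixed = TRUE)
    ppis$protein_a <- vapply(sp, `[`, "", 1L)
    ppis$protein_b <- vapply(sp, `[`, "", 2L)
    ppis$prot1 <- match(ppis$protein_a, proteins$name)
    ppis$prot2 <- match(ppis$protein_b, proteins$name)
  }

  structure(list(
    proteins = proteins, domains = doms, edges = edges, ppis = ppis,
    tfs = tfs, blocked_ddis = blocked, mode = mode,
    params = list(lambda = lambda, alpha = alpha, beta = beta,
                  p_threshold = p_threshold, soft_p_cut = soft_p_cut),
    net = net
  ), class = "ilp_instance")
}

#' @export
print.ilp_instance <- function(x, ...) {
  cat(sprintf("Network-selection ILP (%s mode)\n", x$mode))
  cat(sprintf("  proteins: %d  domains: %d  candidate DDIs: %d  PPIs: %d\n",
              nrow(x$proteins), nrow(x$domains), nrow(x$edges), nrow(x$ppis)))
  cat(sprintf("  TFs in prior: %d (%d significant)  roots: %d\n",
              nrow(x$tfs), sum(x$tfs$significant),
              sum(x$proteins$candidate_root)))
  if (length(x$blocked_ddis)) {
    cat(sprintf("  DDIs blocked by skipped domains: %d\n",
                length(x$blocked_ddis)))
  }
  cat(sprintf("  lambda = %g, alpha = %g, beta = %g\n",
              x$params$lambda, x$params$alpha, x$params$beta))
  invisible(x)
}

# Explicit variable/constraint system used by the LP and MPS exporters.
# Variable names: y_<P>, z_<P>.<m>, u<i>f/u<i>r (directed DDI), vf_<ppi>/
# vr_<ppi>, r_<P>, t_<T>, d_<P> (integer depth).
build_constraint_system <- function(inst) {
  pr <- inst$proteins; dm <- inst$domains; ed <- inst$edges; pp <- inst$ppis
  N <- nrow(pr)
  lam <- inst$params$lambda; alp <- inst$params$alpha; bet <- inst$params$beta

  nm_y <- paste0("y_", seq_len(N))
  nm_z <- paste0("z_", seq_len(nrow(dm)))
  nm_u <- if (nrow(ed)) c(rbind(paste0("uf_", seq_len(nrow(ed))),
                                paste0("ur_", seq_len(nrow(ed))))) else character(0)
  nm_v <- if (nrow(pp)) c(rbind(paste0("vf_", seq_len(nrow(pp))),
                                paste0("vr_", seq_len(nrow(pp))))) else character(0)
  roots <- which(pr$candidate_root)
  nm_r <- paste0("r_", roots)
  tf_idx <- match(inst$tfs$tf, pr$name)
  nm_t <- paste0("t_", tf_idx)
  nm_d <- paste0("d_", seq_len(N))

  obj <- c(stats::setNames(rep(-lam, N), nm_y),
           stats::setNames(rep(-lam, nrow(dm)) -
                             (if (inst$mode == "soft") bet * dm$s else 0),
                           nm_z),
           stats::setNames(rep(-lam, length(nm_u)), nm_u),
           stats::setNames(rep(-lam, length(nm_v)), nm_v),
           stats::setNames(rep(0, length(nm_r)), nm_r),
           stats::setNames(ifelse(inst$tfs$significant, inst$tfs$weight, -alp),
                           nm_t),
           stats::setNames(rep(0, N), nm_d))
  vars <- data.frame(name = names(obj), obj = unname(obj),
                     type = c(rep("B", N + nrow(dm) + length(nm_u) +
                                    length(nm_v) + length(nm_r) +
                                    length(nm_t)),
                              rep("I", N)),
                     lb = 0,
                     ub = c(rep(1, length(obj) - N), rep(N, N)),
                     stringsAsFactors = FALSE)

  cons <- list()
  add <- function(coef, sense, rhs, name) {
    cons[[length(cons) + 1L]] <<- list(coef = coef, sense = sense, rhs = rhs,
                                       name = name)
  }
  # C1 domain implies protein
  for (i in seq_len(nrow(dm))) {
    add(stats::setNames(c(1, -1), c(nm_z[i], nm_y[dm$prot_idx[i]])),
        "<=", 0, sprintf("C1_%d", i))
  }
  # C2 DDI implies its endpoint domains; C4 orientation exclusivity (u)
  for (i in seq_len(nrow(ed))) {
    for (d in c("f", "r")) {
      uv <- sprintf("u%s_%d", d, i)
      add(stats::setNames(c(1, -1), c(uv, nm_z[ed$dom1[i]])), "<=", 0,
          sprintf("C2a_%d%s", i, d))
      add(stats::setNames(c(1, -1), c(uv, nm_z[ed$dom2[i]])), "<=", 0,
          sprintf("C2b_%d%s", i, d))
      # orientation alignment with the parent PPI
      add(stats::setNames(c(1, -1), c(uv, sprintf("v%s_%d", d, ed$ppi[i]))),
          "<=", 0, sprintf("C3u_%d%s", i, d))
    }
    add(stats::setNames(c(1, 1), c(sprintf("uf_%d", i), sprintf("ur_%d", i))),
        "<=", 1, sprintf("C4u_%d", i))
  }
  # C3 PPI iff some constituent DDI (same orientation); C4 (v)
  for (j in seq_len(nrow(pp))) {
    members <- which(ed$ppi == j)
    for (d in c("f", "r")) {
      add(stats::setNames(c(1, rep(-1, length(members))),
                          c(sprintf("v%s_%d", d, j),
                            sprintf("u%s_%d", d, members))),
          "<=", 0, sprintf("C3v_%d%s", j, d))
    }
    add(stats::setNames(c(1, 1), c(sprintf("vf_%d", j), sprintf("vr_%d", j))),
        "<=", 1, sprintf("C4v_%d", j))
  }
  # C5 parent-or-root and depth-based acyclicity
  for (q in seq_len(N)) {
    inc_f <- which(pp$prot2 == q)   # vf: prot1 -> prot2
    inc_r <- which(pp$prot1 == q)   # vr: prot2 -> prot1
    coef <- stats::setNames(1, nm_y[q])
    if (length(inc_f)) coef <- c(coef, stats::setNames(rep(-1, length(inc_f)),
                                                       sprintf("vf_%d", inc_f)))
    if (length(inc_r)) coef <- c(coef, stats::setNames(rep(-1, length(inc_r)),
                                                       sprintf("vr_%d", inc_r)))
    if (pr$candidate_root[q]) coef <- c(coef, stats::setNames(-1,
                                                              paste0("r_", q)))
    add(coef, "<=", 0, sprintf("C5p_%d", q))
  }
  for (ri in roots) {
    # depth_root = 0 when the root link is active: d_P <= N (1 - r_P)
    add(stats::setNames(c(1, N), c(nm_d[ri], paste0("r_", ri))), "<=", N,
        sprintf("C5r_%d", ri))
  }
  for (j in seq_len(nrow(pp))) {
    p1 <- pp$prot1[j]; p2 <- pp$prot2[j]
    add(stats::setNames(c(-1, 1, N), c(nm_d[p2], nm_d[p1],
                                       sprintf("vf_%d", j))),
        "<=", N - 1, sprintf("C5d_%df", j))
    add(stats::setNames(c(-1, 1, N), c(nm_d[p1], nm_d[p2],
                                       sprintf("vr_%d", j))),
        "<=", N - 1, sprintf("C5d_%dr", j))
  }
  # C6 TF terminal requires the protein and an incoming PPI
  for (k in seq_len(nrow(inst$tfs))) {
    q <- tf_idx[k]
    add(stats::setNames(c(1, -1), c(nm_t[k], nm_y[q])), "<=", 0,
        sprintf("C6a_%d", k))
    inc_f <- which(pp$prot2 == q); inc_r <- which(pp$prot1 == q)
    coef <- stats::setNames(1, nm_t[k])
    if (length(inc_f)) coef <- c(coef, stats::setNames(rep(-1, length(inc_f)),
                                                       sprintf("vf_%d", inc_f)))
    if (length(inc_r)) coef <- c(coef, stats::setNames(rep(-1, length(inc_r)),
                                                       sprintf("vr_%d", inc_r)))
    add(coef, "<=", 0, sprintf("C6b_%d", k))
  }
  # C7 hard mode: skipped domains fixed to zero (their DDIs are already
  # dropped from the candidate edges; the variable fix keeps the exported
  # program faithful)
  if (inst$mode == "hard") {
    for (i in which(inst$domains$skipped)) {
      add(stats::setNames(1, nm_z[i]), "<=", 0, sprintf("C7_%d", i))
    }
  }
  list(vars = vars, cons = cons)
}

#' Export an ILP instance in CPLEX LP format
#' @param instance an `ilp_instance`.
#' @param path output `.lp` file path.
#' @export
export_lp <- function(instance, path) {
  sys <- build_constraint_system(instance)
  term <- function(coef) {
    paste(sprintf("%+.12g %s", unname(coef), names(coef)), collapse = " ")
  }
  nz <- sys$vars$obj != 0
  obj_coef <- stats::setNames(sys$vars$obj[nz], sys$vars$name[nz])
  lines <- c("Maximize", paste(" obj:", term(obj_coef)), "Subject To")
  for (cn in sys$cons) {
    lines <- c(lines, sprintf(" %s: %s %s %.12g", cn$name, term(cn$coef),
                              if (cn$sense == "<=") "<=" else ">=", cn$rhs))
  }
  ints <- sys$vars$name[sys$vars$type == "I"]
  bins <- sys$vars$name[sys$vars$type == "B"]
  lines <- c(lines, "Bounds",
             sprintf(" 0 <= %s <= %g", ints,
                     sys$vars$ub[sys$vars$type == "I"]),
             "Binaries", paste("", paste(bins, collapse = " ")),
             "Generals", paste("", paste(ints, collapse = " ")), "End")
  writeLines(lines, path)
  invisible(path)
}

#' Export an ILP instance in fixed MPS format
#' @param instance an `ilp_instance`.
#' @param path output `.mps` file path.
#' @export
export_mps <- function(instance, path) {
  sys <- build_constraint_system(instance)
  lines <- c("NAME          NETSEL", "ROWS", " N  COST")
  for (cn in sys$cons) {
    lines <- c(lines, sprintf(" L  %s", cn$name))
  }
  lines <- c(lines, "COLUMNS",
             "    MARKER                 'MARKER'                 'INTORG'")
  col_entries <- lapply(sys$cons, function(cn) {
    data.frame(var = names(cn$coef), row = cn$name, val = unname(cn$coef),
               stringsAsFactors = FALSE)
  })
  col_df <- do.call(rbind, col_entries)
  for (v in sys$vars$name) {
    if (sys$vars$obj[sys$vars$name == v] != 0) {
      lines <- c(lines, sprintf("    %-10s%-10s%.12g", v, "COST",
                                # MPS minimizes; negate for maximization
                                -sys$vars$obj[sys$vars$name == v]))
    }
    rows <- col_df[col_df$var == v, , drop = FALSE]
    if (nrow(rows)) {
      lines <- c(lines, sprintf("    %-10s%-10s%.12g", v, rows$row, rows$val))
    }
  }
  lines <- c(lines,
             "    MARKER                 'MARKER'                 'INTEND'",
             "RHS")
  for (cn in sys$cons) {
    if (cn$rhs != 0) {
      lines <- c(lines, sprintf("    RHS       %-10s%.12g", cn$name, cn$rhs))
    }
  }
  lines <- c(lines, "BOUNDS")
  for (i in seq_len(nrow(sys$vars))) {
    lines <- c(lines, sprintf(" UP BND       %-10s%.12g", sys$vars$name[i],
                              sys$vars$ub[i]))
  }
  lines <- c(lines, "ENDATA")
  writeLines(lines, path)
  invisible(path)
}
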