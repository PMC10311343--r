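#' Read a domain-resolved interaction table
#'
#' Parses a delimited export of a domain-centric interaction resource into a
#' validated set of undirected domain-domain interaction (DDI) records. Each
#' row links a Pfam domain on one protein to a Pfam domain on another protein,
#' optionally annotated with the Ensembl exon and transcript identifiers that
#' map into each domain. Duplicate DDIs (after canonical endpoint ordering)
#' are collapsed with merged exon/transcript lists.
#'
#' @param path path to a delimited text file with one DDI per row.
#' @param dialect optional named character vector remapping the canonical
#'   column names (`protein_a`, `domain_a`, `protein_b`, `domain_b`,
#'   `exons_a`, `exons_b`, `transcripts_a`, `transcripts_b`, `direction`) to
#'   the names actually present in the file, e.g.
#'   `c(protein_a = "GeneA", domain_a = "PfamA", ...)`.
#' @param sep field separator of the file (default tab).
#' @param list_sep separator used inside exon/transcript list cells
#'   (default `";"`).
#' @return a `data.frame` of class `interaction_records` with character
#'   columns `protein_a`, `domain_a`, `protein_b`, `domain_b`, `exons_a`,
#'   `exons_b`, `transcripts_a`, `transcripts_b`, `direction` (list cells
#'   `list_sep`-joined; `direction` is `"ab"`, `"ba"` or `""`).
#' @details Rows with an empty or missing protein or domain identifier are
#'   dropped with a warning reporting the count. The optional `direction`
#'   column carries a directed annotation used only for automatic root
#'   designation (see [attach_perturbation()]); conflicting annotations on
#'   merged duplicates are cleared.
#' @seealso [build_network()], [write_interaction_table()]
#' @export
read_interaction_table <- function(path, dialect = NULL, sep = "\t",
                                   list_sep = ";") {
  if (!file.exists(path)) stop_input("interaction table not found: %s", path)
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop_input("interaction table is empty: %s", path)
  canon <- c("protein_a", "domain_a", "protein_b", "domain_b",
             "exons_a", "exons_b", "transcripts_a", "transcripts_b",
             "direction")
  cols <- stats::setNames(canon, canon)
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  required <- canon[1:4]
  missing <- required[!cols[required] %in% names(df)]
  if (length(missing)) {
    stop_input("missing required column(s): %s (looked for '%s')",
               paste(missing, collapse = ", "),
               paste(cols[missing], collapse = "', '"))
  }
  out <- data.frame(matrix("", nrow(df), length(canon)),
                    stringsAsFactors = FALSE)
  names(out) <- canon
  for (cc in canon) {
    if (cols[[cc]] %in% names(df)) {
      v <- trimws(df[[cols[[cc]]]])
      v[is.na(v)] <- ""
      out[[cc]] <- v
    }
  }
  as_interaction_records(out, list_sep = list_sep)
}

# Validate, canonicalize and deduplicate raw record rows.
as_interaction_records <- function(out, list_sep = ";") {
  bad <- !nzchar(out$protein_a) | !nzchar(out$domain_a) |
    !nzchar(out$protein_b) | !nzchar(out$domain_b)
  pert <- !bad & (out$protein_a == PERTURBATION_NODE |
                    out$protein_b == PERTURBATION_NODE)
  if (any(pert)) {
    warning(sprintf(
      "%d row(s) use the reserved node name '%s' and were dropped",
      sum(pert), PERTURBATION_NODE), call. = FALSE)
  }
  if (any(bad)) {
    warning(sprintf("%d malformed row(s) with empty identifiers dropped",
                    sum(bad)), call. = FALSE)
  }
  out <- out[!bad & !pert, , drop = FALSE]
  if (nrow(out) == 0L) stop_input("no valid interaction rows remain")

  swap <- needs_swap(out$protein_a, out$domain_a, out$protein_b, out$domain_b)
  if (any(swap)) {
    tmp <- out[swap, ]
    out[swap, c("protein_a", "domain_a", "protein_b", "domain_b",
                "exons_a", "exons_b", "transcripts_a", "transcripts_b")] <-
      tmp[, c("protein_b", "domain_b", "protein_a", "domain_a",
              "exons_b", "exons_a", "transcripts_b", "transcripts_a")]
    dirs <- out$direction[swap]
    out$direction[swap] <- ifelse(dirs == "ab", "ba",
                                  ifelse(dirs == "ba", "ab", dirs))
  }
  out$direction[!out$direction %in% c("ab", "ba")] <- ""

  key <- ddi_key(out$protein_a, out$domain_a, out$protein_b, out$domain_b)
  if (anyDuplicated(key)) {
    pieces <- split(seq_len(nrow(out)), key)
    rows <- lapply(pieces, function(idx) {
      r <- out[idx[1L], , drop = FALSE]
      for (cc in c("exons_a", "exons_b", "transcripts_a", "transcripts_b")) {
        feats <- unlist(lapply(out[[cc]][idx], split_list_cell, sep = list_sep))
        r[[cc]] <- join_list_cell(feats, sep = list_sep)
      }
      d <- unique(out$direction[idx][nzchar(out$direction[idx])])
      r$direction <- if (length(d) == 1L) d else ""
      r
    })
    out <- do.call(rbind, rows)
  }
  out <- out[order(ddi_key(out$protein_a, out$domain_a,
                           out$protein_b, out$domain_b)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "list_sep") <- list_sep
  class(out) <- c("interaction_records", "data.frame")
  out
}

#' Write interaction records back to a delimited file
#'
#' Inverse of [read_interaction_table()]: re-reading the written file yields
#' the same records after canonical ordering.
#'
#' @param records an `interaction_records` data frame.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @export
write_interaction_table <- function(records, path, sep = "\t") {
  utils::write.table(as.data.frame(records), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a domain-resolved prior network
#'
#' Projects validated DDI records into the prior-network container used by
#' the inference step: proteins, (protein, Pfam) domains, undirected DDIs,
#' and protein-protein interactions (PPIs) as the protein-pair projection of
#' the DDIs, each PPI linked to its constituent DDIs. Exon/transcript to
#' domain mappings are collected for splice-evidence matching.
#'
#' Self-interacting DDIs (both domains on one protein) are retained and
#' flagged, but excluded from path search: they cannot mediate regulation
#' between distinct proteins.
#'
#' @param records an `interaction_records` data frame
#'   (see [read_interaction_table()]).
#' @return an object of class `prior_network`.
#' @export
build_network <- function(records) {
  if (!inherits(records, "interaction_records")) {
    records <- as_interaction_records(as.data.frame(records,
                                                    stringsAsFactors = FALSE))
  }
  if (nrow(records) == 0L) stop_input("no interaction records")
  list_sep <- attr(records, "list_sep") %||% ";"

  proteins <- sort(unique(c(records$protein_a, records$protein_b)))
  dom_df <- unique(rbind(
    data.frame(protein = records$protein_a, domain = records$domain_a,
               stringsAsFactors = FALSE),
    data.frame(protein = records$protein_b, domain = records$domain_b,
               stringsAsFactors = FALSE)))
  dom_df <- dom_df[order(dom_df$protein, dom_df$domain), , drop = FALSE]
  rownames(dom_df) <- NULL

  ddis <- data.frame(
    protein_a = records$protein_a, domain_a = records$domain_a,
    protein_b = records$protein_b, domain_b = records$domain_b,
    stringsAsFactors = FALSE)
  ddis$key <- ddi_key(ddis$protein_a, ddis$domain_a,
                      ddis$protein_b, ddis$domain_b)
  ddis$self_interaction <- ddis$protein_a == ddis$protein_b
  ddis$ppi <- ppi_key(ddis$protein_a, ddis$protein_b)

  ppis <- unique(data.frame(protein_a = ddis$protein_a,
                            protein_b = ddis$protein_b,
                            key = ddis$ppi,
                            self_interaction = ddis$self_interaction,
                            stringsAsFactors = FALSE))
  ppis <- ppis[order(ppis$key), , drop = FALSE]
  rownames(ppis) <- NULL

  feat <- list()
  for (side in c("a", "b")) {
    p <- records[[paste0("protein_", side)]]
    d <- records[[paste0("domain_", side)]]
    for (kind in c("exon", "transcript")) {
      cc <- paste0(if (kind == "exon") "exons_" else "transcripts_", side)
      lst <- lapply(records[[cc]], split_list_cell, sep = list_sep)
      n <- lengths(lst)
      if (sum(n) == 0L) next
      feat[[paste(side, kind)]] <- data.frame(
        protein = rep(p, n), domain = rep(d, n),
        feature_id = unlist(lst), feature_kind = kind,
        stringsAsFactors = FALSE)
    }
  }
  domain_features <- if (length(feat)) unique(do.call(rbind, feat)) else
    data.frame(protein = character(0), domain = character(0),
               feature_id = character(0), feature_kind = character(0),
               stringsAsFactors = FALSE)
  rownames(domain_features) <- NULL

  hints <- records[nzchar(records$direction),
                   c("protein_a", "protein_b", "direction")]
  directed_hints <- unique(data.frame(
    from = ifelse(hints$direction == "ab", hints$protein_a, hints$protein_b),
    to   = ifelse(hints$direction == "ab", hints$protein_b, hints$protein_a),
    stringsAsFactors = FALSE))

  structure(list(
    proteins = proteins,
    domains = dom_df,
    ddis = ddis,
    ppis = ppis,
    domain_features = domain_features,
    directed_hints = directed_hints,
    perturbation_roots = character(0),
    records = records
  ), class = "prior_network")
}

#' Attach the auxiliary perturbation root node
#'
#' Adds the auxiliary `PERTURBATION` node and designates the proteins it
#' connects to (the candidate roots of all inferred paths). Root links are
#' directed, protein-level only, and carry no domain or DDI.
#'
#' When `roots` is omitted, roots are auto-designated: if the table carried
#' directed annotations, every protein with zero incoming annotated edges
#' becomes a root; on a fully undirected prior the fallback makes every
#' non-TF protein a candidate root and leaves the choice to the inference
#' step's size regularization.
#'
#' @param net a `prior_network`.
#' @param roots optional explicit character vector of root proteins.
#' @param tfs optional character vector of TF gene symbols, used only by the
#'   undirected fallback rule to exclude TFs from candidacy.
#' @return the network with `perturbation_roots` filled in.
#' @export
attach_perturbation <- function(net, roots = NULL, tfs = NULL) {
  stopifnot(inherits(net, "prior_network"))
  if (!is.null(roots)) {
    unknown <- setdiff(roots, net$proteins)
    if (length(unknown)) {
      stop_input("explicit root(s) not in network: %s",
                 paste(unknown, collapse = ", "))
    }
    net$perturbation_roots <- sort(unique(roots))
    return(net)
  }
  if (nrow(net$directed_hints) > 0L) {
    has_incoming <- net$proteins %in% net$directed_hints$to
    net$perturbation_roots <- net$proteins[!has_incoming]
  } else {
    net$perturbation_roots <- setdiff(net$proteins, tfs %||% character(0))
  }
  net
}

#' @export
print.prior_network <- function(x, ...) {
  cat("Domain-resolved prior network\n")
  cat(sprintf("  proteins: %d   domains: %d\n",
              length(x$proteins), nrow(x$domains)))
  cat(sprintf("  DDIs: %d (%d self-interacting)   PPIs: %d\n",
              nrow(x$ddis), sum(x$ddis$self_interaction), nrow(x$ppis)))
  cat(sprintf("  exon/transcript mappings: %d\n", nrow(x$domain_features)))
  if (length(x$perturbation_roots)) {
    cat(sprintf("  perturbation roots: %s\n",
                paste(utils::head(x$perturbation_roots, 6), collapse = ", ")))
  } else {
    cat("  perturbation node not attached\n")
  }
  invisible(x)
}

#' Export a network as SIF-like edge and node attribute tables
#'
#' Writes two TSVs: an edge list with columns `source`, `interaction_type`
#' (`ddi`, `ppi` or `perturbation`) and `target`, and a node attribute table.
#' Domain-level nodes are written as `protein:domain`. The perturbation node
#' has out-links only.
#'
#' @param net a `prior_network` (with the perturbation attached if root links
#'   should be exported).
#' @param edge_path,node_path output file paths.
#' @export
export_sif <- function(net, edge_path, node_path) {
  stopifnot(inherits(net, "prior_network"))
  edges <- rbind(
    if (length(net$perturbation_roots)) data.frame(
      source = PERTURBATION_NODE, interaction_type = "perturbation",
      target = net$perturbation_roots, stringsAsFactors = FALSE),
    data.frame(source = net$ppis$protein_a, interaction_type = "ppi",
               target = net$ppis$protein_b, stringsAsFactors = FALSE),
    data.frame(source = paste(net$ddis$protein_a, net$ddis$domain_a, sep = ":"),
               interaction_type = "ddi",
               target = paste(net$ddis$protein_b, net$ddis$domain_b, sep = ":"),
               stringsAsFactors = FALSE))
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- rbind(
    data.frame(node = PERTURBATION_NODE, type = "perturbation",
               stringsAsFactors = FALSE),
    data.frame(node = net$proteins, type = "protein",
               stringsAsFactors = FALSE),
    data.frame(node = paste(net$domains$protein, net$domains$domain, sep = ":"),
               type = "domain", stringsAsFactors = FALSE))
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edge_path)
}
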