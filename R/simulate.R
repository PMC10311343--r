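#' Generate a seeded synthetic inference scenario
#'
#' Builds a complete, self-consistent synthetic input bundle with planted
#' ground truth: a layered, root-identifiable prior (a guaranteed
#' perturbation-to-TF chain plus dead-end decoy proteins and optional random
#' decoy-decoy edges), a regulon per TF whose targets receive strongly
#' signed differential statistics (so the TF scores significant under the
#' permutation null), and exon-level splice evidence planting skipped
#' domains on the chain. With the default single planted skip on the TF-side
#' domain of the final chain edge, the unique perturbation-to-TF path is
#' intact in a splice-unaware analysis and abrogated in hard-constrained
#' splice-aware analysis — the miniature rewiring phenomenon the test suite
#' and acceptance checks recover.
#'
#' The generator produces summary statistics (dPSI, logFC, p-values), which
#' is the pipeline's actual input level; it does not emulate read-level
#' RNA-seq data.
#'
#' @param n_proteins total number of proteins (>= 3; default 8).
#' @param n_domains_per_protein domains per protein (default 2).
#' @param edge_density probability of an extra decoy-decoy DDI (default
#'   0.25).
#' @param n_tfs number of TFs (default 1).
#' @param n_skipped number of planted skipped domains, placed on the chain
#'   starting from the TF side (default 1; 0 plants none).
#' @param n_targets_per_tf regulon size (default 20).
#' @param n_background_genes expression-only background genes (default 200).
#' @param noise_evidence also emit weak, non-significant splice evidence on
#'   decoy domains (default `TRUE`).
#' @param seed RNG seed; identical seeds reproduce identical scenarios.
#' @return an object of class `splice_scenario` with elements `records`,
#'   `regulons`, `gene_stats`, `evidence`, `gene_sets`, `roots`, `tfs`,
#'   `ground_truth`, `params`, `seed`.
#' @export
generate_scenario <- function(n_proteins = 8, n_domains_per_protein = 2,
                              edge_density = 0.25, n_tfs = 1, n_skipped = 1,
                              n_targets_per_tf = 20,
                              n_background_genes = 200,
                              noise_evidence = TRUE, seed = 1) {
  if (n_proteins < 3) stop_input("need at least 3 proteins")
  if (min(n_domains_per_protein, edge_density, n_tfs,
          n_targets_per_tf, n_background_genes) < 0 || n_tfs < 1) {
    stop_input("scenario parameters must be positive")
  }
  L <- min(4L, n_proteins - (n_tfs - 1L))
  if (L < 3L) stop_input("unsatisfiable: too many TFs for %d proteins",
                         n_proteins)
  n_decoys <- n_proteins - (L - 1L) - n_tfs
  chain <- sprintf("P%02d", seq_len(L - 1L))
  tfs <- sprintf("TF%d", seq_len(n_tfs))
  decoys <- if (n_decoys > 0) sprintf("D%02d", seq_len(n_decoys)) else
    character(0)
  prots <- c(chain, tfs, decoys)
  pidx <- stats::setNames(seq_along(prots), prots)

  dom_id <- function(p, slot) sprintf("PF%05d", pidx[[p]] * 10L + slot)
  exon_ids <- function(p, slot) {
    sprintf("ENSE%011d", pidx[[p]] * 1000L + slot * 10L + 1:2)
  }
  tx_id <- function(p, slot) sprintf("ENST%011d", pidx[[p]] * 1000L + slot)
  slot2 <- min(2L, n_domains_per_protein)

  mk_row <- function(pa, sa, pb, sb) {
    data.frame(protein_a = pa, domain_a = dom_id(pa, sa),
               protein_b = pb, domain_b = dom_id(pb, sb),
               exons_a = paste(exon_ids(pa, sa), collapse = ";"),
               exons_b = paste(exon_ids(pb, sb), collapse = ";"),
               transcripts_a = tx_id(pa, sa), transcripts_b = tx_id(pb, sb),
               direction = "ab", stringsAsFactors = FALSE)
  }

  with_seed(seed, {
    rows <- list()
    path <- c(chain, tfs[1L])
    for (i in seq_len(length(path) - 1L)) {
      rows[[length(rows) + 1L]] <- mk_row(path[i], 1L, path[i + 1L], 1L)
    }
    if (n_tfs > 1L) {
      for (tf in tfs[-1L]) {
        rows[[length(rows) + 1L]] <- mk_row(chain[length(chain)], 1L, tf, 1L)
      }
    }
    for (d in decoys) {
      src <- sample(chain, 1L)
      rows[[length(rows) + 1L]] <- mk_row(src, slot2, d, 1L)
    }
    if (length(decoys) > 1L) {
      for (i in seq_len(length(decoys) - 1L)) {
        for (j in (i + 1L):length(decoys)) {
          if (stats::runif(1) < edge_density) {
            rows[[length(rows) + 1L]] <- mk_row(decoys[i], slot2,
                                                decoys[j], slot2)
          }
        }
      }
    }
    records <- as_interaction_records(do.call(rbind, rows))

    # planted skips walk the chain backwards from the TF end
    skip_candidates <- data.frame(
      protein = rev(path), domain = vapply(rev(path), dom_id, "", slot = 1L),
      stringsAsFactors = FALSE)
    if (n_skipped > nrow(skip_candidates)) {
      stop_input("unsatisfiable: %d skips requested but only %d path domains",
                 n_skipped, nrow(skip_candidates))
    }
    skipped <- skip_candidates[seq_len(n_skipped), , drop = FALSE]
    ev <- list()
    for (i in seq_len(nrow(skipped))) {
      ex <- exon_ids(skipped$protein[i],
                     as.integer(substr(skipped$domain[i], 7, 7)) %% 10L)
      ev[[length(ev) + 1L]] <- data.frame(
        feature_id = ex, feature_kind = "exon",
        effect = -stats::runif(length(ex), 0.35, 0.6),
        p_value = stats::runif(length(ex), 1e-4, 5e-3),
        stringsAsFactors = FALSE)
    }
    if (noise_evidence && length(decoys)) {
      for (d in utils::head(decoys, 2L)) {
        ex <- exon_ids(d, 1L)[1L]
        ev[[length(ev) + 1L]] <- data.frame(
          feature_id = ex, feature_kind = "exon",
          effect = stats::runif(1, -0.1, 0.1),
          p_value = stats::runif(1, 0.3, 1),
          stringsAsFactors = FALSE)
      }
    }
    evidence <- if (length(ev)) do.call(rbind, ev) else
      data.frame(feature_id = character(0), feature_kind = character(0),
                 effect = numeric(0), p_value = numeric(0),
                 stringsAsFactors = FALSE)

    regulons <- do.call(rbind, lapply(tfs, function(tf) {
      data.frame(tf = tf,
                 target = sprintf("G_%s_%02d", tf,
                                  seq_len(n_targets_per_tf)),
                 mode = sample(c(1, -1), n_targets_per_tf, replace = TRUE,
                               prob = c(0.7, 0.3)),
                 confidence = "A", stringsAsFactors = FALSE)
    }))
    gene_stats <- rbind(
      data.frame(gene = regulons$target,
                 stat = regulons$mode * stats::runif(nrow(regulons),
                                                     2.5, 3.5),
                 stringsAsFactors = FALSE),
      data.frame(gene = sprintf("BG%04d", seq_len(n_background_genes)),
                 stat = stats::rnorm(n_background_genes),
                 stringsAsFactors = FALSE))

    gene_sets <- list(
      TRUE_PATH = path,
      DECOYS = if (length(decoys)) decoys else chain[1L],
      RANDOM_SET = sort(sample(prots, max(2L, n_proteins %/% 2L))))

    # chain edges whose TF-side endpoint domain is planted-skipped
    chain_keys <- vapply(seq_len(length(path) - 1L), function(i) {
      a <- path[i]; b <- path[i + 1L]
      da <- dom_id(a, 1L); db <- dom_id(b, 1L)
      if (needs_swap(a, da, b, db)) ddi_key(b, db, a, da) else
        ddi_key(a, da, b, db)
    }, "")
    skipped_keys <- paste(skipped$protein, skipped$domain, sep = "|")
    edge_has_skip <- vapply(seq_len(length(path) - 1L), function(i) {
      any(c(paste(path[i], dom_id(path[i], 1L), sep = "|"),
            paste(path[i + 1L], dom_id(path[i + 1L], 1L), sep = "|")) %in%
            skipped_keys)
    }, TRUE)

    structure(list(
      records = records,
      regulons = regulons,
      gene_stats = gene_stats,
      evidence = evidence,
      gene_sets = gene_sets,
      roots = chain[1L],
      tfs = tfs,
      ground_truth = list(
        root = chain[1L],
        path_edges = chain_keys,
        skipped_domains = skipped,
        abrogated_edges = chain_keys[edge_has_skip]),
      params = list(n_proteins = n_proteins,
                    n_domains_per_protein = n_domains_per_protein,
                    edge_density = edge_density, n_tfs = n_tfs,
                    n_skipped = n_skipped,
                    n_targets_per_tf = n_targets_per_tf,
                    n_background_genes = n_background_genes,
                    noise_evidence = noise_evidence),
      seed = seed
    ), class = "splice_scenario")
  })
}

#' @export
print.splice_scenario <- function(x, ...) {
  cat(sprintf("Synthetic splice scenario (seed %s)\n", x$seed))
  cat(sprintf("  DDI records: %d  TFs: %s  root: %s\n", nrow(x$records),
              paste(x$tfs, collapse = ", "), x$ground_truth$root))
  cat(sprintf("  planted skipped domains: %d  path edges: %d\n",
              nrow(x$ground_truth$skipped_domains),
              length(x$ground_truth$path_edges)))
  invisible(x)
}

#' Write a scenario to a directory of standard input files
#'
#' Writes `interactions.tsv`, `regulons.tsv`, `gene_stats.tsv`,
#' `splice_evidence.tsv`, `gene_sets.gmt`, a `ground_truth.yaml` manifest
#' and a `config.yaml` naming the inputs, the root and default thresholds.
#' Regenerating the same seed and rewriting yields byte-identical files.
#'
#' @param scn a `splice_scenario`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  stopifnot(inherits(scn, "splice_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_interaction_table(scn$records, fp("interactions.tsv"))
  utils::write.table(scn$regulons, fp("regulons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scn$gene_stats, fp("gene_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scn$evidence, fp("splice_evidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(scn$gene_sets, fp("gene_sets.gmt"))
  yaml::write_yaml(scn$ground_truth, fp("ground_truth.yaml"))
  yaml::write_yaml(list(
    inputs = list(interactions = "interactions.tsv",
                  regulons = "regulons.tsv",
                  gene_stats = "gene_stats.tsv",
                  splice_evidence = "splice_evidence.tsv",
                  gene_sets = "gene_sets.gmt"),
    roots = scn$roots, mode = "hard",
    thresholds = list(p_skip = 0.05, p_tf = 0.05),
    seed = scn$seed), fp("config.yaml"))
  invisible(dir)
}

#' Random small benchmark instance for solver certification
#'
#' Draws a random prior (3-6 proteins, up to `max_ddis` DDIs, 1-2 domains
#' per protein), a random TF activity table, random splice evidence calls
#' and random model parameters, and assembles the corresponding ILP
#' instance. Sized so that the exhaustive reference solver
#' ([solve_exhaustive()]) stays tractable; used to certify the
#' branch-and-bound against enumeration over many seeds.
#'
#' @param seed RNG seed.
#' @param max_proteins maximum protein count (default 6).
#' @param max_ddis maximum DDI count (default 8).
#' @return a list with the `instance`, its `net`, `tf_table`, `skips` and
#'   the `seed`.
#' @export
random_benchmark_instance <- function(seed, max_proteins = 6L,
                                      max_ddis = 8L) {
  with_seed(seed, {
    np <- sample(3:max_proteins, 1L)
    prots <- LETTERS[seq_len(np)]
    ndom <- stats::setNames(sample(1:2, np, replace = TRUE), prots)
    doms <- lapply(prots, function(p) sprintf("PF%05d",
                                              match(p, prots) * 10L +
                                                seq_len(ndom[[p]])))
    names(doms) <- prots
    m <- sample(3:max_ddis, 1L)
    rows <- lapply(seq_len(m), function(i) {
      pq <- sort(sample(prots, 2L))
      data.frame(protein_a = pq[1L], domain_a = sample(doms[[pq[1L]]], 1L),
                 protein_b = pq[2L], domain_b = sample(doms[[pq[2L]]], 1L),
                 exons_a = "", exons_b = "", transcripts_a = "",
                 transcripts_b = "", direction = "",
                 stringsAsFactors = FALSE)
    })
    records <- as_interaction_records(do.call(rbind, rows))
    net <- build_network(records)

    n_tf <- sample(1:2, 1L)
    tf_names <- sample(net$proteins, n_tf)
    tf_table <- data.frame(
      tf = tf_names,
      n_targets = 10L,
      score = stats::runif(n_tf, 0.5, 2) * sample(c(-1, 1), n_tf, TRUE),
      empirical_p = c(0.001, stats::runif(n_tf - 1L, 0, 0.5)),
      stringsAsFactors = FALSE)
    tf_table$significant <- tf_table$empirical_p <= 0.05
    tf_table$weight <- abs(tf_table$score)
    class(tf_table) <- c("tf_activity_table", "data.frame")

    cand <- setdiff(net$proteins, tf_names)
    if (length(cand) == 0L) cand <- net$proteins[1L]
    roots <- cand[stats::runif(length(cand)) < 0.7]
    if (length(roots) == 0L) roots <- cand[1L]
    net <- attach_perturbation(net, roots = roots)

    nskip <- sample(0:2, 1L)
    skips <- if (nskip > 0L) {
      di <- net$domains[sample(nrow(net$domains), min(nskip,
                                                      nrow(net$domains))), ,
                        drop = FALSE]
      sk <- data.frame(protein = di$protein, domain = di$domain,
                       aggregated_p = stats::runif(nrow(di), 1e-4, 0.2),
                       mean_effect = stats::runif(nrow(di), -0.6, 0.3),
                       n_features = 2L, stringsAsFactors = FALSE)
      sk$skipped <- sk$aggregated_p <= 0.05 & sk$mean_effect < 0
      class(sk) <- c("domain_skip_table", "data.frame")
      sk
    } else empty_skip_table()

    mode <- sample(c("hard", "soft"), 1L)
    instance <- build_ilp(net, tf_table, skips, mode = mode,
                          lambda = 0.01,
                          alpha = stats::runif(1, 0.05, 0.2),
                          beta = stats::runif(1, 0.01, 0.1))
    list(instance = instance, net = net, tf_table = tf_table, skips = skips,
         seed = seed)
  })
}
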