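test_that("scenarios regenerate identically from the same seed", {
  a <- generate_scenario(seed = 7)
  b <- generate_scenario(seed = 7)
  expect_identical(a, b)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(a, d1)
  write_scenario(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_false(identical(a, generate_scenario(seed = 8)))
})

test_that("written scenario files load back through the standard readers", {
  scn <- generate_scenario(seed = 5)
  d <- withr::local_tempdir()
  write_scenario(scn, d)
  recs <- read_interaction_table(file.path(d, "interactions.tsv"))
  expect_equal(as.data.frame(recs), as.data.frame(scn$records))
  expect_equal(nrow(read_regulons(file.path(d, "regulons.tsv"))),
               nrow(scn$regulons))
  expect_length(read_gene_stats(file.path(d, "gene_stats.tsv")),
                nrow(scn$gene_stats))
  expect_equal(nrow(read_splice_evidence(file.path(d,
                                                   "splice_evidence.tsv"))),
               nrow(scn$evidence))
  expect_equal(read_gmt(file.path(d, "gene_sets.gmt")), scn$gene_sets)
  gt <- yaml::read_yaml(file.path(d, "ground_truth.yaml"))
  expect_equal(gt$root, scn$ground_truth$root)
})

test_that("planted skips really are skipped under the default threshold", {
  for (seed in c(2, 9, 21)) {
    scn <- generate_scenario(seed = seed, n_skipped = 2)
    net <- build_network(scn$records)
    sk <- call_skipped_domains(net, scn$evidence)
    planted <- scn$ground_truth$skipped_domains
    got <- merge(planted, as.data.frame(sk))
    expect_equal(nrow(got), nrow(planted))
    expect_true(all(got$skipped))
    expect_true(all(got$aggregated_p <= 0.05))
    expect_true(all(got$mean_effect < 0))
  }
})

test_that("without planted skips the aware and unaware optima coincide", {
  scn <- generate_scenario(seed = 4, n_skipped = 0)
  net <- attach_perturbation(build_network(scn$records), roots = scn$roots)
  tfA <- tf_activity(scn$regulons, scn$gene_stats, n_perm = 99, seed = 1)
  sk <- call_skipped_domains(net, scn$evidence)
  aware <- solve_ilp(build_ilp(net, tfA, sk, mode = "hard"))
  unaware <- solve_ilp(build_ilp(net, tfA, NULL, mode = "hard"))
  expect_equal(aware$objective, unaware$objective, tolerance = 1e-12)
  expect_identical(aware$ddis$key, unaware$ddis$key)
})

test_that("a planted skip on the unique path splits the two analyses", {
  scn <- generate_scenario(seed = 6, n_skipped = 1)
  net <- attach_perturbation(build_network(scn$records), roots = scn$roots)
  tfA <- tf_activity(scn$regulons, scn$gene_stats, n_perm = 99, seed = 1)
  sk <- call_skipped_domains(net, scn$evidence)
  aware <- solve_ilp(build_ilp(net, tfA, sk, mode = "hard"))
  unaware <- solve_ilp(build_ilp(net, tfA, NULL, mode = "hard"))
  planted <- scn$ground_truth$abrogated_edges
  expect_true(all(planted %in% unaware$ddis$key))
  expect_false(any(planted %in% aware$ddis$key))
})

test_that("unsatisfiable scenario parameters fail with an explanation", {
  expect_error(generate_scenario(n_proteins = 2), "at least 3")
  expect_error(generate_scenario(seed = 1, n_skipped = 10), "unsatisfiable")
  expect_error(generate_scenario(n_proteins = 4, n_tfs = 3),
               "unsatisfiable")
})

test_that("benchmark instances are reproducible and within size bounds", {
  a <- random_benchmark_instance(17)
  b <- random_benchmark_instance(17)
  expect_identical(a$instance$edges, b$instance$edges)
  expect_identical(a$tf_table, b$tf_table)
  for (seed in 1:10) {
    bi <- random_benchmark_instance(seed)
    expect_lte(nrow(bi$instance$proteins), 6L)
    expect_lte(nrow(bi$net$ddis), 8L)
  }
})
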