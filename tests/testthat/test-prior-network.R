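test_that("duplicate DDIs collapse with merged exon lists", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protein_a\tdomain_a\tprotein_b\tdomain_b\texons_a\texons_b",
    "A\td1\tB\td2\te1;e2\te5",
    "B\td2\tA\td1\te3\te5;e6",   # same DDI, reversed endpoint order
    "A\td1\tC\td3\te1\te7"), f)
  recs <- read_interaction_table(f)
  expect_equal(nrow(recs), 2L)
  # row 2 lists the same DDI from B's perspective: B-side exon e3 (column
  # exons_a) and A-side exons e5;e6 (column exons_b); after canonical
  # reordering these merge into the A/B sides of row 1
  merged <- recs[recs$protein_b == "B", ]
  expect_equal(sort(split_list_cell(merged$exons_a)),
               c("e1", "e2", "e5", "e6"))
  expect_equal(sort(split_list_cell(merged$exons_b)), c("e3", "e5"))
})

test_that("malformed rows are rejected with a warning, rest loaded", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tdomain_a\tprotein_b\tdomain_b",
               "\td1\tB\td2", "A\td1\tC\td3"), f)
  expect_warning(recs <- read_interaction_table(f), "malformed")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$protein_b, "C")
})

test_that("missing required columns and empty files are reported", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tdomain_a\tprotein_b", "A\td1\tB"), f)
  expect_error(read_interaction_table(f), "domain_b")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("protein_a\tdomain_a\tprotein_b\tdomain_b", f2)
  expect_error(read_interaction_table(f2), "empty")
})

test_that("dialect remapping resolves nonstandard column names", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GeneA\tPfamA\tGeneB\tPfamB", "A\td1\tB\td2"), f)
  recs <- read_interaction_table(f, dialect = c(
    protein_a = "GeneA", domain_a = "PfamA",
    protein_b = "GeneB", domain_b = "PfamB"))
  expect_equal(recs$protein_a, "A")
})

test_that("bundled fixture builds the hand-counted network", {
  f <- system.file("extdata", "toy_interactions.tsv", package = "splinter")
  recs <- read_interaction_table(f)
  net <- build_network(recs)
  expect_equal(length(net$proteins), 4L)
  expect_equal(nrow(net$ddis), 5L)
  # shared STAT3 exon ENSE00004002 maps to one domain from two DDI rows
  expect_true("ENSE00004002" %in% net$domain_features$feature_id)
})

test_that("PPI projection groups constituent DDIs and keeps self-DDIs out of paths", {
  recs <- toy_records(list(
    list("A", "a1", "B", "b1"), list("A", "a2", "B", "b2"),  # same pair
    list("A", "a1", "A", "a2"),                              # self DDI
    list("E", "e1", "F", "f1")))
  net <- build_network(recs)
  ab <- net$ddis[net$ddis$ppi == ppi_key("A", "B"), ]
  expect_equal(nrow(ab), 2L)
  expect_equal(sum(net$ppis$key == ppi_key("A", "B")), 1L)
  expect_true(any(net$ddis$self_interaction))
  # self DDIs never become ILP candidates
  net2 <- attach_perturbation(net, roots = c("A", "E"))
  inst <- build_ilp(net2, simple_tf_table("B"), NULL)
  expect_false(any(inst$edges$protein_a == inst$edges$protein_b))
})

test_that("disconnected proteins stay in the protein set", {
  recs <- toy_records(list(list("A", "a1", "B", "b1"),
                           list("E", "e1", "E", "e2")))
  net <- build_network(recs)
  expect_true("E" %in% net$proteins)
  expect_false(ppi_key("A", "E") %in% net$ppis$key)
})

test_that("perturbation root designation follows annotations with undirected fallback", {
  net <- build_network(toy_records(list(
    list("A", "a1", "B", "b1", "", "", "ab"),
    list("B", "b2", "C", "c1", "", "", "ab"))))
  expect_error(attach_perturbation(net, roots = "Z"), "Z")
  expect_equal(attach_perturbation(net, roots = "A")$perturbation_roots, "A")
  expect_equal(attach_perturbation(net)$perturbation_roots, "A")
  undirected <- build_network(toy_records(list(
    list("A", "a1", "B", "b1"), list("B", "b1", "C", "c1"),
    list("A", "a1", "C", "c1"))))
  expect_setequal(attach_perturbation(undirected)$perturbation_roots,
                  c("A", "B", "C"))
  expect_setequal(attach_perturbation(undirected,
                                      tfs = "C")$perturbation_roots,
                  c("A", "B"))
})

test_that("interaction tables round-trip through write and read", {
  for (seed in 1:5) {
    bi <- random_benchmark_instance(seed)
    recs <- bi$net$records
    f <- withr::local_tempfile(fileext = ".tsv")
    write_interaction_table(recs, f)
    again <- read_interaction_table(f)
    expect_equal(as.data.frame(again), as.data.frame(recs))
  }
})

test_that("PPI projection never exceeds the DDI count", {
  for (seed in 1:10) {
    net <- random_benchmark_instance(seed)$net
    expect_lte(nrow(net$ppis), nrow(net$ddis))
    # removing any DDI cannot add a PPI
    recs <- net$records
    if (nrow(recs) > 1L) {
      sub <- build_network(recs[-1L, , drop = FALSE])
      expect_true(all(sub$ppis$key %in% net$ppis$key))
    }
  }
})

test_that("SIF export gives the perturbation node out-links only", {
  net <- attach_perturbation(build_network(toy_records(list(
    list("A", "a1", "B", "b1")))), roots = "A")
  ef <- withr::local_tempfile(fileext = ".tsv")
  nf <- withr::local_tempfile(fileext = ".tsv")
  export_sif(net, ef, nf)
  edges <- read.delim(ef)
  pert <- edges[edges$interaction_type == "perturbation", ]
  expect_equal(pert$source, "PERTURBATION")
  expect_false("PERTURBATION" %in% edges$target)
})

test_that("rows naming the reserved perturbation node are rejected", {
  expect_warning(
    recs <- as_interaction_records(toy_records(list(
      list("PERTURBATION", "x", "B", "b1"), list("A", "a1", "B", "b1")))),
    "reserved")
  expect_equal(nrow(recs), 1L)
})
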