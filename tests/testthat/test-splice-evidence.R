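test_that("Fisher aggregation matches the chi-square reference values", {
  expect_identical(fisher_aggregate(0.05), 0.05)  # k = 1 is the identity
  # frozen from the closed form e^(-x/2) (1 + x/2) at
  # x = -2 (ln 0.01 + ln 0.04) = 15.64809...
  expect_equal(fisher_aggregate(c(0.01, 0.04)), 3.529618404343e-3,
               tolerance = 1e-10)
  expect_equal(fisher_aggregate(c(1, 1, 1)), 1)
  expect_error(fisher_aggregate(numeric(0)), "empty")
  expect_error(fisher_aggregate(c(0.5, 0)), "0, 1")
  expect_error(fisher_aggregate(1.2), "0, 1")
})

test_that("Fisher aggregation agrees with numerical integration", {
  set.seed(11)
  for (i in 1:100) {
    p <- runif(sample(1:6, 1), min = 1e-6, max = 1)
    expect_equal(fisher_aggregate(p), fisher_numint(p), tolerance = 1e-9)
  }
})

test_that("mean effect is the arithmetic mean", {
  expect_equal(mean_effect(c(-0.3, -0.5)), -0.4)
  expect_equal(mean_effect(0.2), 0.2)
  expect_equal(mean_effect(c(-1, 1)), 0)
  expect_error(mean_effect(numeric(0)), "empty")
})

test_that("domain skip calls combine matched evidence and apply the sign rule", {
  net <- build_network(toy_records(list(
    list("A", "a1", "B", "b1", "e1;e2", "e3"))))
  ev <- data.frame(feature_id = c("e1", "e2"), feature_kind = "exon",
                   effect = c(-0.4, -0.2), p_value = c(0.01, 0.04))
  sk <- call_skipped_domains(net, ev)
  expect_equal(nrow(sk), 1L)
  expect_equal(sk$protein, "A")
  expect_equal(sk$aggregated_p, 3.529618404343e-3, tolerance = 1e-10)
  expect_equal(sk$mean_effect, -0.3)
  expect_equal(sk$n_features, 2L)
  expect_true(sk$skipped)

  # inclusion direction blocks the skip call at identical significance
  ev_pos <- transform(ev, effect = -effect)
  expect_false(call_skipped_domains(net, ev_pos)$skipped)

  # unmatched features leave their domains out of the table entirely
  ev_other <- data.frame(feature_id = "e99", feature_kind = "exon",
                         effect = -0.5, p_value = 0.001)
  expect_warning(sk2 <- call_skipped_domains(net, ev_other), "no evidence")
  expect_equal(nrow(sk2), 0L)
})

test_that("exon and transcript evidence pool into one aggregation", {
  net <- build_network(toy_records(list(
    list("A", "a1", "B", "b1", "e1", ""))))
  net$domain_features <- rbind(net$domain_features, data.frame(
    protein = "A", domain = "a1", feature_id = "tx1",
    feature_kind = "transcript"))
  ev <- data.frame(feature_id = c("e1", "tx1"),
                   feature_kind = c("exon", "transcript"),
                   effect = c(-0.4, -1.2), p_value = c(0.01, 0.04))
  sk <- call_skipped_domains(net, ev)
  expect_equal(sk$n_features, 2L)
  expect_equal(sk$aggregated_p, fisher_aggregate(c(0.01, 0.04)))
  expect_equal(sk$mean_effect, -0.8)
})

test_that("adding uninformative evidence never flips a negative call positive", {
  net <- build_network(toy_records(list(
    list("A", "a1", "B", "b1", "e1;e2;e3", ""))))
  base <- data.frame(feature_id = c("e1", "e2"), feature_kind = "exon",
                     effect = c(-0.3, -0.2), p_value = c(0.2, 0.4))
  sk0 <- call_skipped_domains(net, base)
  extra <- rbind(base, data.frame(feature_id = "e3", feature_kind = "exon",
                                  effect = 0, p_value = 1))
  sk1 <- call_skipped_domains(net, extra)
  expect_false(sk0$skipped)
  expect_false(sk1$skipped)
  expect_gte(sk1$aggregated_p,
             pchisq(-2 * sum(log(base$p_value)), df = 6,
                    lower.tail = FALSE))
})

test_that("lowering the threshold never increases the number of skipped domains", {
  scn <- generate_scenario(seed = 3, n_skipped = 2)
  net <- build_network(scn$records)
  thresholds <- c(0.2, 0.05, 0.01, 0.001, 1e-6)
  counts <- vapply(thresholds, function(th) {
    sum(call_skipped_domains(net, scn$evidence, p_threshold = th)$skipped)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("strict per-feature mode is at least as conservative", {
  net <- build_network(toy_records(list(
    list("A", "a1", "B", "b1", "e1;e2", ""))))
  # aggregated p passes 0.05, but one feature alone does not
  ev <- data.frame(feature_id = c("e1", "e2"), feature_kind = "exon",
                   effect = c(-0.4, -0.2), p_value = c(0.004, 0.09))
  expect_true(call_skipped_domains(net, ev)$skipped)
  expect_false(call_skipped_domains(net, ev, strict_all = TRUE)$skipped)
})

test_that("evidence validation clips dPSI, floors zero p-values, drops junk", {
  ev <- data.frame(feature_id = c("e1", "e2", "e3", "e4"),
                   feature_kind = c("exon", "exon", "exon", "intron"),
                   effect = c(-1.7, 0.5, -0.1, 0.2),
                   p_value = c(0.01, 0, 2, 0.5))
  expect_warning(v <- validate_evidence(ev), "malformed")
  expect_equal(nrow(v), 2L)
  expect_equal(v$effect[1], -1)      # clipped into [-1, 1]
  expect_equal(v$p_value[2], 1e-300) # floored before any log
})
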