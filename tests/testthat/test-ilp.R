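test_that("the two-protein chain instance reproduces enumeration arithmetic", {
  inst <- chain_instance(w = 1, lambda = 0.01, alpha = 0.1)
  sol <- solve_ilp(inst)
  # 1 - 0.01 * (2 proteins + 2 domains + 1 DDI + 1 PPI)
  expect_equal(sol$objective, 0.94, tolerance = 1e-12)
  expect_equal(sol$status, "optimal")
  expect_setequal(sol$proteins, c("A", "T"))
  expect_equal(sol$reached_tfs, "T")
  expect_equal(sol$ddis$from_protein, "A")
  expect_equal(solve_exhaustive(inst)$objective, sol$objective,
               tolerance = 1e-12)
})

test_that("hard mode with a skipped terminal domain yields the empty network", {
  sk <- simple_skips("T", "t1", aggregated_p = 0.01, mean_effect = -0.4)
  inst <- chain_instance(skips = sk, mode = "hard")
  sol <- solve_ilp(inst)
  expect_equal(sol$objective, 0)
  expect_equal(nrow(sol$ddis), 0L)
  expect_equal(solve_exhaustive(inst)$objective, 0)
})

test_that("soft-mode penalties tip the selection exactly at the arithmetic threshold", {
  sk <- simple_skips("T", "t1", aggregated_p = 0.01, mean_effect = -0.4)
  # s = -log10(0.01) = 2; path objective = 1 - 0.06 - beta * 2
  heavy <- solve_ilp(chain_instance(skips = sk, mode = "soft", beta = 0.6))
  expect_equal(heavy$objective, 0)           # 1 - 0.06 - 1.2 < 0: empty wins
  expect_equal(nrow(heavy$ddis), 0L)
  light <- solve_ilp(chain_instance(skips = sk, mode = "soft", beta = 0.2))
  expect_equal(light$objective, 1 - 0.06 - 0.4, tolerance = 1e-12)
  expect_equal(nrow(light$ddis), 1L)
})

test_that("no significant TF means the empty network is optimal", {
  recs <- toy_records(list(list("A", "a1", "T", "t1")))
  net <- attach_perturbation(build_network(recs), roots = "A")
  inst <- build_ilp(net, simple_tf_table("T", significant = FALSE), NULL)
  sol <- solve_ilp(inst)
  expect_equal(sol$objective, 0)
  expect_equal(length(sol$proteins), 0L)
})

test_that("parameter validation rejects negative penalties and missing TFs", {
  recs <- toy_records(list(list("A", "a1", "B", "b1")))
  net <- attach_perturbation(build_network(recs), roots = "A")
  expect_error(build_ilp(net, simple_tf_table("Z"), NULL), "no regulon TF")
  expect_error(chain_instance(lambda = -1), "lambda")
  expect_error(build_ilp(net, simple_tf_table("B"), NULL, alpha = -0.5),
               "alpha")
  net2 <- build_network(recs)
  expect_error(build_ilp(net2, simple_tf_table("B"), NULL),
               "attach_perturbation")
})

test_that("with zero regularization ties are broken deterministically", {
  inst <- chain_instance(lambda = 0)
  a <- solve_ilp(inst)
  b <- solve_ilp(inst)
  expect_identical(a$selected_ids, b$selected_ids)
  expect_equal(a$objective, 1)
  expect_identical(a$selected_ids, solve_exhaustive(inst)$selected_ids)
})

test_that("branch-and-bound equals exhaustive enumeration on random instances", {
  for (seed in 1:40) {
    bi <- random_benchmark_instance(seed)
    a <- solve_ilp(bi$instance)
    b <- solve_exhaustive(bi$instance)
    expect_equal(a$objective, b$objective, tolerance = 1e-12,
                 info = sprintf("seed %d", seed))
    expect_identical(a$selected_ids, b$selected_ids)
    expect_length(validate_solution(bi$net, bi$skips, a), 0L)
  }
})

test_that("increasing the regularization never grows the optimal network", {
  for (seed in c(2, 5, 9, 14)) {
    bi <- random_benchmark_instance(seed)
    sizes <- vapply(c(0, 0.005, 0.02, 0.1, 0.5), function(lam) {
      inst <- build_ilp(bi$net, bi$tf_table, bi$skips,
                        mode = bi$instance$mode, lambda = lam,
                        alpha = bi$instance$params$alpha,
                        beta = bi$instance$params$beta)
      sol <- solve_exhaustive(inst)
      length(sol$proteins) + nrow(sol$domains) + nrow(sol$ddis) +
        nrow(sol$ppis)
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0), info = sprintf("seed %d", seed))
  }
})

test_that("solution certification flags hand-built violations", {
  sk <- simple_skips("T", "t1", aggregated_p = 0.01, mean_effect = -0.4)
  inst <- chain_instance()
  sol <- solve_ilp(inst)
  expect_length(validate_solution(inst$net, NULL, sol), 0L)
  # a skipped domain smuggled into a hard-mode solution
  expect_match(validate_solution(inst$net, sk, sol, mode = "hard"),
               "skipped_domain_selected", all = FALSE)
  # a hand-built 2-cycle
  cyc <- sol
  cyc$ddis <- rbind(cyc$ddis, data.frame(
    key = cyc$ddis$key, from_protein = "T", from_domain = "t1",
    to_protein = "A", to_domain = "a1", ppi_key = cyc$ddis$ppi_key,
    direction = "rev"))
  cyc$ppis <- rbind(cyc$ppis, data.frame(key = cyc$ppis$key, from = "T",
                                         to = "A"))
  expect_match(validate_solution(inst$net, NULL, cyc), "cycle", all = FALSE)
})

test_that("unknown solver backends error with a hint; function backends plug in", {
  inst <- chain_instance()
  expect_error(solve_ilp(inst, backend = "cplex"), "cplex")
  fake <- function(instance, ...) solve_bnb(instance, ...)
  expect_equal(solve_ilp(inst, backend = fake)$objective, 0.94,
               tolerance = 1e-12)
})

test_that("LP and MPS exports carry the model structure", {
  inst <- chain_instance()
  lp <- withr::local_tempfile(fileext = ".lp")
  mps <- withr::local_tempfile(fileext = ".mps")
  export_lp(inst, lp)
  export_mps(inst, mps)
  lp_txt <- readLines(lp)
  expect_true(any(grepl("^Maximize", lp_txt)))
  expect_true(any(grepl("Binaries", lp_txt)))
  expect_true(any(grepl("t_", lp_txt)))     # TF terminal variable
  expect_true(any(grepl("C5d", lp_txt)))    # depth/acyclicity constraints
  mps_txt <- readLines(mps)
  expect_true(any(grepl("^ROWS", mps_txt)))
  expect_true(any(grepl("ENDATA", mps_txt)))
})
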