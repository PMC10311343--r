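test_that("two equal-cost parallel paths give a pool of exactly two", {
  inst <- parallel_instance()
  pool <- enumerate_solutions(inst, k_max = 10, objective_tolerance = 0)
  expect_length(pool, 2L)
  # either single-DDI path: 2 proteins + 2 domains + 1 DDI + 1 PPI
  expect_equal(attr(pool, "base_objective"), 1 - 0.01 * 6)
  keys <- lapply(pool, function(s) s$ddis$key)
  expect_false(identical(keys[[1]], keys[[2]]))
  cons <- consensus_network(pool)
  expect_equal(sort(cons$edges$weight), c(0.5, 0.5))
  expect_equal(cons$proteins$weight, c(1, 1))
})

test_that("a unique optimum gives a pool of one regardless of k_max", {
  inst <- chain_instance()
  pool <- enumerate_solutions(inst, k_max = 50)
  expect_length(pool, 1L)
  pool1 <- enumerate_solutions(inst, k_max = 1)
  expect_length(pool1, 1L)
  expect_identical(pool1[[1]]$selected_ids, solve_ilp(inst)$selected_ids)
  cons <- consensus_network(pool)
  expect_equal(cons$edges$weight, 1)
})

test_that("pool members are pairwise distinct edge sets", {
  for (seed in c(1, 4, 7, 12)) {
    bi <- random_benchmark_instance(seed)
    pool <- enumerate_solutions(bi$instance, k_max = 20,
                                objective_tolerance = 0.05)
    ids <- vapply(pool, function(s) paste(s$selected_ids, collapse = ","),
                  "")
    expect_equal(anyDuplicated(ids), 0L)
    for (s in pool) {
      expect_length(validate_solution(bi$net, bi$skips, s), 0L)
    }
  }
})

test_that("consensus weights are exact appearance fractions", {
  for (seed in c(3, 8)) {
    bi <- random_benchmark_instance(seed)
    pool <- enumerate_solutions(bi$instance, k_max = 25,
                                objective_tolerance = 0.2)
    cons <- consensus_network(pool)
    n <- length(pool)
    for (i in seq_len(nrow(cons$edges))) {
      count <- sum(vapply(pool, function(s)
        cons$edges$key[i] %in% s$ddis$key, TRUE))
      expect_identical(cons$edges$weight[i], count / n)
    }
    expect_true(all(cons$edges$weight > 0 & cons$edges$weight <= 1))
  }
})

test_that("minimum Hamming distance thins the pool", {
  inst <- parallel_instance()
  pool <- enumerate_solutions(inst, k_max = 10, objective_tolerance = 1,
                              min_distance = 3L)
  # the first member is always the unconstrained optimum
  expect_identical(pool[[1]]$selected_ids, solve_ilp(inst)$selected_ids)
  # the distance-2 alternative path is excluded at min_distance = 3
  plain <- enumerate_solutions(inst, k_max = 10, objective_tolerance = 1)
  expect_lt(length(pool), length(plain))
  ids <- lapply(pool, function(s) s$selected_ids)
  if (length(pool) > 1L) {
    for (i in seq_len(length(pool) - 1L)) {
      for (j in (i + 1L):length(pool)) {
        hd <- length(setdiff(ids[[i]], ids[[j]])) +
          length(setdiff(ids[[j]], ids[[i]]))
        expect_gte(hd, 3L)
      }
    }
  }
})

test_that("consensus rejects empty or mode-mixed pools", {
  expect_error(consensus_network(list()), "empty")
  a <- solve_ilp(chain_instance(mode = "hard"))
  b <- solve_ilp(chain_instance(mode = "soft"))
  expect_error(consensus_network(list(a, b)), "mixes")
})

test_that("network differencing partitions, flags and is antisymmetric", {
  sk <- simple_skips("T", "t1", aggregated_p = 0.001, mean_effect = -0.5)
  aware <- consensus_network(list(solve_ilp(chain_instance(skips = sk,
                                                           mode = "hard"))))
  unaware <- consensus_network(list(solve_ilp(chain_instance())))
  d <- diff_networks(aware, unaware, skips = sk)
  expect_equal(d$status, "unaware_only")
  expect_true(all(d$splice_abrogated))
  expect_equal(d$weight_unaware, 1)
  expect_true(is.na(d$weight_aware))
  # swapping the inputs swaps the exclusive partitions
  d2 <- diff_networks(unaware, aware, skips = sk)
  expect_equal(d2$status, "aware_only")
  expect_false(any(d2$splice_abrogated))
  # identical pools difference to all-shared
  d3 <- diff_networks(unaware, unaware)
  expect_true(all(d3$status == "shared"))
})

test_that("consensus export writes the edge table with splice flags", {
  sk <- simple_skips("T", "t1", aggregated_p = 0.001, mean_effect = -0.5)
  cons <- consensus_network(list(solve_ilp(chain_instance())))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_consensus(cons, f, skips = sk)
  tab <- read.delim(f)
  expect_equal(tab$weight, 1)
  expect_equal(tab$splice_flag, "skipped_endpoint")
})
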