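test_that("instrumented counts reproduce the cost-model closed forms", {
  for (N in c(128, 256, 384, 512, 768, 896)) {
    ns <- N %/% 15
    e <- count_operations("energy", N)
    expect_equal(unlist(e[c("additions", "assignments", "comparisons",
                            "multiplications")]),
                 c(additions = N, assignments = N + 1, comparisons = 0,
                   multiplications = N + 1))
    l <- count_operations("line_length", N)
    expect_equal(unlist(l[c("additions", "assignments", "comparisons",
                            "multiplications")]),
                 c(additions = 4 * N - 3, assignments = N,
                   comparisons = N - 1, multiplications = 1))
    a <- count_operations("nlacc", N)
    expect_equal(unlist(a[c("additions", "assignments", "comparisons",
                            "multiplications")]),
                 c(additions = 2 * ns, assignments = 2 * N + 9 * ns - 4,
                   comparisons = 2 * N + 2 * ns - 4, multiplications = 0))
  }
})

test_that("counts are data-independent and match on supplied epochs", {
  set.seed(3)
  a <- count_operations("line_length", x = rnorm(300))
  b <- count_operations("line_length", x = rep(0, 300))
  expect_identical(unclass(a), unclass(b))
})

test_that("fixed cost-model cells hold at any valid epoch size", {
  for (N in c(64, 200, 512)) {
    expect_equal(count_operations("line_length", N)$multiplications, 1)
  }
  expect_equal(count_operations("nlacc", 512)$multiplications, 0)
  expect_equal(count_operations("energy", 512)$comparisons, 0)
})

test_that("invalid requests are rejected", {
  expect_error(count_operations("fourier", 512))
  expect_error(count_operations("nlacc", 30), "3\\*w")
  expect_error(count_operations("line_length", 1), "N >= 2")
})
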