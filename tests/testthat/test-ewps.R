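test_that("PC and BS weights follow their formulas and bounds", {
  expect_equal(weight_pc(100), 0)
  expect_equal(weight_pc(40), 0.6)
  expect_equal(weight_pc(0), 1)
  expect_error(weight_pc(120), "within")
  expect_equal(weight_bs(200, 200), 1)
  expect_equal(weight_bs(0, 200), 0)
  expect_equal(weight_bs(50, 200), 0.25)
  expect_error(weight_bs(10, 0), "positive")
  expect_warning(w <- weight_bs(210, 200), "clamped")
  expect_equal(w, 1)
})

test_that("the worked two-ortholog PC example evaluates to 25", {
  fam <- fake_family(c("o1", "o2"), c(80, 40), c(100, 60), 200)
  res <- compute_ewps(fam, c(10, 30), "PC")
  expect_equal(res$ewps, (0.2 * 10 + 0.6 * 30) / 0.8)  # = 25
  expect_equal(res$ewps, 25)
  expect_equal(res$terms$w, c(0.2, 0.6))
})

test_that("degenerate families are handled as specified", {
  one <- fake_family("o1", 50, 80, 200)
  expect_equal(compute_ewps(one, 17.3, "PC")$ewps, 17.3)
  zeros <- fake_family(c("o1", "o2"), c(70, 30), c(90, 50), 200)
  expect_equal(compute_ewps(zeros, c(0, 0), "BS")$ewps, 0)
  empty <- fake_family(character(0), numeric(0), numeric(0), numeric(0))
  r <- compute_ewps(empty, numeric(0), "PC")
  expect_true(r$undefined)
  all_identical <- fake_family(c("o1", "o2"), c(100, 100), c(200, 200), 200)
  r2 <- compute_ewps(all_identical, c(5, 9), "PC")  # PC weights all zero
  expect_true(r2$undefined)
  expect_error(compute_ewps(one, c(1, 2), "PC"), "scores")
})

test_that("compute_ewps matches the brute-force equation on random families", {
  set.seed(60)
  for (k in 1:200) {
    n <- sample(1:12, 1)
    pid <- runif(n, 0, 99)
    self <- runif(1, 50, 400)
    bits <- runif(n, 0, self)
    P <- ifelse(runif(n) < 0.3, 0, runif(n, 0, 200))  # zeros retained
    fam <- fake_family(sprintf("o%d", 1:n), pid, bits, self)
    pc <- compute_ewps(fam, P, "PC")
    bs <- compute_ewps(fam, P, "BS")
    expect_equal(pc$ewps, ewps_oracle(P, 1 - pid / 100), tolerance = 1e-12)
    expect_equal(bs$ewps, ewps_oracle(P, bits / self), tolerance = 1e-12)
    # convexity when all weights positive
    expect_gte(pc$ewps, min(P) - 1e-12)
    expect_lte(pc$ewps, max(P) + 1e-12)
    # permutation invariance
    perm <- sample(n)
    famp <- fake_family(sprintf("o%d", 1:n), pid[perm], bits[perm], self)
    expect_equal(compute_ewps(famp, P[perm], "PC")$ewps, pc$ewps,
                 tolerance = 1e-12)
    # homogeneity
    expect_equal(compute_ewps(fam, 3.5 * P, "BS")$ewps, 3.5 * bs$ewps,
                 tolerance = 1e-12)
  }
})

test_that("scheme comparison reports deltas and rank agreement", {
  set.seed(61)
  fams <- lapply(1:10, function(i) {
    fake_family(sprintf("f%d_o%d", i, 1:4), runif(4, 10, 90),
                runif(4, 20, 180), 200, ref_id = sprintf("R%d", i))
  })
  P <- lapply(1:10, function(i) runif(4, 0, 100))
  pc <- mapply(compute_ewps, fams, P, MoreArgs = list(scheme = "PC"),
               SIMPLIFY = FALSE)
  bs <- mapply(compute_ewps, fams, P, MoreArgs = list(scheme = "BS"),
               SIMPLIFY = FALSE)
  cmp <- compare_schemes(pc, bs)
  expect_equal(cmp$n, 10L)
  expect_equal(cmp$per_protein$delta,
               abs(cmp$per_protein$ewps_pc - cmp$per_protein$ewps_bs))
  # swapped labels leave absolute deltas unchanged
  cmp2 <- compare_schemes(bs, pc)
  expect_equal(sort(cmp2$per_protein$delta), sort(cmp$per_protein$delta))
  # identical weights under both schemes -> delta 0
  equalw <- fake_family(c("o1", "o2"), c(50, 50), c(100, 100), 200)
  pc1 <- compute_ewps(equalw, c(10, 30), "PC")
  bs1 <- compute_ewps(equalw, c(10, 30), "BS")
  expect_equal(pc1$ewps, bs1$ewps)
})
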