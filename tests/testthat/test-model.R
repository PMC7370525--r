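test_that("relative fitness normalizes to the population mean", {
  # monomorphic population: any clone has fitness 1 relative to itself
  p <- model_params(n = 2, m = 3, s = 0.1, c = 2, N0 = 100, NT = 100, T = 5)
  counts <- matrix(0, 3, 4); counts[2, 3] <- 100
  st <- population_state(counts, 0L, p)
  expect_equal(relative_fitness(st, p)$omega[2, 3], 1)

  # neutral model: all relative fitnesses are 1
  p0 <- model_params(n = 2, m = 3, s = 0, c = 1, N0 = 100, NT = 100, T = 5)
  expect_true(all(relative_fitness(initial_state(p0), p0)$omega == 1))

  # two-clone hand arithmetic: x00 = x11 = 1/2, s = 0.01, c = 2
  p2 <- model_params(n = 1, m = 1, s = 0.01, c = 2, N0 = 2, NT = 2, T = 1)
  counts <- matrix(c(1, 0, 0, 1), 2, 2)
  st2 <- population_state(counts, 0L, p2)
  f <- relative_fitness(st2, p2)
  w00 <- 1 / ((1 + 1.02 * 1.01) / 2)
  expect_equal(f$omega[1, 1], w00)
  expect_equal(f$omega[2, 2], 1.02 * 1.01 * w00)
  # frequency-weighted mean relative fitness is exactly 1
  expect_equal(sum(f$omega * st2$freqs), 1, tolerance = 1e-12)
})

test_that("fitness is increasing in both mutation classes and symmetric at c = 1", {
  p <- model_params(n = 3, m = 3, s = 0.05, c = 2, N0 = 100, NT = 100, T = 5)
  om <- relative_fitness(initial_state(p), p)$omega
  expect_true(all(diff(om) > 0))        # increasing in k down columns
  expect_true(all(t(diff(t(om))) > 0))  # increasing in l along rows
  # c = 1 makes r = s: omega depends on k + l only
  p1 <- model_params(n = 3, m = 3, s = 0.05, c = 1, N0 = 100, NT = 100, T = 5)
  om1 <- relative_fitness(initial_state(p1), p1)$omega
  for (tot in 0:6) {
    idx <- which(outer(0:3, 0:3, "+") == tot)
    expect_equal(max(om1[idx]) - min(om1[idx]), 0, tolerance = 1e-12)
  }
})

test_that("sampling distribution matches the brute-force enumeration oracle", {
  for (fw in c("offspring", "parent")) for (se in c("as_printed", "per_locus")) {
    p <- model_params(n = 1, m = 1, mu = 0.1, s = 0.1, c = 2,
                      N0 = 100, NT = 100, T = 5,
                      fitness_weighting = fw, survival_exponent = se)
    st <- initial_state(p)
    f <- relative_fitness(st, p)
    sdist <- sampling_distribution(st, f, p)
    raw <- enumerate_theta_raw(st$freqs, p, f$omega)
    expect_equal(sdist$raw_sum, sum(raw), tolerance = 1e-12)
    expect_equal(sdist$theta, raw / sum(raw), tolerance = 1e-12)
    expect_equal(sum(sdist$theta), 1, tolerance = 1e-12)
  }
  # larger mixed state
  p <- tiny_oracle_params()
  st <- tiny_mixed_state(p)
  f <- relative_fitness(st, p)
  sdist <- sampling_distribution(st, f, p)
  raw <- enumerate_theta_raw(st$freqs, p, f$omega)
  expect_equal(sdist$theta, raw / sum(raw), tolerance = 1e-12)
})

test_that("sampling distribution limits: no mutation and wild-type term", {
  # mu = 0: selection only, theta = omega * x
  p <- model_params(n = 1, m = 2, mu = 0, s = 0.1, c = 2,
                    N0 = 200, NT = 200, T = 5)
  st <- tiny_mixed_state(p)
  f <- relative_fitness(st, p)
  sdist <- sampling_distribution(st, f, p)
  expect_equal(sdist$raw_sum, 1, tolerance = 1e-12)
  expect_equal(sdist$theta, f$omega * st$freqs, tolerance = 1e-12)

  # monomorphic wild type: raw theta_00 is the no-mutation survival term
  p2 <- model_params(n = 1, m = 2, mu = 0.01, s = 0.1, c = 2,
                     N0 = 200, NT = 200, T = 5)
  st2 <- initial_state(p2)
  f2 <- relative_fitness(st2, p2)
  sdist2 <- sampling_distribution(st2, f2, p2)
  expect_equal(sdist2$theta[1, 1] * sdist2$raw_sum,
               (1 - 0.01)^(1 + 2) * 1, tolerance = 1e-12)
  # renormalization deficit is O((n + m) mu)
  expect_lt(abs(1 - sdist2$raw_sum), 10 * (p2$n + p2$m) * p2$mu)
})

test_that("no back mutation: theta is zero without an eligible ancestor", {
  p <- tiny_oracle_params()
  counts <- matrix(0, 2, 3); counts[1, 2] <- 200   # only clone (0, 1)
  st <- population_state(counts, 0L, p)
  th <- sampling_distribution(st, NULL, p)$theta
  expect_equal(th[1, 1], 0)   # (0,0) unreachable: would need back mutation
  expect_equal(th[2, 1], 0)   # (1,0) likewise
  expect_gt(th[2, 2], 0)      # (1,1) reachable from (0,1)
})

test_that("wf_step follows the schedule, is deterministic, and matches multinomial moments", {
  p <- tiny_oracle_params()
  st <- initial_state(p)
  set.seed(7); a <- wf_step(st, p)
  set.seed(7); b <- wf_step(st, p)
  expect_identical(a$counts, b$counts)
  expect_equal(a$total, 200)
  expect_equal(a$t, 1L)

  # mu = 0 monomorphic: nothing to sample
  p0 <- model_params(n = 1, m = 2, mu = 0, s = 0.1, c = 2,
                     N0 = 200, NT = 400, T = 1)
  nx <- wf_step(initial_state(p0), p0)
  expect_equal(nx$counts[1, 1], 400)
  expect_equal(sum(nx$counts), 400)

  # moment oracle: empirical mean over 2000 draws within 4 SE per cell
  pm <- model_params(n = 1, m = 2, mu = 0.01, s = 0.05, c = 2,
                     N0 = 1000, NT = 1000, T = 5)
  stm <- population_state(matrix(c(600, 200, 150, 50, 0, 0), 2, 3), 0L, pm)
  theta <- sampling_distribution(stm, NULL, pm)$theta
  ndraw <- 2000
  set.seed(11)
  acc <- matrix(0, 2, 3)
  for (i in seq_len(ndraw)) acc <- acc + wf_step(stm, pm)$counts
  emp_mean <- acc / ndraw
  expected <- 1000 * theta
  se <- sqrt(1000 * theta * (1 - theta) / ndraw)
  ok <- abs(emp_mean - expected) <= 4 * se + 1e-9
  expect_true(all(ok))
})

test_that("trajectories start wild type, conserve the schedule, and reproduce under a seed", {
  p <- tiny_oracle_params()
  tr <- simulate_trajectory(p, seed = 5)
  expect_equal(tr$counts[, , 1], matrix(c(200, 0, 0, 0, 0, 0), 2, 3))
  sched <- size_schedule(p)
  expect_equal(apply(tr$counts, 3, sum), sched)
  tr2 <- simulate_trajectory(p, seed = 5)
  expect_identical(tr$counts, tr2$counts)

  # neutral mutation-free run ends monomorphic wild type at NT
  p0 <- model_params(n = 1, m = 2, mu = 0, s = 0, c = 1,
                     N0 = 100, NT = 1000, T = 10)
  tr0 <- simulate_trajectory(p0, seed = 1)
  expect_equal(tr0$counts[1, 1, 11], 1000)
  expect_equal(sum(tr0$counts[, , 11]), 1000)
})

test_that("clones never appear before an eligible ancestor exists", {
  p <- tiny_oracle_params()
  for (seed in 1:5) {
    tr <- simulate_trajectory(p, seed)
    fh <- tr$first_hit
    for (k in 0:p$n) for (l in 0:p$m) {
      if (is.na(fh[k + 1, l + 1]) || (k == 0 && l == 0)) next
      anc <- fh[1:(k + 1), 1:(l + 1)]
      anc <- anc[!is.na(anc)]
      anc <- anc[anc < fh[k + 1, l + 1]]
      expect_gt(length(anc), 0)
    }
  }
})

test_that("mean relative fitness stays normalized along whole trajectories", {
  p <- tiny_oracle_params()
  tr <- simulate_trajectory(p, seed = 3)
  for (t in 0:p$T) {
    st <- clonewave:::state_at(tr, t)
    f <- relative_fitness(st, p)
    expect_equal(sum(f$omega * st$freqs), 1, tolerance = 1e-10)
  }
})

test_that("oracle_step guards its population limit and matches the neutral expectation", {
  p <- tiny_oracle_params()
  big <- model_params(n = 1, m = 2, mu = 0, s = 0, c = 1,
                      N0 = 2e5, NT = 2e5, T = 5)
  expect_error(oracle_step(initial_state(big), big), "1e5|limit|<=")

  # mu = 0 monomorphic: same clone at scheduled size
  p0 <- model_params(n = 1, m = 2, mu = 0, s = 0.1, c = 2,
                     N0 = 200, NT = 200, T = 5)
  o <- oracle_step(initial_state(p0), p0)
  expect_equal(o$counts[1, 1], 200)

  # neutral resampling preserves expected frequencies
  pn <- model_params(n = 1, m = 2, mu = 0, s = 0, c = 1,
                     N0 = 200, NT = 200, T = 5)
  st <- tiny_mixed_state(pn)
  set.seed(13)
  acc <- matrix(0, 2, 3)
  for (i in 1:400) acc <- acc + oracle_step(st, pn)$counts
  emp <- acc / (400 * 200)
  se <- sqrt(st$freqs * (1 - st$freqs) / (400 * 200))
  expect_true(all(abs(emp - st$freqs) <= 4 * se + 1e-9))
})

test_that("step and oracle_step agree distributionally on a mixed small state", {
  p <- tiny_oracle_params()
  st <- tiny_mixed_state(p)
  ndraw <- 300
  set.seed(17)
  cs <- replicate(ndraw, wf_step(st, p)$counts)
  co <- replicate(ndraw, oracle_step(st, p)$counts)
  for (idx in seq_len(6)) {
    a <- cs[(idx - 1) %% 2 + 1, (idx - 1) %/% 2 + 1, ]
    b <- co[(idx - 1) %% 2 + 1, (idx - 1) %/% 2 + 1, ]
    expect_gt(two_sample_chisq_p(a, b), 0.01)
  }
})
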