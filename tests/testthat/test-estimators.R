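test_that("identity and constant perturbations give exact free energies", {
  es0 <- workSamples(rep(0, 100), rep(0, 100))
  expect_equal(zwanzigDG(es0)$total, 0)
  expect_equal(barDG(es0)$total, 0)
  esc <- workSamples(rep(2.5, 50), rep(-2.5, 50))
  expect_equal(zwanzigDG(esc)$total, 2.5)
  expect_equal(barDG(esc)$total, 2.5)
})

test_that("exponential averaging matches the Gaussian cumulant closed form", {
  cfg <- estimatorConfig(method = "zwanzig")
  beta <- betaOf(cfg)
  set.seed(101)
  n <- 1e6
  w <- rnorm(n, mean = 1.0, sd = 0.5)
  es <- workSamples(w, -w)   # reverse unused by the forward estimator
  got <- zwanzigDG(es, cfg)$total
  want <- 1.0 - beta * 0.5^2 / 2          # mu - beta sigma^2 / 2 = 0.7889
  expect_equal(want, 0.7889, tolerance = 1e-4)
  # delta-method standard error of the exponential average
  ew <- exp(-beta * (w - min(w)))
  se <- sd(ew) / (mean(ew) * beta * sqrt(n))
  expect_lt(abs(got - want), 3 * se)
})

test_that("BAR recovers the Crooks-consistent Gaussian free energy", {
  es <- gaussianWorkSamples(dg = 1.0, sigma = 1.0, n = 1e5, seed = 5)
  got <- barDG(es)$total
  # BAR variance is below the single-direction exponential-average variance;
  # use the forward-side delta-method error as a conservative bound
  beta <- betaOf(estimatorConfig())
  wf <- samples(es)$u_forward
  wf <- wf[is.finite(wf)]
  ew <- exp(-beta * (wf - min(wf)))
  se <- sd(ew) / (mean(ew) * beta * sqrt(length(wf)))
  expect_lt(abs(got - 1.0), 3 * se)
})

test_that("mirrored work distributions give zero free energy", {
  set.seed(11)
  w <- rnorm(2e4, 0.3, 0.4)
  es <- workSamples(w, w)   # reverse work identical to forward: dG = 0
  expect_lt(abs(barDG(es)$total), 0.02)
})

test_that("BAR satisfies its fixed-point equation on every interface", {
  reps <- harmonicToyReplicas(harmonicToyModel(1, 4), toyProtocol(10, 100L),
                              seed = 3)
  cfg <- estimatorConfig()
  beta <- betaOf(cfg)
  b <- barDG(reps[[1L]], cfg)
  s <- samples(reps[[1L]])
  wins <- sort(unique(s$window))
  for (j in seq_len(length(wins) - 1L)) {
    wi <- s[s$window == wins[j], ]
    wn <- s[s$window == wins[j + 1L], ]
    wF <- wi$u_forward - wi$u_self
    wR <- wn$u_reverse - wn$u_self
    C <- b$perWindow$dg[j]
    # independently coded residual of the acceptance-ratio equality
    lhs <- mean(1 / (1 + exp(beta * (wF - C))))
    rhs <- mean(1 / (1 + exp(beta * (wR + C))))
    expect_lt(abs(lhs - rhs), 1e-6)
  }
})

test_that("estimators are invariant under a uniform energy offset", {
  es <- harmonicToyFEP(harmonicToyModel(1, 4), toyProtocol(20, 100L), seed = 9)
  s <- samples(es)
  s2 <- s
  s2$u_self <- s2$u_self + 137.4
  s2$u_forward <- s2$u_forward + 137.4
  s2$u_reverse <- s2$u_reverse + 137.4
  es2 <- new("EnergySamples", samples = s2)
  expect_equal(zwanzigDG(es)$total, zwanzigDG(es2)$total, tolerance = 1e-10)
  expect_equal(barDG(es)$total, barDG(es2)$total, tolerance = 1e-6)
})

test_that("Zwanzig and BAR agree on high-overlap fixtures", {
  for (seed in 1:5) {
    es <- gaussianWorkSamples(dg = 0.5, sigma = 0.4, n = 2e4, seed = seed)
    z <- zwanzigDG(es, estimatorConfig(method = "zwanzig"))$total
    b <- barDG(es)$total
    # combined error bound from the forward-side delta method
    beta <- betaOf(estimatorConfig())
    wf <- samples(es)$u_forward; wf <- wf[is.finite(wf)]
    ew <- exp(-beta * (wf - min(wf)))
    se <- sd(ew) / (mean(ew) * beta * sqrt(length(wf)))
    expect_lt(abs(z - b), 3 * sqrt(2) * se)
  }
})

test_that("replica aggregation computes mean and SEM as defined", {
  reps <- lapply(c(1, 2, 3), function(dg)
    gaussianWorkSamples(dg, 0, 10, seed = 1))
  leg <- estimateLeg(reps, estimatorConfig(method = "zwanzig"))
  expect_equal(ddG(leg), 2.0)
  expect_equal(semOf(leg), sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(semOf(leg), 1 / sqrt(3), tolerance = 1e-12)
  # identical replicas have zero spread
  same <- replicate(10, gaussianWorkSamples(1, 0.5, 100, seed = 4),
                    simplify = FALSE)
  leg0 <- estimateLeg(same)
  expect_equal(semOf(leg0), 0)
  # per-replica totals equal the sum of per-window contributions
  es <- harmonicToyFEP(harmonicToyModel(1, 2), toyProtocol(10, 50L), seed = 2)
  legH <- estimateLeg(list(es))
  expect_equal(legH@perReplica[1L], sum(legH@perWindow[[1L]]$dg),
               tolerance = 1e-9)
})

test_that("replicas with mismatched window structure are rejected", {
  a <- harmonicToyFEP(harmonicToyModel(1, 2), toyProtocol(10, 20L), seed = 1)
  b <- harmonicToyFEP(harmonicToyModel(1, 2), toyProtocol(12, 20L), seed = 1)
  expect_error(estimateLeg(list(a, b)), "mismatched")
})

test_that("cycle solving subtracts legs and propagates SEM in quadrature", {
  mkLeg <- function(m, s) new("FepLegResult", perReplica = m, mean = m,
                              sem = s, perWindow = list(),
                              barConstants = list(), method = "bar",
                              structure = c(1L, 2L))
  cyc <- solveCycle(mkLeg(2.0, 0.3), mkLeg(0.5, 0.4))
  expect_equal(ddG(cyc), 1.5)
  expect_equal(semOf(cyc), 0.5)
  same <- mkLeg(1.2, 0.1)
  expect_equal(ddG(solveCycle(same, same)), 0)
  # antisymmetry under leg swap
  expect_equal(ddG(solveCycle(mkLeg(2.0, 0.3), mkLeg(0.5, 0.4))),
               -ddG(solveCycle(mkLeg(0.5, 0.4), mkLeg(2.0, 0.3))))
  # protocol mismatch
  other <- new("FepLegResult", perReplica = 1, mean = 1, sem = 0,
               perWindow = list(), barConstants = list(),
               method = "zwanzig", structure = c(1L, 2L))
  expect_error(solveCycle(mkLeg(1, 0), other), "different protocols")
})

test_that("Ki ratios convert to free energies with RT ln", {
  expect_equal(kiToDdg(3.2, 3.2), 0)
  expect_equal(kiToDdg(1, 10), 0.0019872 * 298 * log(10))
  expect_equal(kiToDdg(1, 10), 1.3634, tolerance = 3e-4)
  expect_equal(kiToDdg(10, 1), -kiToDdg(1, 10))
  pair <- new("AffinityPair", kiWt = 2, kiMut = 8, temperature = 310)
  expect_equal(kiToDdg(pair), 0.0019872 * 310 * log(4))
  expect_error(kiToDdg(-1, 5), "positive|> 0")
})

test_that("energy-sample files round-trip through the tabular format", {
  es <- harmonicToyFEP(harmonicToyModel(1, 4), toyProtocol(8, 25L), seed = 6)
  f <- tempfile(fileext = ".tsv")
  writeEnergySamples(es, f)
  es2 <- readEnergySamples(f)
  expect_equal(samples(es2)$u_self, samples(es)$u_self, tolerance = 1e-12)
  expect_equal(samples(es2)$window, samples(es)$window)
  expect_equal(barDG(es2)$total, barDG(es)$total, tolerance = 1e-9)
})

test_that("malformed energy samples are rejected", {
  s <- samples(workSamples(rep(1, 5), rep(-1, 5)))
  s$u_forward[1L] <- NA   # forward series missing before the last window
  expect_error(new("EnergySamples", samples = s), "forward")
  expect_error(zwanzigDG(new("EnergySamples",
                             samples = s[s$window == 1L, ])),
               "two windows")
})
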