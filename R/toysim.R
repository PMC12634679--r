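# Toy fixture generators with closed-form free energies: Crooks-consistent
# Gaussian work distributions and a 1-D harmonic lambda-coupled system
# sampled by Metropolis Monte Carlo. These exist so that every estimator and
# cycle operation can be validated against exact answers without running
# molecular dynamics.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Gaussian work-distribution fixture
#'
#' Generates one perturbation step whose forward work is drawn from
#' N(dg + beta sigma^2/2, sigma^2) and reverse work from
#' N(-dg + beta sigma^2/2, sigma^2). This pair satisfies the Crooks
#' fluctuation relation exactly, so the true free-energy change is \code{dg}
#' by construction; with sigma = 0 every forward sample equals \code{dg}.
#'
#' @param dg true free-energy change, kcal mol^-1.
#' @param sigma work standard deviation, kcal mol^-1.
#' @param n samples per direction.
#' @param seed RNG seed (sampling is reproducible and leaves the global RNG
#'   state untouched).
#' @param temperature Kelvin.
#' @return an \linkS4class{EnergySamples} with two windows: window 1 carries
#'   the forward series, window 2 the reverse series.
#' @export
gaussianWorkSamples <- function(dg, sigma, n, seed = 1L, temperature = 298) {
  spec <- new("GaussianWorkSpec", dg = dg, sigma = sigma, n = as.integer(n),
              seed = as.integer(seed), temperature = temperature)
  beta <- 1 / (.RGAS * spec@temperature)
  .withSeed(spec@seed, {
    wF <- stats::rnorm(spec@n, mean = spec@dg + beta * spec@sigma^2 / 2,
                       sd = spec@sigma)
    wR <- stats::rnorm(spec@n, mean = -spec@dg + beta * spec@sigma^2 / 2,
                       sd = spec@sigma)
    s <- rbind(
      data.frame(stage = 1L, window = 1L, lambda = 0,
                 u_self = 0, u_forward = wF, u_reverse = NA_real_),
      data.frame(stage = 1L, window = 2L, lambda = 1,
                 u_self = 0, u_forward = NA_real_, u_reverse = wR))
    new("EnergySamples", samples = s)
  })
}

#' Exact free energy of the harmonic toy model
#'
#' Closed-form Gaussian integral: Delta G(A -> B) = ln(k_B/k_A) / (2 beta),
#' independent of the displacement d (a pure translation changes no
#' partition function).
#'
#' @param model a \linkS4class{HarmonicToyModel}.
#' @param config an \linkS4class{EstimatorConfig} (supplies the temperature).
#' @return exact Delta G in kcal mol^-1.
#' @export
analyticDG <- function(model, config = estimatorConfig()) {
  beta <- betaOf(config)
  log(model@kB / model@kA) / (2 * beta)
}

#' Harmonic toy model constructor
#'
#' @param kA,kB end-state force constants, kcal mol^-1 A^-2.
#' @param d displacement of the B-state minimum, Angstrom.
#' @return a \linkS4class{HarmonicToyModel}.
#' @export
harmonicToyModel <- function(kA, kB, d = 0)
  new("HarmonicToyModel", kA = kA, kB = kB, d = d)

#' Reduced sampling protocol for toy simulations
#'
#' 50 sigmoidal windows, 200 samples per window, chosen to keep one replica
#' of the 1-D toy under a second while retaining negligible
#' lambda-discretization bias.
#'
#' @param windows,stepsPerWindow,spacing overridable parameters.
#' @return a \linkS4class{FepProtocol}.
#' @export
toyProtocol <- function(windows = 50L, stepsPerWindow = 200L,
                        spacing = "sigmoidal")
  buildProtocol("custom", windows = windows, stepsPerWindow = stepsPerWindow,
                timestepFs = 2, spacing = spacing)

.uLambda <- function(x, lam, model)
  (1 - lam) * 0.5 * model@kA * x^2 + lam * 0.5 * model@kB * (x - model@d)^2

#' Sample the harmonic toy model along a lambda path
#'
#' Metropolis Monte Carlo on the 1-D coordinate under
#' U_lambda = U_A + lambda (U_B - U_A), one chain per window, recording at
#' every production step the potential energy at the window's own lambda and
#' at the neighboring lambdas. The proposal step size is adapted during
#' equilibration only, targeting an acceptance fraction in [0.3, 0.7];
#' production uses the frozen step size so the chain remains a valid
#' Metropolis sampler.
#'
#' @param model a \linkS4class{HarmonicToyModel}.
#' @param protocol a \linkS4class{FepProtocol}; the first stage's schedule
#'   defines the lambda path and its steps-per-window the production length
#'   (the toy exercises a single subperturbation).
#' @param nEquil equilibration steps per window (default 100).
#' @param seed RNG seed.
#' @param config an \linkS4class{EstimatorConfig} (temperature).
#' @return an \linkS4class{EnergySamples} covering every window.
#' @export
harmonicToyFEP <- function(model, protocol = toyProtocol(), nEquil = 100L,
                           seed = 1L, config = estimatorConfig()) {
  st <- protocol@stages[[1L]]
  lam <- st@schedule@lambdas
  nProd <- st@stepsPerWindow
  beta <- betaOf(config)
  .withSeed(seed, {
    x <- 0
    delta <- 1 / sqrt(beta * max(model@kA, model@kB))
    rows <- vector("list", length(lam))
    for (i in seq_along(lam)) {
      li <- lam[i]
      # equilibration with step-size adaptation
      acc <- 0L
      for (s in seq_len(nEquil)) {
        xp <- x + stats::runif(1L, -delta, delta)
        if (stats::runif(1L) < exp(-beta * (.uLambda(xp, li, model) -
                                            .uLambda(x, li, model)))) {
          x <- xp; acc <- acc + 1L
        }
        if (s %% 25L == 0L) {
          frac <- acc / 25
          if (frac > 0.7) delta <- delta * 1.25
          if (frac < 0.3) delta <- delta / 1.25
          acc <- 0L
        }
      }
      xs <- numeric(nProd)
      u0 <- .uLambda(x, li, model)
      for (s in seq_len(nProd)) {
        xp <- x + stats::runif(1L, -delta, delta)
        up <- .uLambda(xp, li, model)
        if (stats::runif(1L) < exp(-beta * (up - u0))) { x <- xp; u0 <- up }
        xs[s] <- x
      }
      rows[[i]] <- data.frame(
        stage = 1L, window = i, lambda = li,
        u_self = .uLambda(xs, li, model),
        u_forward = if (i < length(lam)) .uLambda(xs, lam[i + 1L], model)
                    else NA_real_,
        u_reverse = if (i > 1L) .uLambda(xs, lam[i - 1L], model)
                    else NA_real_)
    }
    new("EnergySamples", samples = do.call(rbind, rows))
  })
}

#' Replica set of harmonic toy samples
#'
#' @param model a \linkS4class{HarmonicToyModel}.
#' @param protocol a \linkS4class{FepProtocol}; its replica count sets the
#'   list length.
#' @param seed base seed; replica r uses seed + r - 1.
#' @param nEquil equilibration steps per window.
#' @param config an \linkS4class{EstimatorConfig}.
#' @return list of \linkS4class{EnergySamples}.
#' @export
harmonicToyReplicas <- function(model, protocol = toyProtocol(), seed = 1L,
                                nEquil = 100L, config = estimatorConfig()) {
  lapply(seq_len(protocol@replicas), function(r)
    harmonicToyFEP(model, protocol, nEquil = nEquil, seed = seed + r - 1L,
                   config = config))
}

#' Two-leg toy cycle fixture with exact answer
#'
#' Samples both harmonic legs with independent seeds and attaches the
#' closed-form Delta Delta G, exercising the full estimate-then-solve cycle
#' pipeline end to end.
#'
#' @param legA,legB \linkS4class{HarmonicToyModel} legs.
#' @param protocol a \linkS4class{FepProtocol}.
#' @param seedA,seedB base seeds for the two legs.
#' @param nEquil equilibration steps per window.
#' @param config an \linkS4class{EstimatorConfig}.
#' @return a \linkS4class{ToyCycleFixture}.
#' @export
cycleFixture <- function(legA, legB, protocol = toyProtocol(),
                         seedA = 1L, seedB = 10001L, nEquil = 100L,
                         config = estimatorConfig()) {
  sa <- harmonicToyReplicas(legA, protocol, seed = seedA, nEquil = nEquil,
                            config = config)
  sb <- harmonicToyReplicas(legB, protocol, seed = seedB, nEquil = nEquil,
                            config = config)
  new("ToyCycleFixture", legA = legA, legB = legB,
      exactDdg = analyticDG(legA, config) - analyticDG(legB, config),
      samplesA = sa, samplesB = sb)
}
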