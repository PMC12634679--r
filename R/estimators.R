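# Free-energy estimators: exponential (Zwanzig) averaging, Bennett
# acceptance ratio, replica aggregation with SEM, thermodynamic cycles and
# affinity conversion.

#' Estimator configuration
#'
#' @param temperature Kelvin (default 298).
#' @param method "bar" or "zwanzig".
#' @param tolerance convergence tolerance on the BAR constant, kcal mol^-1.
#' @param maxIterations iteration cap for the BAR root search.
#' @return an \linkS4class{EstimatorConfig}.
#' @export
estimatorConfig <- function(temperature = 298, method = c("bar", "zwanzig"),
                            tolerance = 1e-7, maxIterations = 500L) {
  method <- match.arg(method)
  new("EstimatorConfig", temperature = temperature, method = method,
      tolerance = tolerance, maxIterations = as.integer(maxIterations))
}

#' Inverse temperature beta = 1/(R T)
#'
#' Uses R = 1.9872e-3 kcal mol^-1 K^-1.
#'
#' @param config an \linkS4class{EstimatorConfig}.
#' @return beta in mol kcal^-1.
#' @export
betaOf <- function(config) 1 / (.RGAS * config@temperature)

# Split one replica's samples into per-interface forward/reverse work lists.
# Interface i of a stage joins window i (forward work = u_forward - u_self)
# and window i+1 (reverse work = u_reverse - u_self).
.interfaces <- function(es) {
  s <- samples(es)
  out <- list()
  for (st in sort(unique(s$stage))) {
    ss <- s[s$stage == st, , drop = FALSE]
    wins <- sort(unique(ss$window))
    for (j in seq_len(length(wins) - 1L)) {
      wi <- ss[ss$window == wins[j], , drop = FALSE]
      wn <- ss[ss$window == wins[j + 1L], , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        stage = st, interface = j,
        wF = wi$u_forward - wi$u_self,
        wR = wn$u_reverse - wn$u_self)
    }
  }
  out
}

#' Zwanzig exponential free-energy estimate
#'
#' Per interface i, Delta G_i = -beta^-1 ln < exp(-beta (U_(i+1) - U_i)) >_i
#' computed with a numerically stable log-sum-exp; the leg total is the sum
#' over interfaces of all stages. Forward-only by default (the reverse
#' series is unused).
#'
#' @param es an \linkS4class{EnergySamples} (one replica).
#' @param config an \linkS4class{EstimatorConfig}.
#' @return list with \code{perWindow} (data.frame stage, interface, dg) and
#'   \code{total} (kcal mol^-1).
#' @export
zwanzigDG <- function(es, config = estimatorConfig(method = "zwanzig")) {
  beta <- betaOf(config)
  ifs <- .interfaces(es)
  if (!length(ifs)) stop("need at least two windows")
  pw <- do.call(rbind, lapply(ifs, function(f) {
    if (!length(f$wF) || anyNA(f$wF)) stop("empty or incomplete forward series")
    data.frame(stage = f$stage, interface = f$interface,
               dg = -logMeanExp(-beta * f$wF) / beta)
  }))
  list(perWindow = pw, total = sum(pw$dg))
}

# Fermi-weighted BAR score function; root in dg is the BAR estimate.
# Uses plogis for overflow-free logistic evaluation.
.barScore <- function(dg, wF, wR, beta, M) {
  sum(stats::plogis(-(M + beta * (wF - dg)))) -
    sum(stats::plogis(-(-M + beta * (wR + dg))))
}

.barOne <- function(wF, wR, beta, tol, maxit) {
  if (!length(wF) || !length(wR)) stop("BAR needs forward and reverse series")
  M <- log(length(wF) / length(wR))
  f <- function(x) .barScore(x, wF, wR, beta, M)
  # monotone increasing in dg: bracket by expansion around the midpoint guess
  x0 <- (mean(wF) - mean(wR)) / 2
  if (f(x0) == 0) return(x0)  # degenerate perfect-overlap fixed point
  lo <- x0 - 1; hi <- x0 + 1
  it <- 0L
  while (f(lo) > 0 && it < maxit) { lo <- lo - 2 * (x0 - lo + 1); it <- it + 1L }
  while (f(hi) < 0 && it < maxit) { hi <- hi + 2 * (hi - x0 + 1); it <- it + 1L }
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf("BAR bracketing failed after %d iterations (residual %.3g)",
                 it, min(abs(f(lo)), abs(f(hi)))))
  r <- stats::uniroot(f, c(lo, hi), tol = tol, maxiter = maxit)
  if (abs(r$estim.prec) > max(tol * 100, 1e-4))
    warning(sprintf("BAR root search converged loosely (precision %.3g)",
                    r$estim.prec))
  r$root
}

#' Bennett acceptance ratio free-energy estimate
#'
#' Per interface, the BAR constant C_i is found by a bracketed root search on
#' the implicit acceptance-ratio equation (the weighted forward and reverse
#' Fermi-function averages are made equal), to within the configured
#' tolerance; at convergence Delta G_i = C_i. Requires forward samples from
#' window i and reverse samples from window i+1. Interfaces whose forward
#' and negated-reverse work distributions do not overlap at all are flagged
#' with a warning attached to the result.
#'
#' @param es an \linkS4class{EnergySamples} (one replica).
#' @param config an \linkS4class{EstimatorConfig}.
#' @return list with \code{perWindow} (data.frame stage, interface, dg),
#'   \code{constants} (the converged C_i), \code{total}, and
#'   \code{warnings} (character, possibly empty).
#' @export
barDG <- function(es, config = estimatorConfig()) {
  beta <- betaOf(config)
  ifs <- .interfaces(es)
  if (!length(ifs)) stop("need at least two windows")
  warns <- character(0)
  pw <- do.call(rbind, lapply(ifs, function(f) {
    if (anyNA(f$wF) || anyNA(f$wR)) stop("incomplete forward/reverse series")
    if (min(f$wF) > max(-f$wR) || max(f$wF) < min(-f$wR))
      warns <<- c(warns, sprintf(
        "stage %d interface %d: forward and reverse work distributions do not overlap",
        f$stage, f$interface))
    dg <- .barOne(f$wF, f$wR, beta, config@tolerance, config@maxIterations)
    data.frame(stage = f$stage, interface = f$interface, dg = dg)
  }))
  list(perWindow = pw, constants = pw$dg, total = sum(pw$dg),
       warnings = warns)
}

#' Estimate one FEP leg from replica samples
#'
#' Applies the configured estimator to each replica and aggregates: the leg
#' free energy is the arithmetic mean over replicas and its uncertainty the
#' standard error of the mean (sample standard deviation with n-1
#' denominator over sqrt of the replica count).
#'
#' @param replicaSamples list of \linkS4class{EnergySamples}, one per replica.
#' @param config an \linkS4class{EstimatorConfig}.
#' @return a \linkS4class{FepLegResult}.
#' @export
estimateLeg <- function(replicaSamples, config = estimatorConfig()) {
  if (!length(replicaSamples)) stop("need at least one replica")
  key <- function(es) {
    s <- samples(es)
    u <- unique(s[, c("stage", "window", "lambda")])
    paste(u$stage, u$window, signif(u$lambda, 12), collapse = ";")
  }
  k1 <- key(replicaSamples[[1L]])
  if (!all(vapply(replicaSamples, key, character(1L)) == k1))
    stop("replicas have mismatched window structure")
  est <- lapply(replicaSamples, function(es)
    if (config@method == "bar") barDG(es, config) else zwanzigDG(es, config))
  per <- vapply(est, function(e) e$total, numeric(1L))
  n <- length(per)
  semv <- if (n > 1L) stats::sd(per) / sqrt(n) else 0
  s1 <- samples(replicaSamples[[1L]])
  struct <- c(stages = length(unique(s1$stage)),
              windows = length(unique(paste(s1$stage, s1$window))))
  new("FepLegResult", perReplica = per, mean = mean(per), sem = semv,
      perWindow = lapply(est, function(e) e$perWindow),
      barConstants = if (config@method == "bar")
        lapply(est, function(e) e$constants) else list(),
      method = config@method, structure = as.integer(struct))
}

#' Solve a two-leg thermodynamic cycle
#'
#' Delta Delta G = Delta G(leg A) - Delta G(leg B) with the SEMs of the two
#' legs propagated in quadrature. For a stability cycle, leg A is the folded
#' protein and leg B the reference peptide (unfolded state); for
#' ligand-binding cycles the legs are holo/apo, and for protein-protein
#' cycles complex/free monomer.
#'
#' @param legA,legB \linkS4class{FepLegResult} objects computed with the same
#'   estimator and window structure.
#' @param kind "stability", "ligand-binding" or "PPI".
#' @return a \linkS4class{CycleResult}.
#' @export
solveCycle <- function(legA, legB,
                       kind = c("stability", "ligand-binding", "PPI")) {
  kind <- match.arg(kind)
  if (legA@method != legB@method ||
      !identical(legA@structure, legB@structure))
    stop("legs were computed with different protocols (method or window structure)")
  new("CycleResult", ddg = legA@mean - legB@mean,
      sem = sqrt(legA@sem^2 + legB@sem^2),
      legA = legA, legB = legB, kind = kind)
}

#' Convert a Ki pair to a relative binding free energy
#'
#' Delta Delta G = R T ln(Ki_mut / Ki_wt), kcal mol^-1.
#'
#' @param pair an \linkS4class{AffinityPair}, or the wild-type Ki when the
#'   mutant Ki is given via \code{kiMut}.
#' @param kiMut mutant Ki (same units as the wild-type value).
#' @param temperature Kelvin (default 298; ignored when \code{pair} is an
#'   \linkS4class{AffinityPair}, which carries its own).
#' @return Delta Delta G in kcal mol^-1.
#' @examples
#' kiToDdg(1, 10)   # tenfold affinity loss: +1.3634 kcal/mol at 298 K
#' @export
kiToDdg <- function(pair, kiMut = NULL, temperature = 298) {
  if (is(pair, "AffinityPair")) {
    kw <- pair@kiWt; km <- pair@kiMut; temp <- pair@temperature
  } else {
    kw <- pair; km <- kiMut; temp <- temperature
  }
  if (is.null(km)) stop("mutant Ki missing")
  if (kw <= 0 || km <= 0) stop("Ki values must be positive")
  .RGAS * temp * log(km / kw)
}

# --- energy-sample file I/O -------------------------------------------------

#' Write energy samples to a tabular text file
#'
#' One file per (leg, replica): tab-separated columns stage, window, lambda,
#' u_self, u_forward, u_reverse, with a commented header. NA marks the
#' absent forward series of a stage's last window and reverse series of its
#' first window.
#'
#' @param es an \linkS4class{EnergySamples}.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeEnergySamples <- function(es, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "# energy samples: one row per recorded MD sample",
    "# u_self/u_forward/u_reverse: potential energy (kcal/mol) at the window's",
    "# own lambda, the next lambda, and the previous lambda",
    paste("stage", "window", "lambda", "u_self", "u_forward", "u_reverse",
          sep = "\t")), con)
  s <- samples(es)
  utils::write.table(s, con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(file)
}

#' Read energy samples written by \code{writeEnergySamples}
#'
#' @param file path to a sample file.
#' @return an \linkS4class{EnergySamples}.
#' @export
readEnergySamples <- function(file) {
  s <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                         na.strings = "NA")
  new("EnergySamples", samples = s)
}
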