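## run expr under a fixed RNG seed without disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a positional deacetylation rate model
#'
#' Rates can be given per position (\code{rates}), or by position class:
#' non-reducing end (position 1), internal (2..DP-1) and reducing end
#' (position DP).  The class defaults encode the positional preference
#' seen for CE4 chitooligosaccharide deacetylases — internal sugars most
#' reactive, the non-reducing end an order of magnitude slower, the
#' reducing end slower still — with arbitrary absolute magnitudes, since
#' only the ordering is established.
#'
#' @param dp degree of polymerization (1-12)
#' @param rates optional numeric vector of per-position rate constants
#'   (s^-1), length \code{dp}; overrides the class rates
#' @param internal,nonReducingEnd,reducingEnd class rate constants
#'   (s^-1) used when \code{rates} is NULL
#' @param neighborPenalty multiplicative factor in (0, 1] applied to a
#'   position's rate once per already-deacetylated adjacent residue;
#'   1 (default) makes positions independent
#' @return a \linkS4class{RateModel}
#' @examples
#' rateModel(5)
#' rateModel(5, rates = c(0, 1, 1, 1, 0.2) * 1e-3)
#' @export
rateModel <- function(dp, rates = NULL, internal = 1e-3,
                      nonReducingEnd = 1e-4, reducingEnd = 2.5e-5,
                      neighborPenalty = 1) {
  stopifnot(dp >= 1L, dp <= 12L)
  if (is.null(rates)) {
    rates <- rep(internal, dp)
    rates[1L] <- nonReducingEnd
    rates[dp] <- reducingEnd
    if (dp == 1L) rates <- reducingEnd
  }
  if (length(rates) != dp)
    stop("rates must have one entry per position (length ", dp, ")")
  if (any(rates < 0)) stop("rate constants must be non-negative")
  new("RateModel", rates = as.numeric(rates),
      neighborPenalty = neighborPenalty)
}

setMethod("show", "RateModel", function(object) {
  cat("RateModel over", length(object@rates),
      "positions (non-reducing -> reducing end)\n")
  cat("  k (s^-1):", paste(format(object@rates, digits = 4),
                           collapse = " "), "\n")
  cat("  neighbor penalty:", object@neighborPenalty, "\n")
})

## per-molecule Gillespie trajectory: returns the deacetylation time of
## every position (Inf if never).  Rates shrink by penalty^(deacetylated
## neighbors), so each event recomputes the hazard of the survivors.
gillespieMolecule <- function(rates, penalty) {
  dp <- length(rates)
  tDeac <- rep(Inf, dp)
  state <- rep(FALSE, dp)   # TRUE = deacetylated
  now <- 0
  repeat {
    nb <- vapply(seq_len(dp), function(i) {
      sum(state[c(i - 1L, i + 1L)[c(i > 1L, i < dp)]])
    }, numeric(1L))
    hz <- ifelse(state, 0, rates * penalty^nb)
    total <- sum(hz)
    if (total <= 0) break
    now <- now + stats::rexp(1L, total)
    j <- sample.int(dp, 1L, prob = hz)
    state[j] <- TRUE
    tDeac[j] <- now
  }
  tDeac
}

#' Simulate an ensemble of sequentially deacetylated CHOS molecules
#'
#' Continuous-time Markov simulation of enzymatic deacetylation: every
#' acetylated position carries an exponential clock with its model rate.
#' With \code{neighborPenalty = 1} positions are independent and the
#' clocks are sampled directly; with a penalty < 1 a Gillespie algorithm
#' re-evaluates the hazards after each event (subsequent deacetylations
#' next to an existing D are slower).  Fully reproducible under a fixed
#' seed.
#'
#' @param dp degree of polymerization
#' @param model a \linkS4class{RateModel} with \code{dp} positions
#' @param times numeric vector of observation times (s)
#' @param nMolecules ensemble size
#' @param seed integer RNG seed
#' @return list with elements \code{times}, \code{patternFreq} (one
#'   named frequency vector per time point, frequencies summing to 1),
#'   \code{acetatePerMolecule} (expected A -> D conversions per molecule
#'   at each time), \code{dp}, \code{nMolecules}
#' @examples
#' sim <- simulateDeacetylation(5, rateModel(5), times = c(600, 3600),
#'                              nMolecules = 500, seed = 7)
#' sim$patternFreq[[2]]
#' @export
simulateDeacetylation <- function(dp, model, times, nMolecules = 1000L,
                                  seed = 1L) {
  stopifnot(is(model, "RateModel"), dp >= 1L, dp <= 12L, nMolecules >= 1L,
            all(times >= 0))
  if (length(model@rates) != dp)
    stop("model has ", length(model@rates), " positions, dp is ", dp)
  k <- model@rates
  tDeac <- withSeed(seed, {
    if (model@neighborPenalty == 1) {
      ## independent exponential clocks, vectorized
      m <- matrix(Inf, nrow = nMolecules, ncol = dp)
      for (i in seq_len(dp))
        if (k[i] > 0) m[, i] <- stats::rexp(nMolecules, k[i])
      m
    } else {
      t(vapply(seq_len(nMolecules), function(.)
        gillespieMolecule(k, model@neighborPenalty), numeric(dp)))
    }
  })
  patternFreq <- vector("list", length(times))
  acetate <- numeric(length(times))
  for (ti in seq_along(times)) {
    isD <- tDeac <= times[ti]
    pats <- apply(isD, 1L, function(z)
      paste0(ifelse(z, "D", "A"), collapse = ""))
    tab <- table(pats) / nMolecules
    patternFreq[[ti]] <- stats::setNames(as.numeric(tab), names(tab))
    acetate[ti] <- mean(rowSums(isD))
  }
  list(times = times, patternFreq = patternFreq,
       acetatePerMolecule = acetate, dp = dp, nMolecules = nMolecules)
}

#' Closed-form positional occupancy for independent positions
#'
#' With no neighbor penalty each position deacetylates independently, so
#' the probability that position i is deacetylated at time t is
#' P_i(t) = 1 - exp(-k_i t) and the expected acetate release per
#' molecule is the sum of the P_i.
#'
#' @param dp degree of polymerization
#' @param model a \linkS4class{RateModel} with \code{neighborPenalty = 1}
#' @param t time (s)
#' @return list with \code{p} (per-position D probabilities) and
#'   \code{expectedAcetate}
#' @examples
#' analyticOccupancy(5, rateModel(5, rates = c(0, 1, 1, 1, 0.2) * 1e-3),
#'                   t = 693)
#' @export
analyticOccupancy <- function(dp, model, t) {
  stopifnot(is(model, "RateModel"), length(model@rates) == dp, t >= 0)
  if (model@neighborPenalty != 1)
    stop("closed form holds only for independent positions ",
         "(neighborPenalty = 1)")
  p <- 1 - exp(-model@rates * t)
  names(p) <- paste0("pos", seq_len(dp))
  list(p = p, expectedAcetate = sum(p))
}
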