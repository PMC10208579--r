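# Steady-state model of the stripe-forming incoherent feedforward loop.
#
# The sensor is activated by arabinose; it represses both the regulator
# and the output. The regulator also represses the output. At low inducer
# the regulator is fully expressed and shuts the output off; at high
# inducer the sensor itself shuts the output off; in between neither
# repressor dominates and the output peaks, producing the low-high-low
# "stripe" along the gradient. The circuit is modelled algebraically with
# standard activating/repressing Hill terms evaluated at steady state;
# node expression is
#
#   S(a) = beta_S * (b_S + (1 - b_S) * a^n_a / (K_a^n_a + a^n_a))
#   R(S) = beta_R * (b_R + (1 - b_R) * rep(S; K_SR, n_SR))
#   O(S, R) = scale * beta_O * (b_O + (1 - b_O) * rep(S; K_SO, n_SO)
#                                              * rep(R; K_RO, n_RO))
#
# with rep(x; K, n) = K^n / (K^n + x^n) and b_* a basal fraction.

hill_act <- function(x, K, n) {
  ifelse(x <= 0, 0, x^n / (K^n + x^n))
}

hill_rep <- function(x, K, n) K^n / (K^n + x^n)

#' Circuit parameters for the stripe network
#'
#' Default parameters are tuned so that the wild-type output expression is
#' strictly highest at the medium (0.0002% arabinose) of the three assay
#' concentrations, i.e. the network shows a stripe.
#'
#' @param beta Maximal promoter rates, named `c(sensor=, regulator=,
#'   output=)`, arbitrary units.
#' @param basal Basal expression fraction per node, in `[0, 1]`.
#' @param K_a Arabinose concentration (% w/v) of half-maximal sensor
#'   activation; `n_a` its Hill coefficient.
#' @param n_a Hill coefficient of inducer activation.
#' @param K_SR,n_SR Repression of the regulator by the sensor: sensor
#'   level (a.u.) of half repression and Hill coefficient.
#' @param K_SO,n_SO Repression of the output by the sensor.
#' @param K_RO,n_RO Repression of the output by the regulator.
#' @param scale Reporter scale factor (a.u.) applied to the output node.
#' @return A list of class `circuit_params`.
#' @export
circuit_params <- function(beta = c(sensor = 100, regulator = 50, output = 1000),
                           basal = c(sensor = 0.01, regulator = 0.01, output = 0.01),
                           K_a = 5e-4, n_a = 1,
                           K_SR = 10, n_SR = 2,
                           K_SO = 30, n_SO = 2,
                           K_RO = 5, n_RO = 2,
                           scale = 1) {
  p <- list(beta = beta[nodes()], basal = basal[nodes()],
            K_a = K_a, n_a = n_a, K_SR = K_SR, n_SR = n_SR,
            K_SO = K_SO, n_SO = n_SO, K_RO = K_RO, n_RO = n_RO,
            scale = scale)
  if (any(unlist(p$beta) <= 0) || any(c(K_a, K_SR, K_SO, K_RO, scale) <= 0)) {
    stop("rates, repression constants and scale must be positive")
  }
  if (any(c(n_a, n_SR, n_SO, n_RO) < 1)) stop("Hill coefficients must be >= 1")
  if (any(p$basal < 0 | p$basal > 1)) stop("basal fractions must lie in [0, 1]")
  structure(p, class = "circuit_params")
}

#' Cis-regulatory mutation effect
#'
#' A mutant allele perturbs only the cis-regulatory region of its own
#' node: multiplicatively on the node's maximal promoter rate (promoter
#' mutations) and on the binding constants of the regulatory inputs acting
#' at that node (operator mutations). For the sensor the "operator" input
#' is the inducer response (`K_a`); for the regulator it is repression by
#' the sensor (`K_SR`); for the output it is repression by the sensor
#' (`K_SO`) and by the regulator (`K_RO`).
#'
#' @param node One of `"sensor"`, `"regulator"`, `"output"`.
#' @param beta_mult Multiplier (> 0) on the node's promoter rate.
#' @param operator_mult Named numeric multipliers (> 0) on the K of each
#'   regulatory input at this node; unnamed scalars apply to all inputs of
#'   the node. Multipliers of 1 leave the allele wild type.
#' @return A list of class `mutation_effect`.
#' @export
mutation_effect <- function(node, beta_mult = 1, operator_mult = 1) {
  node <- match.arg(node, nodes())
  valid <- switch(node, sensor = "K_a", regulator = "K_SR",
                  output = c("K_SO", "K_RO"))
  if (is.null(names(operator_mult))) {
    operator_mult <- stats::setNames(rep(operator_mult[[1]], length(valid)), valid)
  }
  if (!all(names(operator_mult) %in% valid)) {
    stop("operator_mult names must be among: ", paste(valid, collapse = ", "))
  }
  if (beta_mult <= 0 || any(operator_mult <= 0)) {
    stop("multipliers must be positive")
  }
  structure(list(node = node, beta_mult = beta_mult,
                 operator_mult = operator_mult),
            class = "mutation_effect")
}

apply_effects <- function(params, effects) {
  if (length(effects) == 0L) return(params)
  hit <- vapply(effects, function(e) e$node, character(1))
  if (anyDuplicated(hit)) stop("at most one mutation effect per node")
  for (e in effects) {
    params$beta[[e$node]] <- params$beta[[e$node]] * e$beta_mult
    for (k in names(e$operator_mult)) {
      params[[k]] <- params[[k]] * e$operator_mult[[k]]
    }
  }
  params
}

#' Steady-state expression of the circuit
#'
#' @param params A [circuit_params()] object.
#' @param effects List of [mutation_effect()]s (at most one per node), or
#'   `NULL` for the wild type.
#' @param inducer Arabinose concentration(s), % w/v, non-negative;
#'   vectorized.
#' @param node Node whose steady-state expression to return; default the
#'   output (reporter) node.
#' @return Numeric vector of noiseless steady-state expression (a.u.),
#'   strictly positive.
#' @export
steady_state <- function(params, effects = NULL, inducer = 0,
                         node = c("output", "sensor", "regulator")) {
  node <- match.arg(node)
  if (any(inducer < 0)) stop("inducer concentration must be non-negative")
  p <- apply_effects(params, effects)
  S <- p$beta[["sensor"]] *
    (p$basal[["sensor"]] + (1 - p$basal[["sensor"]]) * hill_act(inducer, p$K_a, p$n_a))
  if (node == "sensor") return(S)
  R <- p$beta[["regulator"]] *
    (p$basal[["regulator"]] + (1 - p$basal[["regulator"]]) * hill_rep(S, p$K_SR, p$n_SR))
  if (node == "regulator") return(R)
  p$scale * p$beta[["output"]] *
    (p$basal[["output"]] + (1 - p$basal[["output"]]) *
       hill_rep(S, p$K_SO, p$n_SO) * hill_rep(R, p$K_RO, p$n_RO))
}

#' Does a set of expression values form a stripe?
#'
#' @param low,medium,high Output expression at the three assay inducer
#'   concentrations.
#' @return Logical: `TRUE` when the medium value is strictly the largest.
#' @export
is_stripe <- function(low, medium, high) {
  medium > low & medium > high
}

#' Draw mutant allele effects that preserve the stripe
#'
#' Samples, for each node, `mutants_per_node` mutant alleles as
#' multiplicative perturbations of that node's promoter rate and operator
#' binding constants (log-uniform in `range`). Alleles whose single-mutant
#' network does not itself form a stripe at the given inducer levels are
#' rejected and redrawn, mirroring a library from which only
#' stripe-retaining mutants were kept.
#'
#' @param params A [circuit_params()] object.
#' @param mutants_per_node Alleles per node (M).
#' @param levels Numeric inducer concentrations `c(low, medium, high)`
#'   used for the stripe check.
#' @param range Two-sided multiplier range; multipliers are drawn
#'   log-uniformly between `range[1]` and `range[2]`.
#' @param max_tries Rejection-sampling cap per allele.
#' @return Nested list `effects[[node]][[allele_index]]`, each entry a
#'   list of one [mutation_effect()].
#' @export
draw_mutant_effects <- function(params, mutants_per_node = 10L,
                                levels = c(0, 2e-4, 0.2),
                                range = c(1 / 2.5, 2.5),
                                max_tries = 1000L) {
  stopifnot(length(levels) == 3L, range[1] > 0, range[2] > range[1])
  lr <- log(range)
  draw_mult <- function(k) exp(stats::runif(k, lr[1], lr[2]))
  effects <- list()
  for (nd in nodes()) {
    n_ops <- switch(nd, sensor = 1L, regulator = 1L, output = 2L)
    effects[[nd]] <- vector("list", mutants_per_node)
    for (i in seq_len(mutants_per_node)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        eff <- mutation_effect(nd, beta_mult = draw_mult(1L),
                               operator_mult = switch(nd,
                                 sensor = c(K_a = draw_mult(1L)),
                                 regulator = c(K_SR = draw_mult(1L)),
                                 output = c(K_SO = draw_mult(1L), K_RO = draw_mult(1L))))
        out <- steady_state(params, list(eff), levels)
        if (is_stripe(out[1], out[2], out[3])) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw a stripe-retaining mutant for node ", nd)
      effects[[nd]][[i]] <- list(eff)
    }
  }
  effects
}
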