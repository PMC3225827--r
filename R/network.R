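#' Propensity definitions
#'
#' Declarative propensity definitions for the channels of a reaction
#' network.  Keeping propensities declarative (a kind plus parameters,
#' rather than an opaque function) lets networks round-trip through plain
#' text configuration files and lets the simulation kernels evaluate them
#' in compiled code.
#'
#' * `mass_action(rate, reactants)` defines a mass-action channel.  The
#'   propensity at state `x` is `rate * prod_i x_i (x_i - 1) ... (x_i -
#'   rho_i + 1) / rho_i!` over the reactant multiplicities `rho_i`, i.e.
#'   the number of distinct reactant combinations: `x*(x-1)/2` for two
#'   identical molecules, `x*(x-1)*(x-2)/6` for three — not
#'   concentration-style powers.  `reactants` is a named integer vector of
#'   multiplicities (names are species); an empty vector gives a
#'   zeroth-order (constant) channel.
#' * `linear_propensity(coef)` defines a unimolecular/linear channel with
#'   `a(x) = sum_i c_i x_i`; `coef` is named by species or a full-length
#'   vector.  All coefficients must be nonnegative.
#' * `fn_propensity(fn)` wraps an arbitrary function `a(x) >= 0`.  It is
#'   an escape hatch for experimentation: networks containing function
#'   propensities cannot be serialized and are simulated by the (slower)
#'   pure-R kernels.
#'
#' @param rate nonnegative rate constant.
#' @param reactants named integer vector of reactant multiplicities.
#' @param coef named (or full-length) nonnegative coefficient vector.
#' @param fn function of the state vector returning a scalar propensity.
#' @return An object of class `"propensity"` describing one channel.
#' @seealso [reaction_network()]
#' @export
mass_action <- function(rate, reactants = integer()) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  if (length(reactants)) {
    stopifnot(!is.null(names(reactants)), all(reactants >= 1))
    storage.mode(reactants) <- "integer"
  }
  structure(list(kind = "mass_action", rate = as.numeric(rate),
                 reactants = reactants),
            class = "propensity")
}

#' @rdname mass_action
#' @export
linear_propensity <- function(coef) {
  stopifnot(is.numeric(coef), all(coef >= 0))
  structure(list(kind = "linear", coef = coef), class = "propensity")
}

#' @rdname mass_action
#' @export
fn_propensity <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(kind = "function", fn = fn), class = "propensity")
}

#' Well-stirred reaction network
#'
#' Bundles the two sets of quantities that characterise a chemical
#' reaction system — the stoichiometric update vectors `nu_j` and the
#' propensity functions `a_j(x)` — together with species names and an
#' integer initial state.
#'
#' @param species character vector of `N` species names.
#' @param nu stoichiometry: a list of `m` integer vectors of length `N`,
#'   or an `N x m` integer matrix (one column per channel).
#' @param propensities list of `m` [propensity][mass_action] definitions.
#' @param initial_state integer vector of length `N`, entries `>= 0`.
#' @return An object of class `"reaction_network"` with fields `species`,
#'   `nu` (an `N x m` matrix), `propensities`, `initial_state`, `N`, `m`.
#' @examples
#' net <- isomerisation_network(k1 = 10, k2 = 10, T = 200)
#' propensities(net, c(100, 100))
#' drift(net, c(100, 100))
#' @export
reaction_network <- function(species, nu, propensities, initial_state) {
  species <- as.character(species)
  N <- length(species)
  if (is.list(nu)) nu <- do.call(cbind, nu)
  nu <- as.matrix(nu)
  storage.mode(nu) <- "double"
  m <- ncol(nu)
  if (N < 1L || m < 1L) stop("need at least one species and one channel")
  if (nrow(nu) != N)
    stop("every update vector must have length ", N)
  if (any(nu != round(nu))) stop("stoichiometric entries must be integers")
  if (!is.list(propensities) || length(propensities) != m)
    stop("need one propensity definition per channel (", m, ")")
  propensities <- lapply(propensities, function(p) {
    if (!inherits(p, "propensity")) stop("propensities must be built with ",
      "mass_action(), linear_propensity() or fn_propensity()")
    if (p$kind == "mass_action" && length(p$reactants)) {
      bad <- setdiff(names(p$reactants), species)
      if (length(bad)) stop("unknown reactant species: ",
                            paste(bad, collapse = ", "))
    }
    if (p$kind == "linear") {
      co <- p$coef
      if (!is.null(names(co)) && any(nzchar(names(co)))) {
        full <- stats::setNames(numeric(N), species)
        bad <- setdiff(names(co), species)
        if (length(bad)) stop("unknown species in linear coefficients: ",
                              paste(bad, collapse = ", "))
        full[names(co)] <- co
        p$coef <- unname(full)
      } else if (length(co) != N) {
        stop("linear coefficient vector must have length ", N)
      } else p$coef <- unname(as.numeric(co))
    }
    p
  })
  if (length(initial_state) != N)
    stop("initial_state must have length ", N)
  if (any(initial_state < 0) || any(initial_state != round(initial_state)))
    stop("initial_state must be nonnegative integers")
  dimnames(nu) <- list(species, NULL)
  structure(list(species = species, nu = nu, propensities = propensities,
                 initial_state = as.numeric(initial_state), N = N, m = m),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", x$N, " species (",
      paste(x$species, collapse = ", "), "), ", x$m, " channels\n", sep = "")
  kinds <- vapply(x$propensities, `[[`, "", "kind")
  cat("  propensity kinds:", paste(unique(kinds), collapse = ", "), "\n")
  cat("  initial state:", paste(x$initial_state, collapse = " "), "\n")
  invisible(x)
}

eval_one_propensity <- function(p, x, species) {
  switch(p$kind,
    mass_action = {
      a <- p$rate
      if (length(p$reactants)) {
        idx <- match(names(p$reactants), species)
        for (k in seq_along(idx)) {
          xi <- x[idx[k]]; rho <- p$reactants[k]
          for (q in 0:(rho - 1L)) a <- a * (xi - q)
          a <- a / factorial(rho)
        }
      }
      a
    },
    linear = sum(p$coef * x),
    `function` = p$fn(x),
    stop("unknown propensity kind: ", p$kind))
}

#' Evaluate channel propensities
#'
#' Evaluates the stored propensity definitions of every channel at a state
#' `x`.  The state may be non-integer (Runge-Kutta stage values are
#' real-valued) and no clamping is applied: mass-action formulas are
#' evaluated as written even at slightly negative stage excursions.
#'
#' @param net a [reaction_network()].
#' @param x numeric state vector of length `N`.
#' @return Numeric vector `(a_1(x), ..., a_m(x))`.
#' @export
propensities <- function(net, x) {
  stopifnot(inherits(net, "reaction_network"))
  if (length(x) != net$N)
    stop("state vector must have length ", net$N)
  vapply(net$propensities, eval_one_propensity, numeric(1),
         x = as.numeric(x), species = net$species)
}

#' Drift (expected step-change) of a network
#'
#' Returns `f(x) = sum_j nu_j a_j(x)`, the expected change of the state
#' per unit time, used both by the deterministic stages of Runge-Kutta
#' tau-leap methods and in the compensated-Poisson decomposition of the
#' leap update.
#'
#' @inheritParams propensities
#' @return Numeric vector of length `N`.
#' @export
drift <- function(net, x) {
  a <- propensities(net, x)
  drift_from_propensities(net$nu, a)
}

# f = sum_j nu_j a_j accumulated channel by channel; the simulation kernels
# use the same accumulation order so that per-step algebra is reproducible.
drift_from_propensities <- function(nu, a) {
  f <- numeric(nrow(nu))
  for (j in seq_along(a)) f <- f + nu[, j] * a[j]
  f
}

#' Linear-kinetics structure of a unimolecular network
#'
#' For a network in which every channel propensity is linear,
#' `a_j(x) = c_j' x`, the drift is `f(x) = W x` with
#' `W = sum_j nu_j c_j'`.  This matrix drives the mean propagation of all
#' tau-leap methods on linear kinetics (see [mean_propagator()]).
#'
#' @param net a [reaction_network()] whose channels are all linear.
#' @return An object of class `"linear_kinetics"`: a list with the `m`
#'   coefficient vectors `c_vectors` and the `N x N` matrix `W`.
#' @examples
#' lk <- linear_kinetics_matrix(isomerisation_network(10, 10))
#' lk$W
#' @export
linear_kinetics_matrix <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  kinds <- vapply(net$propensities, `[[`, "", "kind")
  if (!all(kinds == "linear"))
    stop("not a linear kinetics system: channel(s) ",
         paste(which(kinds != "linear"), collapse = ", "),
         " are not linear propensities")
  cv <- lapply(net$propensities, `[[`, "coef")
  W <- matrix(0, net$N, net$N, dimnames = list(net$species, net$species))
  for (j in seq_len(net$m)) W <- W + tcrossprod(net$nu[, j], cv[[j]])
  structure(list(c_vectors = cv, W = W), class = "linear_kinetics")
}

#' @export
print.linear_kinetics <- function(x, ...) {
  cat("<linear_kinetics> W:\n"); print(x$W); invisible(x)
}

#' Read and write network configuration files
#'
#' Serializes a [reaction_network()] to a YAML document (species,
#' channels with their declarative propensities and update vectors,
#' initial state) and reads it back.  Networks containing
#' [fn_propensity()] channels cannot be serialized.
#'
#' @param net a [reaction_network()].
#' @param path file path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a [reaction_network()].
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "reaction_network"))
  kinds <- vapply(net$propensities, `[[`, "", "kind")
  if (any(kinds == "function"))
    stop("networks with function propensities cannot be serialized")
  chans <- lapply(seq_len(net$m), function(j) {
    p <- net$propensities[[j]]
    ch <- list(nu = as.integer(net$nu[, j]))
    if (p$kind == "mass_action") {
      ch$kind <- "mass_action"; ch$rate <- p$rate
      ch$reactants <- as.list(p$reactants)
    } else {
      ch$kind <- "linear"; ch$coef <- as.numeric(p$coef)
    }
    ch
  })
  doc <- list(species = as.list(net$species),
              initial_state = as.integer(net$initial_state),
              channels = chans)
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- yaml::read_yaml(path)
  species <- unlist(doc$species)
  props <- lapply(doc$channels, function(ch) {
    if (ch$kind == "mass_action") {
      re <- unlist(ch$reactants)
      mass_action(ch$rate, if (length(re)) re else integer())
    } else {
      linear_propensity(as.numeric(unlist(ch$coef)))
    }
  })
  nu <- lapply(doc$channels, function(ch) as.integer(unlist(ch$nu)))
  reaction_network(species, nu, props, as.numeric(unlist(doc$initial_state)))
}
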