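#' Specification of stochastic symptom-activation dynamics
#'
#' Couples a symptom graph with the parameters of the activation process.
#' At each day t, symptom i switches on with probability
#' \deqn{p_{it} = a + (1-a)\left[\frac{e^{b_i A_i(t-1) - c_i}}
#'   {1 + e^{b_i A_i(t-1) - c_i}} - a\right]}
#' where `A_i(t-1)` counts i's active neighbors on the previous day, `b_i`
#' is the symptom's sensitivity to neighbor activation, `c_i` its threshold,
#' and the single global parameter `a` sets both the floor (a symptom can
#' ignite spontaneously: probability `a^2` when the logistic term vanishes)
#' and the ceiling (a symptom can recover even under full neighbor pressure:
#' deactivation probability `1 - a - (1-a)^2 = a(1-a)` in that limit).
#'
#' @param graph an `igraph` symptom graph with named vertices.
#' @param a global floor/ceiling parameter, strictly in (0, 1).
#' @param b,c numeric vectors of per-symptom sensitivity (>= 0) and
#'   threshold, either named by symptom or in vertex order (scalars are
#'   recycled).
#' @return object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(graph, a, b, c) {
  stopifnot(igraph::is_igraph(graph))
  if (!(is.numeric(a) && length(a) == 1L && a > 0 && a < 1))
    stop("a must be a single number strictly inside (0, 1)")
  sym <- igraph::V(graph)$name
  if (is.null(sym)) stop("graph vertices must be named")
  k <- length(sym)
  expand <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, k)
    if (!is.null(names(x))) {
      if (!all(sym %in% names(x)))
        stop("missing ", what, " parameter for symptom(s): ",
             paste(setdiff(sym, names(x)), collapse = ", "))
      x <- x[sym]
    } else if (length(x) != k) {
      stop(what, " must have length 1 or ", k)
    }
    stats::setNames(as.numeric(x), sym)
  }
  b <- expand(b, "b")
  c <- expand(c, "c")
  if (any(b < 0)) stop("b must be nonnegative")
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  adj <- (adj > 0) + 0
  dimnames(adj) <- list(sym, sym)
  structure(list(graph = graph, adjacency = adj, symptoms = sym,
                 a = a, b = b, c = c),
            class = "dynamics_spec")
}

#' @export
print.dynamics_spec <- function(x, ...) {
  cat(sprintf("Symptom dynamics: %d symptoms, %d edges, a = %g\n",
              length(x$symptoms), igraph::ecount(x$graph), x$a))
  cat(sprintf("  b in [%g, %g]; c in [%g, %g]\n",
              min(x$b), max(x$b), min(x$c), max(x$c)))
  invisible(x)
}

#' Per-day activation probability
#'
#' @param a global floor/ceiling parameter in (0, 1).
#' @param b,c symptom sensitivity and threshold (vectorized).
#' @param active_neighbors count of active neighbors at the previous day.
#' @return probability in the open interval `(a^2, a + (1-a)^2)`, monotone
#'   nondecreasing in `active_neighbors` when `b >= 0`.
#' @examples
#' activation_probability(0.22, 1, 0, 0)   # logistic at 0: 0.4384
#' @export
activation_probability <- function(a, b, c, active_neighbors) {
  if (any(a <= 0 | a >= 1)) stop("a must lie strictly inside (0, 1)")
  a + (1 - a) * (stats::plogis(b * active_neighbors - c) - a)
}

#' Simulate one person's symptom history
#'
#' Synchronous update: every symptom's state on day t is drawn independently
#' with [activation_probability()] evaluated at the neighbor counts of day
#' t-1; the state at day 0 is all-off (configurable). A symptom's own
#' previous state does not enter the update; "turning off" is simply failing
#' to turn on.
#'
#' @param spec a [dynamics_spec()].
#' @param days number of days T >= 1.
#' @param seed integer seed; fixed seed reproduces the history exactly.
#' @param init optional initial 0/1 state vector (day 0), default all off.
#' @return integer matrix, symptoms x days (dimnames set).
#' @export
simulate_person <- function(spec, days, seed = 1L, init = NULL) {
  stopifnot(inherits(spec, "dynamics_spec"), days >= 1)
  k <- length(spec$symptoms)
  if (is.null(init)) init <- rep(0L, k)
  stopifnot(length(init) == k, all(init %in% c(0L, 1L)))
  set.seed(seed)
  u <- matrix(stats::runif(k * days), nrow = k)
  out <- matrix(0L, k, days, dimnames = list(spec$symptoms, seq_len(days)))
  state <- as.numeric(init)
  for (t in seq_len(days)) {
    A <- drop(spec$adjacency %*% state)
    p <- activation_probability(spec$a, spec$b, spec$c, A)
    state <- as.numeric(u[, t] < p)
    out[, t] <- as.integer(state)
  }
  out
}

#' Simulate a population of independent persons
#'
#' Persons are independent; each person's random stream is derived
#' deterministically from the master seed by a counter-based split, so the
#' panel equals stacking [simulate_person()] with the derived seeds, and
#' person-level results do not depend on evaluation order. Internally all
#' persons are advanced day by day in one matrix recursion.
#'
#' @param spec a [dynamics_spec()].
#' @param n_persons number of persons >= 1.
#' @param days number of days.
#' @param seed master integer seed.
#' @param max_cells resource guard: refuse panels with more than this many
#'   person-symptom-day cells.
#' @return object of class `symptom_panel`: integer array `states` with
#'   dimensions (persons, symptoms, days), plus `symptoms`, `days`, `seed`,
#'   `person_seeds`.
#' @export
simulate_population <- function(spec, n_persons, days, seed = 1L,
                                max_cells = 2e8) {
  stopifnot(inherits(spec, "dynamics_spec"), n_persons >= 1, days >= 1)
  k <- length(spec$symptoms)
  if (as.numeric(n_persons) * days * k > max_cells)
    stop(sprintf(
      "panel of %d persons x %d symptoms x %d days exceeds max_cells = %g; raise max_cells if intended",
      n_persons, k, days, max_cells))
  seeds <- derive_seeds(seed, n_persons)
  # one uniform stream per person, identical draw order to simulate_person
  U <- vapply(seeds, function(s) { set.seed(s); stats::runif(k * days) },
              numeric(k * days))
  states <- array(0L, dim = c(n_persons, k, days),
                  dimnames = list(NULL, spec$symptoms, NULL))
  state <- matrix(0, k, n_persons)            # symptoms x persons
  for (t in seq_len(days)) {
    A <- spec$adjacency %*% state
    p <- activation_probability(spec$a, spec$b, spec$c, A)
    rows <- ((t - 1L) * k + 1L):(t * k)
    state <- (U[rows, , drop = FALSE] < p) + 0
    states[, , t] <- as.integer(t(state))
  }
  structure(list(states = states, symptoms = spec$symptoms,
                 days = days, n_persons = n_persons,
                 seed = seed, person_seeds = seeds),
            class = "symptom_panel")
}

#' @export
print.symptom_panel <- function(x, ...) {
  cat(sprintf("Symptom panel: %d persons x %d symptoms x %d days (seed %d)\n",
              x$n_persons, length(x$symptoms), x$days, x$seed))
  cat(sprintf("  overall activation rate: %.4f\n", mean(x$states)))
  invisible(x)
}

#' Extract one person's history from a panel
#'
#' @param panel a [simulate_population()] result.
#' @param person person index.
#' @return symptoms x days integer matrix, as from [simulate_person()].
#' @export
person_history <- function(panel, person) {
  stopifnot(inherits(panel, "symptom_panel"),
            person >= 1, person <= panel$n_persons)
  h <- panel$states[person, , , drop = TRUE]
  matrix(h, length(panel$symptoms), panel$days,
         dimnames = list(panel$symptoms, seq_len(panel$days)))
}

#' Cross-sectional slice of a panel
#'
#' @param panel a [simulate_population()] result.
#' @param day day index; default the final day.
#' @return persons x symptoms 0/1 matrix.
#' @export
panel_slice <- function(panel, day = panel$days) {
  stopifnot(inherits(panel, "symptom_panel"), day >= 1, day <= panel$days)
  m <- panel$states[, , day, drop = TRUE]
  matrix(m, panel$n_persons, length(panel$symptoms),
         dimnames = list(NULL, panel$symptoms))
}

#' Per-symptom marginal activation rates
#'
#' @param panel a [simulate_population()] result.
#' @return named vector: fraction of person-days each symptom is active.
#' @export
activation_rates <- function(panel) {
  stopifnot(inherits(panel, "symptom_panel"))
  apply(panel$states, 2L, mean)
}

#' Estimate symptom parameters by logistic regression
#'
#' Emulates the derivation of (b_i, c_i) from cross-sectional survey data:
#' each symptom's endorsement is regressed (logistic) on the number of the
#' disorder's *other* symptoms the person endorses; the slope is `b_i` and
#' the negated intercept is the location `c_i`, so the linear predictor is
#' `b_i * count - c_i`. Excluding the symptom itself avoids the degeneracy
#' of regressing an indicator on a sum containing it; set
#' `include_self = TRUE` for the literal total-count predictor. A symptom
#' belonging to several disorders is fitted once per disorder and the
#' estimates averaged.
#'
#' @param slice persons x symptoms 0/1 matrix with symptom column names.
#' @param disorder_sets named list of symptom sets (one per disorder).
#' @param include_self include the symptom itself in the count predictor.
#' @param cap absolute bound applied to (b, c) under perfect separation; the
#'   affected symptom is flagged.
#' @return data frame: `symptom`, `b`, `c`, `separation`.
#' @export
estimate_symptom_params <- function(slice, disorder_sets,
                                    include_self = FALSE, cap = 10) {
  stopifnot(is.matrix(slice), !is.null(colnames(slice)))
  if (nrow(slice) < 30L) stop("need at least 30 persons")
  if (!all(slice %in% c(0, 1))) stop("slice must be binary")
  fits <- list()
  for (d in names(disorder_sets)) {
    set <- disorder_sets[[d]]
    if (!all(set %in% colnames(slice)))
      stop("slice lacks symptom column(s) of disorder ", d)
    for (s in set) {
      y <- slice[, s]
      if (length(unique(y)) < 2L)
        stop("symptom ", s, " is constant: perfect separation")
      others <- if (include_self) set else setdiff(set, s)
      x <- rowSums(slice[, others, drop = FALSE])
      fit <- suppressWarnings(
        stats::glm(y ~ x, family = stats::binomial()))
      co <- stats::coef(fit)
      bb <- unname(co[2L]); cc <- unname(-co[1L])
      sep <- !fit$converged || any(abs(co) > cap) ||
        any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
      if (sep) {
        warning("possible separation for symptom ", s, " in disorder ", d,
                "; estimates capped at ", cap)
        bb <- max(min(bb, cap), -cap)
        cc <- max(min(cc, cap), -cap)
      }
      fits[[length(fits) + 1L]] <-
        data.frame(symptom = s, b = bb, c = cc, separation = sep)
    }
  }
  all <- do.call(rbind, fits)
  agg <- stats::aggregate(cbind(b, c) ~ symptom, all, mean)
  sep <- stats::aggregate(separation ~ symptom, all, any)
  out <- merge(agg, sep, by = "symptom", sort = FALSE)
  out[match(unique(all$symptom), out$symptom), , drop = FALSE]
}
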