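#' The 14-symptom MDE/GAD network fixture
#'
#' The canonical two-disorder network: major depressive episode (MDE) and
#' generalized anxiety disorder (GAD), nine symptoms each, sharing four
#' bridge symptoms. Core MDE symptoms are depressed mood (`mDep`), loss of
#' interest (`mInt`), weight problems (`mWei`), self-reproach (`mRep`) and
#' thoughts of suicide (`mSui`); the bridges are sleep problems (`bSle`),
#' fatigue (`bFat`), concentration problems (`bCon`) and psychomotor
#' problems (`bMot`); core GAD symptoms are chronic anxiety (`gAnx`),
#' anxiety about more than one event (`gEve`), no control over the anxiety
#' (`gCtr`), muscle tension (`gMus`) and irritability (`gIrr`). In the
#' projection (66 edges) comorbidity can only arise through the bridges:
#' no core MDE symptom is adjacent to a core GAD symptom.
#'
#' The bundled dynamics parameters are the package's own calibration (see
#' the methods vignette): `a = 0.22` with per-symptom sensitivities `b` and
#' thresholds `c` tuned by [calibrate_thresholds()] so that marginal daily
#' symptom rates hit the default targets in `targets`.
#'
#' @return list with `table` (the [incidence_table()]), `rules` (list of
#'   [diagnosis_rule()] for MDE and GAD), `a`, `params` (data frame
#'   `symptom`, `b`, `c`), and `targets` (named daily activation-rate
#'   targets used in the calibration).
#' @examples
#' fx <- mde_gad_fixture()
#' igraph::ecount(project_to_symptom_graph(fx$table))  # 66
#' @export
mde_gad_fixture <- function() {
  core_mde <- c("mDep", "mInt", "mWei", "mRep", "mSui")
  bridges  <- c("bSle", "bFat", "bCon", "bMot")
  core_gad <- c("gAnx", "gEve", "gCtr", "gMus", "gIrr")
  mde <- c(core_mde, bridges)
  gad <- c(core_gad, bridges)
  tab <- incidence_table(
    data.frame(symptom = c(mde, gad),
               disorder = rep(c("MDE", "GAD"), each = 9L)),
    symptoms = c(core_mde, bridges, core_gad),
    disorders = c("MDE", "GAD"))
  rules <- list(
    MDE = diagnosis_rule("MDE", mde, core = c("mDep", "mInt"),
                         min_count = 5L, window = 14L,
                         criterion = "every-day"),
    GAD = diagnosis_rule("GAD", gad, core = c("gAnx", "gEve", "gCtr"),
                         min_count = 5L, window = 182L,
                         criterion = "most-days"))
  list(table = tab, rules = rules, a = 0.22,
       params = fixture_default_params(),
       targets = fixture_default_targets())
}

# Calibrated package defaults for the fixture dynamics (see the methods
# vignette for the regime analysis): core symptoms are more sensitive than
# the high-degree bridges, GAD cores slightly more than MDE cores, and the
# thresholds are the calibration output for the marginal-rate targets below.
# MDE cores run at low daily rates with occasional intense episodes; GAD
# cores sustain a chronic moderate-duty cluster; bridges sit in between so
# the two sides can also activate separately.
fixture_default_params <- function() {
  data.frame(
    symptom = c("mDep", "mInt", "mWei", "mRep", "mSui",
                "bSle", "bFat", "bCon", "bMot",
                "gAnx", "gEve", "gCtr", "gMus", "gIrr"),
    b = c(rep(1.3, 5L), rep(0.8, 4L), rep(1.4, 5L)),
    c = c(rep(6.5, 5L), rep(4.2, 4L), rep(4.2, 5L)),
    stringsAsFactors = FALSE)
}

# daily marginal activation-rate targets per symptom: anxiety-side symptoms
# are the more prevalent ones, yet GAD prevalence stays below MDE's because
# of the 182- vs 14-day duration criteria
fixture_default_targets <- function() {
  stats::setNames(
    c(rep(0.077, 5L), rep(0.149, 4L), rep(0.192, 5L)),
    c("mDep", "mInt", "mWei", "mRep", "mSui",
      "bSle", "bFat", "bCon", "bMot",
      "gAnx", "gEve", "gCtr", "gMus", "gIrr"))
}

#' Dynamics specification for the MDE/GAD fixture
#'
#' @param fixture result of [mde_gad_fixture()] (built if omitted).
#' @return a [dynamics_spec()] on the fixture projection with the bundled
#'   calibrated parameters.
#' @export
fixture_dynamics_spec <- function(fixture = mde_gad_fixture()) {
  g <- project_to_symptom_graph(fixture$table)
  dynamics_spec(g, a = fixture$a,
                b = stats::setNames(fixture$params$b, fixture$params$symptom),
                c = stats::setNames(fixture$params$c, fixture$params$symptom))
}

#' Generate a structured synthetic incidence table
#'
#' Builds `n_disorders` disorders of `size` symptoms each, with adjacent
#' disorders sharing `bridge` symptoms, arranged as a chain or a ring. With
#' `bridge = 0` the projection is a disjoint union of cliques.
#'
#' @param n_disorders,size,bridge counts; `bridge < size`, and internal
#'   disorders need `size >= 2 * bridge` (chain; every disorder on a ring).
#' @param topology `"chain"` or `"ring"`.
#' @param seed accepted for interface symmetry; the construction is
#'   deterministic.
#' @return an [incidence_table()].
#' @examples
#' tab <- generate_incidence(10, 8, 2)  # 10*8 - 9*2 = 62 unique symptoms
#' length(tab$symptoms)
#' @export
generate_incidence <- function(n_disorders, size, bridge = 0L,
                               topology = c("chain", "ring"), seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_disorders >= 1, size >= 1, bridge >= 0)
  if (bridge >= size) stop("bridge overlap must be smaller than disorder size")
  n_pairs <- if (topology == "ring") n_disorders else n_disorders - 1L
  if (bridge > 0 && n_disorders > 2L && 2L * bridge > size)
    stop("infeasible overlap: internal disorders need size >= 2 * bridge")
  if (topology == "ring" && n_disorders < 3L && bridge > 0)
    stop("ring topology needs at least 3 disorders")
  dis <- sprintf("D%02d", seq_len(n_disorders))
  new_per <- c(size, rep(size - bridge, n_disorders - 1L))
  if (topology == "ring" && bridge > 0) new_per[n_disorders] <- size - 2L * bridge
  total <- sum(new_per)
  sym <- sprintf("s%03d", seq_len(total))
  rows <- vector("list", n_disorders)
  start <- cumsum(c(1L, new_per))[seq_len(n_disorders)]
  own <- lapply(seq_len(n_disorders), function(i)
    sym[seq.int(start[i], length.out = new_per[i])])
  for (i in seq_len(n_disorders)) {
    s <- own[[i]]
    if (bridge > 0 && i > 1L)
      s <- c(utils::tail(own[[i - 1L]], bridge), s)
    if (topology == "ring" && bridge > 0 && i == n_disorders)
      s <- c(s, utils::head(own[[1L]], bridge))
    rows[[i]] <- data.frame(symptom = s, disorder = dis[i])
  }
  incidence_table(do.call(rbind, rows), symptoms = sym, disorders = dis)
}

#' Generate a block-structured, DSM-like incidence table
#'
#' Emulates the redundancy structure of a real diagnostic taxonomy: symptoms
#' come in blocks (criterion groups) that recur as units across disorders,
#' plus a few idiosyncratic extra symptoms per disorder. Because the same
#' symptom pairs co-occur in several disorders, the projected graph is much
#' sparser and more clustered than a degree-preserving random re-assortment
#' of the same margins - the structure behind a small-world symptom space.
#'
#' @param n_blocks,block_size number and size of symptom blocks.
#' @param n_disorders number of disorders.
#' @param blocks_per blocks drawn (without replacement) per disorder.
#' @param extra idiosyncratic symptoms added per disorder.
#' @param seed integer seed.
#' @return an [incidence_table()].
#' @export
generate_dsm_like <- function(n_blocks = 20L, block_size = 5L,
                              n_disorders = 30L, blocks_per = 1L,
                              extra = 2L, seed = 1L) {
  stopifnot(blocks_per >= 1, blocks_per <= n_blocks, extra >= 0)
  set.seed(seed)
  total <- n_blocks * block_size
  sym <- sprintf("s%03d", seq_len(total))
  blocks <- split(sym, rep(seq_len(n_blocks), each = block_size))
  rows <- vector("list", n_disorders)
  for (d in seq_len(n_disorders)) {
    bs <- sample(n_blocks, blocks_per)
    s <- unique(c(unlist(blocks[bs]), sample(sym, extra)))
    rows[[d]] <- data.frame(symptom = s, disorder = sprintf("D%02d", d))
  }
  tab <- do.call(rbind, rows)
  incidence_table(tab, symptoms = intersect(sym, tab$symptom))
}

#' Draw per-symptom dynamics parameters
#'
#' Sensitivities `b` are drawn from a truncated normal (at 0) and thresholds
#' `c` from a normal; [calibrate_thresholds()] can then tune `c` against
#' target activation rates.
#'
#' @param symptoms character vector of symptom names.
#' @param seed integer seed.
#' @param b_mean,b_sd,c_mean,c_sd distribution parameters.
#' @return data frame `symptom`, `b`, `c`.
#' @export
generate_params <- function(symptoms, seed = 1L, b_mean = 1, b_sd = 0.2,
                            c_mean = 5, c_sd = 1) {
  set.seed(seed)
  b <- pmax(stats::rnorm(length(symptoms), b_mean, b_sd), 0)
  c <- stats::rnorm(length(symptoms), c_mean, c_sd)
  data.frame(symptom = symptoms, b = b, c = c, stringsAsFactors = FALSE)
}

#' Shuffle (b, c) parameter pairs across symptoms
#'
#' Pairs are kept intact and permuted as units, so the multiset of pairs is
#' preserved; only the assignment of pairs to symptoms changes.
#'
#' @param params data frame `symptom`, `b`, `c`.
#' @param seed integer seed.
#' @return data frame with the same symptoms and permuted pairs.
#' @export
shuffle_params <- function(params, seed = 1L) {
  stopifnot(all(c("symptom", "b", "c") %in% names(params)),
            nrow(params) >= 2L)
  set.seed(seed)
  perm <- sample.int(nrow(params))
  data.frame(symptom = params$symptom,
             b = params$b[perm], c = params$c[perm],
             stringsAsFactors = FALSE)
}

#' Calibrate thresholds against target activation rates
#'
#' Tunes each symptom's threshold `c` (holding `b` and `a` fixed) so that
#' the simulated marginal daily activation rate matches its target. The
#' marginal rate is monotone decreasing in the symptom's own threshold, so
#' the scheme runs simultaneous per-symptom bisection first; because early
#' bracket decisions are made while the *other* thresholds are still far
#' from their final values, a damped proportional refinement phase then
#' corrects the residual interaction bias.
#'
#' @param graph symptom graph (`igraph`, named vertices).
#' @param a global dynamics parameter.
#' @param b named vector (or data frame `symptom`, `b`) of sensitivities.
#' @param targets named vector of target marginal rates in (0, 1).
#' @param n_persons,days simulation size per bisection step.
#' @param seed integer seed.
#' @param tol convergence tolerance on each achieved rate.
#' @param max_iter bisection iterations.
#' @param refine_iter damped-correction iterations after bisection.
#' @param gain proportional gain of the refinement (threshold units per unit
#'   rate error).
#' @param c_range initial bracket for every threshold.
#' @return data frame `symptom`, `b`, `c`, `achieved`, `target`.
#' @export
calibrate_thresholds <- function(graph, a, b, targets, n_persons = 2000,
                                 days = 100, seed = 1L, tol = 0.02,
                                 max_iter = 18L, refine_iter = 12L,
                                 gain = 8, c_range = c(-5, 30)) {
  if (is.data.frame(b)) b <- stats::setNames(b$b, b$symptom)
  sym <- igraph::V(graph)$name
  stopifnot(all(sym %in% names(b)), all(sym %in% names(targets)))
  if (any(targets <= 0 | targets >= 1)) stop("targets must lie in (0, 1)")
  targets <- targets[sym]
  lo <- stats::setNames(rep(c_range[1L], length(sym)), sym)
  hi <- stats::setNames(rep(c_range[2L], length(sym)), sym)
  seeds <- derive_seeds(seed + 7L, max_iter + refine_iter + 1L)
  rate_at <- function(cc, it) {
    sp <- dynamics_spec(graph, a, b[sym], cc)
    activation_rates(simulate_population(sp, n_persons, days,
                                         seed = seeds[it]))
  }
  mid <- (lo + hi) / 2
  for (it in seq_len(max_iter)) {
    achieved <- rate_at(mid, it)
    high <- achieved > targets     # rate too high -> threshold too low
    lo[high] <- mid[high]
    hi[!high] <- mid[!high]
    mid <- (lo + hi) / 2
  }
  cc <- mid
  for (it in seq_len(refine_iter)) {
    achieved <- rate_at(cc, max_iter + it)
    err <- achieved - targets
    if (all(abs(err) <= tol / 2) && it > 2L) break
    # stochastic-approximation step: decaying gain and clipped moves keep
    # the steep (near-bistable) regimes from oscillating
    step <- (gain / (1 + (it - 1) / 3)) * err
    cc <- cc + pmin(pmax(step, -0.5), 0.5)
  }
  achieved <- rate_at(cc, max_iter + refine_iter + 1L)
  if (any(abs(achieved - targets) > tol)) {
    worst <- which.max(abs(achieved - targets))
    stop(sprintf(
      "threshold calibration did not converge: symptom %s achieved %.3f vs target %.3f (consider wider c_range, more refine_iter or larger n)",
      sym[worst], achieved[worst], targets[worst]))
  }
  data.frame(symptom = sym, b = unname(b[sym]), c = unname(cc),
             achieved = unname(achieved), target = unname(targets),
             stringsAsFactors = FALSE)
}

#' Generate a full comorbidity test scenario
#'
#' Builds a chain of disorders, calibrates dynamics on the projected graph,
#' simulates a population, diagnoses every disorder with a generic
#' cross-sectional majority rule (more than half of its symptoms active on
#' the final day) and returns the phi coefficients between diagnoses as the
#' comorbidity matrix. Because the comorbidity truly arises from activation
#' spreading on the graph, the scenario provides a ground truth for the
#' distance-comorbidity analysis.
#'
#' @param n_disorders,size,bridge chain layout (>= 4 disorders).
#' @param a,b_value dynamics parameters (`b` constant across symptoms).
#' @param target_rate common marginal daily activation-rate target.
#' @param n_persons,days final simulation size.
#' @param calib_persons,calib_days calibration simulation size.
#' @param seed integer seed.
#' @return list: `table`, `graph`, `comorbidity` (phi matrix, unit
#'   diagonal), `prevalence`, `params`, `panel_seed`.
#' @export
generate_comorbidity_scenario <- function(n_disorders = 6L, size = 6L,
                                          bridge = 1L, a = 0.22,
                                          b_value = 0.9, target_rate = 0.3,
                                          n_persons = 4000L, days = 120L,
                                          calib_persons = 1500L,
                                          calib_days = 80L, seed = 1L) {
  stopifnot(n_disorders >= 4L)
  tab <- generate_incidence(n_disorders, size, bridge, topology = "chain")
  g <- project_to_symptom_graph(tab)
  b <- stats::setNames(rep(b_value, length(tab$symptoms)), tab$symptoms)
  targets <- stats::setNames(rep(target_rate, length(tab$symptoms)),
                             tab$symptoms)
  params <- calibrate_thresholds(g, a, b, targets,
                                 n_persons = calib_persons,
                                 days = calib_days, seed = seed)
  sp <- dynamics_spec(g, a, stats::setNames(params$b, params$symptom),
                      stats::setNames(params$c, params$symptom))
  panel_seed <- derive_seeds(seed + 101L, 1L)
  panel <- simulate_population(sp, n_persons, days, seed = panel_seed)
  slice <- panel_slice(panel)
  sets <- disorder_symptoms(tab)
  diags <- vapply(sets, function(s)
    rowSums(slice[, s, drop = FALSE]) > length(s) / 2,
    logical(n_persons))
  prev <- colMeans(diags)
  if (any(prev %in% c(0, 1)))
    stop("degenerate prevalence (0 or 1) for disorder(s) ",
         paste(names(prev)[prev %in% c(0, 1)], collapse = ", "),
         "; recalibrate with a different target_rate")
  phi <- stats::cor(diags)
  diag(phi) <- 1
  list(table = tab, graph = g, comorbidity = phi, prevalence = prev,
       params = params, panel_seed = panel_seed)
}

#' Write / read a simulation scenario directory
#'
#' A scenario is stored as plain text: `edges.tsv` (the symptom graph),
#' `params.csv` (per-symptom `b`, `c`), and `config.yaml` (global `a`,
#' `n_persons`, `days`, `seed`).
#'
#' @param spec a [dynamics_spec()].
#' @param dir directory (created if needed).
#' @param n_persons,days,seed simulation settings stored in the config.
#' @return the directory path, invisibly.
#' @export
write_scenario <- function(spec, dir, n_persons, days, seed = 1L) {
  stopifnot(inherits(spec, "dynamics_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_graph_file(spec$graph, file.path(dir, "edges.tsv"), "edgelist")
  utils::write.csv(
    data.frame(symptom = spec$symptoms, b = unname(spec$b),
               c = unname(spec$c)),
    file.path(dir, "params.csv"), row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("a: %g", spec$a),
               sprintf("n_persons: %d", as.integer(n_persons)),
               sprintf("days: %d", as.integer(days)),
               sprintf("seed: %d", as.integer(seed))),
             file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_scenario
#' @return for `read_scenario`: list with `spec` ([dynamics_spec()]),
#'   `n_persons`, `days`, `seed`.
#' @export
read_scenario <- function(dir) {
  cfgf <- file.path(dir, "config.yaml")
  if (!file.exists(cfgf)) stop("missing config.yaml in ", dir)
  cfg <- if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(cfgf)
  } else {
    lines <- readLines(cfgf)
    kv <- strsplit(lines, ":\\s*")
    stats::setNames(lapply(kv, function(x) as.numeric(x[2L])),
                    vapply(kv, `[[`, "", 1L))
  }
  g <- read_graph_file(file.path(dir, "edges.tsv"), "edgelist")
  pars <- utils::read.csv(file.path(dir, "params.csv"),
                          stringsAsFactors = FALSE)
  # restore the stored vertex order: simulation streams assign uniforms by
  # symptom position, so order must survive the round trip
  if (setequal(igraph::V(g)$name, pars$symptom))
    g <- igraph::permute(g, match(igraph::V(g)$name, pars$symptom))
  spec <- dynamics_spec(g, cfg$a,
                        stats::setNames(pars$b, pars$symptom),
                        stats::setNames(pars$c, pars$symptom))
  list(spec = spec, n_persons = as.integer(cfg$n_persons),
       days = as.integer(cfg$days), seed = as.integer(cfg$seed))
}
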