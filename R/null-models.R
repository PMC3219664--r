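#' Degree-preserving randomization of an incidence table
#'
#' Randomly re-assorts symptoms with disorders while keeping each symptom's
#' bipartite degree and each disorder's symptom count exactly fixed. Sampling
#' uses a chain of checkerboard swaps: a 2x2 submatrix of the binary
#' incidence matrix with pattern `10/01` (or `01/10`) is exchanged for its
#' mirror, which preserves both margins; the chain runs until
#' `swap_factor` times the number of memberships swaps have been accepted.
#'
#' @param table an [incidence_table()].
#' @param seed integer seed.
#' @param swap_factor accepted swaps per membership (burn-in length).
#' @param max_attempt_factor give-up threshold: if no swap is accepted within
#'   `max_attempt_factor` consecutive attempts the margins are treated as
#'   degenerate (they admit a single matrix) and the input is returned
#'   unchanged with a notice.
#' @return a new [incidence_table()] with identical margins.
#' @export
randomize_bipartite <- function(table, seed = 1L, swap_factor = 10,
                                max_attempt_factor = 5000) {
  stopifnot(inherits(table, "incidence_table"))
  m <- as_incidence_matrix(table) > 0L
  nr <- nrow(m); nc <- ncol(m)
  n_mem <- sum(m)
  if (nr < 2L || nc < 2L) {
    message("degenerate margins: no checkerboard swap possible; returning input")
    return(table)
  }
  set.seed(seed)
  target <- swap_factor * n_mem
  accepted <- 0L
  since_last <- 0L
  max_idle <- max_attempt_factor
  while (accepted < target) {
    r <- sample.int(nr, 2L)
    cc <- sample.int(nc, 2L)
    a <- m[r[1L], cc[1L]]; b <- m[r[1L], cc[2L]]
    d <- m[r[2L], cc[1L]]; e <- m[r[2L], cc[2L]]
    if ((a && e && !b && !d) || (!a && !e && b && d)) {
      m[r[1L], cc[1L]] <- !a; m[r[1L], cc[2L]] <- !b
      m[r[2L], cc[1L]] <- !d; m[r[2L], cc[2L]] <- !e
      accepted <- accepted + 1L
      since_last <- 0L
    } else {
      since_last <- since_last + 1L
      if (since_last >= max_idle) {
        if (accepted == 0L) {
          message("degenerate margins: no checkerboard swap found; returning input")
          return(table)
        }
        break
      }
    }
  }
  idx <- which(m, arr.ind = TRUE)
  incidence_table(
    data.frame(symptom = rownames(m)[idx[, 1L]],
               disorder = colnames(m)[idx[, 2L]]),
    symptoms = table$symptoms, disorders = table$disorders)
}

#' Permutation-null distribution of the small-world-ness index
#'
#' Builds `reps` degree-preserving randomizations of the incidence table
#' ([randomize_bipartite()]), projects each onto the symptom space, restricts
#' to the giant component (or keeps the full graph), and records per
#' replicate the clustering, average path length, density and SWI. The
#' observed table is processed identically, and its SWI percentile within
#' the ensemble is reported.
#'
#' @param table an [incidence_table()].
#' @param reps number of randomizations.
#' @param seed integer seed; replicate seeds are derived deterministically.
#' @param restrict `"giant"` (default: statistics on each replicate's own
#'   giant component) or `"full"` (whole projected graph; must be connected).
#' @param swap_factor passed to [randomize_bipartite()].
#' @return object of class `permutation_ensemble`: data frame `ensemble`
#'   (`C`, `L`, `swi`, `density`), `observed` (same fields), `percentile`
#'   of the observed SWI, `reps`, `seed`.
#' @export
permutation_swi_distribution <- function(table, reps, seed = 1L,
                                         restrict = c("giant", "full"),
                                         swap_factor = 10) {
  stopifnot(inherits(table, "incidence_table"), reps >= 1)
  restrict <- match.arg(restrict)
  stat_of <- function(tab) {
    g <- project_to_symptom_graph(tab)
    if (restrict == "giant") g <- giant_component(g)$graph
    n <- igraph::vcount(g); m <- igraph::ecount(g)
    C <- transitivity_global(g)
    L <- igraph::mean_distance(g, directed = FALSE)
    c(C = C, L = L,
      swi = small_world_index(C, L, n, m)$swi,
      density = m / choose(n, 2L), n = n, m = m)
  }
  obs <- stat_of(table)
  seeds <- derive_seeds(seed, reps)
  ens <- vapply(seq_len(reps), function(i)
    stat_of(randomize_bipartite(table, seed = seeds[i],
                                swap_factor = swap_factor)),
    numeric(6))
  ens <- as.data.frame(t(ens))
  structure(list(ensemble = ens,
                 observed = as.list(obs),
                 percentile = mean(ens$swi <= obs[["swi"]]),
                 reps = reps, seed = seed, restrict = restrict),
            class = "permutation_ensemble")
}

#' @export
print.permutation_ensemble <- function(x, digits = 3, ...) {
  cat(sprintf("Permutation null (%d reps, restrict = %s)\n", x$reps, x$restrict))
  cat(sprintf("  observed SWI %s at ensemble percentile %s\n",
              format(x$observed$swi, digits = digits),
              format(x$percentile, digits = digits)))
  cat(sprintf("  ensemble SWI: mean %s sd %s; density: mean %s (observed %s)\n",
              format(mean(x$ensemble$swi), digits = digits),
              format(stats::sd(x$ensemble$swi), digits = digits),
              format(mean(x$ensemble$density), digits = digits),
              format(x$observed$density, digits = digits)))
  invisible(x)
}

#' @export
plot.permutation_ensemble <- function(x, ...) {
  dens <- stats::density(x$ensemble$swi)
  plot(dens, main = "Permutation-null SWI density", xlab = "SWI", ...)
  graphics::abline(v = x$observed$swi, col = "red", lwd = 2)
  invisible(x)
}

# Deterministic, well-mixed child seeds from one master seed. Uses R's own
# generator as the mixing function (nested linear schemes are not safe: two
# masters differing by the increment would share shifted streams) and
# restores the caller's RNG state afterwards.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  sample.int(2147483646L, n)
}
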