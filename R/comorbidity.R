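#' Inter-disorder distances in the symptom graph
#'
#' The distance between two disorders is the expected number of edges one
#' must travel to reach a randomly chosen symptom of one from a randomly
#' chosen symptom of the other: the mean shortest path length over all
#' ordered symptom pairs (s in A, t in B), where a symptom shared by both
#' disorders contributes distance-0 self pairs. Consequently the diagonal
#' (a disorder against itself) is below 1 for any multi-symptom clique.
#'
#' @param graph the projected symptom graph (`igraph`).
#' @param table the source [incidence_table()].
#' @param disorders subset of disorder identifiers; default all.
#' @return object of class `disorder_distance`: symmetric matrix `distance`
#'   (`NA` where a pair spans components, flagged in `unreachable`), logical
#'   matrix `shares_symptoms`.
#' @export
disorder_distance_matrix <- function(graph, table, disorders = NULL) {
  stopifnot(igraph::is_igraph(graph), inherits(table, "incidence_table"))
  if (is.null(disorders)) disorders <- table$disorders
  missing <- setdiff(disorders, table$disorders)
  if (length(missing))
    stop("disorder(s) absent from table: ", paste(missing, collapse = ", "))
  sets <- disorder_symptoms(table)[disorders]
  nm <- igraph::V(graph)$name
  for (d in disorders)
    if (!all(sets[[d]] %in% nm))
      stop("symptoms of disorder ", d, " missing from graph")
  dmat <- igraph::distances(graph, weights = NA)
  k <- length(disorders)
  dist <- matrix(NA_real_, k, k, dimnames = list(disorders, disorders))
  shares <- matrix(FALSE, k, k, dimnames = list(disorders, disorders))
  for (i in seq_len(k)) {
    for (j in i:k) {
      block <- dmat[sets[[i]], sets[[j]], drop = FALSE]
      val <- if (any(is.infinite(block))) NA_real_ else mean(block)
      dist[i, j] <- dist[j, i] <- val
      sh <- length(intersect(sets[[i]], sets[[j]])) > 0L
      shares[i, j] <- shares[j, i] <- sh
    }
  }
  structure(list(distance = dist, shares_symptoms = shares,
                 unreachable = is.na(dist), disorders = disorders),
            class = "disorder_distance")
}

#' @export
print.disorder_distance <- function(x, digits = 3, ...) {
  cat(sprintf("Disorder distance matrix (%d disorders)\n", length(x$disorders)))
  print(round(x$distance, digits))
  invisible(x)
}

#' Pair table of distances and comorbidities
#'
#' @param dist a [disorder_distance_matrix()] result.
#' @param comorb symmetric comorbidity matrix with matching dimnames.
#' @return data frame with one row per unordered disorder pair: `disorderA`,
#'   `disorderB`, `distance`, `comorbidity`, `shares_symptoms`.
#' @export
distance_comorbidity_pairs <- function(dist, comorb) {
  stopifnot(inherits(dist, "disorder_distance"), is.matrix(comorb))
  ids <- intersect(dist$disorders, rownames(comorb))
  if (length(ids) < 2L) stop("fewer than 2 shared disorder identifiers")
  pr <- t(utils::combn(ids, 2L))
  data.frame(
    disorderA = pr[, 1L], disorderB = pr[, 2L],
    distance = dist$distance[pr],
    comorbidity = comorb[pr],
    shares_symptoms = dist$shares_symptoms[pr],
    stringsAsFactors = FALSE)
}

#' Correlation between graph distance and comorbidity
#'
#' Correlates, across unordered disorder pairs, the average shortest path
#' length between two disorders' symptoms with their empirical comorbidity
#' (e.g., tetrachoric correlations supplied as input). If symptom activation
#' spreads along graph edges, the correlation should be negative: disorders
#' farther apart co-occur less.
#'
#' @param dist a [disorder_distance_matrix()] result.
#' @param comorb symmetric comorbidity matrix, values in `[-1, 1]`, dimnames
#'   naming disorders.
#' @param subset `"all"` pairs or `"no-shared-symptoms"` (drop pairs sharing
#'   at least one symptom).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list of class `distance_comorbidity_cor`: `estimate`, `n_pairs`,
#'   `subset`, `method`, and the pair table used.
#' @export
distance_comorbidity_correlation <- function(dist, comorb,
                                             subset = c("all", "no-shared-symptoms"),
                                             method = c("pearson", "spearman")) {
  subset <- match.arg(subset)
  method <- match.arg(method)
  pairs <- distance_comorbidity_pairs(dist, comorb)
  pairs <- pairs[!is.na(pairs$distance), , drop = FALSE]
  if (subset == "no-shared-symptoms")
    pairs <- pairs[!pairs$shares_symptoms, , drop = FALSE]
  if (nrow(pairs) < 3L) stop("fewer than 3 usable disorder pairs")
  if (stats::sd(pairs$distance) == 0 || stats::sd(pairs$comorbidity) == 0)
    stop("zero variance in distances or comorbidities: correlation undefined")
  r <- stats::cor(pairs$distance, pairs$comorbidity, method = method)
  structure(list(estimate = r, n_pairs = nrow(pairs), subset = subset,
                 method = method, pairs = pairs),
            class = "distance_comorbidity_cor")
}

#' @export
print.distance_comorbidity_cor <- function(x, digits = 3, ...) {
  cat(sprintf("r = %s (%s, %d pairs, subset = %s)\n",
              format(x$estimate, digits = digits), x$method, x$n_pairs,
              x$subset))
  invisible(x)
}

#' Positive-manifold check of a comorbidity matrix
#'
#' If symptoms only promote (never protect against) one another, all
#' pairwise disorder associations should be nonnegative. Reports any
#' off-diagonal entries below `-tol`.
#'
#' @param comorb symmetric comorbidity matrix with dimnames.
#' @param tol tolerance: entries in `[-tol, 0)` still count as nonnegative
#'   (use a small positive value for sampled matrices).
#' @return list with `ok` (logical) and `violations` (data frame of pairs).
#' @export
positive_manifold_check <- function(comorb, tol = 0) {
  stopifnot(is.matrix(comorb), nrow(comorb) == ncol(comorb), tol >= 0)
  idx <- which(upper.tri(comorb) & comorb < -tol, arr.ind = TRUE)
  viol <- data.frame(
    disorderA = rownames(comorb)[idx[, 1L]],
    disorderB = colnames(comorb)[idx[, 2L]],
    value = comorb[idx],
    stringsAsFactors = FALSE)
  list(ok = nrow(viol) == 0L, violations = viol)
}

#' Read a comorbidity matrix from labeled square CSV
#'
#' @param path CSV file: first column row labels, header column labels.
#' @return symmetric numeric matrix.
#' @export
read_comorbidity <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[-1L])
  rownames(m) <- trimws(as.character(raw[[1L]]))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("comorbidity matrix must be square")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("comorbidity matrix must be symmetric")
  if (any(abs(m[!is.na(m)]) > 1 + 1e-8))
    stop("comorbidity values must lie in [-1, 1]")
  m
}
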