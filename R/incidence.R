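#' Symptom-disorder incidence tables
#'
#' An incidence table records which symptoms serve as diagnostic criteria for
#' which disorders: the bipartite structure underlying a symptom network.
#' Projecting it onto the symptom mode (see
#' [project_to_symptom_graph()]) connects two symptoms whenever they are
#' criteria for the same disorder, so each disorder's symptom set induces a
#' clique.
#'
#' @param memberships a two-column data frame (symptom, disorder), one row per
#'   symptom-disorder membership. Whitespace around identifiers is trimmed;
#'   case is preserved. Duplicate rows are collapsed with a warning.
#' @param symptoms,disorders optional character vectors fixing identifier
#'   order; defaults to order of first appearance.
#' @param chapters optional named character vector of category labels, one per
#'   disorder.
#' @return an object of class `incidence_table` with components `symptoms`,
#'   `disorders`, `membership` (data frame), and optionally `chapters`.
#' @examples
#' tab <- incidence_table(data.frame(
#'   symptom  = c("mDep", "mInt"),
#'   disorder = c("MDE", "MDE")))
#' tab
#' @seealso [read_incidence()], [project_to_symptom_graph()]
#' @export
incidence_table <- function(memberships, symptoms = NULL, disorders = NULL,
                            chapters = NULL) {
  stopifnot(is.data.frame(memberships), ncol(memberships) >= 2)
  mem <- data.frame(
    symptom  = trimws(as.character(memberships[[1L]])),
    disorder = trimws(as.character(memberships[[2L]])),
    stringsAsFactors = FALSE)
  if (any(!nzchar(mem$symptom)) || any(!nzchar(mem$disorder)))
    stop("empty symptom or disorder identifier in membership rows")
  dup <- duplicated(mem)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate membership row(s)", sum(dup)))
    mem <- mem[!dup, , drop = FALSE]
  }
  if (is.null(symptoms))  symptoms  <- unique(mem$symptom)
  if (is.null(disorders)) disorders <- unique(mem$disorder)
  symptoms  <- trimws(symptoms)
  disorders <- trimws(disorders)
  if (anyDuplicated(symptoms))  stop("duplicate symptom identifiers")
  if (anyDuplicated(disorders)) stop("duplicate disorder identifiers")
  if (!all(mem$symptom %in% symptoms))
    stop("membership references undeclared symptom(s): ",
         paste(setdiff(mem$symptom, symptoms), collapse = ", "))
  if (!all(mem$disorder %in% disorders))
    stop("membership references undeclared disorder(s): ",
         paste(setdiff(mem$disorder, disorders), collapse = ", "))
  missing_d <- setdiff(disorders, mem$disorder)
  if (length(missing_d))
    stop("disorder(s) with no symptoms: ", paste(missing_d, collapse = ", "))
  missing_s <- setdiff(symptoms, mem$symptom)
  if (length(missing_s))
    stop("symptom(s) with no disorder membership: ",
         paste(missing_s, collapse = ", "))
  out <- list(symptoms = symptoms, disorders = disorders, membership = mem)
  if (!is.null(chapters)) {
    stopifnot(!is.null(names(chapters)), all(disorders %in% names(chapters)))
    out$chapters <- chapters[disorders]
  }
  structure(out, class = "incidence_table")
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("Symptom-disorder incidence table: %d symptoms, %d disorders, %d memberships\n",
              length(x$symptoms), length(x$disorders), nrow(x$membership)))
  invisible(x)
}

#' @export
summary.incidence_table <- function(object, ...) {
  sizes <- table(object$membership$disorder)
  deg   <- table(object$membership$symptom)
  cat(sprintf("%d symptoms, %d disorders, %d memberships\n",
              length(object$symptoms), length(object$disorders),
              nrow(object$membership)))
  cat(sprintf("disorder size: min %d, median %g, max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  cat(sprintf("symptom bipartite degree: min %d, median %g, max %d\n",
              min(deg), stats::median(deg), max(deg)))
  invisible(object)
}

#' Symptom sets per disorder
#'
#' @param table an [incidence_table()].
#' @return named list mapping each disorder to its character vector of symptoms.
#' @export
disorder_symptoms <- function(table) {
  stopifnot(inherits(table, "incidence_table"))
  out <- split(table$membership$symptom, table$membership$disorder)
  out[table$disorders]
}

#' Disorders per symptom (back-map)
#'
#' @param table an [incidence_table()].
#' @return named list mapping each symptom to the disorders it belongs to.
#' @export
symptom_disorders <- function(table) {
  stopifnot(inherits(table, "incidence_table"))
  out <- split(table$membership$disorder, table$membership$symptom)
  out[table$symptoms]
}

#' Read an incidence table from file
#'
#' Accepts two dialects: long-form two-column text (`symptom<sep>disorder`,
#' header required; the canonical format) and a labeled 0/1 matrix whose rows
#' are symptoms and columns disorders. The separator is taken from the file
#' extension (`.tsv` tab, `.csv` comma) unless `sep` is given.
#'
#' @param path file path.
#' @param dialect `"auto"` (default; matrices are detected by all columns
#'   beyond the first being 0/1-valued and more than 2 columns, or by an empty
#'   top-left header cell), `"long"`, or `"matrix"`.
#' @param sep field separator; default by extension.
#' @return an [incidence_table()].
#' @export
read_incidence <- function(path, dialect = c("auto", "long", "matrix"),
                           sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  if (dialect == "auto") {
    is01 <- ncol(raw) > 2 &&
      all(vapply(raw[-1L], function(col) all(col %in% c(0, 1)), logical(1)))
    dialect <- if (is01) "matrix" else "long"
  }
  if (dialect == "long") {
    if (ncol(raw) < 2)
      stop("malformed long-form file (need two columns): ", path)
    bad <- which(is.na(raw[[1L]]) | is.na(raw[[2L]]) |
                   !nzchar(trimws(raw[[1L]])) | !nzchar(trimws(raw[[2L]])))
    if (length(bad))
      stop(sprintf("malformed row(s) at line(s) %s of %s",
                   paste(bad + 1L, collapse = ", "), path))
    incidence_table(raw[, 1:2])
  } else {
    m <- as.matrix(raw[-1L])
    if (!all(m %in% c(0, 1))) stop("matrix dialect requires 0/1 entries")
    rownames(m) <- trimws(as.character(raw[[1L]]))
    idx <- which(m == 1, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("matrix has no memberships")
    empty <- colnames(m)[colSums(m) == 0]
    if (length(empty))
      stop("disorder(s) with no symptoms: ", paste(empty, collapse = ", "))
    incidence_table(
      data.frame(symptom = rownames(m)[idx[, 1L]],
                 disorder = colnames(m)[idx[, 2L]]),
      symptoms = rownames(m)[rowSums(m) > 0], disorders = colnames(m))
  }
}

#' Write an incidence table as long-form TSV
#'
#' @param table an [incidence_table()].
#' @param path output file path.
#' @export
write_incidence <- function(table, path) {
  stopifnot(inherits(table, "incidence_table"))
  utils::write.table(table$membership, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Incidence table as a binary matrix
#'
#' @param table an [incidence_table()].
#' @return integer 0/1 matrix, symptoms in rows, disorders in columns.
#' @export
as_incidence_matrix <- function(table) {
  stopifnot(inherits(table, "incidence_table"))
  m <- matrix(0L, length(table$symptoms), length(table$disorders),
              dimnames = list(table$symptoms, table$disorders))
  m[cbind(table$membership$symptom, table$membership$disorder)] <- 1L
  m
}

#' Project an incidence table onto the symptom space
#'
#' Two symptoms are joined by an edge whenever they are criteria for at least
#' one common disorder, so each disorder's symptom set induces a clique and
#' all its symptoms lie in one connected component. The graph is simple: a
#' pair co-occurring in several disorders yields a single edge, with the
#' co-occurrence count kept as edge attribute `weight` (unused by the
#' statistics).
#'
#' @param table an [incidence_table()].
#' @return an undirected simple `igraph` graph with vertex names equal to the
#'   symptom identifiers (including symptoms isolated in the projection).
#' @examples
#' g <- project_to_symptom_graph(mde_gad_fixture()$table)
#' igraph::ecount(g)  # 66
#' @export
project_to_symptom_graph <- function(table) {
  stopifnot(inherits(table, "incidence_table"))
  sets <- disorder_symptoms(table)
  pairs <- lapply(sets, function(s) {
    s <- sort(unique(s))
    if (length(s) < 2L) return(NULL)
    t(utils::combn(s, 2L))
  })
  ep <- do.call(rbind, pairs)
  g <- igraph::make_empty_graph(n = length(table$symptoms), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = table$symptoms)
  if (!is.null(ep)) {
    key <- paste(ep[, 1L], ep[, 2L], sep = "\r")
    w <- table(key)
    uq <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(uq)))
    g <- igraph::set_edge_attr(g, "weight", value = as.integer(w))
  }
  g
}

#' Write / read a symptom graph
#'
#' Edge lists are plain text, one `u<TAB>v` line per edge (isolated vertices
#' are not representable in this format); GraphML round-trips the full graph
#' including isolated vertices and node labels.
#'
#' @param graph an `igraph` graph with named vertices.
#' @param path file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @export
write_graph_file <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(graph))
  if (format == "edgelist") {
    el <- igraph::as_edgelist(graph, names = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(el))
      writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  } else {
    igraph::write_graph(graph, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_graph_file
#' @export
read_graph_file <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "edgelist") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(igraph::make_empty_graph(directed = FALSE))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed edge-list line(s) in ", path)
    el <- do.call(rbind, parts)
    igraph::graph_from_edgelist(el, directed = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    igraph::as_undirected(g, mode = "collapse")
  }
}

#' Check the disorder-clique property of a projection
#'
#' Verifies that every disorder's symptom set induces a complete subgraph of
#' `graph`, which is the defining invariant of the projection.
#'
#' @param graph projected symptom graph.
#' @param table the source [incidence_table()].
#' @return `TRUE` (invisibly) or an error naming the offending disorder.
#' @export
assert_disorder_cliques <- function(graph, table) {
  sets <- disorder_symptoms(table)
  for (d in names(sets)) {
    s <- unique(sets[[d]])
    if (length(s) < 2L) next
    sub <- igraph::induced_subgraph(graph, s)
    want <- choose(length(s), 2L)
    if (igraph::ecount(sub) != want)
      stop(sprintf("disorder %s does not induce a clique (%d of %d edges)",
                   d, igraph::ecount(sub), want))
  }
  invisible(TRUE)
}
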