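#' Region adjacency graphs
#'
#' A `region_graph` holds the neighbourhood structure of the administrative
#' regions a survey is stratified on: an ordered vector of region labels and a
#' symmetric set of adjacent (unordered) label pairs. It is the support of the
#' structured (intrinsic CAR) spatial prior: two regions are smoothed towards
#' each other exactly when they are adjacent. The label order given at
#' construction is the canonical index order for every matrix derived from the
#' graph and is never re-sorted.
#'
#' @param labels character vector of unique region labels, in canonical order.
#' @param adjacency two-column character matrix (or data.frame) of adjacent
#'   label pairs; each pair is stored unordered, duplicates are collapsed.
#' @return an object of class `region_graph` with elements `labels`
#'   (character) and `adjacency` (two-column character matrix, one row per
#'   unordered pair, pair members sorted within row).
#' @examples
#' g <- region_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' region_degrees(g)
#' @export
region_graph <- function(labels, adjacency = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("duplicate region labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (length(labels) < 1L) stop("at least one region label required")
  if (is.null(adjacency) || NROW(adjacency) == 0L) {
    adj <- matrix(character(0), ncol = 2L)
  } else {
    adj <- as.matrix(adjacency)
    if (ncol(adj) != 2L) stop("adjacency must have two columns")
    adj <- matrix(as.character(adj), ncol = 2L)
    bad <- setdiff(c(adj), labels)
    if (length(bad)) {
      stop("adjacency references unknown labels: ", paste(bad, collapse = ", "))
    }
    if (any(adj[, 1L] == adj[, 2L])) {
      i <- which(adj[, 1L] == adj[, 2L])[1L]
      stop("self-adjacency not allowed: ", adj[i, 1L])
    }
    adj <- t(apply(adj, 1L, sort))
    adj <- adj[!duplicated(paste(adj[, 1L], adj[, 2L], sep = "\r")), ,
               drop = FALSE]
    # deterministic row order: by canonical label positions
    o <- order(match(adj[, 1L], labels), match(adj[, 2L], labels))
    adj <- adj[o, , drop = FALSE]
  }
  colnames(adj) <- c("from", "to")
  structure(list(labels = labels, adjacency = adj), class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph:", length(x$labels), "regions,",
      nrow(x$adjacency), "adjacent pairs\n")
  cat("labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.region_graph <- function(x, ...) {
  paste0("region_graph<", length(x$labels), " regions, ",
         nrow(x$adjacency), " pairs>")
}

#' Number of neighbours per region
#'
#' @param graph a [region_graph].
#' @return named integer vector in canonical label order.
#' @export
region_degrees <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  d <- integer(length(graph$labels))
  names(d) <- graph$labels
  if (nrow(graph$adjacency)) {
    t1 <- table(factor(graph$adjacency[, 1L], levels = graph$labels))
    t2 <- table(factor(graph$adjacency[, 2L], levels = graph$labels))
    d <- as.integer(t1 + t2)
    names(d) <- graph$labels
  }
  d
}

adjacency_matrix <- function(graph) {
  n <- length(graph$labels)
  A <- matrix(0L, n, n, dimnames = list(graph$labels, graph$labels))
  if (nrow(graph$adjacency)) {
    i <- match(graph$adjacency[, 1L], graph$labels)
    j <- match(graph$adjacency[, 2L], graph$labels)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  A
}

#' Read a BayesX-style .gra adjacency file
#'
#' The format is: first non-empty token the number of regions, then one block
#' per region consisting of its label, its neighbour count, and that many
#' neighbour references. Neighbour references may be labels or 1-based indices
#' into the label order of the file; labels are canonical. Symmetry is checked,
#' not assumed: a file declaring A next to B but not B next to A is rejected.
#'
#' @param path path to a `.gra` file.
#' @return a validated [region_graph]; its `labels` order is the file order.
#' @export
read_gra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  toks_by_line <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  flat <- list() # token with originating line number
  for (ln in seq_along(toks_by_line)) {
    for (tk in toks_by_line[[ln]]) {
      if (nzchar(tk)) flat[[length(flat) + 1L]] <- list(tok = tk, line = ln)
    }
  }
  if (!length(flat)) stop("empty .gra file: ", path)
  pos <- 1L
  take <- function() {
    if (pos > length(flat)) stop("unexpected end of file in ", path)
    v <- flat[[pos]]
    pos <<- pos + 1L
    v
  }
  n_tok <- take()
  n <- suppressWarnings(as.integer(n_tok$tok))
  if (is.na(n) || n < 1L) {
    stop("line ", n_tok$line, ": region count expected, got '", n_tok$tok, "'")
  }
  labels <- character(n)
  raw_nbrs <- vector("list", n)
  nbr_lines <- vector("list", n)
  for (i in seq_len(n)) {
    labels[i] <- take()$tok
    cnt_tok <- take()
    cnt <- suppressWarnings(as.integer(cnt_tok$tok))
    if (is.na(cnt) || cnt < 0L) {
      stop("line ", cnt_tok$line, ": neighbour count expected for region '",
           labels[i], "', got '", cnt_tok$tok, "'")
    }
    nb <- character(cnt)
    nl <- integer(cnt)
    for (k in seq_len(cnt)) {
      v <- take()
      nb[k] <- v$tok
      nl[k] <- v$line
    }
    raw_nbrs[[i]] <- nb
    nbr_lines[[i]] <- nl
  }
  if (pos <= length(flat)) {
    stop("line ", flat[[pos]]$line, ": trailing tokens after last region block",
         " (count mismatch?)")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate region labels in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  # resolve references: label first, else 1-based index
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- raw_nbrs[[i]]
    out <- character(length(nb))
    for (k in seq_along(nb)) {
      if (nb[k] %in% labels) {
        out[k] <- nb[k]
      } else {
        idx <- suppressWarnings(as.integer(nb[k]))
        if (!is.na(idx) && idx >= 1L && idx <= n &&
            !(as.character(idx) %in% labels)) {
          out[k] <- labels[idx]
        } else {
          stop("line ", nbr_lines[[i]][k], ": unknown neighbour '", nb[k],
               "' for region '", labels[i], "'")
        }
      }
    }
    if (labels[i] %in% out) {
      stop("region '", labels[i], "' listed as its own neighbour")
    }
    nbrs[[i]] <- out
  }
  # symmetry check
  for (i in seq_len(n)) {
    for (nb in nbrs[[i]]) {
      j <- match(nb, labels)
      if (!(labels[i] %in% nbrs[[j]])) {
        stop("asymmetric pair (", labels[i], ",", nb, "): '", labels[i],
             "' lists '", nb, "' but not vice versa")
      }
    }
  }
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(nbrs[[i]])) cbind(labels[i], nbrs[[i]]) else NULL
  }))
  region_graph(labels, pairs)
}

#' Write a region graph to a .gra adjacency file
#'
#' Emits the label-reference dialect accepted by [read_gra]; the round trip
#' `read_gra(write_gra(g))` reproduces `g` exactly (same label order, same
#' adjacency set).
#'
#' @param graph a [region_graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gra <- function(graph, path) {
  stopifnot(inherits(graph, "region_graph"))
  nbrs <- neighbour_list(graph)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(as.character(length(graph$labels)), con)
  for (lab in graph$labels) {
    writeLines(lab, con)
    nb <- nbrs[[lab]]
    writeLines(as.character(length(nb)), con)
    if (length(nb)) writeLines(paste(nb, collapse = " "), con)
  }
  invisible(path)
}

neighbour_list <- function(graph) {
  out <- stats::setNames(vector("list", length(graph$labels)), graph$labels)
  for (lab in graph$labels) out[[lab]] <- character(0)
  if (nrow(graph$adjacency)) {
    for (r in seq_len(nrow(graph$adjacency))) {
      a <- graph$adjacency[r, 1L]
      b <- graph$adjacency[r, 2L]
      out[[a]] <- c(out[[a]], b)
      out[[b]] <- c(out[[b]], a)
    }
  }
  lapply(out, function(v) v[order(match(v, graph$labels))])
}

#' Read a two-column edge list as a region graph
#'
#' Tab- or whitespace-separated, one adjacent pair per line; optional isolated
#' regions can be appended through `extra_labels`.
#'
#' @param path path to the edge-list file.
#' @param extra_labels labels with no edges to include in the graph.
#' @return a [region_graph]; label order is first-appearance order.
#' @export
read_edge_list <- function(path, extra_labels = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pairs <- do.call(rbind, lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) != 2L) {
      stop("line ", i, ": expected two labels, got ", length(toks))
    }
    toks
  }))
  labels <- unique(c(if (!is.null(pairs)) as.vector(t(pairs)),
                     as.character(extra_labels)))
  region_graph(labels, pairs)
}

#' Intrinsic-CAR (graph Laplacian) precision matrix
#'
#' Returns the degree-minus-adjacency matrix that scales the structured
#' spatial prior: diagonal entries are region degrees, off-diagonals are -1
#' for adjacent pairs and 0 otherwise. Every row sums to zero exactly and the
#' rank equals the number of regions minus the number of connected components,
#' which is why the prior is improper and the structured effect needs a
#' sum-to-zero constraint per component.
#'
#' @param graph a [region_graph] with at least 2 regions.
#' @return an object of class `icar_precision`: the integer matrix with
#'   attributes `rank` (integer) and `n_components`.
#' @export
icar_precision <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  if (length(graph$labels) < 2L) stop("at least 2 regions required")
  A <- adjacency_matrix(graph)
  d <- region_degrees(graph)
  if (any(d == 0L)) {
    warning("isolated region(s): ", paste(names(d)[d == 0L], collapse = ", "),
            "; structured effect pinned to 0 there by its own",
            " sum-to-zero block")
  }
  Q <- diag(d) - A
  dimnames(Q) <- dimnames(A)
  comp <- connected_components(graph)
  structure(Q, rank = length(graph$labels) - length(comp),
            n_components = length(comp), class = c("icar_precision", "matrix"))
}

#' Connected components of a region graph
#'
#' @param graph a [region_graph].
#' @return list of character vectors, each a component in canonical label
#'   order; components ordered by their first label.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  labels <- graph$labels
  nbrs <- neighbour_list(graph)
  seen <- stats::setNames(rep(FALSE, length(labels)), labels)
  comps <- list()
  for (lab in labels) {
    if (seen[[lab]]) next
    stack <- lab
    comp <- character(0)
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[[cur]]) next
      seen[[cur]] <- TRUE
      comp <- c(comp, cur)
      stack <- c(stack, nbrs[[cur]][!seen[nbrs[[cur]]]])
    }
    comps[[length(comps) + 1L]] <- comp[order(match(comp, labels))]
  }
  comps
}

#' Per-region component index
#'
#' @param graph a [region_graph].
#' @return integer vector (canonical order) giving each region's component id.
#' @keywords internal
component_index <- function(graph) {
  comps <- connected_components(graph)
  idx <- integer(length(graph$labels))
  names(idx) <- graph$labels
  for (k in seq_along(comps)) idx[comps[[k]]] <- k
  idx
}
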