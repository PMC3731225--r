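#' Construct a signed gene regulatory network
#'
#' A `grn` holds gene nodes and signed regulatory edges. Nodes carry a
#' 1-based order number, a symbol and a marker role; edges carry a sign
#' (`"act"` or `"rep"`) and an optional per-link strength. Edges without a
#' strength fall back to the global activation/repression constants of the
#' kinetic parameter set when the force field is evaluated.
#'
#' @param nodes data frame with columns `id` (1-based contiguous integers),
#'   `name` (unique gene symbols) and optionally `role` (one of
#'   `"stem_marker"`, `"diff_marker"`, `"stem_activated"`, `"other"`;
#'   defaults to `"other"`).
#' @param edges data frame with columns `source`, `target` (gene names or
#'   integer ids), `sign` (`"act"` or `"rep"`) and optionally `strength`
#'   (positive real, `NA` for the global default).
#' @return An object of class `grn`.
#' @export
grn <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(nodes$role)) nodes$role <- "other"
  nodes$id <- as.integer(nodes$id)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (!identical(nodes$id, seq_len(nrow(nodes))))
    stop("node ids must be unique and contiguous from 1")
  if (anyDuplicated(nodes$name))
    stop("node names must be unique")
  roles <- c("stem_marker", "diff_marker", "stem_activated", "other")
  if (!all(nodes$role %in% roles))
    stop("unknown node role: ", paste(setdiff(nodes$role, roles), collapse = ", "))
  edges$source <- resolve_nodes(edges$source, nodes)
  edges$target <- resolve_nodes(edges$target, nodes)
  if (!all(edges$sign %in% c("act", "rep")))
    stop("edge sign must be 'act' or 'rep', got: ",
         paste(unique(setdiff(edges$sign, c("act", "rep"))), collapse = ", "))
  if (is.null(edges$strength)) edges$strength <- rep(NA_real_, nrow(edges))
  edges$strength <- as.numeric(edges$strength)
  if (any(!is.na(edges$strength) & edges$strength <= 0))
    stop("edge strengths must be positive")
  if (anyDuplicated(edges[, c("source", "target", "sign")]))
    stop("duplicate (source, target, sign) edge")
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "grn")
}

resolve_nodes <- function(x, nodes) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    bad <- !(x %in% nodes$id)
  } else {
    ix <- match(x, nodes$name)
    bad <- is.na(ix)
    x <- ix
  }
  if (any(bad))
    stop("edge references unknown node(s): ", paste(unique(x[bad]), collapse = ", "))
  x
}

#' @export
print.grn <- function(x, ...) {
  ne <- nrow(x$edges)
  cat(sprintf("Gene regulatory network: %d nodes, %d edges (%d activation, %d repression)\n",
              nrow(x$nodes), ne, sum(x$edges$sign == "act"), sum(x$edges$sign == "rep")))
  rl <- table(x$nodes$role)
  cat("Roles:", paste(sprintf("%s=%d", names(rl), rl), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.grn <- function(object, ...) {
  print(object)
  deg_in <- tabulate(object$edges$target, nrow(object$nodes))
  deg_out <- tabulate(object$edges$source, nrow(object$nodes))
  cat(sprintf("In-degree: median %g, max %d; out-degree: median %g, max %d\n",
              stats::median(deg_in), max(deg_in), stats::median(deg_out), max(deg_out)))
  invisible(object)
}

#' Global Hill kinetic constants
#'
#' Constants of the additive Hill rate law
#' \deqn{dx_i/dt = -k x_i + \sum_{j \in act(i)} a \frac{x_j^n}{S^n + x_j^n}
#'   + \sum_{j \in rep(i)} b \frac{S^n}{S^n + x_j^n}.}
#' `S` is the regulation threshold (inflection point) and `n` the Hill
#' coefficient; `a` and `b` are the default activation and repression
#' strengths used by edges without an explicit per-link strength.
#'
#' @param a activation constant (> 0, concentration/time).
#' @param b repression constant (> 0).
#' @param k first-order degradation constant (> 0, 1/time).
#' @param S Hill threshold (> 0, concentration).
#' @param n Hill coefficient (>= 1, dimensionless).
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(a = 0.5, b = 0.5, k = 1, S = 0.5, n = 4) {
  stopifnot(a > 0, b > 0, k > 0, S > 0, n >= 1)
  structure(list(a = a, b = b, k = k, S = S, n = n), class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill kinetics: a=%g, b=%g, k=%g, S=%g, n=%g\n", x$a, x$b, x$k, x$S, x$n))
  invisible(x)
}

# Resolved edge arrays for the force field / compiled simulators.
edge_arrays <- function(net, p) {
  e <- net$edges
  w <- e$strength
  w[is.na(w)] <- ifelse(e$sign[is.na(w)] == "act", p$a, p$b)
  list(src = e$source - 1L, tgt = e$target - 1L,
       act = as.integer(e$sign == "act"), w = w)
}

#' Read a network from a tab-separated edge list
#'
#' One edge per line: `SOURCE<TAB>act|rep<TAB>TARGET`, `#` comment lines
#' allowed. An optional annotation sidecar (`name<TAB>id<TAB>role`) fixes
#' node order numbers and marker roles; otherwise nodes are numbered in
#' order of first appearance with role `"other"`. An optional strengths
#' file (`SOURCE<TAB>act|rep<TAB>TARGET<TAB>value`) sets per-link strengths.
#'
#' @param path edge-list file.
#' @param annotations_path optional node annotation TSV.
#' @param strengths_path optional per-link strength TSV.
#' @return A [grn].
#' @export
read_network <- function(path, annotations_path = NULL, strengths_path = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  ln <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", ln)
  rows <- strsplit(ln[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) < 3)
      stop(sprintf("parse error at line %d: expected SOURCE<TAB>SIGN<TAB>TARGET", lineno[i]))
    if (!rows[[i]][2] %in% c("act", "rep"))
      stop(sprintf("parse error at line %d: unknown sign token '%s'", lineno[i], rows[[i]][2]))
  }
  edges <- data.frame(source = vapply(rows, `[`, "", 1),
                      sign = vapply(rows, `[`, "", 2),
                      target = vapply(rows, `[`, "", 3),
                      stringsAsFactors = FALSE)
  if (!is.null(annotations_path)) {
    ann <- utils::read.table(annotations_path, sep = "\t", header = FALSE,
                             col.names = c("name", "id", "role"),
                             stringsAsFactors = FALSE, comment.char = "#")
    nodes <- data.frame(id = as.integer(ann$id), name = ann$name, role = ann$role,
                        stringsAsFactors = FALSE)
    unknown <- setdiff(unique(c(edges$source, edges$target)), nodes$name)
    if (length(unknown))
      stop("edge references node(s) absent from annotations: ",
           paste(unknown, collapse = ", "))
  } else {
    nm <- unique(c(rbind(edges$source, edges$target)))
    nodes <- data.frame(id = seq_along(nm), name = nm, role = "other",
                        stringsAsFactors = FALSE)
  }
  net <- grn(nodes, edges[, c("source", "target", "sign")])
  if (!is.null(strengths_path)) {
    st <- utils::read.table(strengths_path, sep = "\t", header = FALSE,
                            col.names = c("source", "sign", "target", "value"),
                            stringsAsFactors = FALSE, comment.char = "#")
    for (i in seq_len(nrow(st)))
      net <- set_link_strength(net, st$source[i], st$target[i], st$sign[i],
                               st$value[i])
  }
  net
}

#' Write a network to the tab-separated edge-list format
#'
#' Inverse of [read_network()]: writes the edge list, a node annotation
#' sidecar and (when any per-link strength is set) a strengths file.
#'
#' @param net a [grn].
#' @param path edge-list file to write.
#' @param annotations_path,strengths_path optional sidecar paths.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, annotations_path = NULL,
                          strengths_path = NULL) {
  nm <- net$nodes$name
  writeLines(sprintf("%s\t%s\t%s", nm[net$edges$source], net$edges$sign,
                     nm[net$edges$target]), path)
  if (!is.null(annotations_path))
    writeLines(sprintf("%s\t%d\t%s", nm, net$nodes$id, net$nodes$role),
               annotations_path)
  if (!is.null(strengths_path)) {
    has <- !is.na(net$edges$strength)
    writeLines(sprintf("%s\t%s\t%s\t%.17g", nm[net$edges$source[has]],
                       net$edges$sign[has], nm[net$edges$target[has]],
                       net$edges$strength[has]), strengths_path)
  }
  invisible(path)
}

find_edge <- function(net, source, target, sign) {
  source <- resolve_nodes(source, net$nodes)
  target <- resolve_nodes(target, net$nodes)
  i <- which(net$edges$source == source & net$edges$target == target &
             net$edges$sign == sign)
  if (!length(i))
    stop(sprintf("no %s edge %s -> %s in the network", sign,
                 net$nodes$name[source], net$nodes$name[target]))
  i
}

#' Set the strength of one regulatory link
#'
#' Returns a modified copy; the input network is untouched. A strength
#' equal to the global default makes the force field identical to the
#' unmodified network.
#'
#' @param net a [grn].
#' @param source,target gene name or id.
#' @param sign `"act"` or `"rep"`.
#' @param value positive real strength.
#' @return The modified [grn].
#' @export
set_link_strength <- function(net, source, target, sign, value) {
  stopifnot(is.numeric(value), value > 0)
  i <- find_edge(net, source, target, sign)
  net$edges$strength[i] <- value
  net
}
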