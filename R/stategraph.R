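#' Binarize a trajectory to high/low codes
#'
#' Per-gene cutoff `(max - min)/2 + min` over the trajectory; values at
#' or above the cutoff code as 1 (high), below as 0. Genes constant over
#' the whole trajectory are flagged with a warning and coded 0.
#'
#' @param traj state matrix (rows = time points, columns = genes).
#' @param cutoffs optional explicit per-gene cutoffs overriding the
#'   trajectory-derived ones.
#' @return Object of class `grn_btraj`: integer `codes` matrix and the
#'   `cutoffs` used.
#' @export
binarize <- function(traj, cutoffs = NULL) {
  traj <- as.matrix(traj)
  if (!nrow(traj)) stop("empty trajectory")
  lo <- apply(traj, 2, min); hi <- apply(traj, 2, max)
  derived <- is.null(cutoffs)
  # midpoint (max - min)/2 + min, computed as the mean for exact ties
  if (derived) cutoffs <- (hi + lo) / 2
  codes <- matrix(0L, nrow(traj), ncol(traj),
                  dimnames = dimnames(traj))
  codes[traj >= rep(cutoffs, each = nrow(traj))] <- 1L
  const <- hi == lo
  if (derived && any(const)) {
    codes[, const] <- 0L
    cn <- colnames(traj)
    warning("constant gene(s) coded 0: ",
            paste(if (is.null(cn)) which(const) else cn[const], collapse = ", "))
  }
  structure(list(codes = codes, cutoffs = cutoffs), class = "grn_btraj")
}

#' Project binary codes onto marker genes
#'
#' Keeps only the marker columns, in the given order. With the packaged
#' 52-gene network and markers 1-22 the stem attractor reads as eleven 1s
#' followed by eleven 0s and the differentiated attractor as the
#' complementary block pattern.
#'
#' @param btraj a `grn_btraj`.
#' @param marker_ids ordered integer ids or gene names.
#' @return A `grn_btraj` over the markers only.
#' @export
project_markers <- function(btraj, marker_ids) {
  stopifnot(inherits(btraj, "grn_btraj"))
  if (!length(marker_ids)) stop("empty marker list")
  if (is.character(marker_ids)) {
    ix <- match(marker_ids, colnames(btraj$codes))
    if (any(is.na(ix)))
      stop("unknown marker(s): ", paste(marker_ids[is.na(ix)], collapse = ", "))
  } else {
    ix <- as.integer(marker_ids)
    if (any(ix < 1 | ix > ncol(btraj$codes)))
      stop("marker id(s) out of range")
  }
  structure(list(codes = btraj$codes[, ix, drop = FALSE],
                 cutoffs = btraj$cutoffs[ix]), class = "grn_btraj")
}

code_strings <- function(codes) apply(codes, 1, paste, collapse = "")

hamming <- function(code, ref) {
  sum(utf8ToInt(code) != utf8ToInt(ref))
}

#' Build the probability-weighted cell-state transition graph
#'
#' State probability is occupancy fraction over the discretized
#' trajectory; transition probability is the fraction each ordered code
#' pair contributes among consecutive pairs with *different* codes
#' (self-transitions are excluded from the edge statistics; set
#' `conditional = TRUE` for per-source conditional probabilities
#' instead of joint fractions). States and transitions below
#' `prob_cutoff` are dropped, and each kept state is annotated with its
#' Hamming distance to the stem and differentiated reference codes.
#'
#' @param btraj a `grn_btraj` (typically marker-projected).
#' @param prob_cutoff probability cutoff in `[0, 1)`; the published
#'   analysis used 0.0002.
#' @param stem_code,diff_code reference code strings (default: all-ones /
#'   all-zeros blocks of half the code length, the marker convention).
#' @param conditional report per-source conditional transition
#'   probabilities instead of joint fractions.
#' @return Object of class `grn_stategraph`: data frames `states`
#'   (`code`, `prob`, `hamming_stem`, `hamming_diff`) and `transitions`
#'   (`from`, `to`, `prob`), plus metadata.
#' @export
build_state_graph <- function(btraj, prob_cutoff = 0, stem_code = NULL,
                              diff_code = NULL, conditional = FALSE) {
  stopifnot(inherits(btraj, "grn_btraj"),
            prob_cutoff >= 0, prob_cutoff < 1)
  if (!nrow(btraj$codes)) stop("empty trajectory")
  L <- ncol(btraj$codes)
  if (is.null(stem_code))
    stem_code <- paste(rep(c("1", "0"), c(ceiling(L / 2), floor(L / 2))),
                       collapse = "")
  if (is.null(diff_code))
    diff_code <- paste(rev(strsplit(stem_code, "")[[1]]) , collapse = "")
  cs <- code_strings(btraj$codes)
  occ <- table(cs) / length(cs)
  from <- cs[-length(cs)]; to <- cs[-1]
  move <- from != to
  tr <- data.frame(from = from[move], to = to[move], stringsAsFactors = FALSE)
  if (nrow(tr)) {
    key <- paste(tr$from, tr$to, sep = ">")
    cnt <- table(key)
    parts <- strsplit(names(cnt), ">", fixed = TRUE)
    tr <- data.frame(from = vapply(parts, `[`, "", 1),
                     to = vapply(parts, `[`, "", 2),
                     count = as.integer(cnt), stringsAsFactors = FALSE)
    if (conditional) {
      tot <- tapply(tr$count, tr$from, sum)
      tr$prob <- tr$count / as.numeric(tot[tr$from])
    } else tr$prob <- tr$count / sum(tr$count)
  } else tr <- data.frame(from = character(0), to = character(0),
                          count = integer(0), prob = numeric(0))
  states <- data.frame(code = names(occ), prob = as.numeric(occ),
                       stringsAsFactors = FALSE)
  states$hamming_stem <- vapply(states$code, hamming, 0L, ref = stem_code)
  states$hamming_diff <- vapply(states$code, hamming, 0L, ref = diff_code)
  keep <- states$prob >= prob_cutoff | prob_cutoff == 0
  states <- states[keep, , drop = FALSE]
  tr <- tr[tr$from %in% states$code & tr$to %in% states$code &
           tr$prob >= prob_cutoff, , drop = FALSE]
  rownames(states) <- rownames(tr) <- NULL
  structure(list(states = states[order(-states$prob), , drop = FALSE],
                 transitions = tr[order(-tr$prob), , drop = FALSE],
                 stem_code = stem_code, diff_code = diff_code,
                 prob_cutoff = prob_cutoff, conditional = conditional,
                 self_loops = "excluded"),
            class = "grn_stategraph")
}

#' @export
print.grn_stategraph <- function(x, ...) {
  cat(sprintf("Cell-state graph: %d states, %d transitions (cutoff %g, %s edge probabilities)\n",
              nrow(x$states), nrow(x$transitions), x$prob_cutoff,
              if (x$conditional) "conditional" else "joint"))
  print(utils::head(x$states, 5))
  invisible(x)
}

#' Export a state graph to GraphML, SIF or TSV
#'
#' GraphML (via igraph) carries node attributes `prob`, `hamming_stem`,
#' `hamming_diff` and edge attribute `weight` (= transition probability)
#' and round-trips losslessly. SIF (`from<TAB>to<TAB>target`) and TSV
#' (edge table with probabilities) are lossy convenience formats.
#'
#' @param g a `grn_stategraph` (nonempty).
#' @param path output file.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "sif", "tsv")) {
  stopifnot(inherits(g, "grn_stategraph"))
  if (!nrow(g$states)) stop("empty graph")
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- igraph::graph_from_data_frame(
      d = data.frame(from = g$transitions$from, to = g$transitions$to,
                     weight = g$transitions$prob),
      directed = TRUE,
      vertices = data.frame(name = g$states$code, prob = g$states$prob,
                            hamming_stem = g$states$hamming_stem,
                            hamming_diff = g$states$hamming_diff))
    igraph::write_graph(ig, path, format = "graphml")
  } else if (format == "sif") {
    writeLines(sprintf("%s\tto\t%s", g$transitions$from, g$transitions$to),
               path)
  } else {
    utils::write.table(g$transitions[, c("from", "to", "prob")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a GraphML state graph
#'
#' Inverse of [export_graph()] for the GraphML format.
#'
#' @param path GraphML file.
#' @return A `grn_stategraph` (without cutoff metadata).
#' @export
import_graph <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  vs <- igraph::as_data_frame(ig, "vertices")
  es <- igraph::as_data_frame(ig, "edges")
  structure(list(states = data.frame(code = vs$name, prob = vs$prob,
                                     hamming_stem = vs$hamming_stem,
                                     hamming_diff = vs$hamming_diff,
                                     stringsAsFactors = FALSE),
                 transitions = data.frame(from = es$from, to = es$to,
                                          prob = es$weight,
                                          stringsAsFactors = FALSE),
                 stem_code = NA, diff_code = NA, prob_cutoff = NA,
                 conditional = NA, self_loops = "excluded"),
            class = "grn_stategraph")
}
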