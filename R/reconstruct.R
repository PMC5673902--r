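## Long-range rearrangement reconstruction from phase-partitioned split
## alignments: merged segment nodes, read-co-support edges, greedy
## maximum-weight contig paths, and junction chaining into derivative
## chromosomes.

#' Build the segment-overlap graph
#'
#' Segments (pre-filtered to one haplotype) are sorted by left reference
#' coordinate and greedily merged into nodes: a segment joins an existing
#' node when it overlaps the node interval and at least two of the node's
#' member segments extend past its start by `min_ext` bp (for the first
#' member of a node, one such supporter suffices — a pairwise seed). Edges
#' connect nodes co-supported by two segments of one read and are weighted
#' by the number of such reads.
#'
#' @param segments Segment `data.frame` (one haplotype: e.g. paternal plus
#'   unphased reads).
#' @param min_ext Minimum supporter extension past the candidate's start
#'   (default 20 bp).
#' @return List of class `"segment_graph"`: `nodes` (`data.frame`: `node`,
#'   `chrom`, `start`, `end`, `n_segments`), `edges` (`data.frame`:
#'   `from`, `to`, `weight`, `same_strand`), and `membership` (node id per
#'   input segment row, in input order).
#' @export
build_segment_graph <- function(segments, min_ext = 20) {
  check_segments(segments)
  n <- nrow(segments)
  node_of <- integer(n)
  nodes <- list()
  ord <- order(segments$chrom, segments$ref_start, segments$ref_end)
  for (i in ord) {
    placed <- FALSE
    if (length(nodes) > 0) {
      last <- nodes[[length(nodes)]]
      if (last$chrom == segments$chrom[i] &&
          segments$ref_start[i] <= last$end) {
        supporters <- sum(last$ends - segments$ref_start[i] >= min_ext)
        if (supporters >= min(2L, length(last$ends))) {
          last$end <- max(last$end, segments$ref_end[i])
          last$ends <- c(last$ends, segments$ref_end[i])
          last$members <- c(last$members, i)
          nodes[[length(nodes)]] <- last
          node_of[i] <- length(nodes)
          placed <- TRUE
        }
      }
    }
    if (!placed) {
      nodes[[length(nodes) + 1]] <- list(
        chrom = segments$chrom[i],
        start = segments$ref_start[i], end = segments$ref_end[i],
        ends = segments$ref_end[i], members = i)
      node_of[i] <- length(nodes)
    }
  }
  node_df <- data.frame(
    node = seq_along(nodes),
    chrom = vapply(nodes, `[[`, "", "chrom"),
    start = vapply(nodes, function(x) min(segments$ref_start[x$members]), 0),
    end = vapply(nodes, `[[`, 0, "end"),
    n_segments = vapply(nodes, function(x) length(x$members), 0L),
    stringsAsFactors = FALSE)
  ## edges: all node pairs co-supported by segments of one read
  edge_env <- new.env(parent = emptyenv())
  for (idx in split(seq_len(n), segments$read_id)) {
    if (length(idx) < 2) next
    idx <- idx[order(segments$read_start[idx])]
    nd <- node_of[idx]
    st <- segments$strand[idx]
    pairs <- utils::combn(seq_along(idx), 2)
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      if (nd[a] == nd[b]) next
      key <- paste(min(nd[a], nd[b]), max(nd[a], nd[b]), sep = "-")
      cur <- if (exists(key, edge_env)) get(key, edge_env)
        else list(weight = 0L, same = 0L)
      cur$weight <- cur$weight + 1L
      cur$same <- cur$same + as.integer(st[a] == st[b])
      assign(key, cur, edge_env)
    }
  }
  keys <- ls(edge_env)
  edges <- if (length(keys) == 0) {
    data.frame(from = integer(), to = integer(), weight = integer(),
               same_strand = logical())
  } else {
    parts <- strsplit(keys, "-", fixed = TRUE)
    data.frame(
      from = as.integer(vapply(parts, `[`, "", 1)),
      to = as.integer(vapply(parts, `[`, "", 2)),
      weight = vapply(keys, function(k) get(k, edge_env)$weight, 0L),
      same_strand = vapply(keys, function(k) {
        e <- get(k, edge_env)
        e$same * 2L >= e$weight
      }, TRUE),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = node_df, edges = edges, membership = node_of),
            class = "segment_graph")
}

#' Build contigs by greedy maximum-weight paths
#'
#' Drops edges below weight `min_weight` (default 2), then repeatedly seeds a
#' path at the unused node with the highest total incident weight and
#' extends it greedily at both ends, always taking the locally heaviest
#' unused edge to an unvisited node (ties broken by node span, then by
#' coordinate). Each node and edge is used in at most one contig; paths with
#' no qualifying edge are not reported.
#'
#' @param graph `"segment_graph"` from [build_segment_graph()].
#' @param min_weight Minimum edge weight considered (default 2).
#' @return `data.frame` with one row per contig: `contig`, `n_nodes`,
#'   `total_weight`, `span` (bp sum of node widths), and a list-column
#'   `nodes` of ordered node ids with orientations (`+`/`-`) relative to the
#'   first node.
#' @export
build_contigs <- function(graph, min_weight = 2) {
  nodes <- graph$nodes
  edges <- graph$edges[graph$edges$weight >= min_weight, , drop = FALSE]
  empty <- data.frame(contig = integer(), n_nodes = integer(),
                      total_weight = integer(), span = double())
  empty$nodes <- list()
  if (nrow(edges) == 0) return(empty)
  adj <- lapply(seq_len(nrow(nodes)), function(i)
    which(edges$from == nodes$node[i] | edges$to == nodes$node[i]))
  incident_weight <- vapply(adj, function(e) sum(edges$weight[e]), 0)
  used_node <- rep(FALSE, nrow(nodes))
  used_edge <- rep(FALSE, nrow(edges))
  span_of <- nodes$end - nodes$start
  contigs <- list()
  repeat {
    avail <- which(!used_node & incident_weight > 0)
    avail <- avail[vapply(avail, function(i)
      any(!used_edge[adj[[i]]]), TRUE)]
    if (length(avail) == 0) break
    seed <- avail[order(-incident_weight[avail], nodes$chrom[avail],
                        nodes$start[avail])][1]
    path <- seed
    orient <- "+"
    used_node[seed] <- TRUE
    total_w <- 0L
    for (side in c("tail", "head")) {
      repeat {
        endn <- if (side == "tail") path[length(path)] else path[1]
        cand <- adj[[endn]]
        cand <- cand[!used_edge[cand]]
        other <- ifelse(edges$from[cand] == endn,
                        edges$to[cand], edges$from[cand])
        ok <- !used_node[other]
        cand <- cand[ok]; other <- other[ok]
        if (length(cand) == 0) break
        pick <- order(-edges$weight[cand], -span_of[other],
                      nodes$chrom[other], nodes$start[other])[1]
        e <- cand[pick]; nxt <- other[pick]
        used_edge[e] <- TRUE
        used_node[nxt] <- TRUE
        total_w <- total_w + edges$weight[e]
        prev_or <- if (side == "tail") orient[length(orient)] else orient[1]
        nxt_or <- if (edges$same_strand[e]) prev_or
          else if (prev_or == "+") "-" else "+"
        if (side == "tail") {
          path <- c(path, nxt)
          orient <- c(orient, nxt_or)
        } else {
          path <- c(nxt, path)
          orient <- c(nxt_or, orient)
        }
      }
    }
    if (length(path) > 1)
      contigs[[length(contigs) + 1]] <- list(path = path, orient = orient,
                                             weight = total_w)
  }
  if (length(contigs) == 0) return(empty)
  out <- data.frame(
    contig = seq_along(contigs),
    n_nodes = vapply(contigs, function(x) length(x$path), 0L),
    total_weight = vapply(contigs, function(x) as.integer(x$weight), 0L),
    span = vapply(contigs, function(x) sum(span_of[x$path]), 0))
  out$nodes <- lapply(contigs, function(x)
    data.frame(node = x$path, orientation = x$orient,
               chrom = nodes$chrom[x$path], start = nodes$start[x$path],
               end = nodes$end[x$path], stringsAsFactors = FALSE))
  out
}

#' Chain breakpoint junctions into derivative chromosome layouts
#'
#' Partitions each involved chromosome at the junction breakpoints and
#' chains the resulting reference segments by matching free segment ends
#' across junctions, respecting orientation: a `+` breakend consumes the
#' right (3') end of the segment ending at that coordinate, a `-` breakend
#' the left (5') end of the segment starting there. Chains are walked from
#' free (telomeric) segment ends; segments attached to no junction —
#' deletion-bounded pieces — appear in no chain. With centromere
#' annotations, each chain is checked to contain exactly one centromere.
#'
#' @param junctions Canonicalized junction set: `data.frame` with `chrom1`,
#'   `pos1`, `ori1`, `chrom2`, `pos2`, `ori2` (e.g. calls or truth
#'   junctions).
#' @param chrom_lengths Named integer vector of chromosome (or region)
#'   lengths.
#' @param centromeres Optional `data.frame` (`chrom`, `start`, `end`) of
#'   centromere intervals (0-based half-open).
#' @param tol Breakpoints closer than `tol` bp are treated as the same
#'   boundary (default 10).
#' @return List of class `"derivative_set"`: `chains` (list of
#'   `data.frame`s: `chrom`, `start`, `end`, `orientation` in derivative
#'   order), `conflicts` (junction indices whose segment end was already
#'   consumed), and `centromere_counts` (or `NULL`).
#' @export
chain_derivatives <- function(junctions, chrom_lengths, centromeres = NULL,
                              tol = 10) {
  j <- junctions
  stopifnot(!is.null(names(chrom_lengths)))
  ## boundary positions per chromosome: a '+' breakend at pos cuts after pos
  ## (boundary pos + 1), a '-' breakend cuts at pos
  bp <- data.frame(
    chrom = c(j$chrom1, j$chrom2),
    cut = c(ifelse(j$ori1 == "+", j$pos1 + 1L, j$pos1),
            ifelse(j$ori2 == "+", j$pos2 + 1L, j$pos2)))
  seg_list <- list()
  for (ch in unique(bp$chrom)) {
    if (!(ch %in% names(chrom_lengths)))
      stop("no length given for chromosome ", ch)
    cuts <- sort(unique(bp$cut[bp$chrom == ch]))
    ## merge boundaries closer than tol
    if (length(cuts) > 1) {
      keep <- c(TRUE, diff(cuts) > tol)
      cuts <- cuts[keep]
    }
    cuts <- cuts[cuts > 0 & cuts < chrom_lengths[ch]]
    bounds <- c(0L, cuts, chrom_lengths[[ch]])
    seg_list[[ch]] <- data.frame(
      chrom = ch, start = bounds[-length(bounds)], end = bounds[-1])
  }
  segs <- do.call(rbind, seg_list)
  rownames(segs) <- NULL
  ns <- nrow(segs)
  ## ports: (segment, side) with side 1 = left/5', 2 = right/3'
  port_junction <- matrix(NA_integer_, nrow = ns, ncol = 2)
  port_partner <- matrix(NA_integer_, nrow = ns, ncol = 2)
  conflicts <- integer(0)
  find_port <- function(chrom, pos, ori) {
    if (ori == "+") {
      k <- which(segs$chrom == chrom & abs(segs$end - (pos + 1L)) <= tol)
      side <- 2L
    } else {
      k <- which(segs$chrom == chrom & abs(segs$start - pos) <= tol)
      side <- 1L
    }
    if (length(k) == 0) return(NULL)
    c(k[1], side)
  }
  for (i in seq_len(nrow(j))) {
    pa <- find_port(j$chrom1[i], j$pos1[i], j$ori1[i])
    pb <- find_port(j$chrom2[i], j$pos2[i], j$ori2[i])
    if (is.null(pa) || is.null(pb)) { conflicts <- c(conflicts, i); next }
    if (!is.na(port_junction[pa[1], pa[2]]) ||
        !is.na(port_junction[pb[1], pb[2]])) {
      conflicts <- c(conflicts, i)
      next
    }
    port_junction[pa[1], pa[2]] <- i
    port_junction[pb[1], pb[2]] <- i
    port_partner[pa[1], pa[2]] <- pb[1] * 2L + pb[2] - 2L ## encode (seg,side)
    port_partner[pb[1], pb[2]] <- pa[1] * 2L + pa[2] - 2L
  }
  ## encoding: code = seg * 2 + side - 2 (side 1 -> odd, side 2 -> even)
  decode <- function(code) c((code + 1L) %/% 2L, 2L - code %% 2L)
  attached <- !is.na(port_junction[, 1]) | !is.na(port_junction[, 2])
  visited <- rep(FALSE, ns)
  chains <- list()
  ## walk from segments with exactly one attached port (telomeric ends)
  starts <- which(attached & (is.na(port_junction[, 1]) |
                                is.na(port_junction[, 2])))
  walk <- function(seg0, enter_side) {
    chain <- data.frame(chrom = character(), start = integer(),
                        end = integer(), orientation = character(),
                        stringsAsFactors = FALSE)
    seg <- seg0; side_in <- enter_side
    repeat {
      visited[seg] <<- TRUE
      orientation <- if (side_in == 1L) "+" else "-"
      chain <- rbind(chain, data.frame(
        chrom = segs$chrom[seg], start = segs$start[seg],
        end = segs$end[seg], orientation = orientation,
        stringsAsFactors = FALSE))
      side_out <- 3L - side_in
      code <- port_partner[seg, side_out]
      if (is.na(code)) break
      nxt <- decode(code)
      if (visited[nxt[1]]) break  ## circular layout; stop
      seg <- nxt[1]; side_in <- nxt[2]
    }
    chain
  }
  for (s in starts) {
    if (visited[s]) next
    enter <- if (is.na(port_junction[s, 1])) 1L else 2L
    chains[[length(chains) + 1]] <- walk(s, enter)
  }
  ## any remaining attached-but-unvisited segments form circular chains
  for (s in which(attached & !visited)) {
    if (visited[s]) next
    chains[[length(chains) + 1]] <- walk(s, 1L)
  }
  cent <- NULL
  if (!is.null(centromeres)) {
    cent <- vapply(chains, function(ch) {
      sum(vapply(seq_len(nrow(ch)), function(r)
        any(centromeres$chrom == ch$chrom[r] &
              centromeres$start < ch$end[r] &
              centromeres$end > ch$start[r]), TRUE))
    }, 0)
  }
  if (length(conflicts) > 0)
    warning("inconsistent junction set: ", length(conflicts),
            " junction(s) re-use a consumed segment end; partial chains",
            " emitted")
  structure(list(chains = chains, conflicts = conflicts,
                 centromere_counts = cent),
            class = "derivative_set")
}
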