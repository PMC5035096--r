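#' @useDynLib neuroscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx lm nls coef predict rnorm runif setNames uniroot optimize
#' @importFrom utils write.table read.table head tail
NULL

# ---------------------------------------------------------------------------
# Morphology container: a branched tree of sections.
#
# A section is an unbranched stretch of neurite described by a 3D polyline
# with per-point diameters.  Exactly one root section (the soma) has no
# parent; every other section attaches to a parent section at an arc
# fraction in [0, 1].  Sections carry a region label (soma/dendrite/axon)
# and a tree label (e.g. "1", "2", "axon") naming the subtree they belong to.
# ---------------------------------------------------------------------------

new_section <- function(id, region, label, points, parent = NULL) {
  stopifnot(is.matrix(points), ncol(points) == 4, nrow(points) >= 2)
  colnames(points) <- c("x", "y", "z", "diam")
  if (any(!is.finite(points))) stop("section ", id, ": non-finite coordinates")
  if (any(points[, "diam"] <= 0)) stop("section ", id, ": diameter must be > 0")
  list(id = as.integer(id), region = region, label = label,
       points = points, parent = parent)
}

new_morphology <- function(sections, name = "morphology") {
  m <- structure(list(name = name, sections = sections), class = "ns_morphology")
  validate_morphology(m)
  m
}

validate_morphology <- function(m) {
  ids <- vapply(m$sections, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) stop("duplicate section ids")
  roots <- which(vapply(m$sections, function(s) is.null(s$parent), logical(1)))
  if (length(roots) != 1L) stop("morphology must have exactly one root section")
  if (m$sections[[roots]]$region != "soma") stop("root section must be the soma")
  for (s in m$sections) {
    if (!s$region %in% c("soma", "dendrite", "axon"))
      stop("unknown region label: ", s$region)
    if (!is.null(s$parent)) {
      if (!s$parent$id %in% ids) stop("section ", s$id, ": unknown parent id")
      if (s$parent$frac < 0 || s$parent$frac > 1)
        stop("section ", s$id, ": attachment fraction outside [0,1]")
    }
  }
  # acyclicity / connectivity: every section must reach the root
  par <- setNames(
    vapply(m$sections, function(s) if (is.null(s$parent)) NA_integer_ else s$parent$id,
           integer(1)), as.character(ids))
  for (id in ids) {
    seen <- integer(0); cur <- id
    while (!is.na(par[[as.character(cur)]])) {
      if (cur %in% seen) stop("cycle in section parent graph at section ", cur)
      seen <- c(seen, cur)
      cur <- par[[as.character(cur)]]
    }
  }
  invisible(m)
}

#' @export
print.ns_morphology <- function(x, ...) {
  regions <- vapply(x$sections, `[[`, character(1), "region")
  cat("Morphology '", x$name, "': ", length(x$sections), " sections (",
      sum(regions == "dendrite"), " dendrite, ", sum(regions == "axon"),
      " axon), total length ", round(total_length(x), 1), " um\n", sep = "")
  invisible(x)
}

get_section <- function(morph, id) {
  for (s in morph$sections) if (s$id == id) return(s)
  stop("no section with id ", id)
}

section_ids <- function(morph) vapply(morph$sections, `[[`, integer(1), "id")

# cumulative 3D arc length at each polyline point (um)
section_cumlen <- function(points) {
  d <- sqrt(rowSums(diff(points[, 1:3, drop = FALSE])^2))
  c(0, cumsum(d))
}

section_length <- function(section) {
  cl <- section_cumlen(section$points)
  cl[length(cl)]
}

total_length <- function(morph) {
  sum(vapply(morph$sections, section_length, numeric(1)))
}

# interpolate position and diameter at arc fraction
section_at <- function(section, frac) {
  cl <- section_cumlen(section$points)
  L <- cl[length(cl)]
  s <- frac * L
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- max(1L, min(i, nrow(section$points) - 1L))
  w <- if (cl[i + 1] > cl[i]) (s - cl[i]) / (cl[i + 1] - cl[i]) else 0
  p0 <- section$points[i, ]; p1 <- section$points[i + 1, ]
  (1 - w) * p0 + w * p1
}

# children of each section: list of (id, frac)
section_children <- function(morph) {
  kids <- setNames(vector("list", length(morph$sections)),
                   as.character(section_ids(morph)))
  for (s in morph$sections) {
    if (!is.null(s$parent)) {
      k <- as.character(s$parent$id)
      kids[[k]] <- rbind(kids[[k]], c(s$id, s$parent$frac))
    }
  }
  kids
}

# ---------------------------------------------------------------------------
# SWC input / output
# ---------------------------------------------------------------------------

#' Read a neuronal morphology from an SWC file
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent id; type 1 = soma, 2 = axon, 3+ = dendrite) into a morphology made
#' of unbranched sections.  The soma samples (1-3 supported) become the root
#' section, treated as a cylinder sequence; radii are converted to diameters.
#' Dendritic and axonal trees attached to the soma are labelled "1", "2", ...
#' in order of appearance (axonal trees are labelled "axon").
#'
#' @param path path to an SWC file ('#' comments allowed).
#' @return an object of class \code{ns_morphology}.
#' @export
read_swc <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (length(lines) == 0) stop("empty SWC file: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC line ", lineno[bad[1]], ": expected 7 fields")
  tab <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 7, byrow = TRUE)
  nn <- which(apply(tab, 1, function(r) any(is.na(r))))
  if (length(nn))
    stop("malformed SWC line ", lineno[nn[1]], ": non-numeric field")
  colnames(tab) <- c("id", "type", "x", "y", "z", "r", "parent")
  ids <- tab[, "id"]
  if (anyDuplicated(ids)) stop("duplicate node id in SWC file")
  par <- tab[, "parent"]
  orphan <- which(par != -1 & !(par %in% ids))
  if (length(orphan))
    stop("structural error at SWC line ", lineno[orphan[1]],
         ": parent id ", par[orphan[1]], " not declared")
  roots <- which(par == -1)
  if (length(roots) != 1L) stop("SWC file must have exactly one root node")
  if (tab[roots, "type"] != 1) stop("SWC root node must be a soma sample (type 1)")

  idx <- setNames(seq_len(nrow(tab)), as.character(ids))
  children <- split(seq_len(nrow(tab))[par != -1],
                    factor(as.character(par[par != -1]),
                           levels = as.character(ids)))
  nchild <- lengths(children)

  soma_rows <- which(tab[, "type"] == 1)
  # soma must be a chain beginning at the root
  soma_pts <- tab[soma_rows, c("x", "y", "z", "r"), drop = FALSE]
  soma_pts[, 4] <- 2 * soma_pts[, 4]
  colnames(soma_pts) <- c("x", "y", "z", "diam")
  if (nrow(soma_pts) == 1) {
    # single-sample soma: cylinder of length = diameter along x
    d <- soma_pts[1, "diam"]
    soma_pts <- rbind(soma_pts, soma_pts)
    soma_pts[1, "x"] <- soma_pts[1, "x"] - d / 2
    soma_pts[2, "x"] <- soma_pts[2, "x"] + d / 2
  }
  sections <- list(new_section(1L, "soma", "soma", soma_pts, NULL))
  # arc fraction of each soma sample along the soma section
  soma_cl <- section_cumlen(soma_pts)
  soma_frac_of <- function(row) {
    k <- match(row, soma_rows)
    if (nrow(soma_pts) > length(soma_rows)) return(0.5)  # single-sample soma
    soma_cl[k] / soma_cl[length(soma_cl)]
  }

  # run starts: non-soma nodes whose parent is soma, is a branch point,
  # or has a different type
  is_soma <- tab[, "type"] == 1
  starts <- which(vapply(seq_len(nrow(tab)), function(i) {
    if (is_soma[i] || par[i] == -1) return(FALSE)
    p <- idx[[as.character(par[i])]]
    is_soma[p] || nchild[[as.character(tab[p, "id"])]] >= 2 ||
      tab[p, "type"] != tab[i, "type"]
  }, logical(1)))

  next_id <- 2L
  sec_of_node <- integer(nrow(tab))   # section whose distal end is this node
  node_sec_frac <- numeric(nrow(tab))
  queue <- starts[order(ids[starts])]
  # map: run start -> built section; build in an order where parents exist
  built <- rep(FALSE, length(queue))
  tree_counter <- 0L
  labels_by_stem <- character(0)
  while (any(!built)) {
    progressed <- FALSE
    for (qi in seq_along(queue)) {
      if (built[qi]) next
      st <- queue[qi]
      p <- idx[[as.character(par[st])]]
      parent_ready <- is_soma[p] || sec_of_node[p] > 0L
      if (!parent_ready) next
      # walk the run
      run <- st
      cur <- st
      repeat {
        ch <- children[[as.character(tab[cur, "id"])]]
        if (length(ch) != 1L) break
        if (tab[ch, "type"] != tab[cur, "type"]) break
        run <- c(run, ch); cur <- ch
      }
      pts <- tab[run, c("x", "y", "z", "r"), drop = FALSE]
      pts[, 4] <- 2 * pts[, 4]
      # prepend the attachment point unless the run already starts there;
      # soma-attached runs keep their own starting diameter (no cone from
      # the soma), deeper runs continue the parent's end diameter
      if (sum((tab[p, c("x", "y", "z")] - pts[1, 1:3])^2) > 1e-12) {
        att_d <- if (is_soma[p]) pts[1, 4] else 2 * tab[p, "r"]
        att <- c(tab[p, c("x", "y", "z")], att_d)
        pts <- rbind(att, pts)
      }
      colnames(pts) <- c("x", "y", "z", "diam")
      region <- if (tab[st, "type"] == 2) "axon" else "dendrite"
      if (is_soma[p]) {
        parent <- list(id = 1L, frac = soma_frac_of(p))
        if (region == "axon") label <- "axon"
        else {
          tree_counter <- tree_counter + 1L
          label <- as.character(tree_counter)
        }
      } else {
        parent <- list(id = sections[[sec_of_node[p]]]$id,
                       frac = node_sec_frac[p])
        label <- sections[[sec_of_node[p]]]$label
      }
      sec <- new_section(next_id, region, label, pts, parent)
      sections[[length(sections) + 1L]] <- sec
      cl <- section_cumlen(pts)
      off <- nrow(pts) - length(run)
      for (k in seq_along(run)) {
        sec_of_node[run[k]] <- length(sections)
        node_sec_frac[run[k]] <- cl[k + off] / cl[length(cl)]
      }
      next_id <- next_id + 1L
      built[qi] <- TRUE
      progressed <- TRUE
    }
    if (!progressed) stop("structural error: disconnected SWC nodes")
  }
  new_morphology(sections, name = sub("\\.swc$", "", basename(path)))
}

#' Write a morphology to an SWC file
#'
#' Inverse of \code{\link{read_swc}}: soma polyline points become type-1
#' samples; each section's points (minus the duplicated attachment point)
#' become a run of type 2 (axon) or 3 (dendrite) samples.
#'
#' @param morph an \code{ns_morphology}.
#' @param path output file path.
#' @export
write_swc <- function(morph, path) {
  rows <- list()
  nid <- 0L
  last_node_of <- list()  # per section: node id of each polyline point
  soma <- get_section(morph, 1L)
  soma_nodes <- integer(nrow(soma$points))
  for (i in seq_len(nrow(soma$points))) {
    nid <- nid + 1L
    soma_nodes[i] <- nid
    rows[[nid]] <- c(nid, 1, soma$points[i, 1:3],
                     soma$points[i, 4] / 2, if (i == 1) -1 else nid - 1L)
  }
  last_node_of[["1"]] <- soma_nodes
  # order sections so parents are written first
  remaining <- Filter(function(s) s$id != 1L, morph$sections)
  while (length(remaining)) {
    progressed <- FALSE
    keep <- logical(length(remaining))
    for (i in seq_along(remaining)) {
      s <- remaining[[i]]
      pkey <- as.character(s$parent$id)
      if (is.null(last_node_of[[pkey]])) { keep[i] <- TRUE; next }
      pnodes <- last_node_of[[pkey]]
      psec <- get_section(morph, s$parent$id)
      cl <- section_cumlen(psec$points)
      arc <- s$parent$frac * cl[length(cl)]
      pk <- which.min(abs(cl - arc))
      parent_node <- pnodes[pk]
      type <- if (s$region == "axon") 2 else 3
      nodes <- integer(nrow(s$points))
      # re-emit the attachment point only when it adds information
      # (a diameter different from the parent node's)
      same <- isTRUE(all.equal(unname(s$points[1, 4] / 2),
                               unname(rows[[parent_node]][6]),
                               tolerance = 1e-9)) &&
        isTRUE(all.equal(unname(s$points[1, 1:3]),
                         unname(rows[[parent_node]][3:5]),
                         tolerance = 1e-9))
      if (same) {
        nodes[1] <- parent_node
      } else {
        nid <- nid + 1L
        nodes[1] <- nid
        rows[[nid]] <- c(nid, type, s$points[1, 1:3],
                         s$points[1, 4] / 2, parent_node)
      }
      for (k in 2:nrow(s$points)) {
        nid <- nid + 1L
        nodes[k] <- nid
        rows[[nid]] <- c(nid, type, s$points[k, 1:3],
                         s$points[k, 4] / 2, nodes[k - 1])
      }
      last_node_of[[as.character(s$id)]] <- nodes
      progressed <- TRUE
    }
    remaining <- remaining[keep]
    if (length(remaining) && !progressed) stop("cannot order sections for SWC output")
  }
  m <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by neuroscreen", con)
  write.table(format(m, trim = TRUE, scientific = FALSE, digits = 10),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Axon trimming
# ---------------------------------------------------------------------------

#' Trim the axonal arborization to a stub
#'
#' Removes all axonal cable beyond \code{keep_length} um of axonal path
#' distance (measured from the axon's attachment to the soma).  Dendrites and
#' soma are untouched.  \code{keep_length <= 0} removes the axon entirely
#' (with a warning).
#'
#' @param morph an \code{ns_morphology}.
#' @param keep_length axonal path length to keep, um.
#' @return the trimmed \code{ns_morphology}.
#' @export
trim_axon <- function(morph, keep_length) {
  regions <- vapply(morph$sections, `[[`, character(1), "region")
  if (!any(regions == "axon")) return(morph)
  if (keep_length <= 0) {
    warning("keep_length <= 0: removing all axon sections")
    keep <- morph$sections[regions != "axon"]
    return(new_morphology(keep, morph$name))
  }
  # axonal start distance for each axon section (distance from soma attachment
  # walking only axonal cable)
  lens <- setNames(vapply(morph$sections, section_length, numeric(1)),
                   as.character(section_ids(morph)))
  start_dist <- function(s) {
    d <- 0
    while (!is.null(s$parent)) {
      p <- get_section(morph, s$parent$id)
      if (p$region != "axon") break
      d <- d + s$parent$frac * lens[[as.character(p$id)]]
      s <- p
    }
    d
  }
  out <- list()
  for (s in morph$sections) {
    if (s$region != "axon") { out[[length(out) + 1L]] <- s; next }
    d0 <- start_dist(s)
    L <- lens[[as.character(s$id)]]
    if (d0 >= keep_length) next                       # fully beyond the stub
    if (d0 + L <= keep_length) { out[[length(out) + 1L]] <- s; next }
    # truncate at arc where axonal distance reaches keep_length
    cut_frac <- (keep_length - d0) / L
    cl <- section_cumlen(s$points)
    arc <- cut_frac * cl[length(cl)]
    i <- findInterval(arc, cl, rightmost.closed = TRUE)
    newp <- s$points[seq_len(i), , drop = FALSE]
    endp <- section_at(s, cut_frac)
    if (arc > cl[i] + 1e-9) newp <- rbind(newp, endp)
    if (nrow(newp) < 2) newp <- rbind(s$points[1, ], endp)
    s$points <- newp
    out[[length(out) + 1L]] <- s
  }
  kept_ids <- vapply(out, `[[`, integer(1), "id")
  out <- lapply(out, function(s) {
    if (!is.null(s$parent) && !(s$parent$id %in% kept_ids))
      stop("internal error: kept section with removed parent")
    s
  })
  new_morphology(out, morph$name)
}

# ---------------------------------------------------------------------------
# Path distance
# ---------------------------------------------------------------------------

#' Path distance from the soma center
#'
#' Arc length along the unique path from the soma section midpoint to a
#' location \code{(section id, fraction)}.  The soma half-length is included,
#' so distances to dendritic locations start at half the soma length.
#'
#' @param morph an \code{ns_morphology}.
#' @param location numeric vector \code{c(section_id, fraction)}.
#' @return distance in um.
#' @export
path_distance <- function(morph, location) {
  sec_id <- as.integer(location[1]); frac <- location[2]
  if (frac < 0 || frac > 1) stop("fraction outside [0,1]")
  s <- get_section(morph, sec_id)
  if (s$region == "soma") {
    L <- section_length(s)
    return(abs(frac - 0.5) * L)
  }
  d <- frac * section_length(s)
  while (!is.null(s$parent)) {
    p <- get_section(morph, s$parent$id)
    if (p$region == "soma") {
      L <- section_length(p)
      d <- d + abs(s$parent$frac - 0.5) * L
      return(d)
    }
    d <- d + s$parent$frac * section_length(p)
    s <- p
  }
  d
}

# ---------------------------------------------------------------------------
# Tree morphometrics
# ---------------------------------------------------------------------------

# trapezoidal lateral surface area of a polyline frustum sequence (um^2)
polyline_area <- function(points) {
  if (nrow(points) < 2) return(0)
  seglen <- sqrt(rowSums(diff(points[, 1:3, drop = FALSE])^2))
  dmean <- (points[-nrow(points), "diam"] + points[-1, "diam"]) / 2
  sum(pi * dmean * seglen)
}

section_area <- function(section) polyline_area(section$points)

#' Total membrane surface area of a morphology
#' @param morph an \code{ns_morphology}.
#' @return area in um^2 (trapezoidal integration over all sections).
#' @export
surface_area <- function(morph) {
  sum(vapply(morph$sections, section_area, numeric(1)))
}

#' Per-tree morphometrics
#'
#' For every tree (subtree attached to the soma, identified by its tree
#' label) reports the number of branch points (nodes with >= 2 child
#' sections; the soma is excluded), the trapezoidal surface area, the most
#' distal path length (from the tree's attachment point), and the summed
#' length of all branches.
#'
#' @param morph an \code{ns_morphology}.
#' @return a data.frame with columns \code{tree_label, n_branch_points,
#'   surface_area_um2, max_distal_length_um, summed_length_um}.
#' @export
tree_stats <- function(morph) {
  labs <- unique(vapply(morph$sections, `[[`, character(1), "label"))
  labs <- setdiff(labs, "soma")
  kids <- section_children(morph)
  lens <- setNames(vapply(morph$sections, section_length, numeric(1)),
                   as.character(section_ids(morph)))
  # distance of a section's distal end from the tree attachment point
  end_dist <- function(s) {
    d <- lens[[as.character(s$id)]]
    while (!is.null(s$parent)) {
      p <- get_section(morph, s$parent$id)
      if (p$region == "soma") break
      d <- d + s$parent$frac * lens[[as.character(p$id)]]
      s <- p
    }
    d
  }
  out <- lapply(labs, function(lab) {
    secs <- Filter(function(s) s$label == lab, morph$sections)
    nbp <- 0L
    for (s in secs) {
      ch <- kids[[as.character(s$id)]]
      if (!is.null(ch)) {
        grp <- table(round(ch[, 2], 9))
        nbp <- nbp + sum(grp >= 2)
      }
    }
    data.frame(tree_label = lab,
               n_branch_points = nbp,
               surface_area_um2 = sum(vapply(secs, section_area, numeric(1))),
               max_distal_length_um = max(vapply(secs, end_dist, numeric(1))),
               summed_length_um = sum(vapply(secs, section_length, numeric(1))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a tree-stats table as delimited text
#' @param stats data.frame from \code{\link{tree_stats}}.
#' @param path output path (tab-separated, with header).
#' @export
write_tree_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
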