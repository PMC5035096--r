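# ---------------------------------------------------------------------------
# Discretization of a morphology into isopotential compartments.
#
# Each section is split into an odd number of equal-arc compartments.  Under
# the default "lambda" policy the compartment length is at most a fraction
# (default 0.1) of the AC length constant at 100 Hz computed from the
# section's mean diameter and the regional passive parameters (the classical
# d-lambda rule).  A "fixed" policy with a maximum compartment length is
# available for tests and quick passive work.
# ---------------------------------------------------------------------------

# split a section polyline at the given arc fractions; returns one point
# matrix per interval
split_polyline <- function(points, fracs) {
  cl <- section_cumlen(points)
  L <- cl[length(cl)]
  out <- vector("list", length(fracs) - 1L)
  for (k in seq_len(length(fracs) - 1L)) {
    s0 <- fracs[k] * L; s1 <- fracs[k + 1] * L
    inner <- which(cl > s0 + 1e-9 & cl < s1 - 1e-9)
    interp <- function(s) {
      i <- findInterval(s, cl, rightmost.closed = TRUE)
      i <- max(1L, min(i, nrow(points) - 1L))
      w <- if (cl[i + 1] > cl[i]) (s - cl[i]) / (cl[i + 1] - cl[i]) else 0
      (1 - w) * points[i, ] + w * points[i + 1, ]
    }
    m <- rbind(interp(s0), points[inner, , drop = FALSE], interp(s1))
    colnames(m) <- colnames(points)
    out[[k]] <- m
  }
  out
}

# axial resistance (MOhm) of a polyline piece, frustum formula per segment
polyline_axial_R <- function(points, ra_ohm_cm) {
  if (nrow(points) < 2) return(0)
  seglen <- sqrt(rowSums(diff(points[, 1:3, drop = FALSE])^2))
  d0 <- points[-nrow(points), "diam"]
  d1 <- points[-1, "diam"]
  sum(0.01 * 4 * ra_ohm_cm * seglen / (pi * d0 * d1))
}

# AC length constant (um) at frequency f (Hz) for diameter d (um)
lambda_ac <- function(d_um, freq, ra_ohm_cm, cm_uF_cm2) {
  0.5e5 * sqrt(d_um / (pi * freq * ra_ohm_cm * cm_uF_cm2))
}

#' Discretize a morphology into isopotential compartments
#'
#' @param morph an \code{ns_morphology}.
#' @param policy \code{"lambda"} (default: compartment length at most
#'   \code{frac} of the AC length constant at \code{freq} Hz) or
#'   \code{"fixed"} (at most \code{max_len} um).
#' @param frac fraction of the length constant per compartment (default 0.1).
#' @param freq frequency for the AC length constant, Hz (default 100).
#' @param max_len maximum compartment length for the fixed policy, um.
#' @param passive a region passive map (see \code{\link{default_passive}});
#'   supplies Ra and Cm for the lambda rule and is stored with the model.
#' @return an object of class \code{ns_cmodel}: the morphology plus a
#'   compartment table (arc interval, length, trapezoidal surface area, path
#'   distance of the midpoint, half-axial resistances, and the axial coupling
#'   conductance toward the parent compartment).
#' @export
compartmentalize <- function(morph, policy = c("lambda", "fixed"),
                             frac = 0.1, freq = 100, max_len = NULL,
                             passive = default_passive()) {
  policy <- match.arg(policy)
  if (policy == "fixed" && is.null(max_len))
    stop("fixed policy requires max_len")
  kids <- section_children(morph)
  ids <- section_ids(morph)
  root <- ids[vapply(morph$sections, function(s) is.null(s$parent), logical(1))]
  # breadth-first section order (parents before children)
  order_ids <- root
  qi <- 1L
  while (qi <= length(order_ids)) {
    ch <- kids[[as.character(order_ids[qi])]]
    if (!is.null(ch)) order_ids <- c(order_ids, as.integer(ch[, 1]))
    qi <- qi + 1L
  }

  rows <- list()
  r_a <- numeric(0); r_b <- numeric(0)
  comp_range <- list()  # per section id: first/last comp index + boundaries
  for (sid in order_ids) {
    s <- get_section(morph, sid)
    if (any(s$points[, "diam"] <= 0)) stop("zero-diameter point in section ", sid)
    L <- section_length(s)
    pp <- passive[[s$region]]
    n <- if (policy == "fixed") {
      max(1L, as.integer(ceiling(L / max_len)))
    } else {
      d_mean <- section_area(s) / (pi * L)
      lam <- lambda_ac(d_mean, freq, pp$ra, pp$cm)
      max(1L, as.integer(ceiling(L / (frac * lam))))
    }
    if (n %% 2L == 0L) n <- n + 1L
    bounds <- seq(0, 1, length.out = n + 1L)
    pieces <- split_polyline(s$points, bounds)
    first_idx <- length(rows) + 1L
    for (k in seq_len(n)) {
      mid <- (bounds[k] + bounds[k + 1]) / 2
      halves <- split_polyline(s$points, c(bounds[k], mid, bounds[k + 1]))
      idx <- length(rows) + 1L
      rows[[idx]] <- data.frame(
        comp = idx, sec_id = sid, label = s$label, region = s$region,
        a = bounds[k], b = bounds[k + 1],
        length_um = L / n,
        area_um2 = polyline_area(pieces[[k]]),
        path_dist_um = path_distance(morph, c(sid, mid)),
        parent = NA_integer_, g_ax = NA_real_,
        stringsAsFactors = FALSE)
      r_a[idx] <- polyline_axial_R(halves[[1]], pp$ra)
      r_b[idx] <- polyline_axial_R(halves[[2]], pp$ra)
      if (k > 1L) {
        rows[[idx]]$parent <- idx - 1L
        rr <- r_b[idx - 1L] + r_a[idx]
        rows[[idx]]$g_ax <- 1 / rr
      }
    }
    comp_range[[as.character(sid)]] <- list(first = first_idx,
                                            last = length(rows),
                                            bounds = bounds)
    if (!is.null(s$parent)) {
      # couple the section's first compartment into the parent section
      pinfo <- comp_range[[as.character(s$parent$id)]]
      pb <- pinfo$bounds
      host_k <- max(1L, min(findInterval(s$parent$frac, pb,
                                         rightmost.closed = TRUE),
                            length(pb) - 1L))
      host <- pinfo$first + host_k - 1L
      psec <- get_section(morph, s$parent$id)
      pmid <- (pb[host_k] + pb[host_k + 1]) / 2
      f0 <- min(pmid, s$parent$frac); f1 <- max(pmid, s$parent$frac)
      extra <- if (f1 > f0) {
        piece <- split_polyline(psec$points, c(f0, f1))[[1]]
        polyline_axial_R(piece, passive[[psec$region]]$ra)
      } else 0
      rows[[first_idx]]$parent <- host
      rows[[first_idx]]$g_ax <- 1 / (r_a[first_idx] + extra)
    } else {
      rows[[first_idx]]$parent <- 0L
      rows[[first_idx]]$g_ax <- 0
    }
  }
  comps <- do.call(rbind, rows)
  comps$r_half_a <- r_a
  comps$r_half_b <- r_b
  structure(list(morph = morph, passive = passive, comps = comps,
                 policy = policy, frac = frac, freq = freq,
                 max_len = max_len),
            class = "ns_cmodel")
}

#' @export
print.ns_cmodel <- function(x, ...) {
  cat("Compartmental model of '", x$morph$name, "': ", nrow(x$comps),
      " compartments, total area ", round(sum(x$comps$area_um2), 1),
      " um^2\n", sep = "")
  invisible(x)
}

# compartment index containing a (section, fraction) location
comp_at <- function(cmodel, sec_id, frac) {
  cc <- cmodel$comps
  i <- which(cc$sec_id == sec_id & cc$a - 1e-12 <= frac & frac <= cc$b + 1e-12)
  if (!length(i)) stop("no compartment at section ", sec_id, " fraction ", frac)
  i[1]
}

# compartment holding the soma center
soma_comp <- function(cmodel) {
  sid <- cmodel$comps$sec_id[cmodel$comps$region == "soma"][1]
  comp_at(cmodel, sid, 0.5)
}
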