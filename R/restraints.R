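# Restraint terms and the composite objective: crosslink distances with
# copy ambiguity, domain connectivity, excluded volume on the bead
# representation, and the linear combination with the EM fit term.

#' Ambiguity-resolved crosslink distances
#'
#' Computes per-link Calpha-Calpha distances on the current model
#' coordinates. For subunits present in two copies the reported distance
#' is the minimum over all copy-pair combinations consistent with the
#' link; dimeric links (same residue to itself) are forced to cross
#' copies. Links whose residues are absent from every copy are flagged
#' unmappable (and counted), never silently dropped.
#'
#' @param model an `atomic_model` with current coordinates.
#' @param crosslinks a `crosslink_table`.
#' @return data.frame: `link` (row index into `crosslinks`), `distance`
#'   (Angstrom, `NA` if unmappable), `chain1`, `chain2`, `mappable`.
#' @export
crosslink_distances <- function(model, crosslinks) {
  ca <- calpha(model)
  sub <- model$subunit_of_chain
  cop <- model$copy_of_chain
  out <- data.frame(link = seq_len(nrow(crosslinks)),
                    distance = NA_real_,
                    chain1 = NA_character_, chain2 = NA_character_,
                    mappable = FALSE, stringsAsFactors = FALSE)
  find_cas <- function(protein, resno) {
    chains <- names(sub)[sub == protein]
    hit <- ca[ca$chain %in% chains & ca$resno == resno, , drop = FALSE]
    hit
  }
  for (i in seq_len(nrow(crosslinks))) {
    l <- crosslinks[i, ]
    a <- find_cas(l$protein1, l$residue1)
    b <- find_cas(l$protein2, l$residue2)
    if (nrow(a) == 0L || nrow(b) == 0L) next
    best <- Inf; bc1 <- NA_character_; bc2 <- NA_character_
    for (ia in seq_len(nrow(a))) for (ib in seq_len(nrow(b))) {
      if (l$is_dimeric && cop[[a$chain[ia]]] == cop[[b$chain[ib]]]) next
      if (a$chain[ia] == b$chain[ib] && a$resno[ia] == b$resno[ib]) next
      d <- sqrt((a$x[ia] - b$x[ib])^2 + (a$y[ia] - b$y[ib])^2 +
                  (a$z[ia] - b$z[ib])^2)
      if (d < best) { best <- d; bc1 <- a$chain[ia]; bc2 <- b$chain[ib] }
    }
    if (is.finite(best)) {
      out$distance[i] <- best
      out$chain1[i] <- bc1; out$chain2[i] <- bc2
      out$mappable[i] <- TRUE
    }
  }
  out
}

#' Crosslink restraint score
#'
#' Per-link penalty 0 for distances within the threshold, otherwise
#' `((d - threshold) / sigma)^2`, capped at `cap`; summed over mappable
#' links. The cap makes the restraint robust: identification tables
#' carry an expected false-positive fraction, and an unbounded
#' quadratic would let a single decoy link dominate the composite
#' objective and drag domains off their density.
#'
#' @param distances numeric vector of link distances (Angstrom); `NA`
#'   entries (unmappable) are ignored.
#' @param threshold Calpha-Calpha distance threshold, default 30.
#' @param sigma softness of the upper bound, default 3.
#' @param cap maximum per-link penalty, default 9 (flat beyond
#'   `threshold + 3 * sigma`).
#' @return Non-negative score.
#' @export
crosslink_restraint <- function(distances, threshold = 30, sigma = 3,
                                cap = 9) {
  if (threshold <= 0) stop("threshold must be > 0")
  d <- distances[is.finite(distances)]
  sum(pmin(pmax(0, (d - threshold) / sigma)^2, cap))
}

#' Domain connectivity restraint
#'
#' For each pair of linker-connected bodies of one chain, the gap between
#' the terminal Calpha atoms must not exceed the linker's maximum
#' extension (`n_linker x 3.8` Angstrom plus `slack`); quadratic penalty
#' beyond.
#'
#' @param model an `atomic_model` with current coordinates.
#' @param bodies list of `rigid_body` from [segment_rigid_bodies()].
#' @param slack extension slack in Angstrom, default 5.
#' @param sigma penalty softness, default 3.
#' @return Non-negative score.
#' @export
connectivity_restraint <- function(model, bodies, slack = 5, sigma = 3) {
  ca <- calpha(model)
  score <- 0
  seen <- character(0)
  for (b in bodies) {
    if (!nrow(b$linker_neighbors)) next
    for (i in seq_len(nrow(b$linker_neighbors))) {
      other <- b$linker_neighbors$other[i]
      key <- paste(sort(c(b$name, other)), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      n_link <- b$linker_neighbors$n_linker[i]
      ends <- linker_termini(ca, b, bodies[[other]])
      if (is.null(ends)) next
      d <- sqrt(sum((ends[1, ] - ends[2, ])^2))
      max_len <- n_link * 3.8 + slack
      if (d > max_len) score <- score + ((d - max_len) / sigma)^2
    }
  }
  score
}

# internal: terminal CA pair between two consecutive bodies of a chain
linker_termini <- function(ca, body_a, body_b) {
  for (ch in intersect(body_a$ranges$chain, body_b$ranges$chain)) {
    ra <- body_a$ranges[body_a$ranges$chain == ch, ]
    rb <- body_b$ranges[body_b$ranges$chain == ch, ]
    if (max(ra$end) < min(rb$start)) {
      e1 <- max(ra$end); s2 <- min(rb$start)
    } else if (max(rb$end) < min(ra$start)) {
      e1 <- max(rb$end); s2 <- min(ra$start)
    } else next
    a <- ca[ca$chain == ch & ca$resno <= e1, , drop = FALSE]
    b <- ca[ca$chain == ch & ca$resno >= s2, , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    a <- a[which.max(a$resno), ]
    b <- b[which.min(b$resno), ]
    return(rbind(ca_xyz(a), ca_xyz(b)))
  }
  NULL
}

#' Excluded-volume clash score on the bead representation
#'
#' Sum over inter-body bead pairs of `max(0, r_i + r_j - d_ij)^2`; zero
#' exactly when no beads of different bodies overlap.
#'
#' @param beads a `bead_model` with a `body` column.
#' @return Non-negative score.
#' @export
clash_score <- function(beads) {
  n <- nrow(beads)
  if (n < 2) return(0)
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  rr <- outer(beads$radius, beads$radius, "+")
  inter <- outer(beads$body, beads$body, "!=")
  ov <- pmax(0, rr - d) * inter
  sum(ov[upper.tri(ov)]^2)
}

#' Composite assembly score
#'
#' Linear combination of the (negated) EM cross-correlation scores of
#' the per-domain fits, the crosslink restraint, the domain connectivity
#' restraint, and the clash score; lower is better. The EM term uses
#' precomputed library scores when `em_ncc` is given, or recomputes the
#' correlation against `map` for each body otherwise (continuous mode).
#'
#' @param model an `atomic_model` carrying the configuration's current
#'   coordinates.
#' @param bodies list of `rigid_body`.
#' @param crosslinks a `crosslink_table` (may be `NULL`).
#' @param em_ncc named numeric vector of per-body NCC scores, or `NULL`
#'   to recompute from `map`.
#' @param map `density_map` for continuous-mode EM scoring.
#' @param weights numeric(4): `em`, `xl`, `conn`, `clash`; all >= 0.
#'   The default EM weight (60) is calibrated on the standard synthetic
#'   fixture so that the EM term's discrimination between alternative
#'   placements outweighs the capped penalty of a false-positive link.
#' @param xl_threshold,xl_sigma,xl_cap crosslink restraint parameters.
#' @param conn_slack,conn_sigma connectivity restraint parameters.
#' @param resolution simulation resolution for continuous-mode scoring.
#' @return list of class `score_breakdown`: `em`, `xl`, `conn`,
#'   `clash`, `weights`, `total` (the exact weighted sum).
#' @export
composite_score <- function(model, bodies, crosslinks = NULL,
                            em_ncc = NULL, map = NULL,
                            weights = c(em = 60, xl = 1, conn = 1,
                                        clash = 0.1),
                            xl_threshold = 30, xl_sigma = 3, xl_cap = 9,
                            conn_slack = 5, conn_sigma = 3,
                            resolution = NULL) {
  if (any(weights < 0)) stop("weights must be >= 0")
  weights <- unname(weights)
  em <- 0
  if (!is.null(em_ncc)) {
    em <- -sum(em_ncc)
  } else if (!is.null(map) && weights[1] > 0) {
    if (is.null(resolution)) resolution <- map$resolution
    sigma <- resolution_sigma(resolution)
    for (b in bodies) {
      fc <- fit_coords(body_model(model, b))
      v <- cpp_pose_ncc(as.numeric(map$values), dim(map$values),
                        map$origin, map$voxel, fc$coords, fc$weights,
                        colMeans(fc$coords), c(1, 0, 0, 0), c(0, 0, 0),
                        sigma, 0.3)
      em <- em - ifelse(is.na(v), -1, v)
    }
  }
  xl <- if (!is.null(crosslinks) && nrow(crosslinks)) {
    dists <- crosslink_distances(model, crosslinks)
    crosslink_restraint(dists$distance, xl_threshold, xl_sigma, xl_cap)
  } else 0
  conn <- connectivity_restraint(model, bodies, conn_slack, conn_sigma)
  beads <- coarse_grain(model, body_of = body_lookup(bodies))
  clash <- clash_score(beads)
  total <- weights[1] * em + weights[2] * xl + weights[3] * conn +
    weights[4] * clash
  structure(list(em = em, xl = xl, conn = conn, clash = clash,
                 weights = weights, total = total),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("score: total %.4f (em %.4f, xl %.4f, conn %.4f, clash %.4f)\n",
              x$total, x$em, x$xl, x$conn, x$clash))
  invisible(x)
}

# internal: function (chain, resno) -> body name (NA outside all bodies)
body_lookup <- function(bodies) {
  function(chain, resno) {
    for (b in bodies) {
      r <- b$ranges
      if (any(r$chain == chain & r$start <= resno & r$end >= resno))
        return(b$name)
    }
    NA_character_
  }
}

#' Crosslink satisfaction report
#'
#' Counts mapped links whose ambiguity-resolved distance is within the
#' threshold, formatted as the conventional "k out of n (p%)" with the
#' percentage rounded to an integer.
#'
#' @param model an `atomic_model` with configuration coordinates.
#' @param crosslinks a `crosslink_table`.
#' @param threshold distance threshold in Angstrom, default 30.
#' @return list: `n_satisfied`, `n_mapped`, `n_unmappable`, `fraction`,
#'   `text`, `empty` flag, and the `per_link` table.
#' @export
satisfaction_report <- function(model, crosslinks, threshold = 30) {
  dists <- crosslink_distances(model, crosslinks)
  mapped <- dists[dists$mappable, , drop = FALSE]
  n_map <- nrow(mapped)
  if (n_map == 0L) {
    return(list(n_satisfied = 0L, n_mapped = 0L,
                n_unmappable = sum(!dists$mappable),
                fraction = NA_real_, text = "no mappable crosslinks",
                empty = TRUE, per_link = dists))
  }
  sat <- sum(mapped$distance <= threshold)
  frac <- sat / n_map
  dists$satisfied <- dists$mappable & !is.na(dists$distance) &
    dists$distance <= threshold
  list(n_satisfied = sat, n_mapped = n_map,
       n_unmappable = sum(!dists$mappable), fraction = frac,
       text = sprintf("%d out of %d (%d%%)", sat, n_map,
                      round(100 * frac)),
       empty = FALSE, per_link = dists)
}
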