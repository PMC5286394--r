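# Ground-truth synthetic data: compact random domains assembled into
# (optionally C2-symmetric) complexes with known poses, simulated noisy
# maps, and crosslink tables carrying a controlled decoy fraction. Every
# generator is bit-reproducible given (parameters, seed).

# internal: compact self-avoiding random walk of n Calpha positions,
# 3.8 A steps, 3.5 A exclusion; steps that increase the radius of
# gyration are only accepted with probability 0.3 (compactness bias).
saw_chain <- function(n, step = 3.8, min_sep = 3.5, p_expand = 0.3,
                      max_restart = 100) {
  for (attempt in seq_len(max_restart)) {
    pos <- matrix(NA_real_, n, 3)
    pos[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in seq_len(n - 1) + 1) {
      placed <- FALSE
      ctr <- colMeans(pos[seq_len(i - 1), , drop = FALSE])
      r_prev <- sqrt(sum((pos[i - 1, ] - ctr)^2))
      for (try in 1:300) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- pos[i - 1, ] + step * u
        if (i > 2) {
          d2 <- rowSums(sweep(pos[seq_len(i - 2), , drop = FALSE], 2,
                              cand)^2)
          if (min(d2) < min_sep^2) next
        }
        expands <- sqrt(sum((cand - ctr)^2)) > r_prev
        if (expands && runif(1) > p_expand) next
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(sweep(pos, 2, colMeans(pos)))
  }
  stop("self-avoiding walk failed; try a smaller body")
}

# internal: bounding radius of a coordinate set about its centroid
bound_radius <- function(xyz) {
  ctr <- colMeans(xyz)
  sqrt(max(rowSums(sweep(xyz, 2, ctr)^2)))
}

# internal: do two Calpha sets clash at the bead level? tol = 1 means
# volume-equivalent beads may touch but not overlap.
beads_clash <- function(a, b, spacing = 10, tol = 1.0) {
  ba <- chain_beads(a); bb <- chain_beads(b)
  d <- sqrt(outer(rowSums(ba$xyz^2), rowSums(bb$xyz^2), "+") -
              2 * ba$xyz %*% t(bb$xyz))
  rr <- outer(ba$r, bb$r, "+")
  any(d < rr * tol)
}

# internal: quick beads for a bare coordinate matrix
chain_beads <- function(xyz, stretch = 10) {
  n <- nrow(xyz)
  starts <- seq(1, n, by = stretch)
  ctr <- t(vapply(starts, function(s) {
    e <- min(s + stretch - 1, n)
    colMeans(xyz[s:e, , drop = FALSE])
  }, numeric(3)))
  spans <- pmin(starts + stretch - 1, n) - starts + 1
  list(xyz = ctr, r = bead_radius(spans))
}

#' Generate a ground-truth synthetic assembly
#'
#' Builds `n_bodies` compact random domains (self-avoiding 3.8 A-step
#' Calpha walks with a compactness bias), packs them into a clash-free
#' lobe, optionally duplicates the lobe by a 180-degree rotation about
#' the z axis (C2), and optionally attaches a group of extra bodies
#' asymmetrically to the first lobe only. Every 8th residue is
#' link-eligible (standing in for lysines).
#'
#' @param n_bodies number of distinct scaffold bodies per lobe.
#' @param body_size residues per body (recycled to `n_bodies`).
#' @param symmetry `"none"` or `"C2"`.
#' @param extra_bodies number of extra asymmetric bodies (0 for none).
#' @param extra_size residues per extra body (recycled to
#'   `extra_bodies`).
#' @param seed RNG seed; identical seeds give identical assemblies.
#' @param lobe_offset distance of the lobe center from the symmetry
#'   axis, Angstrom.
#' @param gap extra separation pushed between packed bodies after the
#'   clash-free distance, Angstrom. Visible inter-domain separation is
#'   typical of negative-stain lobed complexes and keeps the individual
#'   domains resolvable at 25-60 Angstrom.
#' @return An object of class `synthetic_truth`: `model` (ground-truth
#'   `atomic_model`), `bodies` (one `rigid_body` per chain, named
#'   `<subunit>_<copy>`), `body_types`, `poses_true` (identity for copy
#'   1; the C2 operation for copy 2), `symmetry`, `seed`.
#' @export
generate_assembly <- function(n_bodies, body_size = 100,
                              symmetry = c("none", "C2"),
                              extra_bodies = 0, extra_size = 60,
                              seed = 1, lobe_offset = 55, gap = 8) {
  symmetry <- match.arg(symmetry)
  if (n_bodies < 1) stop("n_bodies must be >= 1")
  set.seed(seed)
  sizes <- rep_len(body_size, n_bodies)
  chains_xyz <- lapply(sizes, saw_chain)
  # pack the lobe: body 1 at the lobe center, others docked against a
  # random placed body, pushed outward until clash-free
  L1 <- c(lobe_offset, 0, 0)
  placed <- list(sweep(chains_xyz[[1]], 2, L1, "+"))
  for (i in seq_len(n_bodies)[-1]) {
    ri <- bound_radius(chains_xyz[[i]])
    done <- FALSE
    for (try in 1:200) {
      anchor <- placed[[sample.int(length(placed), 1)]]
      ra <- bound_radius(anchor)
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      d0 <- (ra + ri) * 0.75
      for (push in seq(0, 40, by = 2)) {
        ctr <- colMeans(anchor) + (d0 + push + gap) * u
        cand <- sweep(chains_xyz[[i]], 2, ctr, "+")
        if (!any(vapply(placed, beads_clash, TRUE, b = cand))) {
          placed[[length(placed) + 1]] <- cand
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    if (!done) stop("placement failed; use fewer or smaller bodies")
  }
  # optional extra (asymmetric) group docked onto the first lobe
  extras <- list()
  if (extra_bodies > 0) {
    extra_sizes <- rep_len(extra_size, extra_bodies)
    ring_dir <- c(0, 0, 1)
    ring_ctr <- colMeans(placed[[1]]) +
      (bound_radius(placed[[1]]) + bead_radius(max(extra_sizes)) + 14 +
         2 * gap) * ring_dir
    for (j in seq_len(extra_bodies)) {
      xyz <- saw_chain(extra_sizes[j])
      rj <- bound_radius(xyz)
      ang <- 2 * pi * (j - 1) / max(1, extra_bodies)
      done <- FALSE
      for (push in seq(0, 60, by = 2)) {
        ctr <- ring_ctr + (rj + 2 * gap + push) *
          c(cos(ang), sin(ang), 0) * (extra_bodies > 1) +
          c(0, 0, push) * (extra_bodies == 1)
        cand <- sweep(xyz, 2, ctr, "+")
        others <- c(placed, extras)
        if (!any(vapply(others, beads_clash, TRUE, b = cand))) {
          extras[[j]] <- cand
          done <- TRUE
          break
        }
      }
      if (!done) stop("placement failed for extra body ", j)
    }
  }
  # assemble chains: copy 1, then (C2) copy 2, then extras
  all_xyz <- placed
  subunits <- paste0("S", seq_len(n_bodies))
  copies <- rep(1L, n_bodies)
  if (symmetry == "C2") {
    flip <- function(xyz) cbind(-xyz[, 1], -xyz[, 2], xyz[, 3])
    all_xyz <- c(all_xyz, lapply(placed, flip))
    subunits <- c(subunits, paste0("S", seq_len(n_bodies)))
    copies <- c(copies, rep(2L, n_bodies))
  }
  if (extra_bodies > 0) {
    all_xyz <- c(all_xyz, extras)
    subunits <- c(subunits, paste0("R", seq_len(extra_bodies)))
    copies <- c(copies, rep(1L, extra_bodies))
  }
  chain_ids <- LETTERS[seq_along(all_xyz)]
  atoms <- do.call(rbind, lapply(seq_along(all_xyz), function(ci) {
    xyz <- all_xyz[[ci]]
    data.frame(chain = chain_ids[ci], resno = seq_len(nrow(xyz)),
               resname = "ALA", elety = "CA",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }))
  model <- atomic_model(atoms,
                        subunits = setNames(subunits, chain_ids),
                        copies = setNames(copies, chain_ids))
  body_names <- paste0(subunits, "_", copies)
  defs <- data.frame(body = body_names, chain = chain_ids,
                     start = 1L,
                     end = vapply(all_xyz, nrow, 0L))
  bodies <- segment_rigid_bodies(model, defs)
  # true poses relative to the copy-1 reference frames
  poses_true <- list()
  for (bi in seq_along(body_names)) {
    nm <- body_names[bi]
    if (copies[bi] == 1L) {
      poses_true[[nm]] <- list(q = c(1, 0, 0, 0), t = c(0, 0, 0))
    } else {
      c0 <- colMeans(all_xyz[[bi - n_bodies]])  # copy-1 centroid
      Rz <- axis_angle_matrix(c(0, 0, 1), pi)
      poses_true[[nm]] <- list(q = matrix_to_quat(Rz),
                               t = as.numeric(Rz %*% c0) - c0)
    }
  }
  structure(list(model = model, bodies = bodies,
                 body_types = setNames(subunits, body_names),
                 poses_true = poses_true, symmetry = symmetry,
                 n_bodies = n_bodies, extra_bodies = extra_bodies,
                 seed = seed),
            class = "synthetic_truth")
}

#' Reference model with copy-1 coordinates on every copy
#'
#' Returns the model in which each duplicated chain carries its
#' subunit's copy-1 coordinates, i.e. the "starting structures" frame in
#' which all shared fit libraries and poses are expressed.
#'
#' @param truth a `synthetic_truth`.
#' @return An `atomic_model`.
#' @export
reference_model <- function(truth) {
  model <- truth$model
  at <- model$atoms
  sub <- model$subunit_of_chain
  cop <- model$copy_of_chain
  for (ch in names(cop)) {
    if (cop[[ch]] == 1L) next
    src <- names(sub)[sub == sub[[ch]] & cop == 1L][1]
    a <- at[at$chain == src, c("resno", "x", "y", "z")]
    sel <- which(at$chain == ch)
    at[sel, c("x", "y", "z")] <-
      a[match(at$resno[sel], a$resno), c("x", "y", "z")]
  }
  model$atoms <- at
  model
}

#' Simulate a noisy density map of a synthetic assembly
#'
#' The clean map is [simulate_density()] of the ground truth; Gaussian
#' voxel noise with standard deviation `noise_sd` times the clean map's
#' value standard deviation is added on top. Different seeds change only
#' the noise, never the signal.
#'
#' @param truth a `synthetic_truth` (or an `atomic_model`).
#' @param resolution map resolution in Angstrom.
#' @param noise_sd noise level relative to the signal sd.
#' @param voxel voxel size in Angstrom.
#' @param seed noise seed.
#' @param padding passed to [simulate_density()].
#' @return A `density_map`.
#' @export
simulate_noisy_map <- function(truth, resolution = 28, noise_sd = 0.05,
                               voxel = 4, seed = 1, padding = resolution) {
  model <- if (inherits(truth, "synthetic_truth")) truth$model else truth
  clean <- simulate_density(model, resolution, voxel, padding)
  if (noise_sd > 0) {
    set.seed(seed)
    s <- sd(as.numeric(clean$values))
    clean$values <- clean$values +
      array(rnorm(length(clean$values), sd = noise_sd * s),
            dim(clean$values))
  }
  clean
}

#' Simulate a crosslink table from a ground-truth assembly
#'
#' True links are drawn uniformly from link-eligible residue pairs
#' (every 8th residue) whose ambiguity-resolved ground-truth
#' Calpha-Calpha distance is within `reach`; decoys are drawn uniformly
#' from *intra-body* pairs beyond `reach`, so they are violated by
#' construction and their violation is pose-independent (a rigid body
#' cannot shorten a distance internal to itself). Restricting decoys to
#' intra-body pairs is deliberate: an inter-body decoy in a small
#' assembly with duplicated subunits creates a score degeneracy -- a
#' spare subunit copy can relocate to satisfy the decoy while the
#' min-over-copies ambiguity rule keeps every true link satisfied --
#' that is an artifact of the reduced fixture rather than a property of
#' the method under test. ld scores are drawn above the confidence
#' cutoff for both classes (true links centered at 40, decoys at 33,
#' truncated at 30) so that decoys survive filtering and are exercised
#' downstream.
#'
#' @param truth a `synthetic_truth`.
#' @param n_links total links to emit.
#' @param decoy_fraction expected decoy fraction, default 0.05 (the
#'   XL-MS false-positive regime).
#' @param reach distance reach of the linker, Angstrom, default 30.
#' @param seed RNG seed.
#' @param linker linker chemistry label for the table.
#' @return A `crosslink_table` (also valid input for
#'   [write_crosslink_table()]); attribute `is_decoy` marks the decoys.
#' @export
simulate_crosslinks <- function(truth, n_links, decoy_fraction = 0.05,
                                reach = 30, seed = 1, linker = "DSS") {
  if (decoy_fraction < 0 || decoy_fraction > 1)
    stop("decoy_fraction must be in [0, 1]")
  set.seed(seed)
  model <- truth$model
  ca <- calpha(model)
  sub <- model$subunit_of_chain
  elig <- ca[ca$resno %% 8 == 1, , drop = FALSE]
  for (ch in unique(ca$chain))
    if (sum(elig$chain == ch) < 2)
      stop("not enough link-eligible residues in chain ", ch)
  # subunit-level site list and ambiguity-resolved pair distances
  elig$protein <- unname(sub[elig$chain])
  sites <- unique(elig[, c("protein", "resno")])
  key <- paste(elig$protein, elig$resno)
  xyz <- ca_xyz(elig)
  ns <- nrow(sites)
  pair_i <- rep(seq_len(ns), times = ns)
  pair_j <- rep(seq_len(ns), each = ns)
  keep <- pair_i < pair_j
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]
  site_key <- paste(sites$protein, sites$resno)
  mind <- vapply(seq_along(pair_i), function(k) {
    a <- which(key == site_key[pair_i[k]])
    b <- which(key == site_key[pair_j[k]])
    min(sqrt(outer(rowSums(xyz[a, , drop = FALSE]^2),
                   rowSums(xyz[b, , drop = FALSE]^2), "+") -
               2 * xyz[a, , drop = FALSE] %*% t(xyz[b, , drop = FALSE])))
  }, 0)
  near <- which(mind <= reach)
  # decoy pool: intra-body pairs beyond reach (same protein, both
  # residues inside one rigid body of that subunit)
  same_body <- vapply(seq_along(pair_i), function(k) {
    if (sites$protein[pair_i[k]] != sites$protein[pair_j[k]]) return(FALSE)
    prot <- sites$protein[pair_i[k]]
    ch <- names(sub)[sub == prot][1]
    lookup <- body_lookup(truth$bodies)
    b1 <- lookup(ch, sites$resno[pair_i[k]])
    b2 <- lookup(ch, sites$resno[pair_j[k]])
    !is.na(b1) && !is.na(b2) && b1 == b2
  }, TRUE)
  far <- which(mind > reach & same_body)
  n_decoy <- round(n_links * decoy_fraction)
  n_true <- n_links - n_decoy
  if (length(near) < n_true) stop("not enough eligible pairs within reach")
  if (n_decoy > 0 && length(far) < n_decoy)
    stop("not enough intra-body pairs beyond reach for decoys")
  pick_true <- sample(near, n_true)
  pick_decoy <- if (n_decoy > 0) sample(far, n_decoy) else integer(0)
  draw_ld <- function(n, mean, sd) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      v <- rnorm(1, mean, sd)
      while (v < 30) v <- rnorm(1, mean, sd)
      out[i] <- v
    }
    out
  }
  mk <- function(idx, ld) {
    data.frame(protein1 = sites$protein[pair_i[idx]],
               residue1 = sites$resno[pair_i[idx]],
               protein2 = sites$protein[pair_j[idx]],
               residue2 = sites$resno[pair_j[idx]],
               linker = linker, ld_score = ld,
               stringsAsFactors = FALSE)
  }
  df <- mk(pick_true, draw_ld(n_true, 40, 5))
  if (n_decoy > 0) df <- rbind(df, mk(pick_decoy, draw_ld(n_decoy, 33, 2)))
  decoy_flag <- c(rep(FALSE, n_true), rep(TRUE, n_decoy))
  out <- crosslink_table(df)
  # re-derive flags after canonical reordering via unordered-pair keys
  ukey <- function(d) {
    a <- paste(d$protein1, d$residue1); b <- paste(d$protein2, d$residue2)
    paste(pmin(a, b), pmax(a, b))
  }
  attr(out, "is_decoy") <- decoy_flag[match(ukey(out), ukey(df))]
  out
}

#' Standard two-lobed fixture with an asymmetric ring
#'
#' The standard end-to-end test case: three scaffold bodies in two
#' C2-related copies forming a two-lobed scaffold, plus a three-body
#' ring bound asymmetrically to one lobe. All six body types have
#' clearly distinct sizes (as do real multi-subunit complexes) and are
#' packed with visible separation, so each domain is individually
#' resolvable in the maps at 28 Angstrom. Two noisy maps are emitted
#' (scaffold-only and full assembly, both at 28 Angstrom) together with
#' a crosslink table carrying 5% decoys.
#'
#' @param seed master seed; map noise and crosslink seeds are derived
#'   from it.
#' @param resolution map resolution, default 28 (the 27-31 Angstrom
#'   negative-stain regime).
#' @param voxel voxel size, default 4.
#' @param noise_sd relative map noise, default 0.05.
#' @param n_links crosslinks to simulate, default 60.
#' @return list of class `elongator_fixture`: `truth`,
#'   `scaffold_model`, `ref_model`, `map_full`, `map_scaffold`,
#'   `crosslinks`, and the parameters.
#' @export
elongator_like_fixture <- function(seed = 1, resolution = 28, voxel = 4,
                                   noise_sd = 0.05, n_links = 60) {
  truth <- generate_assembly(n_bodies = 3, body_size = c(170, 130, 95),
                             symmetry = "C2", extra_bodies = 3,
                             extra_size = c(145, 110, 75), seed = seed)
  scaffold_chains <- names(truth$model$subunit_of_chain)[
    grepl("^S", truth$model$subunit_of_chain)]
  sm <- truth$model
  sm$atoms <- sm$atoms[sm$atoms$chain %in% scaffold_chains, ]
  sm <- atomic_model(sm$atoms, sm$subunit_of_chain[scaffold_chains],
                     sm$copy_of_chain[scaffold_chains])
  map_full <- simulate_noisy_map(truth, resolution, noise_sd, voxel,
                                 seed = run_seed(seed, 11))
  map_scaffold <- simulate_noisy_map(sm, resolution, noise_sd, voxel,
                                     seed = run_seed(seed, 12))
  xl <- simulate_crosslinks(truth, n_links, decoy_fraction = 0.05,
                            reach = 30, seed = run_seed(seed, 13))
  structure(list(truth = truth, scaffold_model = sm,
                 ref_model = reference_model(truth),
                 map_full = map_full, map_scaffold = map_scaffold,
                 crosslinks = xl,
                 params = list(seed = seed, resolution = resolution,
                               voxel = voxel, noise_sd = noise_sd,
                               n_links = n_links, decoy_fraction = 0.05)),
            class = "elongator_fixture")
}

#' Pose recovery errors against the ground truth
#'
#' For each body, the translational error is the distance between the
#' posed centroid and the true centroid of the matching copy, and the
#' rotational error the quaternion angle to the matching true rotation.
#' Copies of a subunit type are interchangeable: each body is matched
#' to the copy (of its own type) that minimizes its error, and for
#' two-copy types a configuration-level check can additionally require
#' a one-to-one assignment via [assignment_errors()].
#'
#' @param poses named pose list (or `assembly_config`) in the copy-1
#'   reference frame.
#' @param truth the `synthetic_truth`.
#' @return data.frame: `body`, `trans_err` (Angstrom), `rot_err`
#'   (degrees), `matched_copy`.
#' @export
pose_errors <- function(poses, truth) {
  if (inherits(poses, "assembly_config")) poses <- poses$poses
  out <- list()
  for (nm in names(poses)) {
    type <- truth$body_types[[nm]]
    cands <- names(truth$body_types)[truth$body_types == type]
    best <- c(Inf, Inf); bc <- NA_character_
    for (cn in cands) {
      tp <- truth$poses_true[[cn]]
      te <- sqrt(sum((poses[[nm]]$t - tp$t)^2))
      re <- cpp_quat_angle(poses[[nm]]$q, tp$q) * 180 / pi
      if (te < best[1]) { best <- c(te, re); bc <- cn }
    }
    out[[nm]] <- data.frame(body = nm, trans_err = best[1],
                            rot_err = best[2], matched_copy = bc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname pose_errors
#' @details `assignment_errors` additionally enforces a one-to-one
#'   matching of the two copies of each type to the two true poses
#'   (choosing the pairing that minimizes the larger error).
#' @export
assignment_errors <- function(poses, truth) {
  if (inherits(poses, "assembly_config")) poses <- poses$poses
  res <- list()
  types <- unique(truth$body_types[names(poses)])
  for (type in types) {
    members <- names(poses)[truth$body_types[names(poses)] == type]
    truths <- names(truth$body_types)[truth$body_types == type]
    err <- function(nm, cn) {
      tp <- truth$poses_true[[cn]]
      sqrt(sum((poses[[nm]]$t - tp$t)^2))
    }
    if (length(members) == 2 && length(truths) == 2) {
      e1 <- c(err(members[1], truths[1]), err(members[2], truths[2]))
      e2 <- c(err(members[1], truths[2]), err(members[2], truths[1]))
      pick <- if (max(e1) <= max(e2)) e1 else e2
      res[[type]] <- data.frame(body = members, trans_err = pick)
    } else {
      res[[type]] <- data.frame(
        body = members,
        trans_err = vapply(members, function(nm)
          min(vapply(truths, function(cn) err(nm, cn), 0)), 0))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
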