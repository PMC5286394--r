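# Rigid-body segmentation and the two-resolution representation:
# Calpha atoms for distance restraints, 10-residue beads for the clash
# term and for cheap density scoring.

#' Segment a model into rigid bodies
#'
#' Body definitions give disjoint residue ranges per chain; whole domains
#' move as rigid units while the linker residues between consecutive
#' bodies of one chain stay flexible. Linker residue counts are derived
#' from the sequence gaps between consecutive bodies.
#'
#' @param model an `atomic_model`.
#' @param defs data.frame with columns `body`, `chain`, `start`, `end`
#'   (author residue numbering, inclusive); a body may span several rows.
#' @return list of `rigid_body` objects, each with `name`, `ranges`, and
#'   `linker_neighbors` (data.frame `other`, `n_linker`).
#' @export
segment_rigid_bodies <- function(model, defs) {
  need <- c("body", "chain", "start", "end")
  if (!all(need %in% names(defs)))
    stop("defs needs columns: ", paste(need, collapse = ", "))
  if (any(defs$end < defs$start)) stop("range end before start")
  # overlap check within each chain
  for (ch in unique(defs$chain)) {
    d <- defs[defs$chain == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1) {
      bad <- which(d$start[-1] <= d$end[-nrow(d)])
      if (length(bad))
        stop(sprintf("overlapping body definitions on chain %s: %s (%d-%d) and %s (%d-%d)",
                     ch, d$body[bad[1]], d$start[bad[1]], d$end[bad[1]],
                     d$body[bad[1] + 1], d$start[bad[1] + 1], d$end[bad[1] + 1]))
    }
  }
  bodies <- lapply(unique(defs$body), function(nm) {
    structure(list(name = nm,
                   ranges = defs[defs$body == nm, c("chain", "start", "end"),
                                 drop = FALSE],
                   linker_neighbors = data.frame(other = character(),
                                                 n_linker = integer())),
              class = "rigid_body")
  })
  names(bodies) <- unique(defs$body)
  # linker neighbors: consecutive bodies along each chain
  for (ch in unique(defs$chain)) {
    d <- defs[defs$chain == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2) next
    for (i in seq_len(nrow(d) - 1)) {
      a <- d$body[i]; b <- d$body[i + 1]
      if (a == b) next
      n_link <- max(0L, as.integer(d$start[i + 1] - d$end[i] - 1L))
      bodies[[a]]$linker_neighbors <- rbind(
        bodies[[a]]$linker_neighbors,
        data.frame(other = b, n_linker = n_link))
      bodies[[b]]$linker_neighbors <- rbind(
        bodies[[b]]$linker_neighbors,
        data.frame(other = a, n_linker = n_link))
    }
  }
  bodies
}

#' @export
print.rigid_body <- function(x, ...) {
  cat(sprintf("rigid_body %s: %s\n", x$name,
              paste(sprintf("%s:%d-%d", x$ranges$chain, x$ranges$start,
                            x$ranges$end), collapse = ", ")))
  invisible(x)
}

# residue-count-based bead radius: sphere of volume span * 135 A^3
# (mean amino-acid volume 0.135 nm^3 per residue)
bead_radius <- function(span) (3 * span * 135 / (4 * pi))^(1 / 3)

#' Coarse-grain a model into beads
#'
#' Converts each consecutive `stretch`-residue run of Calpha atoms into
#' one bead centered at the stretch's Calpha centroid. The bead radius is
#' that of a sphere with volume `span x 135 A^3` (mean amino-acid
#' volume). A trailing stretch shorter than `stretch` yields a smaller
#' bead, so the bead spans always sum to the structured residue count.
#'
#' @param model an `atomic_model` (or a `calpha` table).
#' @param stretch residues per bead, default 10.
#' @param body_of optional function `(chain, resno) -> body name` used to
#'   label beads with their parent body; beads never straddle bodies.
#' @return data.frame of class `bead_model`: `x`,`y`,`z`, `radius`,
#'   `span`, `chain`, `res_start`, `res_end`, `body`.
#' @export
coarse_grain <- function(model, stretch = 10, body_of = NULL) {
  ca <- if (inherits(model, "atomic_model")) calpha(model) else model
  if (nrow(ca) == 0L) stop("chain with no CA atoms")
  grp_body <- if (is.null(body_of)) ca$chain
              else mapply(body_of, ca$chain, ca$resno)
  out <- list()
  for (g in unique(paste(ca$chain, grp_body, sep = "\r"))) {
    sel <- paste(ca$chain, grp_body, sep = "\r") == g
    cc <- ca[sel, , drop = FALSE]
    cc <- cc[order(cc$resno), , drop = FALSE]
    n <- nrow(cc)
    starts <- seq(1, n, by = stretch)
    for (s in starts) {
      e <- min(s + stretch - 1, n)
      span <- e - s + 1
      xyz <- colMeans(cc[s:e, c("x", "y", "z")])
      out[[length(out) + 1]] <- data.frame(
        x = xyz[1], y = xyz[2], z = xyz[3],
        radius = bead_radius(span), span = span,
        chain = cc$chain[1], res_start = cc$resno[s], res_end = cc$resno[e],
        body = grp_body[sel][1], stringsAsFactors = FALSE)
    }
  }
  beads <- do.call(rbind, out)
  rownames(beads) <- NULL
  class(beads) <- c("bead_model", "data.frame")
  beads
}

# internal: beads for one rigid body of a model
body_beads <- function(model, body, stretch = 10) {
  bm <- body_model(model, body)
  b <- coarse_grain(bm, stretch = stretch)
  b$body <- body$name
  b
}
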