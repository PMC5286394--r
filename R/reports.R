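# End-stage comparisons and summaries.

#' Least-squares superposition RMSD
#'
#' Pairs atoms by chain id, residue number, and atom name over the
#' selection, computes the optimal proper rigid superposition (Kabsch,
#' SVD with determinant guard -- no reflection even when one would score
#' better), and reports the RMSD over the paired atoms. The number of
#' paired atoms is reported alongside the RMSD, since residue coverage
#' differences between depositions change the selection.
#'
#' @param modelA,modelB `atomic_model` objects.
#' @param selection `"calpha"` (default) or `"all"` atom names.
#' @return list: `rmsd` (Angstrom), `n_atoms`, `rotation` (3x3, applied
#'   to centered B), `translation`.
#' @export
superpose_rmsd <- function(modelA, modelB, selection = c("calpha", "all")) {
  selection <- match.arg(selection)
  a <- modelA$atoms; b <- modelB$atoms
  if (selection == "calpha") {
    a <- a[a$elety == "CA", ]; b <- b[b$elety == "CA", ]
  }
  key <- function(df) paste(df$chain, df$resno, df$elety, sep = "|")
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  if (length(common) < 3) stop("fewer than 3 paired atoms")
  A <- as.matrix(a[match(common, ka), c("x", "y", "z")])
  B <- as.matrix(b[match(common, kb), c("x", "y", "z")])
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(t(B0) %*% A0)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  Bfit <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Bfit)^2)))
  list(rmsd = rmsd, n_atoms = length(common), rotation = R,
       translation = ca - as.numeric(R %*% cb))
}

#' Crosslink network summary
#'
#' Counts unique links by category: inter-subunit (different proteins,
#' plus dimeric links, which join two copies of one protein and are
#' counted as inter-copy), intra-subunit (same protein, different
#' residues), and the dimeric subset; plus a per-protein-pair count
#' matrix. `n_inter + n_intra` partitions the unique links.
#'
#' @param crosslinks a `crosslink_table`.
#' @return list: `n_inter`, `n_intra`, `n_dimeric`, `pair_matrix`.
#' @export
crosslink_network_summary <- function(crosslinks) {
  if (nrow(crosslinks) == 0L) {
    return(list(n_inter = 0L, n_intra = 0L, n_dimeric = 0L,
                pair_matrix = matrix(0L, 0, 0)))
  }
  inter <- crosslinks$is_interlink | crosslinks$is_dimeric
  prots <- sort(unique(c(crosslinks$protein1, crosslinks$protein2)))
  m <- matrix(0L, length(prots), length(prots),
              dimnames = list(prots, prots))
  for (i in seq_len(nrow(crosslinks))) {
    p1 <- crosslinks$protein1[i]; p2 <- crosslinks$protein2[i]
    m[p1, p2] <- m[p1, p2] + 1L
    if (p1 != p2) m[p2, p1] <- m[p2, p1] + 1L
  }
  list(n_inter = sum(inter), n_intra = sum(!inter),
       n_dimeric = sum(crosslinks$is_dimeric), pair_matrix = m)
}

#' Formatted handedness comparison
#'
#' Runs [handedness_test()] and emits a serializable report: best-fit
#' P-value and score per hand, score histogram data, and the verdict.
#' The report round-trips losslessly through its JSON form.
#'
#' @param body,map,... passed to [handedness_test()].
#' @param path optional path; when given the report is written as JSON.
#' @return list of class `handedness_report`.
#' @export
handedness_report <- function(body, map, ..., path = NULL) {
  ht <- handedness_test(body, map, ...)
  brk <- seq(-1, 1, by = 0.05)
  rep <- list(pvalue_native = ht$pvalue_native,
              pvalue_mirrored = ht$pvalue_mirrored,
              ncc_native = ht$ncc_native,
              ncc_mirrored = ht$ncc_mirrored,
              log10_ratio = ht$log10_ratio,
              preferred_hand = ht$preferred_hand,
              histogram = list(
                breaks = brk,
                native = as.integer(table(cut(ht$fits_native$ncc, brk))),
                mirrored = as.integer(table(cut(ht$fits_mirrored$ncc, brk)))))
  class(rep) <- "handedness_report"
  if (!is.null(path))
    jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, digits = NA)
  rep
}

#' @rdname handedness_report
#' @param path JSON file written by `handedness_report`.
#' @export
read_handedness_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "handedness_report"
  rep
}

#' @export
print.handedness_report <- function(x, ...) {
  cat(sprintf("handedness: %s (P native %.3g, mirrored %.3g)\n",
              x$preferred_hand, x$pvalue_native, x$pvalue_mirrored))
  invisible(x)
}
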