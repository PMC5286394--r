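# Crosslink identification tables (xQuest-style export): one row per
# identified residue-residue link with linker chemistry and an ld
# (linear discriminant) confidence score.

#' Read a crosslink table
#'
#' Reads a tab- or comma-delimited table with header columns `Protein1`,
#' `AbsPos1`, `Protein2`, `AbsPos2`, `linker`, `ld-score` (case
#' insensitive; `ld_score`/`ldscore` accepted). Only links with
#' `ld_score >= min_ld` are retained ("highly confident" at the default
#' cutoff of 30). Duplicates -- the same unordered residue pair with the
#' same linker -- are collapsed to one record keeping the maximum score.
#'
#' @param path file path.
#' @param min_ld inclusive ld-score threshold; default 30.
#' @return data.frame of class `crosslink_table` with columns `protein1`,
#'   `residue1`, `protein2`, `residue2`, `linker`, `ld_score`,
#'   `is_interlink`, `is_dimeric`.
#' @export
read_crosslink_table <- function(path, min_ld = 30) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  nm <- tolower(gsub("[^a-z0-9]", "", tolower(names(df))))
  pick <- function(keys) {
    i <- which(nm %in% keys)
    if (!length(i)) NA_integer_ else i[1]
  }
  idx <- c(protein1 = pick("protein1"), residue1 = pick(c("abspos1", "residue1")),
           protein2 = pick("protein2"), residue2 = pick(c("abspos2", "residue2")),
           linker = pick("linker"), ld_score = pick(c("ldscore", "ld")))
  if (anyNA(idx))
    stop("schema error: missing required column(s): ",
         paste(names(idx)[is.na(idx)], collapse = ", "))
  out <- data.frame(protein1 = as.character(df[[idx["protein1"]]]),
                    residue1 = as.integer(df[[idx["residue1"]]]),
                    protein2 = as.character(df[[idx["protein2"]]]),
                    residue2 = as.integer(df[[idx["residue2"]]]),
                    linker = as.character(df[[idx["linker"]]]),
                    ld_score = as.numeric(df[[idx["ld_score"]]]),
                    stringsAsFactors = FALSE)
  crosslink_table(out, min_ld = min_ld)
}

#' Validate and normalize a crosslink table
#'
#' Applies the ld-score filter, orders each pair canonically, collapses
#' duplicates keeping the maximum score, and derives the `is_interlink`
#' and `is_dimeric` flags. A dimeric link joins the same residue of the
#' same protein across two copies.
#'
#' @param df data.frame with columns `protein1`, `residue1`, `protein2`,
#'   `residue2`, `linker`, `ld_score`.
#' @param min_ld inclusive ld-score threshold.
#' @return A `crosslink_table` data.frame.
#' @export
crosslink_table <- function(df, min_ld = -Inf) {
  if (any(df$residue1 <= 0 | df$residue2 <= 0))
    stop("residue positions must be positive")
  if (any(!is.finite(df$ld_score))) stop("non-finite ld scores")
  df <- df[df$ld_score >= min_ld, , drop = FALSE]
  if (nrow(df)) {
    # canonical unordered pair ordering
    swap <- df$protein1 > df$protein2 |
      (df$protein1 == df$protein2 & df$residue1 > df$residue2)
    tmp_p <- df$protein1[swap]; tmp_r <- df$residue1[swap]
    df$protein1[swap] <- df$protein2[swap]
    df$residue1[swap] <- df$residue2[swap]
    df$protein2[swap] <- tmp_p; df$residue2[swap] <- tmp_r
    key <- paste(df$protein1, df$residue1, df$protein2, df$residue2,
                 df$linker, sep = "|")
    df <- df[order(key, -df$ld_score), , drop = FALSE]
    df <- df[!duplicated(paste(df$protein1, df$residue1, df$protein2,
                               df$residue2, df$linker, sep = "|")), ,
             drop = FALSE]
  }
  df$is_interlink <- df$protein1 != df$protein2
  df$is_dimeric <- df$protein1 == df$protein2 & df$residue1 == df$residue2
  rownames(df) <- NULL
  class(df) <- c("crosslink_table", "data.frame")
  df
}

#' Write a crosslink table
#'
#' Writes the tab-delimited dialect that [read_crosslink_table()] parses
#' (`Protein1`, `AbsPos1`, `Protein2`, `AbsPos2`, `linker`, `ld-score`).
#'
#' @param xl a `crosslink_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_crosslink_table <- function(xl, path) {
  out <- data.frame(Protein1 = xl$protein1, AbsPos1 = xl$residue1,
                    Protein2 = xl$protein2, AbsPos2 = xl$residue2,
                    linker = xl$linker, `ld-score` = xl$ld_score,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
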