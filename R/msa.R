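#' Construct an alignment object
#'
#' @param rows Named character vector of equal-length gapped sequences
#'   (names are sequence ids).
#' @return An object of class `shsp_alignment`: list with `rows`, `ncols`.
#' @export
new_alignment <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  if (anyDuplicated(names(rows))) stop("duplicate row ids")
  len <- unique(nchar(rows))
  if (length(len) != 1L) stop("alignment rows differ in length")
  structure(list(rows = rows, ncols = len), class = "shsp_alignment")
}

#' @export
print.shsp_alignment <- function(x, ...) {
  cat("<shsp_alignment> ", length(x$rows), " rows x ", x$ncols, " columns\n",
      sep = "")
  invisible(x)
}

#' Remove gaps from an aligned row
#' @param x Character vector of gapped sequences.
#' @return Ungapped sequences.
#' @export
degap <- function(x) gsub("[-.]", "", x)

default_submat <- function() {
  # Standard BLOSUM62 shipped with Biostrings.
  get(utils::data("BLOSUM62", package = "Biostrings",
                  envir = environment()), envir = environment())
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (via Biostrings) under a BLOSUM62-type
#' substitution table; a gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param a,b Single records (1-row data frames) or residue strings.
#' @param submat Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend Gap penalties (defaults 10 and 0.5).
#' @return List with `alignment` (an `shsp_alignment` of the two gapped
#'   rows) and `score`.
#' @export
pairwise_align <- function(a, b, submat = default_submat(),
                           gap_open = 10, gap_extend = 0.5) {
  sa <- record_residues(a)
  sb <- record_residues(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  ida <- if (is.data.frame(a)) a$id else "a"
  idb <- if (is.data.frame(b)) b$id else "b"
  rows <- stats::setNames(
    c(as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa))),
    c(ida, idb))
  list(alignment = new_alignment(rows), score = Biostrings::score(pa))
}

#' Progressive multiple alignment
#'
#' Aligns two or more records with MAFFT (fixed, deterministic options:
#' progressive FFT-NS-2, no iterative refinement). Input order is preserved.
#'
#' @param records Record data frame (>= 2 rows).
#' @return An `shsp_alignment`.
#' @export
progressive_align <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 2L) {
    stop("progressive alignment needs at least 2 records")
  }
  mafft <- Sys.which("mafft")
  if (!nzchar(mafft)) stop("mafft executable not found on PATH")
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(records, fin)
  status <- system2(mafft,
                    c("--retree", "2", "--maxiterate", "0", "--anysymbol",
                      "--quiet", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  aln <- read_alignment(fout)
  # mafft preserves input order; re-key defensively anyway
  rows <- aln$rows[records$id]
  if (anyNA(rows)) stop("aligner dropped sequences")
  ungapped <- degap(rows)
  if (!identical(unname(ungapped), records$residues)) {
    stop("aligner altered residues")
  }
  new_alignment(rows)
}

# For row `r` (gapped), residue index at each column; 0 where gap.
residue_index_by_column <- function(row) {
  chars <- strsplit(row, "")[[1]]
  nongap <- !(chars %in% c("-", "."))
  idx <- cumsum(nongap)
  idx[!nongap] <- 0L
  idx
}

#' Extract the ACD + C-terminal extension columns of an alignment
#'
#' Keeps alignment columns where at least `min_occupancy` of the rows place
#' a residue belonging to their ACD or C-terminal extension; within kept
#' columns, residues outside those regions (N-arm residues) are masked to
#' gaps. This is the column set used for phylogeny.
#'
#' @param alignment An `shsp_alignment`.
#' @param annotations Named list of `region_annotation` covering every row.
#' @param min_occupancy Minimum fraction of rows with an in-region residue
#'   for a column to be kept (default 0.5).
#' @return An `shsp_alignment`; attribute `column_provenance` maps its
#'   columns to the input alignment's column indices.
#' @export
extract_region_columns <- function(alignment, annotations,
                                   min_occupancy = 0.5) {
  stopifnot(inherits(alignment, "shsp_alignment"))
  ids <- names(alignment$rows)
  missing_ann <- setdiff(ids, names(annotations))
  if (length(missing_ann) > 0L) {
    stop("missing annotation for row(s): ", paste(missing_ann, collapse = ", "))
  }
  n <- length(ids)
  in_region <- matrix(FALSE, nrow = n, ncol = alignment$ncols)
  charmat <- do.call(rbind, strsplit(alignment$rows, ""))
  for (i in seq_len(n)) {
    ann <- annotations[[ids[i]]]
    idx <- residue_index_by_column(alignment$rows[i])
    # ACD + C-terminal extension = every position from acd_start onward
    in_region[i, ] <- idx >= ann$acd_start
  }
  keep <- which(colMeans(in_region) >= min_occupancy)
  if (length(keep) == 0L) stop("no ACD/C-extension columns found")
  charmat[!in_region] <- "-"
  rows <- apply(charmat[, keep, drop = FALSE], 1, paste, collapse = "")
  out <- new_alignment(stats::setNames(rows, ids))
  attr(out, "column_provenance") <- keep
  out
}

#' Write an alignment as aligned FASTA
#' @param alignment An `shsp_alignment`.
#' @param path Output path.
#' @param width Wrap width.
#' @export
write_alignment <- function(alignment, path, width = 60L) {
  recs <- data.frame(id = names(alignment$rows), description = "",
                     residues = unname(alignment$rows),
                     stringsAsFactors = FALSE)
  # bypass residue validation: rows contain gaps by design
  lines <- unlist(lapply(seq_len(nrow(recs)), function(i) {
    s <- recs$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", recs$id[i]),
      substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an aligned FASTA file as an alignment
#' @param path Path to aligned FASTA.
#' @return An `shsp_alignment`.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("empty alignment file")
  ids <- sub("\\s.*$", "", names(aa))
  new_alignment(stats::setNames(toupper(as.character(aa)), ids))
}
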