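#' Build an ungapped log-odds position-specific scoring matrix
#'
#' Columns whose gap fraction is 50% or more are dropped (the retained-column
#' mapping is kept in `kept_columns`). The score of residue `a` in a column
#' with observed count `c` over `N` non-gap, non-X rows is
#' `log((c + pseudocount * background_a) / (N + pseudocount) / background_a)`.
#' `X` residues are ignored when counting and score 0 when scanned.
#'
#' @param alignment Character vector of equal-length (gapped) rows, or an
#'   `shsp_alignment` (see [new_alignment()]).
#' @param pseudocount Non-negative pseudocount weight (default 1).
#' @param background Named vector of 20 residue frequencies summing to 1;
#'   default uniform.
#' @return An object of class `shsp_pssm`: list with `scores` (20 x width
#'   matrix), `width`, `pseudocount`, `background`, `kept_columns`.
#' @export
build_pssm <- function(alignment, pseudocount = 1, background = NULL) {
  rows <- if (inherits(alignment, "shsp_alignment")) alignment$rows else alignment
  if (length(rows) == 0L) stop("empty alignment")
  len <- unique(nchar(rows))
  if (length(len) != 1L) stop("ragged alignment rows")
  if (len == 0L) stop("zero-length alignment")
  stopifnot(pseudocount >= 0)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA20)
  }
  stopifnot(length(background) == 20L, all(AA20 %in% names(background)),
            abs(sum(background) - 1) < 1e-8)
  background <- background[AA20]
  mat <- do.call(rbind, strsplit(rows, ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gap_frac < 0.5)
  if (length(keep) == 0L) stop("all columns gap-dominated")
  scores <- vapply(keep, function(j) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    n <- length(col)
    cnt <- table(factor(col, levels = AA20))
    log((as.numeric(cnt) + pseudocount * background) /
          (n + pseudocount) / background)
  }, numeric(20))
  scores <- matrix(scores, nrow = 20, dimnames = list(AA20, NULL))
  structure(list(scores = scores, width = length(keep),
                 pseudocount = pseudocount, background = background,
                 kept_columns = keep),
            class = "shsp_pssm")
}

#' Score a sequence window against a PSSM
#'
#' Finds the placement of the full profile that maximizes the summed
#' per-column log-odds; ties broken by the smallest start.
#'
#' @param pssm An `shsp_pssm`.
#' @param record A single record (1-row data frame or residue string).
#' @return List with `start` (1-based) and `score`.
#' @export
best_window <- function(pssm, record) {
  stopifnot(inherits(pssm, "shsp_pssm"))
  s <- record_residues(record)
  L <- nchar(s)
  w <- pssm$width
  if (L < w) stop("sequence shorter than profile width (", w, ")")
  chars <- strsplit(s, "")[[1]]
  idx <- match(chars, AA20)  # NA for X -> column score 0
  nstart <- L - w + 1L
  scores <- vapply(seq_len(nstart), function(st) {
    ii <- idx[st:(st + w - 1L)]
    keep <- !is.na(ii)
    sum(pssm$scores[cbind(ii[keep], which(keep))])
  }, numeric(1))
  st <- which.max(scores)  # which.max returns the first (smallest) maximum
  list(start = as.integer(st), score = scores[st])
}

record_residues <- function(record) {
  if (is.character(record) && length(record) == 1L) return(toupper(record))
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  record$residues
}

record_id <- function(record) {
  if (is.data.frame(record)) record$id else NA_character_
}

#' Read a reference feature map
#'
#' The map file is a TSV with columns `column` (reference-alignment column,
#' 1-based) and `feature` (`beta2` ... `beta9`, `L57`, or `none`), preceded
#' by `#`-prefixed metadata lines `# acd_start=..`, `# acd_end=..` and
#' `# beta7_arg_column=..` giving the ACD bounds and the conserved beta7
#' arginine column in reference coordinates.
#'
#' @param path Path to the map TSV; defaults to the packaged synthetic map.
#' @return List with `acd_start`, `acd_end`, `beta7_arg_column`, `features`
#'   (data frame `column`, `feature`).
#' @export
read_reference_map <- function(path = catalog_path("reference_map_synthetic.tsv")) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*(\\w+)\\s*=\\s*(\\d+)", ml))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- as.integer(m[3])
  }
  need <- c("acd_start", "acd_end", "beta7_arg_column")
  if (!all(need %in% names(meta))) {
    stop("reference map missing metadata: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("column", "feature") %in% names(tab)))
  ok <- c(paste0("beta", 2:9), "L57", "none")
  if (any(!tab$feature %in% ok)) stop("unknown feature in reference map")
  if (meta$beta7_arg_column < meta$acd_start ||
      meta$beta7_arg_column > meta$acd_end) {
    stop("beta7 arginine column outside the ACD")
  }
  list(acd_start = meta$acd_start, acd_end = meta$acd_end,
       beta7_arg_column = meta$beta7_arg_column,
       features = tab[, c("column", "feature")])
}

#' The packaged synthetic ACD profile
#'
#' A PSSM built from the packaged synthetic reference alignment of
#' alpha-crystallin domains (92 columns). An alternative profile can be
#' built from any ungapped ACD alignment with [build_pssm()].
#'
#' @param pseudocount Passed to [build_pssm()].
#' @return An `shsp_pssm` of width 92.
#' @export
default_acd_profile <- function(pseudocount = 1) {
  ref <- read_fasta(catalog_path("acd_reference_synthetic.fasta"))
  build_pssm(ref$residues, pseudocount = pseudocount)
}

feature_intervals <- function(refmap) {
  feats <- refmap$features[refmap$features$feature != "none", ]
  sp <- split(feats$column, feats$feature)
  lapply(sp, function(cols) {
    cols <- sort(cols)
    if (any(diff(cols) != 1L)) stop("non-contiguous feature interval")
    c(start = cols[1], end = cols[length(cols)])
  })
}

#' Delimit N-arm, ACD and C-terminal extension of an sHSP
#'
#' Places the ACD profile at its best-scoring window; everything before is
#' the N-terminal arm and everything after the C-terminal extension. Strand
#' intervals (beta2-beta9), the L57 loop and the beta7 arginine column are
#' projected from reference-map coordinates through the window offset.
#'
#' @param record A single record (1-row data frame).
#' @param acd_pssm ACD profile (default [default_acd_profile()]); its width
#'   must equal the reference map's ACD width.
#' @param refmap Reference feature map (default [read_reference_map()]).
#' @return An object of class `region_annotation`: list with `sequence_id`,
#'   `acd_start`, `acd_end`, `n_arm`, `c_ext` (each `c(start, end)` or
#'   `NULL` when empty), `strand_map` (data frame `feature`, `start`,
#'   `end`), `l57_interval`, `beta7_arg_pos`, `acd_ref_start`, `acd_score`,
#'   `length`.
#' @export
delimit_regions <- function(record, acd_pssm = default_acd_profile(),
                            refmap = read_reference_map()) {
  w <- acd_pssm$width
  ref_w <- refmap$acd_end - refmap$acd_start + 1L
  if (w != ref_w) {
    stop("profile width (", w, ") != reference ACD width (", ref_w, ")")
  }
  s <- record_residues(record)
  L <- nchar(s)
  bw <- best_window(acd_pssm, record)
  acd_start <- bw$start
  acd_end <- acd_start + w - 1L
  offset <- acd_start - refmap$acd_start  # ref column + offset = seq position
  iv <- feature_intervals(refmap)
  clip <- function(x) pmin(pmax(x + offset, acd_start), acd_end)
  strand_names <- paste0("beta", 2:9)
  sm <- do.call(rbind, lapply(strand_names, function(f) {
    if (is.null(iv[[f]])) return(NULL)
    data.frame(feature = f, start = clip(iv[[f]]["start"]),
               end = clip(iv[[f]]["end"]), row.names = NULL)
  }))
  l57 <- if (!is.null(iv[["L57"]])) unname(clip(iv[["L57"]])) else NULL
  structure(list(
    sequence_id = record_id(record),
    acd_start = acd_start, acd_end = acd_end,
    n_arm = if (acd_start > 1L) c(1L, acd_start - 1L) else NULL,
    c_ext = if (acd_end < L) c(acd_end + 1L, L) else NULL,
    strand_map = sm,
    l57_interval = l57,
    beta7_arg_pos = unname(refmap$beta7_arg_column + offset),
    acd_ref_start = refmap$acd_start,
    acd_score = bw$score,
    length = L), class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  fmt <- function(iv) if (is.null(iv)) "-" else paste0("[", iv[1], ",", iv[2], "]")
  cat("<region_annotation> ", x$sequence_id,
      ": n_arm ", fmt(x$n_arm),
      " acd [", x$acd_start, ",", x$acd_end, "]",
      " c_ext ", fmt(x$c_ext),
      " score ", signif(x$acd_score, 4), "\n", sep = "")
  invisible(x)
}

#' Annotate a set of records
#'
#' @param records Record data frame.
#' @inheritParams delimit_regions
#' @return Named list of `region_annotation`, keyed by sequence id.
#' @export
annotate_records <- function(records, acd_pssm = default_acd_profile(),
                             refmap = read_reference_map()) {
  ann <- lapply(seq_len(nrow(records)), function(i) {
    delimit_regions(records[i, , drop = FALSE], acd_pssm, refmap)
  })
  stats::setNames(ann, records$id)
}

#' Tabulate region annotations
#'
#' @param annotations List of `region_annotation`.
#' @return Data frame with one row per sequence.
#' @export
regions_table <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    data.frame(sequence_id = a$sequence_id,
               n_arm_start = if (is.null(a$n_arm)) NA_integer_ else a$n_arm[1],
               n_arm_end = if (is.null(a$n_arm)) NA_integer_ else a$n_arm[2],
               acd_start = a$acd_start, acd_end = a$acd_end,
               c_ext_start = if (is.null(a$c_ext)) NA_integer_ else a$c_ext[1],
               c_ext_end = if (is.null(a$c_ext)) NA_integer_ else a$c_ext[2],
               acd_score = a$acd_score, stringsAsFactors = FALSE)
  }))
}
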