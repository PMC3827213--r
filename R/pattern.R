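#' Parse a PROSITE-style pattern
#'
#' Supported grammar: dash-separated elements, each a single residue letter,
#' a bracketed residue class `[..]`, or a wildcard `x` / `x(n)` with fixed
#' run length `n >= 1`. Ranges `x(a,b)` and anchors are not supported. `X` in
#' a scanned sequence matches only wildcard positions.
#'
#' @param text Pattern string, e.g. `"P-P-[YF]-N-[ILV]-[IV]-x(9)-[EQ]"`.
#' @return An object of class `prosite_pattern` with fields `elements`
#'   (list of `fixed`/`class`/`wild` elements), `width` (total residues
#'   matched) and `source_text`.
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- gsub("\\s+", "", text)
  if (!nzchar(raw)) stop("empty pattern")
  toks <- strsplit(raw, "-", fixed = TRUE)[[1]]
  if (length(toks) == 0L || any(!nzchar(toks))) stop("empty pattern element")
  elements <- lapply(toks, function(tok) {
    if (grepl("^\\[", tok)) {
      if (!grepl("^\\[[A-Z]+\\]$", tok)) {
        stop("malformed residue class: ", tok)
      }
      res <- strsplit(sub("^\\[([A-Z]+)\\]$", "\\1", tok), "")[[1]]
      if (any(!res %in% AA20)) stop("illegal residue letter in class: ", tok)
      list(type = "class", residues = unique(res), n = 1L)
    } else if (grepl("\\]", tok)) {
      stop("unbalanced bracket: ", tok)
    } else if (tok == "x") {
      list(type = "wild", n = 1L)
    } else if (grepl("^x\\(\\d+\\)$", tok)) {
      n <- as.integer(sub("^x\\((\\d+)\\)$", "\\1", tok))
      if (n < 1L) stop("wildcard run length must be >= 1: ", tok)
      list(type = "wild", n = n)
    } else if (grepl("^[A-Z]$", tok)) {
      if (!tok %in% AA20) stop("illegal residue letter: ", tok)
      list(type = "fixed", residues = tok, n = 1L)
    } else {
      stop("unparseable pattern element: ", tok)
    }
  })
  structure(
    list(elements = elements,
         width = sum(vapply(elements, `[[`, 1L, "n")),
         source_text = render_elements(elements)),
    class = "prosite_pattern")
}

render_elements <- function(elements) {
  paste(vapply(elements, function(e) {
    switch(e$type,
           fixed = e$residues,
           class = paste0("[", paste(e$residues, collapse = ""), "]"),
           wild = if (e$n == 1L) "x" else sprintf("x(%d)", e$n))
  }, character(1)), collapse = "-")
}

#' Render a parsed pattern back to PROSITE notation
#' @param pattern A `prosite_pattern`.
#' @return The canonical pattern string.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  render_elements(pattern$elements)
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("<prosite_pattern> ", x$source_text, " (width ", x$width, ")\n", sep = "")
  invisible(x)
}

# Regex over the residue alphabet. Fixed letters and classes exclude X by
# construction (classes may only contain the 20 amino acids); wildcards
# match any residue including X.
pattern_regex <- function(pattern) {
  paste(vapply(pattern$elements, function(e) {
    switch(e$type,
           fixed = e$residues,
           class = paste0("[", paste(e$residues, collapse = ""), "]"),
           wild = sprintf(".{%d}", e$n))
  }, character(1)), collapse = "")
}

#' Scan sequences for a PROSITE-style pattern
#'
#' All matches are reported, including overlapping ones, in ascending start
#' order per sequence. Positions are 1-based inclusive.
#'
#' @param pattern A `prosite_pattern` (see [parse_pattern()]).
#' @param records Record data frame (see [seq_records()]).
#' @return Data frame with columns `sequence_id`, `start`, `end`, `matched`;
#'   zero rows when nothing matches.
#' @export
scan_pattern <- function(pattern, records) {
  stopifnot(inherits(pattern, "prosite_pattern"), is.data.frame(records))
  rx <- paste0("(?=", pattern_regex(pattern), ")")
  out <- lapply(seq_len(nrow(records)), function(i) {
    s <- records$residues[i]
    if (nchar(s) < pattern$width) return(NULL)
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    starts <- as.integer(m)
    ends <- starts + pattern$width - 1L
    data.frame(sequence_id = records$id[i], start = starts, end = ends,
               matched = substring(s, starts, ends),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), matched = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' The cyanophage sHSP signature pattern
#'
#' `P-P-[YF]-N-[ILV]-[IV]-x(9)-[EQ]`, a 16-residue signature located in the
#' beta2/beta3 strands of the alpha-crystallin domain that distinguishes
#' cyanophage sHSPs; suitable for PHI-BLAST-style searches.
#'
#' @format A `prosite_pattern` of width 16 (8 elements, one length-9
#'   wildcard run).
#' @export
CYANOPHAGE_SIGNATURE <- parse_pattern("P-P-[YF]-N-[ILV]-[IV]-x(9)-[EQ]")
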