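# Motif hit rows share one wide data-frame layout so finders can be rbind-ed.
motif_hit <- function(sequence_id, kind, positions, residues, region,
                      preceded_by_L = NA, followed_by_aromatic = NA,
                      is_R = NA, is_basic = NA, is_N = NA,
                      ref_column = NA_integer_, at_117 = NA) {
  data.frame(sequence_id = sequence_id, kind = kind,
             positions = paste(positions, collapse = ","),
             start = positions[1],
             residues = paste(residues, collapse = ""),
             region = region,
             preceded_by_L = preceded_by_L,
             followed_by_aromatic = followed_by_aromatic,
             is_R = is_R, is_basic = is_basic, is_N = is_N,
             ref_column = ref_column, at_117 = at_117,
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  motif_hit("", "", integer(1), "", "")[0, ]
}

region_of <- function(annotation, pos) {
  if (pos < annotation$acd_start) "n_arm"
  else if (pos > annotation$acd_end) "c_ext"
  else "acd"
}

HYDROPHOBIC_ILV <- c("I", "L", "V")
AROMATIC <- c("F", "Y", "W")

#' Find C-terminal anchoring motifs (CAMs)
#'
#' Searches the C-terminal extension only. Reported kinds:
#' `cam_classical` (L-X-I/L/V), `cam_AXP`, `cam_LXG`, `cam_LXA`, and
#' `cam_triple` (I/V-X-I/L/V-X-I/L/V, the organization seen in
#' cyanobacterial sHSPs). Overlapping hits are all reported and a triple
#' does not suppress pair motifs contained in it.
#'
#' @param record A single record (1-row data frame).
#' @param annotation Its `region_annotation` (see [delimit_regions()]).
#' @return Motif-hit data frame (possibly 0 rows); positions are 1-based
#'   coordinates in the full sequence.
#' @export
find_cam <- function(record, annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  if (is.null(annotation$c_ext)) return(empty_hits())
  s <- strsplit(record_residues(record), "")[[1]]
  id <- record_id(record)
  lo <- annotation$c_ext[1]
  hi <- annotation$c_ext[2]
  hits <- list()
  pair_kinds <- list(
    cam_classical = list(first = "L", third = HYDROPHOBIC_ILV),
    cam_AXP = list(first = "A", third = "P"),
    cam_LXG = list(first = "L", third = "G"),
    cam_LXA = list(first = "L", third = "A"))
  if (hi - lo >= 2L) {
    for (i in lo:(hi - 2L)) {
      for (kind in names(pair_kinds)) {
        def <- pair_kinds[[kind]]
        if (s[i] %in% def$first && s[i + 2L] %in% def$third) {
          hits[[length(hits) + 1L]] <-
            motif_hit(id, kind, c(i, i + 2L), s[c(i, i + 2L)], "c_ext")
        }
      }
      if (i <= hi - 4L &&
          s[i] %in% c("I", "V") &&
          s[i + 2L] %in% HYDROPHOBIC_ILV &&
          s[i + 4L] %in% HYDROPHOBIC_ILV) {
        hits[[length(hits) + 1L]] <-
          motif_hit(id, "cam_triple", c(i, i + 2L, i + 4L),
                    s[c(i, i + 2L, i + 4L)], "c_ext")
      }
    }
  }
  if (length(hits) == 0L) return(empty_hits())
  do.call(rbind, hits)
}

#' Find A-G and P-G doublets
#'
#' Scans the ACD plus `flank` residues on each side for the A-G dipeptide
#' (bacterial class A / animal marker) and the P-G dipeptide (plant /
#' bacterial class B marker). Context flags record whether the doublet is
#' preceded by L and followed by an aromatic residue (F/Y/W), the
#' arrangement characteristic of class A.
#'
#' @inheritParams find_cam
#' @param flank Residues of flank around the ACD searched (default 10).
#' @return Motif-hit data frame with kinds `doublet_AG` / `doublet_PG`.
#' @export
find_doublets <- function(record, annotation, flank = 10L) {
  stopifnot(inherits(annotation, "region_annotation"))
  s <- strsplit(record_residues(record), "")[[1]]
  id <- record_id(record)
  lo <- max(1L, annotation$acd_start - flank)
  hi <- min(length(s), annotation$acd_end + flank)
  hits <- list()
  if (hi - lo >= 1L) {
    for (i in lo:(hi - 1L)) {
      kind <- if (s[i] == "A" && s[i + 1L] == "G") "doublet_AG"
              else if (s[i] == "P" && s[i + 1L] == "G") "doublet_PG"
              else next
      hits[[length(hits) + 1L]] <- motif_hit(
        id, kind, c(i, i + 1L), s[c(i, i + 1L)],
        region_of(annotation, i),
        preceded_by_L = i > 1L && s[i - 1L] == "L",
        followed_by_aromatic = i + 2L <= length(s) && s[i + 2L] %in% AROMATIC)
    }
  }
  if (length(hits) == 0L) return(empty_hits())
  do.call(rbind, hits)
}

#' Report the residue at the conserved beta7 arginine column
#'
#' In most cyanophage sHSPs this column carries an arginine that can
#' salt-bridge acidic residues of the partner monomer's L57 loop; known
#' exceptions carry lysine (S-CRM01) or asparagine (S-PM2, S-CAM1, Syn1).
#'
#' @inheritParams find_cam
#' @return One motif-hit row of kind `beta7_residue` with flags `is_R`,
#'   `is_basic` (R or K) and `is_N`.
#' @export
beta7_residue <- function(record, annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  pos <- annotation$beta7_arg_pos
  if (is.null(pos) || is.na(pos) || pos < annotation$acd_start ||
      pos > annotation$acd_end) {
    stop("beta7 arginine column could not be mapped for ",
         annotation$sequence_id)
  }
  s <- strsplit(record_residues(record), "")[[1]]
  aa <- s[pos]
  motif_hit(record_id(record), "beta7_residue", pos, aa, "acd",
            is_R = aa == "R", is_basic = aa %in% c("R", "K"), is_N = aa == "N")
}

#' Find acidic salt-bridge partners in the L57 loop
#'
#' One hit per D/E inside the mapped L57 interval, annotated with its
#' reference column; `at_117` flags the column the beta7 arginine most
#' likely pairs with.
#'
#' @inheritParams find_cam
#' @return Motif-hit data frame with kind `acidic_partner`.
#' @export
acidic_partners <- function(record, annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  iv <- annotation$l57_interval
  if (is.null(iv)) stop("no L57 interval in annotation")
  s <- strsplit(record_residues(record), "")[[1]]
  id <- record_id(record)
  offset <- annotation$acd_ref_start - annotation$acd_start
  hits <- list()
  for (i in iv[1]:iv[2]) {
    if (s[i] %in% c("D", "E")) {
      refcol <- i + offset
      hits[[length(hits) + 1L]] <- motif_hit(
        id, "acidic_partner", i, s[i], "acd",
        ref_column = refcol, at_117 = refcol == 117L)
    }
  }
  if (length(hits) == 0L) return(empty_hits())
  do.call(rbind, hits)
}

#' Run all motif finders on one record
#'
#' @inheritParams find_cam
#' @return Combined motif-hit data frame (CAMs, doublets, beta7 residue,
#'   acidic partners).
#' @export
find_motifs <- function(record, annotation) {
  rbind(find_cam(record, annotation),
        find_doublets(record, annotation),
        beta7_residue(record, annotation),
        acidic_partners(record, annotation))
}
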