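CLASS_LABELS <- c("cyanophage_like", "bacterial_class_A_like",
                  "class_B_plant_like", "cyanobacterial_like", "unclassified")

#' Classify one annotated sHSP sequence
#'
#' Rule cascade, first match wins:
#' 1. at least one signature-pattern hit -> `cyanophage_like`;
#' 2. a hydrophobic triple CAM in the C-terminal extension together with a
#'    P-G doublet -> `cyanobacterial_like`;
#' 3. an A-G doublet -> `bacterial_class_A_like` (this marker is shared
#'    with animal sHSPs; the label is a class-A/animal-type call, not a
#'    taxonomic one);
#' 4. a P-G doublet -> `class_B_plant_like`;
#' 5. otherwise `unclassified`.
#'
#' The signature outranks the doublets because it is specific to cyanophage
#' sHSPs, whereas doublets are markers shared across kingdoms.
#'
#' @param annotation A `region_annotation`.
#' @param pattern_hits Signature hits for this sequence (from
#'   [scan_pattern()]).
#' @param motif_hits Motif hits for this sequence (from [find_motifs()] or
#'   the individual finders).
#' @return List of class `classification_result`: `sequence_id`, `label`,
#'   `rule_fired` (`signature`, `triple_plus_PG`, `AG_doublet`,
#'   `PG_doublet`, `none`), `evidence` (data frame of the supporting hits).
#' @export
classify_sequence <- function(annotation, pattern_hits, motif_hits) {
  stopifnot(inherits(annotation, "region_annotation"))
  id <- annotation$sequence_id
  ph <- pattern_hits[pattern_hits$sequence_id == id, , drop = FALSE]
  mh <- motif_hits[motif_hits$sequence_id == id, , drop = FALSE]
  triples <- mh[mh$kind == "cam_triple" & mh$region == "c_ext", , drop = FALSE]
  ag <- mh[mh$kind == "doublet_AG", , drop = FALSE]
  pg <- mh[mh$kind == "doublet_PG", , drop = FALSE]
  if (nrow(ph) > 0L) {
    res <- list(label = "cyanophage_like", rule_fired = "signature",
                evidence = ph)
  } else if (nrow(triples) > 0L && nrow(pg) > 0L) {
    res <- list(label = "cyanobacterial_like", rule_fired = "triple_plus_PG",
                evidence = rbind(triples, pg))
  } else if (nrow(ag) > 0L) {
    res <- list(label = "bacterial_class_A_like", rule_fired = "AG_doublet",
                evidence = ag)
  } else if (nrow(pg) > 0L) {
    res <- list(label = "class_B_plant_like", rule_fired = "PG_doublet",
                evidence = pg)
  } else {
    res <- list(label = "unclassified", rule_fired = "none",
                evidence = empty_hits())
  }
  structure(c(list(sequence_id = id), res), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> ", x$sequence_id, ": ", x$label,
      " (rule ", x$rule_fired, ", ", nrow(x$evidence), " evidence hits)\n",
      sep = "")
  invisible(x)
}

#' Annotate, scan and classify a set of records
#'
#' Convenience wrapper running [delimit_regions()], the signature scan and
#' all motif finders on every record, then the classification cascade.
#'
#' @param records Record data frame.
#' @param acd_pssm,refmap See [delimit_regions()].
#' @param signature Pattern used for rule 1 (default
#'   [CYANOPHAGE_SIGNATURE]).
#' @return List with `table` (data frame `sequence_id`, `label`,
#'   `rule_fired`, `n_evidence`), `results` (list of
#'   `classification_result`), `annotations`, `pattern_hits`, `motif_hits`.
#' @export
classify_records <- function(records, acd_pssm = default_acd_profile(),
                             refmap = read_reference_map(),
                             signature = CYANOPHAGE_SIGNATURE) {
  annotations <- annotate_records(records, acd_pssm, refmap)
  pattern_hits <- scan_pattern(signature, records)
  motif_hits <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    find_motifs(records[i, , drop = FALSE], annotations[[records$id[i]]])
  }))
  results <- lapply(annotations, classify_sequence,
                    pattern_hits = pattern_hits, motif_hits = motif_hits)
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(sequence_id = r$sequence_id, label = r$label,
               rule_fired = r$rule_fired, n_evidence = nrow(r$evidence),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(table = tab, results = results, annotations = annotations,
       pattern_hits = pattern_hits, motif_hits = motif_hits)
}

#' Summarize classification results
#'
#' @param table Classification table (from `classify_records()$table`).
#' @param catalog Optional catalog data frame; when given, sequence ids are
#'   matched against catalog accessions and a label-by-group confusion
#'   table is added.
#' @return List with `counts` (per-label counts, all labels present) and,
#'   when a catalog is supplied, `confusion`.
#' @export
summarize_classifications <- function(table, catalog = NULL) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  counts <- as.data.frame(base::table(factor(table$label,
                                             levels = CLASS_LABELS)),
                          stringsAsFactors = FALSE)
  names(counts) <- c("label", "n")
  out <- list(counts = counts)
  if (!is.null(catalog)) {
    merged <- merge(table, catalog[, c("accession", "group")],
                    by.x = "sequence_id", by.y = "accession")
    out$confusion <- as.data.frame(base::table(label = merged$label,
                                               group = merged$group),
                                   stringsAsFactors = FALSE)
  }
  out
}
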