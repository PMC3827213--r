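stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full sHSP analysis pipeline
#'
#' Composes the stages: read sequences, delimit regions, scan the
#' cyanophage signature, find motifs, classify, align, extract ACD +
#' C-terminal-extension columns, Poisson-corrected distances, BioNJ tree,
#' and optional clade monophyly checks. All outputs are written as
#' plain-text TSV/FASTA/newick plus a JSON run manifest.
#'
#' @param fasta Path to an input FASTA file, or a record data frame.
#' @param outdir Output directory (created if needed).
#' @param acd_pssm,refmap See [delimit_regions()].
#' @param signature Signature pattern (default [CYANOPHAGE_SIGNATURE]).
#' @param clade_sets Optional named list of tip-label vectors; each is
#'   tested for monophyly on the BioNJ tree.
#' @param extract_regions If `TRUE` (default) the tree is built from the
#'   ACD + C-terminal-extension columns only.
#' @param aligner `"mafft"` (default) to run [progressive_align()], or
#'   `"none"` when the inputs are already equal-length and column-homologous
#'   (e.g. simulator output with `indel_rate = 0`).
#' @param p_cap,d_max Distance saturation parameters
#'   (see [poisson_distance()]).
#' @return Invisibly, a list with all intermediate objects (`records`,
#'   `annotations`, `classification`, `alignment`, `region_alignment`,
#'   `distances`, `tree`, `monophyly`) and `files` (paths written).
#' @export
run_pipeline <- function(fasta, outdir,
                         acd_pssm = default_acd_profile(),
                         refmap = read_reference_map(),
                         signature = CYANOPHAGE_SIGNATURE,
                         clade_sets = NULL,
                         extract_regions = TRUE,
                         aligner = c("mafft", "none"),
                         p_cap = 0.95, d_max = 10) {
  aligner <- match.arg(aligner)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  records <- stage("seqio", {
    if (is.data.frame(fasta)) fasta else read_fasta(fasta)
  })
  cls <- stage("classify", {
    classify_records(records, acd_pssm = acd_pssm, refmap = refmap,
                     signature = signature)
  })
  annotations <- cls$annotations
  alignment <- stage("align", {
    if (aligner == "mafft") {
      progressive_align(records)
    } else {
      new_alignment(stats::setNames(records$residues, records$id))
    }
  })
  region_alignment <- if (extract_regions) {
    stage("regions", extract_region_columns(alignment, annotations))
  } else alignment
  dm <- stage("distances", poisson_distance(region_alignment,
                                            p_cap = p_cap, d_max = d_max))
  tree <- stage("bionj", bionj_tree(dm))
  monophyly <- NULL
  if (!is.null(clade_sets)) {
    monophyly <- stage("monophyly", {
      data.frame(clade = names(clade_sets),
                 n_taxa = vapply(clade_sets, length, 1L),
                 monophyletic = vapply(clade_sets, is_monophyletic,
                                       logical(1), tree = tree),
                 stringsAsFactors = FALSE)
    })
  }
  files <- list(
    regions = file.path(outdir, "regions.tsv"),
    pattern_hits = file.path(outdir, "pattern_hits.tsv"),
    motifs = file.path(outdir, "motifs.tsv"),
    classification = file.path(outdir, "classification.tsv"),
    alignment = file.path(outdir, "alignment.fasta"),
    distances = file.path(outdir, "distances.phylip"),
    tree = file.path(outdir, "tree.nwk"),
    manifest = file.path(outdir, "manifest.json"))
  wtsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage("write", {
    wtsv(regions_table(annotations), files$regions)
    wtsv(cls$pattern_hits, files$pattern_hits)
    wtsv(cls$motif_hits, files$motifs)
    wtsv(cls$table, files$classification)
    write_alignment(region_alignment, files$alignment)
    write_phylip_dm(dm, files$distances)
    write_newick(tree, files$tree)
    if (!is.null(monophyly)) {
      files$monophyly <- file.path(outdir, "monophyly.tsv")
      wtsv(monophyly, files$monophyly)
    }
    manifest <- list(
      package = "cyanoshsp",
      version = as.character(utils::packageVersion("cyanoshsp")),
      n_records = nrow(records),
      aligner = aligner,
      extract_regions = extract_regions,
      p_cap = p_cap, d_max = d_max,
      signature = signature$source_text,
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
  })
  invisible(list(records = records, annotations = annotations,
                 classification = cls, alignment = alignment,
                 region_alignment = region_alignment, distances = dm,
                 tree = tree, monophyly = monophyly, files = files))
}
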