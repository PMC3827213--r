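SHSP_CLASSES <- c("cyanophage", "bacterial_class_A", "class_B_plant",
                  "cyanobacterial")

#' Synthetic sHSP class templates
#'
#' Four full-length (160-residue) template sequences sharing one layout:
#' N-terminal arm 1-54 (ending in the conserved double proline), a
#' 92-residue alpha-crystallin domain at 55-146, and a 14-residue
#' C-terminal extension at 147-160. Class markers are planted at fixed
#' coordinates: the cyanophage signature at 57-72, an A-G doublet
#' (L/aromatic context, positions 87-90) in the cyanophage and class A
#' templates, a P-G doublet (88-89) in the plant-type and cyanobacterial
#' templates, the conserved beta7 arginine at 126, a glutamate at L57-loop
#' reference column 117, and class CAMs in the extension (classical
#' L-X-I/L/V for cyanophage and class A, the hydrophobic triple for the
#' cyanobacterial template, a plant-type I-X-I - matched by none of the
#' CAM kinds - for the plant template).
#'
#' @return Named list per class: `sequence`, `motif_columns` (positions
#'   protected by the simulator's rho factor), and `features` (planted
#'   truth coordinates).
#' @export
class_templates <- function() {
  seqs <- list(
    cyanophage = paste0(
      "VNGCCWKYHQARLYTGSIVTNYTQRRASCKCDKSWITKNSCCQDGFNDIVENPP",
      "NDPPYNIVWSCIKQVVHEWHRFVIIHQVNFLCLAGFLVWFINHIQRLFQKFRFVMFKQWFRCEEHSKHMMWRTILFQMMHCFESQCCMLNLV",
      "PEKLTVAIDNKAEQ"),
    bacterial_class_A = paste0(
      "ETWDVSMWWHSAYAKHEVRYGEMSHLQDQNCGNCKMGHQFSDVTQQSVDSCAPP",
      "EIHECRMQWMWIKQVYISWHEVVVILQTNSLTLAGFRHQQINIIHRDQFTQWVVMFKQIFRCEEFSKHMMWRVIWMCCNHFFESQCYMYILV",
      "PERLSVDWSNKHEA"),
    class_B_plant = paste0(
      "WAAYVANLQHAIHILTNDTYQKQQLGVNINCGHKRGTEHIIHKVHIIKTRCEPP",
      "LKRRFLYFWKHIKQVSVFWHRHVCINQNNYLNVPGKYCLDINVICRMTYNCLFVMFKQFFRCEEDSKHMMWRWIFKDLNHMTESQCMMDDLH",
      "PDSIRIENWKHESA"),
    cyanobacterial = paste0(
      "QATWMAAEQMNIKWQHHLFCISWVASIFHKFAYRQKYSCRAVWDHEAHHLWVPP",
      "NDLFHICTWEDIKQVYMEWHLEVSILQKNHLWVPGKSEHKINQIWRTCDDTDMVMFKQFFRCEEKSKHMMWRMIMFKKVHKCESQCTMMRLQ",
      "PVEIAVALDWKHQS"))
  base_protect <- c(53L, 54L,           # double proline ending the arm
                    87L, 88L, 89L, 90L, # doublet and its context
                    117L,               # acidic partner in the L57 loop
                    126L)               # beta7 arginine
  sig_cols <- c(57:62, 72L)             # constrained signature positions
  cam_cols <- list(cyanophage = c(150L, 152L),
                   bacterial_class_A = c(150L, 152L),
                   class_B_plant = c(150L, 152L),
                   cyanobacterial = c(148L, 150L, 152L, 154L))
  lapply(stats::setNames(SHSP_CLASSES, SHSP_CLASSES), function(cl) {
    feats <- list(
      signature_start = if (cl == "cyanophage") 57L else NA_integer_,
      doublet_kind = if (cl %in% c("cyanophage", "bacterial_class_A"))
        "doublet_AG" else "doublet_PG",
      doublet_pos = 88L,
      cam_kind = switch(cl,
                        cyanophage = "cam_classical",
                        bacterial_class_A = "cam_classical",
                        class_B_plant = "none",
                        cyanobacterial = "cam_triple"),
      cam_positions = paste(cam_cols[[cl]], collapse = ","),
      beta7_pos = 126L, acidic_117_pos = 117L,
      acd_start = 55L, acd_end = 146L)
    protect <- sort(unique(c(base_protect, cam_cols[[cl]],
                             if (cl == "cyanophage") sig_cols)))
    list(sequence = seqs[[cl]], motif_columns = protect, features = feats)
  })
}

#' Build a simulation configuration
#'
#' @param n_per_class Named integer vector of taxa per class (names must be
#'   the four class names); default 50 each, the benchmark family size.
#' @param birth_rate Yule birth rate for the within-class subtrees
#'   (default 1).
#' @param mu Per-branch, per-site substitution probability in `[0, 1)`
#'   (default 0.05).
#' @param rho Motif-column protection factor in `[0, 1]`: motif columns
#'   substitute with probability `rho * mu` (default 0.1).
#' @param indel_rate Per-branch, per-site indel probability (default 0;
#'   when positive, planted-feature coordinates are no longer tracked).
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_per_class = c(cyanophage = 50L,
                                              bacterial_class_A = 50L,
                                              class_B_plant = 50L,
                                              cyanobacterial = 50L),
                              birth_rate = 1, mu = 0.05, rho = 0.1,
                              indel_rate = 0, seed = 1L) {
  stopifnot(all(SHSP_CLASSES %in% names(n_per_class)),
            all(n_per_class >= 1L),
            mu >= 0, mu < 1, rho >= 0, rho <= 1,
            indel_rate >= 0, indel_rate < 1, birth_rate > 0)
  if (sum(n_per_class) < 3L) stop("need at least 3 taxa in total")
  structure(list(n_per_class = n_per_class[SHSP_CLASSES],
                 birth_rate = birth_rate, mu = mu, rho = rho,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

class_subtree <- function(n, birth_rate, labels) {
  if (n == 1L) return(NULL)  # handled by caller as a bare tip
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:0.5,%s:0.5);",
                                        labels[1], labels[2]))
  } else {
    tr <- ape::rphylo(n, birth = birth_rate, death = 0)
    tr$tip.label <- labels
  }
  tr
}

#' Simulate the generating tree of a synthetic sHSP family
#'
#' Each class forms a Yule subtree; the four class subtrees hang off a
#' fixed backbone `((cyanophage, bacterial_class_A), (class_B_plant,
#' cyanobacterial))`, so every class is a planted clade.
#'
#' @param config A `simulation_config`.
#' @return A binary `phylo` tree (rooted; use the unrooted bipartition
#'   convention for clade tests) with tip labels `<class>_<i>`.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  subs <- lapply(SHSP_CLASSES, function(cl) {
    n <- config$n_per_class[[cl]]
    labels <- sprintf("%s_%02d", cl, seq_len(n))
    tr <- class_subtree(n, config$birth_rate, labels)
    if (is.null(tr)) labels else ape::write.tree(tr)
  })
  part <- vapply(subs, function(x) {
    if (length(x) == 1L && !grepl("\\(", x)) paste0(x, ":1")
    else paste0(sub(";$", "", x), ":1")
  }, character(1))
  nwk <- sprintf("((%s,%s):1,(%s,%s):1);",
                 part[1], part[2], part[3], part[4])
  ape::read.tree(text = nwk)
}

mutate_seq <- function(chars, mu, rho, motif_columns) {
  prob <- rep(mu, length(chars))
  prob[motif_columns] <- rho * mu
  hit <- which(stats::runif(length(chars)) < prob)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  chars
}

apply_indels <- function(chars, rate) {
  if (rate <= 0) return(chars)
  u <- stats::runif(length(chars))
  del <- u < rate / 2
  ins <- u >= rate / 2 & u < rate
  out <- character(0)
  for (i in seq_along(chars)) {
    if (!del[i]) out <- c(out, chars[i])
    if (ins[i]) out <- c(out, sample(AA20, 1L))
  }
  if (length(out) == 0L) chars else out
}

evolve_on_subtree <- function(tree, root_chars, mu, rho, motif_columns,
                              indel_rate) {
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- root_chars
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]
    child <- edges[k, 2]
    s <- mutate_seq(seqs[[parent]], mu, rho, motif_columns)
    seqs[[child]] <- apply_indels(s, indel_rate)
  }
  stats::setNames(vapply(seq_len(ntip),
                         function(i) paste(seqs[[i]], collapse = ""),
                         character(1)),
                  tree$tip.label)
}

#' Evolve class templates along a family tree
#'
#' The class template is placed at the root of its clade and evolved
#' towards the tips; each site substitutes with probability `mu` per
#' branch, motif columns with probability `rho * mu`. Substitutions
#' replace the residue by a uniformly drawn different residue.
#'
#' @param tree Tree from [simulate_tree()] (tips labelled
#'   `<class>_<i>`).
#' @param config The `simulation_config` used to build it.
#' @return List with `records` (record data frame, one per tip, in tip
#'   order class by class) and `truth` (data frame of class labels and
#'   planted-feature coordinates; coordinates are only meaningful when
#'   `indel_rate = 0`).
#' @export
evolve_family <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "simulation_config"))
  templates <- class_templates()
  set.seed(config$seed + 1L)
  all_seqs <- character(0)
  truth <- list()
  for (cl in SHSP_CLASSES) {
    tips <- grep(paste0("^", cl, "_"), tree$tip.label, value = TRUE)
    if (length(tips) == 0L) stop("tree has no tips for class ", cl)
    tpl <- templates[[cl]]
    chars <- strsplit(tpl$sequence, "")[[1]]
    if (length(tips) == 1L) {
      leaf <- stats::setNames(
        paste(apply_indels(
          mutate_seq(chars, config$mu, config$rho, tpl$motif_columns),
          config$indel_rate), collapse = ""), tips)
    } else {
      sub <- ape::keep.tip(tree, tips)
      leaf <- evolve_on_subtree(sub, chars, config$mu, config$rho,
                                tpl$motif_columns, config$indel_rate)
      leaf <- leaf[tips]
    }
    all_seqs <- c(all_seqs, leaf)
    truth[[cl]] <- data.frame(taxon = tips, class = cl,
                              as.data.frame(tpl$features,
                                            stringsAsFactors = FALSE),
                              stringsAsFactors = FALSE)
  }
  records <- seq_records(id = names(all_seqs), residues = unname(all_seqs),
                         description = sub("_[0-9]+$", "", names(all_seqs)))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}

#' Simulate a labelled synthetic sHSP family
#'
#' Runs [simulate_tree()] and [evolve_family()] under one configuration.
#'
#' @param config A `simulation_config`.
#' @return List with `records`, `truth` and `tree`.
#' @export
simulate_family <- function(config) {
  tree <- simulate_tree(config)
  fam <- evolve_family(tree, config)
  c(fam, list(tree = tree))
}
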